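# Read processing: raw FASTQ records -> deduplicated mapped chimeras.
#
# Every operation is vectorized over reads; the heavy steps (adapter
# location, contaminant screening, target mapping) use exact
# seed-and-verify strategies so that 10^5-read libraries process in
# seconds without approximating the stated matching rules.

#' Split off the unique molecular identifier
#'
#' @param seqs Character vector of raw read sequences.
#' @param umi_length UMI length (nt); the UMI is the read prefix.
#' @return A list with \code{umi} and \code{remainder} (both \code{NA}
#'   for reads shorter than \code{umi_length}, which are dropped with
#'   fate \code{"too_short"} by [process_reads()]).
#' @export
extract_umi <- function(seqs, umi_length = 10L) {
  umi_length <- as.integer(umi_length)
  if (umi_length < 0L) usage_error("umi_length must be >= 0")
  n <- nchar(seqs)
  ok <- n >= umi_length
  list(umi = ifelse(ok, substr(seqs, 1L, umi_length), NA_character_),
       remainder = ifelse(ok, substring(seqs, umi_length + 1L), NA_character_))
}

#' Trim a 3' adapter from read sequences
#'
#' Removes the longest read suffix that matches a prefix of the adapter
#' with at least \code{min_overlap} bases and a mismatch rate of at most
#' \code{max_mismatch_rate}; a full internal adapter occurrence truncates
#' the read at its start (any bases beyond the adapter are discarded).
#' Reads without a qualifying match are returned unchanged.
#'
#' Internal full-length occurrences at the rate-implied mismatch budget
#' m are located exactly by pigeonhole seeding: the adapter is split into
#' m + 1 pieces, every exact piece occurrence proposes an alignment, and
#' each proposal is verified against the full adapter (an occurrence with
#' at most m mismatches must contain at least one unmutated piece, so no
#' qualifying position can be missed).  Partial adapter prefixes hanging
#' off the read end are checked explicitly for every overlap length.
#' The result is exactly the leftmost qualifying position.
#'
#' @param seqs Character vector of read sequences (DNA).
#' @param adapter Adapter sequence (non-empty DNA string).
#' @param min_overlap Minimum suffix/prefix overlap considered.
#' @param max_mismatch_rate Maximum fraction of mismatched bases in the
#'   compared region.
#' @return Character vector of trimmed sequences.
#' @export
trim_adapter <- function(seqs, adapter, min_overlap = 3L, max_mismatch_rate = 0.1) {
  if (length(adapter) != 1L || nchar(adapter) == 0L)
    usage_error("adapter must be a single non-empty sequence")
  adapter <- as_dna(adapter)
  la <- nchar(adapter)
  n <- nchar(seqs)
  cut <- rep(NA_integer_, length(seqs))  # leftmost qualifying position

  ## internal (full-length) occurrences, allowing the rate-implied budget
  ad_chars <- strsplit(adapter, "")[[1]]
  mm_full <- floor(max_mismatch_rate * la)
  if (la >= min_overlap && length(seqs)) {
    npiece <- min(mm_full + 1L, la)
    bounds <- floor(seq(0L, la, length.out = npiece + 1L))
    cand_idx <- integer(0); cand_pos <- integer(0)
    for (pi in seq_len(npiece)) {
      p_from <- bounds[pi] + 1L
      piece <- substr(adapter, p_from, bounds[pi + 1L])
      g <- stringi::stri_locate_all_fixed(seqs, piece, omit_no_match = TRUE)
      nh <- vapply(g, nrow, integer(1))
      cand_idx <- c(cand_idx, rep(seq_along(seqs), nh))
      cand_pos <- c(cand_pos,
                    unlist(lapply(g, function(x) x[, 1L]), use.names = FALSE) - (p_from - 1L))
    }
    keep <- cand_pos >= 1L & cand_pos + la - 1L <= n[cand_idx]
    cand_idx <- cand_idx[keep]; cand_pos <- cand_pos[keep]
    if (length(cand_idx)) {
      mm <- integer(length(cand_idx))
      rd <- seqs[cand_idx]
      for (k in seq_len(la))
        mm <- mm + (substring(rd, cand_pos + k - 1L, cand_pos + k - 1L) != ad_chars[k])
      ok <- mm <= mm_full
      if (any(ok)) {
        first <- tapply(cand_pos[ok], cand_idx[ok], min)
        cut[as.integer(names(first))] <- as.integer(first)
      }
    }
  }

  ## adapter prefixes running off the read end (overlap < adapter length)
  o_max <- min(la - 1L, if (length(n)) max(n) else 0L)
  for (o in if (o_max >= min_overlap) seq(o_max, min_overlap) else integer(0)) {
    ## scanning long -> short overlaps keeps the smallest qualifying p
    p <- n - o + 1L
    feasible <- p >= 1L & (is.na(cut) | p < cut)
    if (!any(feasible)) next
    mm <- integer(length(seqs))
    for (k in seq_len(o)) {
      ck <- substring(seqs, p + k - 1L, p + k - 1L)
      mm <- mm + (ck != ad_chars[k])
    }
    qual <- feasible & mm <= floor(max_mismatch_rate * o)
    cut[qual] <- p[qual]
  }

  out <- seqs
  hit <- !is.na(cut)
  out[hit] <- substr(seqs[hit], 1L, cut[hit] - 1L)
  out
}

#' Screen reads against a contaminant catalog
#'
#' A read is flagged as contaminant if and only if it aligns end-to-end
#' within any catalog sequence with at most \code{max_mismatches}
#' substitutions (no indels).  Exact containment is tested directly;
#' mismatched containment uses non-overlapping k-mer seeds (pigeonhole:
#' a read with more seeds than allowed mismatches must share at least one
#' exact seed with its source), with full verification of every seed hit,
#' so the decision is exact.
#'
#' @param seqs Character vector of read payloads (after UMI and adapter
#'   removal).
#' @param contaminants Character vector of contaminant sequences (e.g.
#'   snoRNAs); may be empty, in which case everything is kept.
#' @param max_mismatches Maximum substitutions for a contaminant call.
#' @param k Seed length (nt) for the pigeonhole screen.
#' @return Logical vector: \code{TRUE} where the read is a contaminant.
#' @export
is_contaminant <- function(seqs, contaminants, max_mismatches = 1L, k = 12L) {
  if (length(contaminants) == 0L || length(seqs) == 0L)
    return(rep(FALSE, length(seqs)))
  contaminants <- as_dna(contaminants)
  useq <- unique(seqs)
  drop <- rep(FALSE, length(useq))

  for (cseq in contaminants) {
    drop <- drop | stringi::stri_detect_fixed(cseq, useq)
  }

  if (max_mismatches > 0L) {
    m1 <- max_mismatches + 1L
    len <- nchar(useq)
    maxcl <- max(nchar(contaminants))
    ## probe width adapts to the read so that m + 1 disjoint probes always
    ## fit; at least one of them must be error-free in a true containment
    pw <- pmin(as.integer(k), len %/% m1)
    seeded <- rep(FALSE, length(useq))
    brute <- !drop & pw < 6L & len <= maxcl  # too short to seed reliably
    for (w in unique(pw[!drop & pw >= 6L & len <= maxcl])) {
      sel <- which(!drop & pw == w & len <= maxcl)
      kmers <- unique(unlist(lapply(contaminants, function(cs) {
        if (nchar(cs) < w) character(0)
        else substring(cs, seq_len(nchar(cs) - w + 1L), seq(w, nchar(cs)))
      }), use.names = FALSE))
      for (pi in seq_len(m1)) {
        off <- (pi - 1L) * w + 1L
        probes <- substring(useq[sel], off, off + w - 1L)
        seeded[sel] <- seeded[sel] | probes %in% kmers
      }
    }
    cand <- which(!drop & (seeded | brute))
    if (length(cand)) {
      csubj <- lapply(contaminants, Biostrings::DNAString)
      for (i in cand) {
        for (cs in csubj) {
          if (nchar(useq[i]) > length(cs)) next
          m <- Biostrings::matchPattern(useq[i], cs, max.mismatch = max_mismatches,
                                        with.indels = FALSE)
          if (length(m) > 0L) { drop[i] <- TRUE; break }
        }
      }
    }
  }
  drop[match(seqs, useq)]
}

#' Call the miRNA segment at the 5' end of read payloads
#'
#' The chimeric-ligation chemistry puts the miRNA at the read 5' end
#' (after the UMI) and the ligated target fragment after it.  For each
#' payload this finds the catalog miRNA whose 5' prefix matches the
#' payload prefix with at most \code{max_mismatches} substitutions,
#' preferring the longest matched length and then the fewest mismatches.
#' The matched length is the full miRNA length (or the payload length if
#' the read ends inside the miRNA) and must reach
#' \code{min_mirna_match}; everything after the matched segment becomes
#' the target sequence.
#'
#' @param seqs Character vector of read payloads (DNA).
#' @param catalog miRNA catalog data.frame (columns \code{id},
#'   \code{sequence}).
#' @param max_mismatches Maximum substitutions in the miRNA segment.
#' @param min_mirna_match Minimum matched length (nt).
#' @return A data.frame with one row per payload: \code{status}
#'   (\code{"chimera"}, \code{"non_chimera"} or \code{"ambiguous"} for
#'   ties between catalog miRNAs at equal matched length and mismatch
#'   count), \code{mirna_id}, \code{mirna_matched_len},
#'   \code{mirna_mismatches}, \code{target_seq}.
#' @export
call_mirna_segment <- function(seqs, catalog, max_mismatches = 1L, min_mirna_match = 16L) {
  if (nrow(catalog) == 0L) usage_error("miRNA catalog is empty")
  nm <- nrow(catalog)
  mir_dna <- as_dna(catalog$sequence)
  lens <- nchar(mir_dna)
  n <- nchar(seqs)
  nr <- length(seqs)

  maxlen <- max(lens)
  chars <- lapply(seq_len(maxlen), function(kk) substring(seqs, kk, kk))

  score <- matrix(0L, nr, nm)  # 0 = invalid; otherwise higher is better
  mlen <- matrix(0L, nr, nm)
  mmm <- matrix(0L, nr, nm)
  for (j in seq_len(nm)) {
    mj <- strsplit(mir_dna[j], "")[[1]]
    Lj <- lens[j]
    mm <- integer(nr)
    for (kk in seq_len(Lj)) mm <- mm + (chars[[kk]] != mj[kk])
    ## positions beyond a short read compared as "" and counted above;
    ## remove them and clamp the matched length
    ml <- pmin(Lj, n)
    mm <- mm - (Lj - ml)
    valid <- mm <= max_mismatches & ml >= min_mirna_match
    score[, j] <- ifelse(valid, ml * 64L + (63L - mm), 0L)
    mlen[, j] <- ml
    mmm[, j] <- mm
  }

  best <- do.call(pmax, c(lapply(seq_len(nm), function(j) score[, j]), list(0L)))
  nbest <- rowSums(score == best & best > 0L)
  bj <- max.col(score, ties.method = "first")

  status <- ifelse(best == 0L, "non_chimera",
                   ifelse(nbest >= 2L, "ambiguous", "chimera"))
  idx <- cbind(seq_len(nr), bj)
  matched_len <- ifelse(status == "chimera", mlen[idx], NA_integer_)
  out <- data.frame(
    status = status,
    mirna_id = ifelse(status == "chimera", catalog$id[bj], NA_character_),
    mirna_matched_len = matched_len,
    mirna_mismatches = ifelse(status == "chimera", mmm[idx], NA_integer_),
    target_seq = ifelse(status == "chimera", substring(seqs, matched_len + 1L), NA_character_),
    stringsAsFactors = FALSE)
  ## a matched read with no tail is a plain miRNA read, not a chimera
  plain <- out$status == "chimera" & nchar(out$target_seq) == 0L
  out$status[plain] <- "non_chimera"
  out
}

#' Map target fragments to the transcriptome
#'
#' Ungapped, sense-strand search of each target sequence across all
#' transcripts (transcripts are given 5' to 3'; AGO-bound targets are
#' sense transcripts, so the reverse complement is not searched).  A
#' unique best hit (fewest mismatches) is required; ties are dropped as
#' multimapped.  Hits overlapping an optional repeat-exclusion catalog
#' are dropped.
#'
#' @param target_seqs Character vector of target fragments.
#' @param sequences Named character vector of transcript sequences.
#' @param max_mismatches Maximum substitutions for a hit.
#' @param min_len Minimum fragment length; shorter fragments get status
#'   \code{"too_short"}.
#' @param repeat_catalog Optional data.frame
#'   (\code{transcript_id, start, end}, 0-based half-open) of intervals
#'   to exclude; overlapping hits get status \code{"repeat"}.
#' @return A data.frame with one row per input: \code{status}
#'   (\code{mapped}, \code{unmapped}, \code{multimapped},
#'   \code{too_short}, \code{repeat}), \code{transcript_id},
#'   \code{start}, \code{end} (0-based half-open),
#'   \code{mapping_mismatches}.
#' @export
map_target <- function(target_seqs, sequences, max_mismatches = 2L, min_len = 15L,
                       repeat_catalog = NULL) {
  useq <- unique(target_seqs)
  subj <- Biostrings::DNAStringSet(unname(sequences))
  txids <- names(sequences)
  nu <- length(useq)
  nl <- nchar(useq)

  status <- rep("unmapped", nu)
  r_tx <- rep(NA_character_, nu); r_start <- rep(NA_integer_, nu)
  r_mm <- rep(NA_integer_, nu)
  status[nl < min_len] <- "too_short"

  ## exact stage: constant-width prefix index over all fragments at once,
  ## followed by vectorized full-length verification (exact, since an
  ## ungapped exact occurrence implies an exact prefix occurrence)
  cand <- which(nl >= min_len & !grepl("[^ACGT]", useq))
  if (length(cand)) {
    w <- min(nl[cand])
    pd <- Biostrings::PDict(substr(useq[cand], 1L, w))
    nhit <- integer(length(cand))
    for (ti in seq_along(sequences)) {
      m <- Biostrings::matchPDict(pd, Biostrings::DNAString(sequences[[ti]]))
      si <- Biostrings::startIndex(m)
      cnt <- lengths(si)
      if (!sum(cnt)) next
      pidx <- rep(seq_along(cand), cnt)
      pos <- unlist(si[cnt > 0L], use.names = FALSE)
      full <- substring(sequences[[ti]], pos, pos + nl[cand][pidx] - 1L)
      okv <- full == useq[cand][pidx]
      if (!any(okv)) next
      pidx <- pidx[okv]; pos <- pos[okv]
      newhits <- tabulate(pidx, nbins = length(cand))
      firstpos <- pidx[!duplicated(pidx)]
      takes <- nhit[firstpos] == 0L
      if (any(takes)) {
        gi <- cand[firstpos[takes]]
        r_tx[gi] <- txids[ti]
        r_start[gi] <- pos[!duplicated(pidx)][takes] - 1L
        r_mm[gi] <- 0L
      }
      nhit <- nhit + newhits
    }
    status[cand[nhit == 1L]] <- "mapped"
    multi <- nhit > 1L
    status[cand[multi]] <- "multimapped"
    r_tx[cand[multi]] <- NA_character_; r_start[cand[multi]] <- NA_integer_
    r_mm[cand[multi]] <- NA_integer_
  }

  ## mismatch stage for the (few) fragments without an exact hit
  for (ui in which(status == "unmapped")) {
    for (mm in seq_len(max_mismatches)) {
      hits <- Biostrings::vmatchPattern(useq[ui], subj, max.mismatch = mm, fixed = TRUE)
      cnt <- S4Vectors::elementNROWS(hits)
      tot <- sum(cnt)
      if (tot == 0L) next
      if (tot > 1L) { status[ui] <- "multimapped"; break }
      ti <- which(cnt == 1L)
      status[ui] <- "mapped"
      r_tx[ui] <- txids[ti]
      r_start[ui] <- IRanges::start(hits[[ti]])[1] - 1L
      r_mm[ui] <- mm
      break
    }
  }

  pick <- match(target_seqs, useq)
  out <- data.frame(status = status[pick], transcript_id = r_tx[pick],
                    start = r_start[pick], mapping_mismatches = r_mm[pick],
                    stringsAsFactors = FALSE)
  out$end <- out$start + nchar(target_seqs)

  if (!is.null(repeat_catalog) && nrow(repeat_catalog)) {
    hit <- !is.na(out$transcript_id)
    if (any(hit)) {
      q <- GenomicRanges::GRanges(out$transcript_id[hit],
                                  IRanges::IRanges(out$start[hit] + 1L, out$end[hit]))
      r <- GenomicRanges::GRanges(repeat_catalog$transcript_id,
                                  IRanges::IRanges(repeat_catalog$start + 1L,
                                                   repeat_catalog$end))
      ov <- IRanges::overlapsAny(q, r)
      out$status[hit][ov] <- "repeat"
      out$transcript_id[hit][ov] <- NA_character_
      out$start[hit][ov] <- NA_integer_
      out$end[hit][ov] <- NA_integer_
      out$mapping_mismatches[hit][ov] <- NA_integer_
    }
  }
  out
}

#' Collapse PCR duplicates by UMI
#'
#' Keeps one representative per (UMI, miRNA, transcript, target start)
#' key: the lexicographically smallest read id.  Output rows are sorted
#' by key, so the result is deterministic regardless of input order.
#'
#' @param mapped Data.frame of mapped chimeras (columns \code{read_id},
#'   \code{umi}, \code{mirna_id}, \code{transcript_id}, \code{start},
#'   ...).
#' @return The deduplicated subset of \code{mapped}.
#' @export
dedup_chimeras <- function(mapped) {
  if (nrow(mapped) == 0L) return(mapped)
  dt <- data.table::as.data.table(mapped)
  data.table::setorderv(dt, c("umi", "mirna_id", "transcript_id", "start", "read_id"))
  out <- unique(dt, by = c("umi", "mirna_id", "transcript_id", "start"))
  data.table::setcolorder(out, names(mapped))
  as.data.frame(out)
}

#' Read-processing thresholds
#'
#' @param umi_length UMI prefix length (nt).
#' @param adapter 3' adapter sequence.
#' @param adapter_min_overlap,adapter_max_mismatch_rate Adapter-trimming
#'   rule (see [trim_adapter()]).
#' @param contaminant_max_mismatches Mismatch budget for the contaminant
#'   screen.
#' @param mirna_max_mismatches,min_mirna_match miRNA segment calling
#'   thresholds.
#' @param target_max_mismatches,min_target_len Target mapping thresholds.
#' @param contaminant_regex Transcripts whose gene id matches this
#'   pattern form the contaminant catalog (and are excluded from the
#'   mapping index), mirroring snoRNA removal before alignment.
#' @return A list of class \code{process_config}.
#' @export
process_config <- function(umi_length = 10L, adapter = "AGATCGGAAGAGC",
                           adapter_min_overlap = 3L, adapter_max_mismatch_rate = 0.1,
                           contaminant_max_mismatches = 1L,
                           mirna_max_mismatches = 1L, min_mirna_match = 16L,
                           target_max_mismatches = 2L, min_target_len = 15L,
                           contaminant_regex = "^Snord") {
  structure(list(umi_length = as.integer(umi_length), adapter = toupper(adapter),
                 adapter_min_overlap = as.integer(adapter_min_overlap),
                 adapter_max_mismatch_rate = adapter_max_mismatch_rate,
                 contaminant_max_mismatches = as.integer(contaminant_max_mismatches),
                 mirna_max_mismatches = as.integer(mirna_max_mismatches),
                 min_mirna_match = as.integer(min_mirna_match),
                 target_max_mismatches = as.integer(target_max_mismatches),
                 min_target_len = as.integer(min_target_len),
                 contaminant_regex = contaminant_regex),
            class = "process_config")
}

#' Process raw reads into deduplicated mapped chimeras
#'
#' Runs the full read-processing cascade: UMI extraction, adapter
#' trimming, contaminant removal, miRNA segment calling, ungapped target
#' mapping and UMI deduplication.  Every read receives exactly one fate
#' (\code{chimera}, \code{non_chimera}, \code{contaminant},
#' \code{ambiguous}, \code{too_short}, \code{unmapped},
#' \code{multimapped}, \code{dedup_removed}, and \code{repeat} when a
#' repeat catalog is supplied), and the fate counts sum to the input
#' read count.
#'
#' @param reads Data.frame with \code{read_id} and \code{sequence}.
#' @param catalog miRNA catalog.
#' @param transcriptome A \code{transcriptome} object.
#' @param config A [process_config()].
#' @param repeat_catalog Optional repeat-exclusion intervals (see
#'   [map_target()]).
#' @return A list: \code{chimeras} (deduplicated mapped chimeras),
#'   \code{mapped} (before deduplication), \code{fates} (per-read fate),
#'   \code{fate_summary} (fate counts, including \code{n_input}).
#' @export
process_reads <- function(reads, catalog, transcriptome, config = process_config(),
                          repeat_catalog = NULL) {
  n <- nrow(reads)
  fate <- rep(NA_character_, n)
  empty_chim <- data.frame(read_id = character(), umi = character(),
                           mirna_id = character(), mirna_matched_len = integer(),
                           mirna_mismatches = integer(), transcript_id = character(),
                           start = integer(), end = integer(),
                           mapping_mismatches = integer(), target_seq = character(),
                           stringsAsFactors = FALSE)
  finish <- function(chim, mapped) {
    fl <- factor(fate, levels = c("chimera", "non_chimera", "contaminant", "ambiguous",
                                  "too_short", "unmapped", "multimapped",
                                  "dedup_removed", "repeat"))
    summ <- as.data.frame(table(fate = fl), stringsAsFactors = FALSE)
    names(summ)[2] <- "n"
    summ <- rbind(summ, data.frame(fate = "n_input", n = n))
    list(chimeras = chim, mapped = mapped,
         fates = data.frame(read_id = reads$read_id, fate = fate,
                            stringsAsFactors = FALSE),
         fate_summary = summ)
  }
  if (n == 0L) return(finish(empty_chim, empty_chim))

  ex <- extract_umi(reads$sequence, config$umi_length)
  fate[is.na(ex$umi)] <- "too_short"
  live <- which(is.na(fate))

  payload <- trim_adapter(ex$remainder[live], config$adapter,
                          config$adapter_min_overlap, config$adapter_max_mismatch_rate)

  contam_tx <- grepl(config$contaminant_regex, transcriptome$transcripts$gene_id)
  contam_seqs <- transcriptome$sequences[transcriptome$transcripts$transcript_id[contam_tx]]
  subj_seqs <- transcriptome$sequences[transcriptome$transcripts$transcript_id[!contam_tx]]

  isc <- is_contaminant(payload, unname(contam_seqs), config$contaminant_max_mismatches)
  fate[live[isc]] <- "contaminant"
  live <- live[!isc]; payload <- payload[!isc]

  call <- call_mirna_segment(payload, catalog, config$mirna_max_mismatches,
                             config$min_mirna_match)
  fate[live[call$status == "non_chimera"]] <- "non_chimera"
  fate[live[call$status == "ambiguous"]] <- "ambiguous"
  keep <- call$status == "chimera"
  live <- live[keep]; call <- call[keep, , drop = FALSE]

  mp <- map_target(call$target_seq, subj_seqs, config$target_max_mismatches,
                   config$min_target_len, repeat_catalog)
  for (s in c("too_short", "unmapped", "multimapped", "repeat"))
    fate[live[mp$status == s]] <- s
  ok <- mp$status == "mapped"
  live <- live[ok]

  mapped <- data.frame(read_id = reads$read_id[live], umi = ex$umi[live],
                       mirna_id = call$mirna_id[ok],
                       mirna_matched_len = call$mirna_matched_len[ok],
                       mirna_mismatches = call$mirna_mismatches[ok],
                       transcript_id = mp$transcript_id[ok],
                       start = mp$start[ok], end = mp$end[ok],
                       mapping_mismatches = mp$mapping_mismatches[ok],
                       target_seq = call$target_seq[ok], stringsAsFactors = FALSE)
  chim <- dedup_chimeras(mapped)
  fate[live] <- "dedup_removed"
  fate[match(chim$read_id, reads$read_id)] <- "chimera"
  finish(chim, mapped)
}
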