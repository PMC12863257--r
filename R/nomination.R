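# Trigger nomination: candidate evaluation, criterion flags, ranking.

#' Filtering and ranking configuration
#'
#' The stringent criterion set applied to every (miRNA, seed-site)
#' candidate:
#' \itemize{
#'   \item C1 — canonical seed match (6mer, 7mer-A1, 7mer-m8 or 8mer;
#'     perfect Watson-Crick seed pairing is guaranteed by the
#'     classifier).
#'   \item C2 — site in a noncoding RNA or a noncoding region of an
#'     mRNA (5'UTR or 3'UTR), since translating ribosomes suppress TDMD
#'     at ORF-located sites.
#'   \item C3 — no large central bulge: at most
#'     \code{max_central_unpaired_run} (7) consecutive unpaired miRNA
#'     positions after the seed.
#'   \item C4 — at least \code{min_three_prime_run} (6) consecutive base
#'     pairs to the miRNA 3' region (its final
#'     \code{three_prime_region_len} = 13 nt).
#'   \item C5 — positive mean conservation over both the seed-binding
#'     bases and the 3'-paired bases.
#' }
#' Survivors are ranked per miRNA by the 3' MFE (most negative first)
#' and the top \code{top_k} are flagged as selected.
#'
#' @param allowed_seed_classes,allowed_regions Allowed values for C1/C2.
#' @param max_central_unpaired_run C3 threshold (nt).
#' @param min_three_prime_run C4 threshold (bp).
#' @param three_prime_region_len Length (nt) of the miRNA 3' region.
#' @param flank_len Target flank (nt) taken 5' of the seed window for
#'   duplex prediction.
#' @param top_k Number of top-ranked candidates selected per miRNA.
#' @return A list of class \code{filter_config}.
#' @export
filter_config <- function(allowed_seed_classes = c("8mer", "7mer-m8", "7mer-A1", "6mer"),
                          allowed_regions = c("5UTR", "3UTR", "ncRNA_exon"),
                          max_central_unpaired_run = 7L,
                          min_three_prime_run = 6L,
                          three_prime_region_len = 13L,
                          flank_len = 20L,
                          top_k = 3L) {
  if (!length(allowed_seed_classes) || !length(allowed_regions))
    usage_error("filter_config: allowed sets must be non-empty")
  if (max_central_unpaired_run < 0L || min_three_prime_run <= 0L ||
      three_prime_region_len <= 0L || flank_len <= 0L || top_k <= 0L)
    usage_error("filter_config: thresholds must be positive")
  structure(list(allowed_seed_classes = allowed_seed_classes,
                 allowed_regions = allowed_regions,
                 max_central_unpaired_run = as.integer(max_central_unpaired_run),
                 min_three_prime_run = as.integer(min_three_prime_run),
                 three_prime_region_len = as.integer(three_prime_region_len),
                 flank_len = as.integer(flank_len),
                 top_k = as.integer(top_k)),
            class = "filter_config")
}

#' Evaluate one (miRNA, seed-site) candidate against all criteria
#'
#' Computes the seed class, region flag, duplex architecture statistics
#' (central unpaired run over miRNA positions 9..L and longest pair run
#' within the 3' region, both from the minimum-free-energy alignment of
#' miRNA positions 9..L against the flank), conservation means over the
#' seed-binding window and the 3'-paired target bases, and the 3' MFE
#' ranking metric.
#'
#' @param mirna_id,mirna_seq Identity and sequence of the miRNA.
#' @param transcript_id,gene_id,transcript_seq Host transcript.
#' @param conservation Per-base conservation vector for the transcript,
#'   or \code{NULL} if unavailable (C5 then evaluates false, with a
#'   warning).
#' @param region_label Region of the hosting cluster.
#' @param seed_window_start0 0-based start of the 8-nt seed window.
#' @param chimera_support Deduplicated chimera count supporting the
#'   site.
#' @param config A [filter_config()].
#' @param params Energy parameters.
#' @return A one-row data.frame in candidate-table layout (see
#'   [write_candidate_table()]), with criterion flags \code{C1..C5} and
#'   \code{rank}/\code{selected} unset.
#' @export
evaluate_candidate <- function(mirna_id, mirna_seq, transcript_id, gene_id,
                               transcript_seq, conservation, region_label,
                               seed_window_start0, chimera_support,
                               config = filter_config(),
                               params = default_energy_params()) {
  L <- nchar(mirna_seq)
  ws <- as.integer(seed_window_start0)
  window <- subseq0(transcript_seq, ws, ws + 8L)
  seed_class <- classify_seed(mirna_seq, window)

  flank0 <- max(0L, ws - config$flank_len)
  flank <- subseq0(transcript_seq, flank0, ws)
  aln9 <- if (nchar(flank) > 0L) {
    predict_duplex(substring(as_rna(mirna_seq), 9L, L), flank, params, mirna_start = 9L)
  } else {
    structure(list(mirna_seq = substring(as_rna(mirna_seq), 9L, L), target_seq = "",
                   mirna_start = 9L, pair_state = rep("unpaired", L - 8L),
                   target_partner = rep(NA_integer_, L - 8L),
                   energy = NA_real_, status = "no_duplex"),
              class = "duplex_alignment")
  }
  central <- max_unpaired_run_after_seed(aln9)
  run3p <- max_pair_run(aln9, region = c(L - config$three_prime_region_len + 1L, L))
  mfe <- three_prime_mfe(mirna_seq, transcript_seq, ws,
                         flank_len = config$flank_len,
                         region_len = config$three_prime_region_len,
                         params = params)$energy

  cons_ok <- !is.null(conservation) && length(conservation) >= ws + 8L
  if (!cons_ok)
    warning(sprintf("no conservation for transcript %s; conservation criterion fails",
                    transcript_id), call. = FALSE)
  seed_cons <- if (cons_ok) mean(conservation[(ws + 1L):(ws + 8L)]) else NA_real_
  paired_t <- aln9$target_partner[!is.na(aln9$target_partner)]
  cons3_pos <- flank0 + paired_t  # 1-based transcript positions of 3'-paired bases
  three_cons <- if (cons_ok && length(cons3_pos)) mean(conservation[cons3_pos]) else NA_real_

  data.frame(
    mirna = mirna_id, gene = gene_id, transcript = transcript_id,
    site_start = flank0, site_end = ws + 8L,
    region = region_label, seed_class = seed_class,
    central_unpaired_run = central, three_prime_run = run3p,
    seed_cons_mean = round(seed_cons, 4),
    three_prime_cons_mean = round(three_cons, 4),
    three_prime_mfe_kcal_mol = round(mfe, 2),
    chimera_support = as.integer(chimera_support),
    C1 = seed_class %in% config$allowed_seed_classes,
    C2 = region_label %in% config$allowed_regions,
    C3 = central <= config$max_central_unpaired_run,
    C4 = run3p >= config$min_three_prime_run,
    C5 = cons_ok && !is.na(seed_cons) && !is.na(three_cons) &&
      seed_cons > 0 && three_cons > 0,
    rank = NA_integer_, selected = FALSE,
    stringsAsFactors = FALSE)
}

#' Enumerate and evaluate all candidates from clustered chimeras
#'
#' One candidate is emitted per (miRNA, seed hit): for every cluster and
#' every miRNA supporting it, the extended cluster window is scanned for
#' canonical seed sites and each hit is evaluated with
#' [evaluate_candidate()].
#'
#' @param clusters Annotated \code{site_clusters} (see
#'   [annotate_regions()]).
#' @param catalog miRNA catalog.
#' @param transcriptome A \code{transcriptome} object.
#' @param config A [filter_config()].
#' @param params Energy parameters.
#' @return A candidate data.frame (possibly 0 rows).
#' @export
find_candidates <- function(clusters, catalog, transcriptome,
                            config = filter_config(),
                            params = default_energy_params()) {
  cl <- clusters$clusters
  if (is.null(cl$region_label))
    usage_error("clusters must be annotated with annotate_regions() first")
  supp <- clusters$support
  rows <- list()
  for (i in seq_len(nrow(supp))) {
    ci <- match(supp$cluster_id[i], cl$cluster_id)
    tx <- cl$transcript_id[ci]
    mirna <- supp$mirna_id[i]
    mseq <- catalog$sequence[match(mirna, catalog$id)]
    txseq <- transcriptome$sequences[[tx]]
    win_lo <- cl$ext_start[ci]
    hits <- locate_seed_sites(mseq, subseq0(txseq, win_lo, cl$ext_end[ci]),
                              offset0 = win_lo)
    if (nrow(hits) == 0L) next
    gene <- transcriptome$transcripts$gene_id[
      match(tx, transcriptome$transcripts$transcript_id)]
    cons <- transcriptome$conservation[[tx]]
    for (h in seq_len(nrow(hits))) {
      rows[[length(rows) + 1L]] <- evaluate_candidate(
        mirna, mseq, tx, gene, txseq, cons, cl$region_label[ci],
        hits$window_start[h], supp$n[i], config, params)
    }
  }
  if (!length(rows)) {
    return(evaluate_candidate_empty())
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

evaluate_candidate_empty <- function() {
  data.frame(mirna = character(), gene = character(), transcript = character(),
             site_start = integer(), site_end = integer(), region = character(),
             seed_class = character(), central_unpaired_run = integer(),
             three_prime_run = integer(), seed_cons_mean = numeric(),
             three_prime_cons_mean = numeric(), three_prime_mfe_kcal_mol = numeric(),
             chimera_support = integer(), C1 = logical(), C2 = logical(),
             C3 = logical(), C4 = logical(), C5 = logical(), rank = integer(),
             selected = logical(), stringsAsFactors = FALSE)
}

#' Rank filtered candidates by 3' MFE
#'
#' Survivors (all of C1..C5 true) are sorted within each miRNA by 3' MFE
#' ascending (most negative, i.e. most stable, first), with ties broken
#' by higher chimera support and then lexicographically by (transcript,
#' site start).  Ranks are assigned 1..n per miRNA and the top
#' \code{top_k} rows are flagged selected.  Non-survivors keep
#' \code{rank = NA} and \code{selected = FALSE}.
#'
#' @param candidates Candidate data.frame from [find_candidates()].
#' @param config A [filter_config()].
#' @return The candidate table with \code{rank} and \code{selected}
#'   filled in, survivors first in rank order.
#' @export
nominate <- function(candidates, config = filter_config()) {
  if (nrow(candidates) == 0L) return(candidates)
  surv <- candidates$C1 & candidates$C2 & candidates$C3 & candidates$C4 & candidates$C5
  candidates$rank <- NA_integer_
  candidates$selected <- FALSE
  s <- candidates[surv, , drop = FALSE]
  if (nrow(s)) {
    ord <- order(s$mirna, s$three_prime_mfe_kcal_mol, -s$chimera_support,
                 s$transcript, s$site_start)
    s <- s[ord, , drop = FALSE]
    s$rank <- stats::ave(seq_len(nrow(s)), s$mirna, FUN = seq_along)
    s$selected <- s$rank <= config$top_k
  }
  out <- rbind(s, candidates[!surv, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Write / read the candidate table
#'
#' Tab-separated, one row per candidate, stable ordering; energies are
#' serialized with two decimal places.  The written file round-trips
#' losslessly through [read_candidate_table()].
#'
#' @param candidates Candidate table from [nominate()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_candidate_table <- function(candidates, path) {
  out <- candidates
  out$three_prime_mfe_kcal_mol <- sprintf("%.2f", out$three_prime_mfe_kcal_mol)
  ok <- tryCatch({ write_tsv(out, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) data_error(sprintf("cannot write candidate table to %s", path))
  invisible(path)
}

#' @rdname write_candidate_table
#' @export
read_candidate_table <- function(path) {
  if (!file.exists(path)) data_error(sprintf("candidate table not found: %s", path))
  df <- read_tsv(path)
  if (nrow(df) == 0L) return(evaluate_candidate_empty())
  df$three_prime_mfe_kcal_mol <- as.numeric(df$three_prime_mfe_kcal_mol)
  df$rank <- as.integer(df$rank)
  df
}

#' Compare nominated candidates with the simulation truth
#'
#' For every true trigger in the truth manifest: was a matching
#' candidate produced, and at what rank?  For every decoy: which
#' criterion rejected it (a decoy whose designed seed never matches
#' produces no candidate at all and is reported as rejected at C1, the
#' seed criterion).  A candidate matches a truth site when it names the
#' same miRNA and transcript and its seed window lies inside the
#' realized site interval.
#'
#' @param candidates Candidate table from [nominate()].
#' @param truth Truth manifest from [build_transcriptome()].
#' @return A list: \code{sites} (per truth site: \code{recovered},
#'   \code{rank}, \code{selected}, \code{rejected_at}),
#'   \code{top1_recovery} (fraction of true triggers ranked 1),
#'   \code{n_true}.
#' @export
evaluate_recovery <- function(candidates, truth) {
  crit <- c("C1", "C2", "C3", "C4", "C5")
  res <- truth[, c("mirna_id", "transcript_id", "start", "end", "is_true_trigger")]
  res$recovered <- FALSE
  res$rank <- NA_integer_
  res$selected <- FALSE
  res$rejected_at <- NA_character_
  for (i in seq_len(nrow(truth))) {
    ws_cand <- candidates$site_end - 8L
    m <- candidates$mirna == truth$mirna_id[i] &
      candidates$transcript == truth$transcript_id[i] &
      ws_cand >= truth$start[i] & ws_cand + 8L <= truth$end[i]
    if (!any(m)) {
      res$rejected_at[i] <- "C1"  # no qualifying seed match in the site
      next
    }
    sub <- candidates[m, , drop = FALSE]
    res$recovered[i] <- TRUE
    if (any(!is.na(sub$rank))) {
      res$rank[i] <- min(sub$rank, na.rm = TRUE)
      res$selected[i] <- any(sub$selected)
    } else {
      ## best candidate = fewest failed criteria; report its first failure
      nfail <- rowSums(!as.matrix(sub[, crit]))
      best <- sub[which.min(nfail), , drop = FALSE]
      res$rejected_at[i] <- crit[which(!unlist(best[, crit]))[1]]
    }
  }
  n_true <- sum(res$is_true_trigger)
  top1 <- if (n_true) {
    sum(res$is_true_trigger & !is.na(res$rank) & res$rank == 1L) / n_true
  } else NA_real_
  list(sites = res, top1_recovery = top1, n_true = n_true)
}
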