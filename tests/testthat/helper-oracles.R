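# Independent reference implementations used as oracles.  These are
# deliberately naive (enumeration / per-position scans) and share no code
# with the package internals they check.

rand_rna <- function(len) paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
                                collapse = "")
rand_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                                collapse = "")

## Minimum duplex free energy by exhaustive enumeration of every
## non-crossing antiparallel pairing (at least one stack required),
## under the same energy model as the parameter file.
brute_duplex_energy <- function(mir, tgt, p) {
  M <- strsplit(chartr("T", "U", toupper(mir)), "")[[1]]
  R <- rev(strsplit(chartr("T", "U", toupper(tgt)), "")[[1]])
  m <- length(M); n <- length(R)
  ok <- function(a, b) paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  term <- function(a, b) if (paste0(a, b) %in% c("AU", "UA", "GU", "UG")) p$terminal_au else 0
  best <- Inf
  rec <- function(i, lastj, lasti, energy, has_stack) {
    if (!is.na(lasti) && has_stack) {
      e <- energy + term(M[lasti], R[lastj])
      if (e < best) best <<- e
    }
    if (i > m) return()
    rec(i + 1L, lastj, lasti, energy, has_stack)
    jstart <- if (is.na(lastj)) 1L else lastj + 1L
    if (jstart <= n) for (j in jstart:n) {
      if (!ok(M[i], R[j])) next
      if (is.na(lasti)) {
        rec(i + 1L, j, i, p$init + term(M[i], R[j]), FALSE)
      } else {
        gi <- i - lasti - 1L; gj <- j - lastj - 1L
        if (gi == 0L && gj == 0L) {
          st <- p$stack[[paste0(M[lasti], M[i], "|", R[lastj], R[j])]]
          rec(i + 1L, j, i, energy + st, TRUE)
        } else {
          tab <- if (gi == 0L || gj == 0L) p$bulge else p$internal
          lp <- tab[min(gi + gj, length(tab))]
          if (!is.na(lp)) rec(i + 1L, j, i, energy + lp, has_stack)
        }
      }
    }
  }
  rec(1L, NA_integer_, NA_integer_, 0, FALSE)
  best
}

## Scalar reference for adapter trimming: scan every position, apply the
## rule literally.
trim_adapter_ref <- function(seq, adapter, min_overlap = 3L, max_mismatch_rate = 0.1) {
  n <- nchar(seq); la <- nchar(adapter)
  sc <- strsplit(seq, "")[[1]]; ac <- strsplit(adapter, "")[[1]]
  for (p in seq_len(n)) {
    cmplen <- min(n - p + 1L, la)
    if (cmplen < min_overlap) next
    mm <- sum(sc[p:(p + cmplen - 1L)] != ac[seq_len(cmplen)])
    if (mm <= floor(max_mismatch_rate * cmplen)) return(substr(seq, 1L, p - 1L))
  }
  seq
}

## Brute-force contaminant containment check.
is_contaminant_ref <- function(seq, contaminants, max_mismatches = 1L) {
  sc <- strsplit(seq, "")[[1]]
  n <- length(sc)
  for (cs in contaminants) {
    cc <- strsplit(cs, "")[[1]]
    if (n > length(cc)) next
    for (p in seq_len(length(cc) - n + 1L)) {
      if (sum(sc != cc[p:(p + n - 1L)]) <= max_mismatches) return(TRUE)
    }
  }
  FALSE
}

## Hand-built duplex_alignment for run-statistic tests.
make_alignment <- function(pair_state, target_partner, mirna_start = 9L) {
  structure(list(mirna_seq = strrep("A", length(pair_state)), target_seq = "",
                 mirna_start = as.integer(mirna_start),
                 pair_state = pair_state,
                 target_partner = as.integer(target_partner),
                 energy = NA_real_, status = "ok"),
            class = "duplex_alignment")
}

## A small deterministic transcriptome for unit tests.
toy_transcriptome <- function(seqs, segments = NULL, genes = NULL) {
  ids <- names(seqs)
  if (is.null(segments)) {
    segments <- do.call(rbind, lapply(ids, function(id) {
      data.frame(transcript_id = id, segment_label = "ncRNA_exon",
                 start = 0L, end = nchar(seqs[[id]]), stringsAsFactors = FALSE)
    }))
  }
  structure(list(
    transcripts = data.frame(transcript_id = ids,
                             gene_id = genes %||% paste0("G_", ids),
                             biotype = "noncoding",
                             length = unname(nchar(seqs)), stringsAsFactors = FALSE),
    segments = segments,
    sequences = seqs,
    conservation = lapply(seqs, function(s) rep(1, nchar(s)))),
    class = "transcriptome")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
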