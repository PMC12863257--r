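#' Predict the minimum-free-energy miRNA:target duplex
#'
#' Computes the optimal antiparallel intermolecular alignment between a
#' miRNA (sub)sequence and a target sequence under a nearest-neighbor
#' energy model: Watson-Crick and G:U pairs, dinucleotide stacks, bulges
#' and internal loops scored by length, a duplex-initiation term, and a
#' terminal penalty at each duplex end closed by A:U or G:U.  No
#' intramolecular structure and no pseudoknots are considered; pairing is
#' non-crossing, with target partner coordinates strictly decreasing as
#' the miRNA coordinate increases.
#'
#' A duplex is only reported if it contains at least one stack (two
#' adjacent miRNA positions paired to two adjacent target positions);
#' otherwise the result has status \code{"no_duplex"} and \code{NA} energy.
#'
#' The dynamic program tracks, for every candidate last pair, the best
#' partial energy with and without a stack so far, which makes the
#' at-least-one-stack requirement exact rather than a post-hoc filter.
#'
#' @param mirna_subseq miRNA-side sequence, 5' to 3' (RNA or DNA letters).
#' @param target_seq Target-side sequence, 5' to 3'.
#' @param params Energy parameters from [load_energy_params()].
#' @param mirna_start Coordinate (1-based, along the full miRNA) of the
#'   first base of \code{mirna_subseq}; carried into the alignment so that
#'   run statistics can be queried in full-miRNA coordinates.
#' @return An object of class \code{duplex_alignment}: a list with
#'   \code{mirna_seq}, \code{target_seq}, \code{mirna_start},
#'   \code{pair_state} (per miRNA position: \code{"WC"}, \code{"GU"} or
#'   \code{"unpaired"}), \code{target_partner} (1-based position in
#'   \code{target_seq}, \code{NA} when unpaired; strictly decreasing over
#'   paired positions), \code{energy} (kcal/mol, \code{NA} if no duplex)
#'   and \code{status} (\code{"ok"} or \code{"no_duplex"}).
#' @export
#' @examples
#' p <- load_energy_params()
#' predict_duplex("GGG", "CCC", p)$energy  # 4.09 + 2 * (-3.26) = -2.43
predict_duplex <- function(mirna_subseq, target_seq, params = default_energy_params(),
                           mirna_start = 1L) {
  if (length(mirna_subseq) != 1L || length(target_seq) != 1L)
    usage_error("predict_duplex expects single sequences")
  if (nchar(mirna_subseq) == 0L || nchar(target_seq) == 0L)
    usage_error("sequences must be non-empty")
  check_alphabet(mirna_subseq, "miRNA")
  check_alphabet(target_seq, "target")

  M <- strsplit(as_rna(mirna_subseq), "")[[1]]
  Torig <- strsplit(as_rna(target_seq), "")[[1]]
  R <- rev(Torig)  # reversed target: antiparallel pairing becomes co-linear
  m <- length(M); n <- length(R)

  no_duplex <- function() {
    structure(list(mirna_seq = as_rna(mirna_subseq), target_seq = as_rna(target_seq),
                   mirna_start = as.integer(mirna_start),
                   pair_state = rep("unpaired", m),
                   target_partner = rep(NA_integer_, m),
                   energy = NA_real_, status = "no_duplex"),
              class = "duplex_alignment")
  }

  P <- outer(M, R, function(a, b) !is.na(PAIR_TYPE[cbind(a, b)]))
  if (!any(P)) return(no_duplex())

  ## loop-cost lookup: LC[gi + 1, gj + 1] for gi/gj unpaired bases between
  ## adjacent pairs on the two strands; the (0,0) entry is the stack case,
  ## handled separately, so it is set to Inf here.
  LC <- matrix(Inf, m, n)
  if (m > 1L) for (gi in 1:(m - 1L)) LC[gi + 1L, 1L] <- loop_penalty(params, gi, 0L)
  if (n > 1L) for (gj in 1:(n - 1L)) LC[1L, gj + 1L] <- loop_penalty(params, 0L, gj)
  if (m > 1L && n > 1L) {
    for (gi in 1:(m - 1L)) for (gj in 1:(n - 1L))
      LC[gi + 1L, gj + 1L] <- loop_penalty(params, gi, gj)
  }

  term_pen <- matrix(0, m, n)
  term_pen[outer(M, R, is_au_or_gu)] <- params$terminal_au

  E0 <- matrix(Inf, m, n); E1 <- matrix(Inf, m, n)
  ## back pointers: encoded predecessor cell (i' - 1) * n + j', 0 = chain start;
  ## layer of the predecessor stored separately for E1
  B0 <- matrix(0L, m, n); B1 <- matrix(0L, m, n); B1L <- matrix(0L, m, n)

  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      if (!P[i, j]) next
      e0 <- params$init + term_pen[i, j]; b0 <- 0L
      e1 <- Inf; b1 <- 0L; b1l <- 0L
      if (i > 1L && j > 1L) {
        sub_rows <- seq_len(i - 1L); sub_cols <- seq_len(j - 1L)
        C <- LC[i - sub_rows, j - sub_cols, drop = FALSE]
        cand0 <- E0[sub_rows, sub_cols, drop = FALSE] + C
        k0 <- which.min(cand0)
        if (length(k0) && cand0[k0] < e0) {
          e0 <- cand0[k0]
          ip <- sub_rows[(k0 - 1L) %% (i - 1L) + 1L]
          jp <- sub_cols[(k0 - 1L) %/% (i - 1L) + 1L]
          b0 <- (ip - 1L) * n + jp
        }
        cand1 <- E1[sub_rows, sub_cols, drop = FALSE] + C
        k1 <- which.min(cand1)
        if (length(k1) && cand1[k1] < e1) {
          e1 <- cand1[k1]
          ip <- sub_rows[(k1 - 1L) %% (i - 1L) + 1L]
          jp <- sub_cols[(k1 - 1L) %/% (i - 1L) + 1L]
          b1 <- (ip - 1L) * n + jp; b1l <- 1L
        }
        if (P[i - 1L, j - 1L]) {
          st <- stack_energy(params, paste0(M[i - 1L], M[i]), paste0(R[j - 1L], R[j]))
          if (!is.na(st)) {
            prev <- (i - 2L) * n + (j - 1L)
            if (E1[i - 1L, j - 1L] + st < e1) {
              e1 <- E1[i - 1L, j - 1L] + st; b1 <- prev; b1l <- 1L
            }
            if (E0[i - 1L, j - 1L] + st < e1) {
              e1 <- E0[i - 1L, j - 1L] + st; b1 <- prev; b1l <- 0L
            }
          }
        }
      }
      E0[i, j] <- e0; B0[i, j] <- b0
      E1[i, j] <- e1; B1[i, j] <- b1; B1L[i, j] <- b1l
    }
  }

  total <- E1 + term_pen
  best <- which.min(total)
  if (!length(best) || !is.finite(total[best])) return(no_duplex())
  bi <- (best - 1L) %% m + 1L
  bj <- (best - 1L) %/% m + 1L
  energy <- total[best]

  ## traceback
  pairs_i <- integer(0); pairs_j <- integer(0)
  i <- bi; j <- bj; layer <- 1L
  repeat {
    pairs_i <- c(i, pairs_i); pairs_j <- c(j, pairs_j)
    code <- if (layer == 1L) B1[i, j] else B0[i, j]
    if (layer == 1L) layer <- B1L[i, j]
    if (code == 0L) break
    i <- (code - 1L) %/% n + 1L
    j <- (code - 1L) %% n + 1L
  }

  pair_state <- rep("unpaired", m)
  partner <- rep(NA_integer_, m)
  tpos <- n - pairs_j + 1L  # back to original target coordinates
  pair_state[pairs_i] <- PAIR_TYPE[cbind(M[pairs_i], R[pairs_j])]
  partner[pairs_i] <- tpos

  structure(list(mirna_seq = as_rna(mirna_subseq), target_seq = as_rna(target_seq),
                 mirna_start = as.integer(mirna_start),
                 pair_state = pair_state, target_partner = partner,
                 energy = energy, status = "ok"),
            class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat("miRNA:target duplex (", x$status, ")\n", sep = "")
  cat("  miRNA  5'-", x$mirna_seq, "-3' (positions ",
      x$mirna_start, "-", x$mirna_start + nchar(x$mirna_seq) - 1L, ")\n", sep = "")
  marks <- ifelse(x$pair_state == "WC", "|",
                  ifelse(x$pair_state == "GU", ":", "."))
  cat("            ", paste(marks, collapse = ""), "\n", sep = "")
  cat("  target 3'-", revchar(x$target_seq), "-5'\n", sep = "")
  if (!is.na(x$energy)) cat("  energy: ", x$energy, " kcal/mol\n", sep = "")
  invisible(x)
}

#' Longest run of consecutive base pairs in a duplex alignment
#'
#' Counts the longest stretch of consecutive miRNA positions (within an
#' optional miRNA-coordinate region) that are paired (Watson-Crick or G:U)
#' to consecutive target partners.  A target-side bulge between two pairs
#' breaks the run even though no miRNA position is unpaired.
#'
#' @param alignment A \code{duplex_alignment}.
#' @param region Optional inclusive range \code{c(lo, hi)} of 1-based
#'   full-miRNA coordinates to restrict the count to (e.g. the final 13 nt
#'   of the miRNA); positions outside the alignment are ignored.
#' @return Integer run length (0 if nothing is paired in the region).
#' @export
max_pair_run <- function(alignment, region = NULL) {
  st <- alignment$pair_state
  pt <- alignment$target_partner
  pos <- alignment$mirna_start + seq_along(st) - 1L
  keep <- if (is.null(region)) rep(TRUE, length(st)) else pos >= region[1] & pos <= region[2]
  best <- 0L; run <- 0L; prev_partner <- NA_integer_
  for (k in seq_along(st)) {
    if (!keep[k] || st[k] == "unpaired") {
      run <- 0L; prev_partner <- NA_integer_
      next
    }
    if (!is.na(prev_partner) && pt[k] == prev_partner - 1L) run <- run + 1L else run <- 1L
    prev_partner <- pt[k]
    best <- max(best, run)
  }
  best
}

#' Longest run of unpaired miRNA positions after the seed
#'
#' Returns the longest run of consecutive unpaired miRNA positions at or
#' 3' of \code{from} (default position 9, the first position after the
#' extended seed).  This is the "central bulge" statistic: unpaired
#' target-side bases do not contribute.
#'
#' @param alignment A \code{duplex_alignment} covering miRNA positions
#'   \code{from..L}.
#' @param from First 1-based miRNA coordinate to include.
#' @return Integer run length.
#' @export
max_unpaired_run_after_seed <- function(alignment, from = 9L) {
  st <- alignment$pair_state
  pos <- alignment$mirna_start + seq_along(st) - 1L
  unp <- st == "unpaired" & pos >= from
  best <- 0L; run <- 0L
  for (k in seq_along(st)) {
    if (unp[k]) { run <- run + 1L; best <- max(best, run) } else run <- 0L
  }
  best
}

#' Minimum free energy of the miRNA 3' region against a trigger flank
#'
#' Hybridizes the 3' region of the miRNA (its final
#' \code{three_prime_region_len} nt, default 13) against the target flank
#' immediately 5' of the seed-binding window, via [predict_duplex()].
#' This is the ranking metric for candidate TDMD trigger sites: the
#' extensive 3' pairing that distinguishes a trigger from an ordinary
#' target site shows up as a strongly negative 3' MFE.
#'
#' @param mirna_seq Full miRNA sequence, 5' to 3' (>= 18 nt).
#' @param transcript_seq Transcript sequence containing the site.
#' @param seed_window_start0 0-based transcript coordinate of the first
#'   base of the 8-nt seed-binding window.
#' @param flank_len Flank length (nt) taken immediately 5' of the window
#'   (truncated at the transcript start).
#' @param region_len Length of the miRNA 3' region (nt).
#' @param params Energy parameters.
#' @return A list with \code{energy} (kcal/mol; \code{Inf} when no duplex
#'   forms, so that ranking by increasing energy puts it last),
#'   \code{alignment} (a \code{duplex_alignment} whose \code{mirna_start}
#'   is the full-miRNA coordinate of the region start) and
#'   \code{flank_start0} (0-based transcript coordinate of the flank).
#' @export
three_prime_mfe <- function(mirna_seq, transcript_seq, seed_window_start0,
                            flank_len = 20L, region_len = 13L,
                            params = default_energy_params()) {
  L <- nchar(mirna_seq)
  if (L < 18L) usage_error("miRNA must be >= 18 nt for 3' region analysis")
  if (region_len > L) usage_error("three_prime region longer than the miRNA")
  region <- substring(as_rna(mirna_seq), L - region_len + 1L, L)
  flank_start0 <- max(0L, seed_window_start0 - as.integer(flank_len))
  flank <- subseq0(transcript_seq, flank_start0, seed_window_start0)
  if (nchar(flank) == 0L) {
    aln <- structure(list(mirna_seq = region, target_seq = "",
                          mirna_start = L - region_len + 1L,
                          pair_state = rep("unpaired", region_len),
                          target_partner = rep(NA_integer_, region_len),
                          energy = NA_real_, status = "no_duplex"),
                     class = "duplex_alignment")
    return(list(energy = Inf, alignment = aln, flank_start0 = flank_start0))
  }
  aln <- predict_duplex(region, flank, params, mirna_start = L - region_len + 1L)
  list(energy = if (aln$status == "ok") aln$energy else Inf,
       alignment = aln, flank_start0 = flank_start0)
}

## compact pairing string for report files: per miRNA position of the
## alignment, "(" = Watson-Crick pair, ":" = G:U wobble, "." = unpaired
duplex_pairing_string <- function(alignment) {
  paste(ifelse(alignment$pair_state == "WC", "(",
               ifelse(alignment$pair_state == "GU", ":", ".")), collapse = "")
}
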