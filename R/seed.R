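#' Classify a target window against a miRNA seed
#'
#' Classifies an 8-nt target window into the canonical seed-match classes
#' \code{8mer}, \code{7mer-m8}, \code{7mer-A1}, \code{6mer} or \code{none}.
#' The window is given 5' to 3' with its 3'-most base opposite miRNA
#' position 1 (the "t1" position), so \code{window8[8]} is t1 and
#' \code{window8[1]} is t8.  Only Watson-Crick complementarity counts in
#' the seed; a G:U wobble is treated as a mismatch.
#'
#' Definitions (precedence 8mer > 7mer-m8 > 7mer-A1 > 6mer):
#' \itemize{
#'   \item 8mer: t2-t8 complementary to miRNA positions 2-8 and t1 = A.
#'   \item 7mer-m8: t2-t8 complementary, t1 != A.
#'   \item 7mer-A1: t2-t7 complementary, t8 not complementary, t1 = A.
#'   \item 6mer: t2-t7 complementary only.
#' }
#'
#' @param mirna_seq miRNA sequence, 5' to 3', RNA or DNA alphabet.
#' @param window8 Character vector of 8-nt target windows (5' to 3').
#' @return Character vector of seed classes, one per window.
#' @export
#' @examples
#' classify_seed("UGAGGUAGUAGGUUGUAUAGUU", "CUACCUCA")  # let-7a-5p: 8mer
classify_seed <- function(mirna_seq, window8) {
  if (length(mirna_seq) != 1L) usage_error("mirna_seq must be a single sequence")
  if (any(nchar(window8) != 8L)) usage_error("seed windows must be exactly 8 nt")
  check_alphabet(mirna_seq, "miRNA")
  check_alphabet(window8, "window")
  m <- as_rna(mirna_seq)
  if (nchar(m) < 8L) usage_error("miRNA must be at least 8 nt for seed classification")
  w <- as_rna(window8)

  ## required Watson-Crick partner of miRNA position k sits at window
  ## position 9 - k
  need <- comp_rna(substring(m, 2:8, 2:8))          # for positions 2..8
  tk <- function(k) substring(w, 9L - k, 9L - k)    # target base opposite pos k

  core <- Reduce(`&`, lapply(2:7, function(k) tk(k) == need[k - 1L]))
  m8   <- tk(8L) == need[7L]
  a1   <- tk(1L) == "A"

  out <- rep("none", length(w))
  out[core & m8 & a1]  <- "8mer"
  out[core & m8 & !a1] <- "7mer-m8"
  out[core & !m8 & a1] <- "7mer-A1"
  out[core & !m8 & !a1] <- "6mer"
  out
}

#' Locate canonical seed-match sites along a sequence
#'
#' Slides [classify_seed()] across every 8-nt window of a transcript (or
#' window) sequence and reports all non-\code{none} hits.
#'
#' @param mirna_seq miRNA sequence, 5' to 3'.
#' @param seq Target sequence to scan (length >= 8).
#' @param offset0 0-based transcript coordinate of \code{seq}'s first base;
#'   added to the reported coordinates so windows can be scanned in place.
#' @return A data.frame with 0-based columns \code{window_start} (first
#'   base of the 8-nt window), \code{t1_pos} (coordinate of the t1 base,
#'   i.e. \code{window_start + 7}) and \code{seed_class}.
#' @export
locate_seed_sites <- function(mirna_seq, seq, offset0 = 0L) {
  if (length(seq) != 1L) usage_error("seq must be a single sequence")
  n <- nchar(seq)
  if (n < 8L) {
    return(data.frame(window_start = integer(), t1_pos = integer(),
                      seed_class = character(), stringsAsFactors = FALSE))
  }
  starts <- seq_len(n - 7L)  # 1-based window starts
  windows <- substring(seq, starts, starts + 7L)
  cls <- classify_seed(mirna_seq, windows)
  hit <- cls != "none"
  data.frame(window_start = offset0 + starts[hit] - 1L,
             t1_pos = offset0 + starts[hit] + 6L,
             seed_class = cls[hit], stringsAsFactors = FALSE)
}
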