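# Internal helpers: alphabet handling, coordinates, condition classes.
#
# Coordinate convention used throughout the package: transcript-space,
# 0-based half-open intervals [start, end), matching the BED/bedGraph
# fixtures.  Conversion to 1-based R substring indexing happens only at
# the point of sequence extraction (subseq0) or at the IRanges boundary.

RNA_BASES <- c("A", "C", "G", "U")
DNA_BASES <- c("A", "C", "G", "T")

## this package uses data.table semantics via :: only
.datatable.aware <- TRUE

as_rna <- function(x) chartr("Tt", "Uu", toupper(x))
as_dna <- function(x) chartr("Uu", "Tt", toupper(x))

comp_rna <- function(x) chartr("ACGU", "UGCA", x)

revchar <- function(x) {
  vapply(strsplit(x, ""), function(s) paste(rev(s), collapse = ""), character(1))
}

revcomp_rna <- function(x) revchar(comp_rna(as_rna(x)))
revcomp_dna <- function(x) chartr("ACGT", "TGCA", revchar(as_dna(x)))

## substring in 0-based half-open coordinates
subseq0 <- function(seq, start0, end0) substring(seq, start0 + 1L, end0)

check_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGUTacgut]", x)
  if (any(bad)) {
    usage_error(sprintf("%s contains characters outside the RNA/DNA alphabet: %s",
                        what, x[which(bad)[1L]]))
  }
  invisible(x)
}

rand_seq <- function(n, len, alphabet = DNA_BASES) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len[min(i, length(len))], replace = TRUE), collapse = "")
  }, character(1))
}

## condition classes mapped to CLI exit codes: usage/config errors -> 2,
## data errors -> 1
usage_error <- function(msg, call. = FALSE) {
  stop(structure(class = c("tdmd_usage_error", "error", "condition"),
                 list(message = msg, call = if (call.) sys.call(-1))))
}

data_error <- function(msg, call. = FALSE) {
  stop(structure(class = c("tdmd_data_error", "error", "condition"),
                 list(message = msg, call = if (call.) sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
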