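#' Load nearest-neighbor duplex energy parameters
#'
#' Reads the plain-text nearest-neighbor parameter table shipped with the
#' package (or a user-supplied file in the same format) into the lookup
#' structure used by [predict_duplex()].  The shipped table holds
#' Watson-Crick stack free energies from the Xia et al. measurement set and
#' G:U wobble stacks plus bulge/internal-loop length penalties from the
#' Turner 2004 compilation, all at 37 degrees C in kcal/mol.
#'
#' File format, one record per line, tab-separated:
#' \itemize{
#'   \item \code{init <dG>} — intermolecular duplex initiation energy.
#'   \item \code{terminal_au <dG>} — penalty applied once per duplex end
#'     whose closing pair is A:U or G:U.
#'   \item \code{stack <top> <bot> <dG>} — a dinucleotide stack written as
#'     the helix \code{5'-top-3'} over \code{3'-bot-5'}, i.e. \code{top[k]}
#'     pairs \code{bot[k]}.
#'   \item \code{bulge <len> <dG>} / \code{internal <len> <dG>} — loop
#'     destabilization by total unpaired length (nt).
#' }
#'
#' @param path Path to a parameter file.  Defaults to the shipped
#'   Turner-style table.
#' @return An object of class \code{energy_params}: a list with elements
#'   \code{init}, \code{terminal_au}, \code{stack} (named numeric vector
#'   keyed \code{"<top>|<bot>"}), \code{bulge} and \code{internal}
#'   (numeric vectors indexed by loop length).
#' @export
#' @examples
#' p <- load_energy_params()
#' p$init
#' p$stack[["GG|CC"]]
load_energy_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nn_params_turner2004.txt",
                        package = "tdmdscan", mustWork = TRUE)
  }
  if (!file.exists(path)) usage_error(sprintf("energy parameter file not found: %s", path))
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  fields <- strsplit(ln, "\t", fixed = TRUE)
  kind <- vapply(fields, `[[`, character(1), 1L)

  take <- function(k, nf) {
    rows <- fields[kind == k]
    if (!all(lengths(rows) == nf)) usage_error(sprintf("malformed '%s' record in %s", k, path))
    rows
  }
  stacks <- take("stack", 4L)
  stack <- vapply(stacks, function(r) as.numeric(r[[4]]), numeric(1))
  names(stack) <- vapply(stacks, function(r) paste0(r[[2]], "|", r[[3]]), character(1))

  lens <- function(k) {
    rows <- take(k, 3L)
    idx <- vapply(rows, function(r) as.integer(r[[2]]), integer(1))
    val <- vapply(rows, function(r) as.numeric(r[[3]]), numeric(1))
    out <- rep(NA_real_, max(idx))
    out[idx] <- val
    out
  }
  scalar <- function(k) as.numeric(take(k, 2L)[[1]][[2]])

  p <- structure(list(
    init        = scalar("init"),
    terminal_au = scalar("terminal_au"),
    stack       = stack,
    bulge       = lens("bulge"),
    internal    = lens("internal")
  ), class = "energy_params")
  if (any(stats::na.omit(p$bulge) < 0) || any(stats::na.omit(p$internal) < 0))
    usage_error("loop penalties must be non-negative")
  p
}

## cached default parameter set
.tdmd_env <- new.env(parent = emptyenv())

default_energy_params <- function() {
  if (is.null(.tdmd_env$params)) .tdmd_env$params <- load_energy_params()
  .tdmd_env$params
}

## Pairing alphabet: Watson-Crick plus G:U wobble.  Bases are RNA letters.
PAIR_TYPE <- local({
  b <- c("A", "C", "G", "U")
  m <- matrix(NA_character_, 4, 4, dimnames = list(b, b))
  m["A", "U"] <- m["U", "A"] <- m["C", "G"] <- m["G", "C"] <- "WC"
  m["G", "U"] <- m["U", "G"] <- "GU"
  m
})

pair_type <- function(a, b) PAIR_TYPE[cbind(a, b)]

is_au_or_gu <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "U") | (a == "U" & b == "G")
}

stack_energy <- function(params, top, bot) {
  v <- params$stack[paste0(top, "|", bot)]
  unname(v)
}

loop_penalty <- function(params, gap_m, gap_t) {
  ## gap_m / gap_t: unpaired nts on the two strands between adjacent pairs
  if (gap_m == 0L && gap_t == 0L) return(0)
  tab <- if (gap_m == 0L || gap_t == 0L) params$bulge else params$internal
  len <- min(gap_m + gap_t, length(tab))
  v <- tab[len]
  if (is.na(v)) Inf else v
}
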