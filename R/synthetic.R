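#' Configuration for the synthetic AGO-CLASH data generator
#'
#' Bundles and validates all knobs of the synthetic read simulator.  The
#' defaults describe the study conditions emulated throughout the package:
#' a probe-enriched AGO-CLASH library in which chimeric miRNA:target reads
#' are a small minority of all reads, snoRNA-like contaminants are present,
#' and reads follow the layout \code{[UMI][miRNA][target][adapter]}.
#'
#' @param rng_seed Integer seed; every generator stage derives its stream
#'   from it, so identical configs give byte-identical fixtures.
#' @param n_mirnas Number of mature miRNAs in the catalog.
#' @param n_transcripts Number of (non-contaminant) transcripts.
#' @param transcript_length_range Length range (nt) for transcripts.
#' @param chimera_fraction Fraction of reads carrying a ligated
#'   miRNA:target chimera.
#' @param enrichment_factor Fold-increase in chimera sampling for
#'   probe-enriched miRNAs, emulating biotinylated-probe capture.
#' @param contaminant_fraction Fraction of reads that are snoRNA-like
#'   contaminant fragments.
#' @param sequencing_error_rate Per-base substitution probability.
#' @param umi_length Length (nt) of the unique molecular identifier
#'   prefix.
#' @param adapter_sequence 3' adapter appended to every read.
#' @param reads_total Number of reads to simulate.
#' @param site_chimera_bias For a miRNA with embedded sites, the
#'   probability that one of its chimeras is drawn from an embedded site
#'   rather than a random transcript position (the remainder emulates
#'   ordinary, non-trigger target binding).
#' @param target_frag_range Length range (nt) of ligated target fragments.
#' @param contaminant_frag_range Length range (nt) of contaminant
#'   fragments.
#' @param n_contaminants Number of snoRNA-like contaminant transcripts
#'   added to the transcriptome (gene ids carry the \code{Snord} prefix by
#'   which the read processor recognizes the contaminant catalog).
#' @return A validated list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(rng_seed = 1L,
                             n_mirnas = 10L,
                             n_transcripts = 60L,
                             transcript_length_range = c(500L, 1500L),
                             chimera_fraction = 0.02,
                             enrichment_factor = 8,
                             contaminant_fraction = 0.05,
                             sequencing_error_rate = 0.001,
                             umi_length = 10L,
                             adapter_sequence = "AGATCGGAAGAGC",
                             reads_total = 200000L,
                             site_chimera_bias = 0.8,
                             target_frag_range = c(20L, 40L),
                             contaminant_frag_range = c(20L, 60L),
                             n_contaminants = 4L) {
  cfg <- list(rng_seed = as.integer(rng_seed), n_mirnas = as.integer(n_mirnas),
              n_transcripts = as.integer(n_transcripts),
              transcript_length_range = as.integer(transcript_length_range),
              chimera_fraction = chimera_fraction,
              enrichment_factor = enrichment_factor,
              contaminant_fraction = contaminant_fraction,
              sequencing_error_rate = sequencing_error_rate,
              umi_length = as.integer(umi_length),
              adapter_sequence = toupper(adapter_sequence),
              reads_total = as.integer(reads_total),
              site_chimera_bias = site_chimera_bias,
              target_frag_range = as.integer(target_frag_range),
              contaminant_frag_range = as.integer(contaminant_frag_range),
              n_contaminants = as.integer(n_contaminants))

  bad <- function(field, why) usage_error(sprintf("invalid synthetic_config: %s (%s)", field, why))
  for (f in c("chimera_fraction", "contaminant_fraction", "sequencing_error_rate",
              "site_chimera_bias")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      bad(f, "must be a probability in [0, 1]")
  }
  if (cfg$chimera_fraction + cfg$contaminant_fraction > 1)
    bad("chimera_fraction", "chimera_fraction + contaminant_fraction must be <= 1")
  if (is.na(cfg$rng_seed) || cfg$rng_seed < 0L) bad("rng_seed", "must be a non-negative integer")
  if (is.na(cfg$n_mirnas) || cfg$n_mirnas < 1L) bad("n_mirnas", "must be >= 1")
  if (is.na(cfg$n_transcripts) || cfg$n_transcripts < 1L) bad("n_transcripts", "must be >= 1")
  if (cfg$umi_length < 4L) bad("umi_length", "must be >= 4")
  if (is.na(cfg$reads_total) || cfg$reads_total < 0L) bad("reads_total", "must be >= 0")
  if (length(cfg$transcript_length_range) != 2L ||
      any(cfg$transcript_length_range < 100L) || diff(cfg$transcript_length_range) < 0)
    bad("transcript_length_range", "must be an increasing pair >= 100")
  if (nchar(cfg$adapter_sequence) < 6L || grepl("[^ACGT]", cfg$adapter_sequence))
    bad("adapter_sequence", "must be a DNA string of >= 6 nt")
  if (cfg$enrichment_factor < 1) bad("enrichment_factor", "must be >= 1")
  structure(cfg, class = "synthetic_config")
}

#' Specify a target site to embed in the synthetic transcriptome
#'
#' Describes the pairing architecture of one miRNA binding site: its seed
#' class, the designed run of consecutive base pairs to the miRNA 3'
#' region, the designed run of consecutive unpaired miRNA positions after
#' the seed (central bulge), the transcript region it falls in, and the
#' sign of the conservation signal over its pairing positions.  A site
#' flagged as a true TDMD trigger must satisfy all nomination criteria by
#' construction; decoy sites violate exactly one criterion each.
#'
#' @param mirna_id Catalog id of the miRNA the site pairs with.
#' @param seed_class One of \code{"8mer"}, \code{"7mer-m8"},
#'   \code{"7mer-A1"}, \code{"6mer"}, \code{"none"}.
#' @param three_prime_run Designed consecutive base pairs between the
#'   target and the final 13 nt of the miRNA (0-13).
#' @param central_bulge_run Designed consecutive unpaired miRNA positions
#'   after the seed.
#' @param region_label Transcript region hosting the site.
#' @param conservation_sign \code{"positive"} or \code{"negative"} mean
#'   conservation over the site's pairing positions.
#' @param is_true_trigger Flag marking a site designed to pass all
#'   criteria.
#' @param transcript_id Optional fixed host transcript (assigned
#'   automatically when \code{NA}).
#' @return A list of class \code{site_spec}.
#' @export
site_spec <- function(mirna_id, seed_class = "8mer", three_prime_run = 13L,
                      central_bulge_run = 0L, region_label = "3UTR",
                      conservation_sign = "positive", is_true_trigger = FALSE,
                      transcript_id = NA_character_) {
  s <- list(mirna_id = mirna_id, seed_class = seed_class,
            three_prime_run = as.integer(three_prime_run),
            central_bulge_run = as.integer(central_bulge_run),
            region_label = region_label, conservation_sign = conservation_sign,
            is_true_trigger = isTRUE(is_true_trigger),
            transcript_id = transcript_id)
  if (!s$seed_class %in% c("8mer", "7mer-m8", "7mer-A1", "6mer", "none"))
    usage_error(sprintf("site_spec: unknown seed_class '%s'", s$seed_class))
  if (!s$region_label %in% c("5UTR", "CDS", "3UTR", "ncRNA_exon"))
    usage_error(sprintf("site_spec: unknown region_label '%s'", s$region_label))
  if (!s$conservation_sign %in% c("positive", "negative"))
    usage_error("site_spec: conservation_sign must be 'positive' or 'negative'")
  if (s$three_prime_run < 0L || s$three_prime_run > 13L)
    usage_error("site_spec: three_prime_run must be in 0..13")
  if (s$central_bulge_run < 0L)
    usage_error("site_spec: central_bulge_run must be >= 0")
  if (s$is_true_trigger) {
    if (s$seed_class == "none" || !s$region_label %in% c("5UTR", "3UTR", "ncRNA_exon") ||
        s$central_bulge_run > 7L || s$three_prime_run < 6L ||
        s$conservation_sign != "positive")
      usage_error(sprintf(
        "site_spec: a true trigger for %s must have a seed match, a noncoding region, a central bulge <= 7, a 3' run >= 6 and positive conservation",
        s$mirna_id))
  }
  structure(s, class = "site_spec")
}

#' Default site architectures: three true triggers plus one decoy per
#' failure mode
#'
#' Builds the study-condition site set used throughout the package: three
#' true trigger sites (which must survive every nomination criterion and
#' rank first for their miRNA) and five decoys, each violating exactly one
#' criterion — a CDS-located site, a site with an 8-nt central bulge, a
#' site with only 5 consecutive 3' pairs, a site with negative
#' conservation, and a site with a mismatched seed.
#'
#' @param catalog miRNA catalog from [build_mirna_catalog()]; roles are
#'   assigned to miRNAs whose lengths accommodate the requested
#'   architectures.
#' @return A list of [site_spec()] objects.
#' @export
default_site_specs <- function(catalog) {
  if (nrow(catalog) < 8L)
    usage_error("default_site_specs needs a catalog of >= 8 miRNAs")
  len <- nchar(catalog$sequence)
  ## the 8-nt-bulge decoy needs a miRNA of >= 22 nt (b = L - 14 must
  ## exceed 7) and the 13-bp trigger needs >= 21 nt; put the longest
  ## miRNAs on the roles with the tightest length requirements
  pick <- catalog$id[order(-len)]
  list(
    site_spec(pick[2], "8mer",    three_prime_run = 13L, central_bulge_run = 1L,
              region_label = "3UTR", is_true_trigger = TRUE),
    site_spec(pick[3], "7mer-m8", three_prime_run = 10L, central_bulge_run = 4L,
              region_label = "3UTR", is_true_trigger = TRUE),
    site_spec(pick[4], "7mer-A1", three_prime_run = 8L,  central_bulge_run = 6L,
              region_label = "ncRNA_exon", is_true_trigger = TRUE),
    ## decoys, one per criterion
    site_spec(pick[5], "8mer", three_prime_run = 11L, central_bulge_run = 3L,
              region_label = "CDS"),                                  # fails region
    site_spec(pick[1], "8mer", three_prime_run = 6L,  central_bulge_run = 8L,
              region_label = "3UTR"),                                 # fails bulge
    site_spec(pick[6], "8mer", three_prime_run = 5L,  central_bulge_run = 5L,
              region_label = "3UTR"),                                 # fails 3' run
    site_spec(pick[7], "8mer", three_prime_run = 10L, central_bulge_run = 4L,
              region_label = "3UTR", conservation_sign = "negative"), # fails conservation
    site_spec(pick[8], "none", three_prime_run = 10L, central_bulge_run = 4L,
              region_label = "3UTR")                                  # fails seed
  )
}

#' Generate a catalog of mature miRNA sequences
#'
#' Emulates the study design of focusing on a small set of
#' ZSWIM8-regulated miRNAs, half of which are targeted by enrichment
#' probes.  Sequences are random RNA of 20-23 nt (at least half exactly
#' 22 nt, the modal mature-miRNA length) and deterministic given the
#' config seed.
#'
#' @param config A [synthetic_config()].
#' @param include_known Optional known miRNAs to pass through verbatim,
#'   either a named character vector (\code{c("let-7a-5p" = "UGAGG...")})
#'   or strings of the form \code{"id:SEQUENCE"}.
#' @return A data.frame with columns \code{id}, \code{sequence} (RNA),
#'   \code{probe_enriched}, \code{zswim8_regulated}.
#' @export
build_mirna_catalog <- function(config = synthetic_config(), include_known = NULL) {
  if (!inherits(config, "synthetic_config")) config <- do.call(synthetic_config, config)
  set.seed(config$rng_seed)
  n <- config$n_mirnas

  known <- NULL
  if (!is.null(include_known)) {
    if (is.null(names(include_known)) || any(names(include_known) == "")) {
      parts <- strsplit(include_known, ":", fixed = TRUE)
      if (any(lengths(parts) != 2L))
        usage_error("include_known entries must be named or of the form 'id:SEQUENCE'")
      known <- stats::setNames(vapply(parts, `[[`, character(1), 2L),
                               vapply(parts, `[[`, character(1), 1L))
    } else known <- include_known
    known <- vapply(known, as_rna, character(1))
    check_alphabet(known, "include_known sequence")
    if (any(nchar(known) < 18L | nchar(known) > 26L))
      usage_error("include_known sequences must be 18-26 nt")
  }
  n_rand <- n - length(known)
  if (n_rand < 0L) usage_error("invalid synthetic_config: n_mirnas (fewer than include_known entries)")

  lens <- integer(0)
  if (n_rand > 0L) {
    lens <- c(rep(22L, ceiling(n_rand / 2)),
              sample(c(20L, 21L, 23L), floor(n_rand / 2), replace = TRUE))
    lens <- lens[sample.int(length(lens))]  # shuffle 22-mers among the rest
  }
  seqs <- character(0)
  while (length(seqs) < n_rand) {
    s <- rand_seq(1L, lens[length(seqs) + 1L], RNA_BASES)
    if (!s %in% seqs && !s %in% known) seqs <- c(seqs, s)
  }
  ids <- sprintf("syn-miR-%d-5p", seq_len(n_rand))
  cat_df <- data.frame(id = c(names(known), ids),
                       sequence = c(unname(known), seqs),
                       stringsAsFactors = FALSE)
  cat_df$probe_enriched <- seq_len(n) <= max(1L, ceiling(n / 2))
  cat_df$zswim8_regulated <- TRUE
  rownames(cat_df) <- NULL
  cat_df
}

## ---------------------------------------------------------------------
## site architecture design

## Choose a legal (three_prime_run, bulge, intermediate-helix) layout for
## a miRNA of length L.  The layouts that realize a requested (r, b):
##   contiguous: [seed][b-gap][one helix over all remaining positions],
##     whose in-region pair run is min(13, L - 8 - b); legal iff that
##     equals r;
##   split (two arrangements): a terminal helix of exactly r pairs at the
##     miRNA 3' end plus an intermediate helix A of hA = L - 8 - b - r
##     positions (stable only when hA >= 4), separated from the terminal
##     helix by a 1-nt target bulge; the b-gap sits either between the
##     seed and helix A ("gap_first", helix A at positions 8+b+1..L-r) or
##     between helix A and the terminal helix ("gap_mid", helix A at
##     positions 9..8+hA).  Legal iff helix A's overlap with the final
##     13 nt does not exceed r for at least one arrangement.
## b may be nudged away from the request (within the pass/fail class of
## the bulge criterion) when the requested value is not realizable.
fit_site_arch <- function(L, r, b) {
  region_lo <- L - 12L
  overlap_run <- function(lo, hi) max(0L, hi - max(lo, region_lo) + 1L)
  legal <- function(bb) {
    h <- L - 8L - bb
    if (h < r || bb < 0L) return(list())
    if (min(13L, h) == r)
      return(list(list(b = bb, hA = 0L, arrangement = "contiguous")))
    hA <- h - r
    if (hA < 4L) return(list())
    out <- list()
    if (overlap_run(8L + bb + 1L, L - r) <= r)
      out <- c(out, list(list(b = bb, hA = hA, arrangement = "gap_first")))
    if (overlap_run(9L, 8L + hA) <= r)
      out <- c(out, list(list(b = bb, hA = hA, arrangement = "gap_mid")))
    out
  }
  ## every legal (bulge, arrangement) combination, nearest-b first, never
  ## moving the bulge across the pass/fail boundary of the bulge
  ## criterion (7 nt); structurally different designs let the realization
  ## loop escape register ambiguities in self-similar miRNA sequences
  fits <- list()
  for (delta in 0:8) for (bb in unique(c(b + delta, b - delta))) {
    if ((b <= 7L) != (bb <= 7L)) next
    fits <- c(fits, legal(bb))
  }
  fits
}

## a base that can pair (WC or GU) with none of `bases`, or NA
safe_sep <- function(bases) {
  excluded <- unlist(lapply(bases, function(bb) {
    c(comp_rna(bb), switch(bb, G = "U", U = "G", character(0)))
  }))
  ok <- setdiff(RNA_BASES, excluded)
  if (length(ok)) sample(ok, 1L) else NA_character_
}

## Construct the designed target-site sequence (5'->3') for one spec.
## Fixed-character helix boundaries that could pair (and so let the MFE
## alignment silently extend a designed helix) are protected by 1-nt
## target bulges whose base is chosen to pair with nothing adjacent.
design_site <- function(mirna_rna, spec, attempt = 1L) {
  m <- strsplit(mirna_rna, "")[[1]]
  L <- length(m)
  comp <- function(idx) comp_rna(paste(rev(m[idx]), collapse = ""))  # revcomp of positions
  pairable <- function(a, bb) !is.na(PAIR_TYPE[a, bb])

  ## seed window, written 5'->3' as [t8 t7 ... t1]
  not_comp <- function(base) sample(setdiff(RNA_BASES, comp_rna(base)), 1L)
  w <- comp_rna(m[8:2])                     # t8..t2, complementary
  t1 <- "A"
  sc <- spec$seed_class
  if (sc == "7mer-m8") t1 <- sample(setdiff(RNA_BASES, "A"), 1L)
  if (sc %in% c("7mer-A1", "6mer")) w[1] <- not_comp(m[8])
  if (sc == "6mer") t1 <- sample(setdiff(RNA_BASES, "A"), 1L)
  if (sc == "none") w[5] <- not_comp(m[4])  # mismatch at t4, core broken
  window <- paste(c(w, t1), collapse = "")

  fits <- fit_site_arch(L, spec$three_prime_run, spec$central_bulge_run)
  if (length(fits) == 0L)
    usage_error(sprintf(
      "unrealizable site_spec for %s (L=%d): three_prime_run=%d, central_bulge_run=%d",
      spec$mirna_id, L, spec$three_prime_run, spec$central_bulge_run))
  fit <- fits[[(attempt - 1L) %% length(fits) + 1L]]
  b <- fit$b; r <- spec$three_prime_run; hA <- fit$hA
  arr <- fit$arrangement

  if (arr == "contiguous") {
    pairing <- comp((8L + b + 1L):L)
    ## when the last gap position could pair with t8, the helix would
    ## extend and shrink the designed bulge: insert a guard bulge
    if (b >= 1L && pairable(m[8L + b], w[1])) {
      guard <- safe_sep(m[8L + b])
      if (!is.na(guard)) pairing <- paste0(pairing, guard)
    }
  } else if (arr == "gap_mid") {
    ## [helixB_t][sep][helixA_t][window]; helix A at 9..8+hA (window side)
    sep <- safe_sep(c(m[9L + hA], m[L - r]))
    if (is.na(sep)) sep <- sample(RNA_BASES, 1L)
    pairing <- paste0(comp((L - r + 1L):L), sep, comp(9L:(8L + hA)))
  } else {  # gap_first: helix A at 8+b+1..L-r (window side), gap after seed
    sep <- safe_sep(c(m[L - r]))
    if (is.na(sep)) sep <- sample(RNA_BASES, 1L)
    pairing <- paste0(comp((L - r + 1L):L), sep, comp((8L + b + 1L):(L - r)))
    if (b >= 1L && pairable(m[8L + b], w[1])) {
      guard <- safe_sep(m[8L + b])
      if (!is.na(guard)) pairing <- paste0(pairing, guard)
    }
  }
  list(site_seq = paste0(pairing, window), window = window,
       pairing_len = nchar(pairing), b = b)
}

#' Build a synthetic transcriptome with embedded sites and conservation
#'
#' Generates random transcripts (a mix of coding transcripts with
#' 5'UTR/CDS/3'UTR segmentation and noncoding transcripts, plus
#' snoRNA-like contaminant transcripts), embeds each requested site as an
#' exact subsequence whose pairing architecture — re-derived with the
#' package's own seed classifier and duplex engine — reproduces the
#' requested seed class, 3' pair run and central bulge, and lays down a
#' per-base conservation track: Gaussian background (mean 0, sd 0.5) with
#' a shifted mean of the requested sign (magnitude 1) over site pairing
#' positions.
#'
#' Each realized site is verified by feeding it back through
#' [classify_seed()] and [predict_duplex()]; the random sequence context
#' is resampled when an accidental interaction distorts the architecture,
#' and generation fails with an error identifying the spec if no context
#' realizes it.
#'
#' @param catalog miRNA catalog from [build_mirna_catalog()].
#' @param site_specs List of [site_spec()] objects (possibly empty).
#' @param config A [synthetic_config()].
#' @param flank_len,three_prime_region_len Geometry used for the
#'   verification duplex (defaults match [filter_config()]).
#' @return A list with elements \code{transcriptome} (class
#'   \code{transcriptome}: \code{transcripts}, \code{segments},
#'   \code{sequences}, \code{conservation}) and \code{truth} (the
#'   realized-site manifest, 0-based half-open transcript coordinates).
#' @export
build_transcriptome <- function(catalog, site_specs = list(), config = synthetic_config(),
                                flank_len = 20L, three_prime_region_len = 13L) {
  if (!inherits(config, "synthetic_config")) config <- do.call(synthetic_config, config)
  set.seed(config$rng_seed + 1L)
  for (s in site_specs) {
    if (!inherits(s, "site_spec")) usage_error("site_specs must be a list of site_spec objects")
    if (!s$mirna_id %in% catalog$id)
      usage_error(sprintf("site_spec references unknown miRNA '%s'", s$mirna_id))
  }

  n <- config$n_transcripts
  lens <- sample(config$transcript_length_range[1]:config$transcript_length_range[2],
                 n, replace = TRUE)
  coding <- stats::runif(n) < 0.65
  ## contaminant (snoRNA-like) transcripts appended after the regular ones
  nc <- config$n_contaminants
  ids <- c(sprintf("TX%04d", seq_len(n)), if (nc) sprintf("SNORDTX%02d", seq_len(nc)))
  genes <- c(sprintf("Gene%04d", seq_len(n)), if (nc) sprintf("Snord%02d", seq_len(nc)))
  lens <- c(lens, if (nc) sample(100:180, nc, replace = TRUE))
  coding <- c(coding, rep(FALSE, nc))

  segments <- do.call(rbind, lapply(seq_along(ids), function(i) {
    len <- lens[i]
    if (coding[i]) {
      u <- max(30L, round(len * stats::runif(1, 0.08, 0.15)))
      c_end <- u + max(90L, round(len * stats::runif(1, 0.45, 0.6)))
      c_end <- min(c_end, len - 80L)  # 3'UTR long enough to host a site
                                      # with its full fragment-span margin
      data.frame(transcript_id = ids[i],
                 segment_label = c("5UTR", "CDS", "3UTR"),
                 start = c(0L, u, c_end), end = c(u, c_end, len),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(transcript_id = ids[i], segment_label = "ncRNA_exon",
                 start = 0L, end = len, stringsAsFactors = FALSE)
    }
  }))
  rownames(segments) <- NULL
  sequences <- stats::setNames(rand_seq(length(ids), lens, DNA_BASES), ids)
  conservation <- stats::setNames(
    lapply(lens, function(l) round(stats::rnorm(l, 0, 0.5), 4)), ids)

  transcripts <- data.frame(transcript_id = ids, gene_id = genes,
                            biotype = ifelse(coding, "coding", "noncoding"),
                            length = lens, stringsAsFactors = FALSE)

  ## --- embed sites -------------------------------------------------
  truth <- data.frame(mirna_id = character(), transcript_id = character(),
                      start = integer(), end = integer(),
                      seed_window_start = integer(), region_label = character(),
                      seed_class = character(), three_prime_run = integer(),
                      central_bulge_run = integer(), conservation_sign = character(),
                      is_true_trigger = logical(), stringsAsFactors = FALSE)
  used_tx <- character(0)

  for (spec in site_specs) {
    mseq <- catalog$sequence[match(spec$mirna_id, catalog$id)]
    L <- nchar(mseq)
    placed <- FALSE
    for (attempt in seq_len(40L)) {
      ds <- design_site(mseq, spec, attempt)
      site_len <- nchar(ds$site_seq)
      ## chimera fragments containing the site can extend up to
      ## (max fragment length - site length) nt on either side; keeping
      ## that whole span inside the host segment guarantees the cluster
      ## core annotates to the requested region
      maxext <- max(0L, max(config$target_frag_range) - site_len)
      need <- max(site_len + 2L * maxext, site_len + flank_len) + 6L
      cand <- segments[segments$segment_label == spec$region_label &
                         (segments$end - segments$start) >= need &
                         !segments$transcript_id %in% used_tx &
                         !grepl("^SNORDTX", segments$transcript_id), , drop = FALSE]
      if (!is.na(spec$transcript_id))
        cand <- cand[cand$transcript_id == spec$transcript_id, , drop = FALSE]
      if (nrow(cand) == 0L)
        usage_error(sprintf("no transcript can host site_spec for %s in region %s",
                            spec$mirna_id, spec$region_label))
      seg <- cand[sample(nrow(cand), 1L), ]
      ## 0-based start of the designed pairing region, leaving the
      ## fragment-span margin on both sides and room for the flank
      lo <- max(seg$start + maxext, flank_len - ds$pairing_len) + 2L
      hi <- seg$end - site_len - maxext - 2L
      s0 <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      tx <- seg$transcript_id
      seq0 <- sequences[[tx]]
      site_dna <- as_dna(ds$site_seq)
      newseq <- paste0(substr(seq0, 1, s0), site_dna,
                       substring(seq0, s0 + site_len + 1L))
      ## verify with the pipeline's own oracles
      wstart <- s0 + ds$pairing_len           # 0-based seed-window start
      win <- subseq0(newseq, wstart, wstart + 8L)
      ok <- if (spec$seed_class == "none") {
        nrow(locate_seed_sites(mseq, subseq0(newseq, s0, s0 + site_len))) == 0L
      } else classify_seed(mseq, win) == spec$seed_class
      if (ok) {
        flank0 <- max(0L, wstart - flank_len)
        aln <- predict_duplex(substring(mseq, 9L, L),
                              subseq0(newseq, flank0, wstart), mirna_start = 9L)
        ok <- aln$status == "ok" &&
          max_unpaired_run_after_seed(aln) == ds$b &&
          max_pair_run(aln, region = c(L - three_prime_region_len + 1L, L)) ==
            spec$three_prime_run
      }
      if (ok) {
        sequences[[tx]] <- newseq
        cons <- conservation[[tx]]
        mu <- if (spec$conservation_sign == "positive") 1 else -1
        idx <- (s0 + 1L):(s0 + site_len)
        repeat {
          v <- round(stats::rnorm(length(idx), mu, 0.2), 4)
          if (abs(mean(v)) >= 0.5 && sign(mean(v)) == sign(mu)) break
        }
        cons[idx] <- v
        conservation[[tx]] <- cons
        used_tx <- c(used_tx, tx)
        truth <- rbind(truth, data.frame(
          mirna_id = spec$mirna_id, transcript_id = tx,
          start = s0, end = s0 + site_len, seed_window_start = wstart,
          region_label = spec$region_label, seed_class = spec$seed_class,
          three_prime_run = spec$three_prime_run, central_bulge_run = ds$b,
          conservation_sign = spec$conservation_sign,
          is_true_trigger = spec$is_true_trigger, stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      usage_error(sprintf(
        "could not realize site_spec for %s (seed_class=%s, run=%d, bulge=%d) after 40 attempts",
        spec$mirna_id, spec$seed_class, spec$three_prime_run, spec$central_bulge_run))
  }

  txome <- structure(list(transcripts = transcripts, segments = segments,
                          sequences = sequences, conservation = conservation),
                     class = "transcriptome")
  list(transcriptome = txome, truth = truth)
}

#' Simulate AGO-CLASH reads with a ground-truth manifest
#'
#' Draws \code{reads_total} reads of the layout
#' \code{[UMI][payload][adapter]} where the payload is, with probability
#' \code{chimera_fraction}, a full miRNA followed by a 20-40 nt target
#' fragment (overlapping an embedded site with probability
#' \code{site_chimera_bias} for miRNAs that have one, otherwise a random
#' transcript window); with probability \code{contaminant_fraction} a
#' fragment of a snoRNA-like contaminant transcript; and otherwise the
#' miRNA alone.  Chimera sampling weight is multiplied by
#' \code{enrichment_factor} for probe-enriched miRNAs.  Per-base
#' substitution errors are applied at \code{sequencing_error_rate}.
#'
#' @param transcriptome,catalog,truth Output of [build_transcriptome()]
#'   and [build_mirna_catalog()].
#' @param config A [synthetic_config()].
#' @return A list: \code{reads} (data.frame \code{read_id},
#'   \code{sequence}), \code{read_truth} (per-read fate and, for chimeras,
#'   the true (miRNA, transcript, interval)), and \code{truth} with an
#'   added \code{expected_chimeras} column counting simulated chimeras per
#'   embedded site.
#' @export
simulate_reads <- function(transcriptome, catalog, truth, config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) config <- do.call(synthetic_config, config)
  set.seed(config$rng_seed + 2L)
  n <- config$reads_total
  truth$expected_chimeras <- if (nrow(truth)) 0L else integer(0)
  empty <- list(reads = data.frame(read_id = character(), sequence = character(),
                                   stringsAsFactors = FALSE),
                read_truth = data.frame(read_id = character(), kind = character(),
                                        mirna_id = character(), transcript_id = character(),
                                        start = integer(), end = integer(),
                                        stringsAsFactors = FALSE),
                truth = truth)
  if (n == 0L) return(empty)

  tx <- transcriptome$transcripts
  is_contam_tx <- grepl("^Snord", tx$gene_id)
  reg_tx <- tx[!is_contam_tx, , drop = FALSE]
  sno_tx <- tx[is_contam_tx, , drop = FALSE]

  u <- stats::runif(n)
  cf <- config$chimera_fraction; of <- config$contaminant_fraction
  kind <- ifelse(u < cf, "chimera",
                 ifelse(u < cf + of & nrow(sno_tx) > 0L, "contaminant", "mirna_only"))

  w <- ifelse(catalog$probe_enriched, config$enrichment_factor, 1)
  mirna_idx <- sample.int(nrow(catalog), n, replace = TRUE, prob = w / sum(w))
  mirna_idx[kind == "contaminant"] <- NA_integer_

  frag_tx <- rep(NA_character_, n)
  frag_start <- rep(NA_integer_, n)
  frag_end <- rep(NA_integer_, n)
  site_row <- rep(NA_integer_, n)

  chim <- which(kind == "chimera")
  if (length(chim)) {
    fr <- config$target_frag_range
    flen <- sample(fr[1]:fr[2], length(chim), replace = TRUE)
    directed <- logical(length(chim))
    for (mi in unique(mirna_idx[chim])) {
      rows_k <- which(mirna_idx[chim] == mi)
      sites <- which(truth$mirna_id == catalog$id[mi])
      if (length(sites) == 0L) next
      dir_k <- stats::runif(length(rows_k)) < config$site_chimera_bias
      directed[rows_k] <- dir_k
      if (!any(dir_k)) next
      pick <- sites[sample.int(length(sites), sum(dir_k), replace = TRUE)]
      site_row[chim[rows_k[dir_k]]] <- pick
    }
    ## site-directed fragments: cover the whole designed site, with random
    ## extra context split around it
    d_idx <- chim[!is.na(site_row[chim])]
    if (length(d_idx)) {
      sr <- site_row[d_idx]
      s_start <- truth$start[sr]; s_end <- truth$end[sr]
      s_tx <- truth$transcript_id[sr]
      txlen <- tx$length[match(s_tx, tx$transcript_id)]
      fl <- pmax(flen[match(d_idx, chim)], s_end - s_start)
      extra <- fl - (s_end - s_start)
      off <- floor(stats::runif(length(d_idx)) * (extra + 1L))
      fs <- pmax(0L, s_start - off)
      fe <- pmin(txlen, fs + fl)
      frag_tx[d_idx] <- s_tx; frag_start[d_idx] <- fs; frag_end[d_idx] <- fe
      truth$expected_chimeras <- truth$expected_chimeras +
        tabulate(sr, nbins = nrow(truth))
    }
    ## background fragments from random transcript windows
    r_idx <- chim[is.na(site_row[chim])]
    if (length(r_idx)) {
      ti <- sample.int(nrow(reg_tx), length(r_idx), replace = TRUE)
      txlen <- reg_tx$length[ti]
      fl <- pmin(flen[match(r_idx, chim)], txlen)
      fs <- floor(stats::runif(length(r_idx)) * (txlen - fl + 1L))
      frag_tx[r_idx] <- reg_tx$transcript_id[ti]
      frag_start[r_idx] <- fs; frag_end[r_idx] <- fs + fl
    }
  }
  cont <- which(kind == "contaminant")
  if (length(cont)) {
    cr <- config$contaminant_frag_range
    ti <- sample.int(nrow(sno_tx), length(cont), replace = TRUE)
    txlen <- sno_tx$length[ti]
    fl <- pmin(sample(cr[1]:cr[2], length(cont), replace = TRUE), txlen)
    fs <- floor(stats::runif(length(cont)) * (txlen - fl + 1L))
    frag_tx[cont] <- sno_tx$transcript_id[ti]
    frag_start[cont] <- fs; frag_end[cont] <- fs + fl
  }

  frag_seq <- rep("", n)
  has_frag <- !is.na(frag_tx)
  frag_seq[has_frag] <- substring(transcriptome$sequences[frag_tx[has_frag]],
                                  frag_start[has_frag] + 1L, frag_end[has_frag])

  mirna_dna <- as_dna(catalog$sequence)
  payload <- ifelse(kind == "contaminant", frag_seq,
                    paste0(mirna_dna[mirna_idx], frag_seq))

  umi <- do.call(paste0, as.data.frame(
    matrix(sample(DNA_BASES, n * config$umi_length, replace = TRUE),
           nrow = n), stringsAsFactors = FALSE))
  reads <- paste0(umi, payload, config$adapter_sequence)

  if (config$sequencing_error_rate > 0) {
    nch <- nchar(reads)
    nerr <- stats::rbinom(n, nch, config$sequencing_error_rate)
    for (i in which(nerr > 0L)) {
      for (p in sample.int(nch[i], nerr[i])) {
        old <- substr(reads[i], p, p)
        substr(reads[i], p, p) <- sample(setdiff(DNA_BASES, old), 1L)
      }
    }
  }

  read_id <- sprintf("r%07d", seq_len(n))
  list(reads = data.frame(read_id = read_id, sequence = reads, stringsAsFactors = FALSE),
       read_truth = data.frame(read_id = read_id, kind = kind,
                               mirna_id = ifelse(is.na(mirna_idx), NA_character_,
                                                 catalog$id[mirna_idx]),
                               transcript_id = frag_tx,
                               start = frag_start, end = frag_end,
                               stringsAsFactors = FALSE),
       truth = truth)
}
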