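# Site assembly: mapped chimeras -> clustered, annotated target sites.

#' Cluster mapped chimeras into candidate target sites
#'
#' Per transcript, merges chimera target intervals whose gap is at most
#' \code{merge_gap} (default 0: only touching/overlapping intervals
#' merge) into cluster cores, then extends each core by
#' \code{extend_5p} nt at its 5' end (clipped at the transcript start).
#' The 5' extension exists because the 3'-supplementary pairing of a
#' TDMD trigger lies 5' of the seed match on the target, so a cluster
#' built from seed-anchored fragments can miss part of the pairing
#' region.
#'
#' @param mapped Data.frame of mapped chimeras (deduplicated), with
#'   columns \code{transcript_id}, \code{start}, \code{end},
#'   \code{mirna_id}.
#' @param transcriptome A \code{transcriptome} object (used for bounds
#'   checking and clipping).
#' @param merge_gap Maximum gap (nt) between intervals merged into one
#'   cluster.
#' @param extend_5p 5' extension (nt) of the core interval.
#' @return A list of class \code{site_clusters}: \code{clusters}
#'   (data.frame \code{cluster_id}, \code{transcript_id},
#'   \code{core_start}, \code{core_end}, \code{ext_start},
#'   \code{ext_end}; 0-based half-open), \code{support} (long data.frame
#'   \code{cluster_id}, \code{mirna_id}, \code{n}), and
#'   \code{assignment} (per input chimera, its \code{cluster_id}).
#' @export
cluster_sites <- function(mapped, transcriptome, merge_gap = 0L, extend_5p = 10L) {
  tx_ids <- transcriptome$transcripts$transcript_id
  if (nrow(mapped)) {
    unknown <- setdiff(unique(mapped$transcript_id), tx_ids)
    if (length(unknown))
      data_error(paste("chimeras reference unknown transcript(s):",
                       paste(unknown, collapse = ", ")))
  }
  empty <- list(
    clusters = data.frame(cluster_id = character(), transcript_id = character(),
                          core_start = integer(), core_end = integer(),
                          ext_start = integer(), ext_end = integer(),
                          stringsAsFactors = FALSE),
    support = data.frame(cluster_id = character(), mirna_id = character(),
                         n = integer(), stringsAsFactors = FALSE),
    assignment = character(0))
  if (nrow(mapped) == 0L) return(structure(empty, class = "site_clusters"))

  gr <- GenomicRanges::GRanges(mapped$transcript_id,
                               IRanges::IRanges(mapped$start + 1L, mapped$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap + 1L)
  red <- GenomicRanges::sort(red)
  ov <- GenomicRanges::findOverlaps(gr, red)
  stopifnot(length(ov) == nrow(mapped))  # every chimera in exactly one cluster

  cl_tx <- as.character(GenomicRanges::seqnames(red))
  core_start <- GenomicRanges::start(red) - 1L
  core_end <- GenomicRanges::end(red)
  cluster_id <- sprintf("%s:%d-%d", cl_tx, core_start, core_end)

  clusters <- data.frame(cluster_id = cluster_id, transcript_id = cl_tx,
                         core_start = core_start, core_end = core_end,
                         ext_start = pmax(0L, core_start - as.integer(extend_5p)),
                         ext_end = core_end, stringsAsFactors = FALSE)

  assignment <- cluster_id[S4Vectors::subjectHits(ov)]
  supp <- stats::aggregate(list(n = seq_len(nrow(mapped))),
                           by = list(cluster_id = assignment, mirna_id = mapped$mirna_id),
                           FUN = length)
  supp <- supp[order(supp$cluster_id, supp$mirna_id), ]
  rownames(supp) <- NULL
  structure(list(clusters = clusters, support = supp, assignment = assignment),
            class = "site_clusters")
}

#' Assign a transcript region label to an interval
#'
#' Returns the label of the transcript segment with the largest overlap
#' with the interval; exact ties are broken by the priority
#' 3UTR > 5UTR > ncRNA_exon > CDS (regions in which a trigger is more
#' plausible win).
#'
#' @param start,end Interval in 0-based half-open transcript coordinates.
#' @param segments Segment table for one transcript (columns
#'   \code{segment_label}, \code{start}, \code{end}).
#' @return A single label.
#' @export
annotate_region <- function(start, end, segments) {
  ov <- pmin(end, segments$end) - pmax(start, segments$start)
  ov[ov < 0L] <- 0L
  prio <- match(segments$segment_label, c("3UTR", "5UTR", "ncRNA_exon", "CDS"))
  best <- order(-ov, prio)[1]
  if (ov[best] == 0L && end > start) {
    ## interval outside every segment: malformed transcript model
    data_error(sprintf("interval [%d,%d) overlaps no segment", start, end))
  }
  segments$segment_label[best]
}

#' Annotate clusters with transcript region labels
#'
#' @param clusters A \code{site_clusters} object.
#' @param transcriptome A \code{transcriptome} object.
#' @return \code{clusters} with a \code{region_label} column added to
#'   \code{$clusters} (largest overlap of the core interval; see
#'   [annotate_region()]).
#' @export
annotate_regions <- function(clusters, transcriptome) {
  cl <- clusters$clusters
  seg_split <- split(transcriptome$segments, transcriptome$segments$transcript_id)
  cl$region_label <- vapply(seq_len(nrow(cl)), function(i) {
    annotate_region(cl$core_start[i], cl$core_end[i], seg_split[[cl$transcript_id[i]]])
  }, character(1))
  clusters$clusters <- cl
  clusters
}

#' Per-miRNA chimera statistics
#'
#' Summarizes the mapped, deduplicated chimeras per miRNA: chimera
#' count, chimeras-per-million (count / total chimeras x 1e6), the
#' fraction of its chimeras whose extended cluster contains a canonical
#' seed match for that miRNA, and the transcript-region breakdown of the
#' seed-matched chimeras (the region convention restricts the breakdown
#' to chimeras with a 6mer-or-better predicted seed pairing).
#'
#' @param mapped Deduplicated mapped chimeras.
#' @param clusters Output of [cluster_sites()] on \code{mapped}, after
#'   [annotate_regions()].
#' @param catalog miRNA catalog.
#' @param transcriptome A \code{transcriptome} object.
#' @return A data.frame with one row per catalog miRNA: \code{mirna_id},
#'   \code{n_chimeras}, \code{cpm}, \code{seed_match_fraction}, and one
#'   \code{frac_<region>} column per region label (fractions over
#'   seed-matched chimeras; 0 when there are none).
#' @export
chimera_stats <- function(mapped, clusters, catalog, transcriptome) {
  cl <- clusters$clusters
  if (is.null(cl$region_label) && nrow(cl))
    clusters <- annotate_regions(clusters, transcriptome)
  cl <- clusters$clusters
  regions <- c("5UTR", "CDS", "3UTR", "ncRNA_exon")
  total <- nrow(mapped)

  ## does cluster x miRNA have a seed hit in the extended window?
  key <- unique(data.frame(cluster_id = clusters$assignment,
                           mirna_id = mapped$mirna_id, stringsAsFactors = FALSE))
  has_seed <- logical(nrow(key))
  if (nrow(key)) {
    ci <- match(key$cluster_id, cl$cluster_id)
    for (i in seq_len(nrow(key))) {
      tx <- cl$transcript_id[ci[i]]
      win <- subseq0(transcriptome$sequences[[tx]], cl$ext_start[ci[i]], cl$ext_end[ci[i]])
      mseq <- catalog$sequence[match(key$mirna_id[i], catalog$id)]
      has_seed[i] <- nrow(locate_seed_sites(mseq, win)) > 0L
    }
  }

  out <- do.call(rbind, lapply(catalog$id, function(id) {
    rows <- which(mapped$mirna_id == id)
    nch <- length(rows)
    if (nch == 0L) {
      r <- data.frame(mirna_id = id, n_chimeras = 0L, cpm = 0,
                      seed_match_fraction = 0, stringsAsFactors = FALSE)
      for (rg in regions) r[[paste0("frac_", rg)]] <- 0
      return(r)
    }
    cid <- clusters$assignment[rows]
    sm <- has_seed[match(paste(cid, id), paste(key$cluster_id, key$mirna_id))]
    r <- data.frame(mirna_id = id, n_chimeras = nch,
                    cpm = nch / total * 1e6,
                    seed_match_fraction = mean(sm), stringsAsFactors = FALSE)
    reg <- cl$region_label[match(cid[sm], cl$cluster_id)]
    for (rg in regions)
      r[[paste0("frac_", rg)]] <- if (any(sm)) mean(reg == rg) else 0
    r
  }))
  rownames(out) <- NULL
  out
}
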