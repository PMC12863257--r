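# Fixture file I/O.  All on-disk coordinates are 0-based half-open
# (BED/bedGraph convention); annotation and truth tables are plain TSV.

write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  na.strings = "NA", ...))
}

#' Write a complete fixture set for one simulated experiment
#'
#' Emits the six files that define a synthetic AGO-CLASH experiment:
#' miRNA FASTA (RNA, with catalog flags in the description), transcript
#' FASTA (DNA), a tab-separated transcript-space annotation
#' (\code{transcript_id, gene_id, biotype, segment_label, start, end}),
#' a per-base conservation bedGraph, the reads FASTQ (Phred+33, constant
#' quality \code{"I"}), and the realized-site truth TSV.  Re-reading with
#' [read_fixtures()] reproduces the in-memory objects exactly.
#'
#' @param sim A list with elements \code{catalog}, \code{transcriptome},
#'   \code{truth} and \code{reads} (as produced by the generator stack).
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the file paths.
#' @export
write_fixtures <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) data_error(sprintf("cannot create fixture directory %s", dir))
  paths <- c(mirnas = file.path(dir, "mirnas.fa"),
             transcripts = file.path(dir, "transcripts.fa"),
             annotation = file.path(dir, "annotation.tsv"),
             conservation = file.path(dir, "conservation.bedGraph"),
             reads = file.path(dir, "reads.fastq"),
             truth = file.path(dir, "truth.tsv"))

  cat_df <- sim$catalog
  mir <- Biostrings::RNAStringSet(cat_df$sequence)
  names(mir) <- sprintf("%s probe_enriched=%d zswim8_regulated=%d", cat_df$id,
                        as.integer(cat_df$probe_enriched),
                        as.integer(cat_df$zswim8_regulated))
  Biostrings::writeXStringSet(mir, paths[["mirnas"]])

  txo <- sim$transcriptome
  txs <- Biostrings::DNAStringSet(unname(txo$sequences))
  names(txs) <- names(txo$sequences)
  Biostrings::writeXStringSet(txs, paths[["transcripts"]])

  ann <- merge(txo$segments,
               txo$transcripts[, c("transcript_id", "gene_id", "biotype")],
               by = "transcript_id", sort = FALSE)
  ann <- ann[order(match(ann$transcript_id, txo$transcripts$transcript_id), ann$start),
             c("transcript_id", "gene_id", "biotype", "segment_label", "start", "end")]
  write_tsv(ann, paths[["annotation"]])

  cons <- txo$conservation
  gr <- GenomicRanges::GRanges(
    seqnames = rep(names(cons), lengths(cons)),
    ranges = IRanges::IRanges(start = unlist(lapply(cons, seq_along), use.names = FALSE),
                              width = 1L),
    score = unlist(cons, use.names = FALSE))
  rtracklayer::export(gr, paths[["conservation"]], format = "bedGraph")

  reads <- sim$reads
  if (nrow(reads)) {
    rs <- Biostrings::DNAStringSet(reads$sequence)
    names(rs) <- reads$read_id
    qual <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
    Biostrings::writeXStringSet(rs, paths[["reads"]], format = "fastq", qualities = qual)
  } else {
    file.create(paths[["reads"]])
  }

  write_tsv(sim$truth, paths[["truth"]])
  invisible(paths)
}

#' Read a fixture directory back into memory
#'
#' Inverse of [write_fixtures()].
#'
#' @param dir Fixture directory.
#' @return A list with \code{catalog}, \code{transcriptome},
#'   \code{truth} and \code{reads}, in the same shapes the generator
#'   produces.
#' @export
read_fixtures <- function(dir) {
  need <- file.path(dir, c("mirnas.fa", "transcripts.fa", "annotation.tsv",
                           "conservation.bedGraph", "reads.fastq", "truth.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) data_error(paste("missing fixture file(s):", paste(missing, collapse = ", ")))

  mir <- Biostrings::readRNAStringSet(need[1])
  hdr <- strsplit(names(mir), " ", fixed = TRUE)
  flag <- function(i, key) {
    v <- grep(paste0("^", key, "="), hdr[[i]], value = TRUE)
    if (length(v)) sub(".*=", "", v[1]) == "1" else FALSE
  }
  catalog <- data.frame(
    id = vapply(hdr, `[[`, character(1), 1L),
    sequence = unname(as.character(mir)),
    probe_enriched = vapply(seq_along(hdr), flag, logical(1), key = "probe_enriched"),
    zswim8_regulated = vapply(seq_along(hdr), flag, logical(1), key = "zswim8_regulated"),
    stringsAsFactors = FALSE)
  rownames(catalog) <- NULL

  txs <- Biostrings::readDNAStringSet(need[2])
  sequences <- stats::setNames(unname(as.character(txs)),
                               vapply(strsplit(names(txs), " "), `[[`, character(1), 1L))

  ann <- read_tsv(need[3])
  transcripts <- unique(ann[, c("transcript_id", "gene_id", "biotype")])
  transcripts$length <- unname(nchar(sequences[transcripts$transcript_id]))
  rownames(transcripts) <- NULL
  segments <- ann[, c("transcript_id", "segment_label", "start", "end")]

  bg <- rtracklayer::import(need[4], format = "bedGraph")
  bgdf <- data.frame(st = GenomicRanges::start(bg), en = GenomicRanges::end(bg),
                     sc = bg$score)
  by_tx <- split(bgdf, as.character(GenomicRanges::seqnames(bg)))
  conservation <- lapply(stats::setNames(nm = names(sequences)), function(id) {
    v <- numeric(nchar(sequences[[id]]))
    d <- by_tx[[id]]
    if (!is.null(d)) {
      ## expand (possibly run-length-compressed) intervals to per-base values
      w <- d$en - d$st + 1L
      v[sequence(w, from = d$st)] <- rep(d$sc, w)
    }
    v
  })

  reads <- if (file.size(need[5]) > 0) {
    rf <- Biostrings::readDNAStringSet(need[5], format = "fastq")
    data.frame(read_id = names(rf), sequence = unname(as.character(rf)),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(read_id = character(), sequence = character(), stringsAsFactors = FALSE)
  }

  truth <- read_tsv(need[6])
  list(catalog = catalog,
       transcriptome = structure(list(transcripts = transcripts, segments = segments,
                                      sequences = sequences, conservation = conservation),
                                 class = "transcriptome"),
       truth = truth,
       reads = reads)
}
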