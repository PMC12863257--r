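# Pipeline orchestration: simulate -> process -> nominate -> evaluate,
# as plain functions over a working directory, plus a thin subcommand
# CLI (exit codes: 0 ok, 1 data error, 2 usage/config error).

#' Simulate a complete fixture set into a directory
#'
#' @param dir Output directory.
#' @param config A [synthetic_config()].
#' @param site_specs Site architectures to embed; defaults to
#'   [default_site_specs()] (three true triggers, five decoys).
#' @param include_known Passed to [build_mirna_catalog()].
#' @return Invisibly, a list with the in-memory objects (\code{catalog},
#'   \code{transcriptome}, \code{truth}, \code{reads},
#'   \code{read_truth}) and the fixture \code{paths}.
#' @export
run_simulate <- function(dir, config = synthetic_config(), site_specs = NULL,
                         include_known = NULL) {
  catalog <- build_mirna_catalog(config, include_known)
  specs <- site_specs %||% default_site_specs(catalog)
  bt <- build_transcriptome(catalog, specs, config)
  sim <- simulate_reads(bt$transcriptome, catalog, bt$truth, config)
  paths <- write_fixtures(list(catalog = catalog, transcriptome = bt$transcriptome,
                               truth = sim$truth, reads = sim$reads), dir)
  message(sprintf("simulate: %d miRNAs, %d transcripts, %d sites, %d reads -> %s",
                  nrow(catalog), nrow(bt$transcriptome$transcripts),
                  nrow(sim$truth), nrow(sim$reads), dir))
  invisible(list(catalog = catalog, transcriptome = bt$transcriptome,
                 truth = sim$truth, reads = sim$reads,
                 read_truth = sim$read_truth, paths = paths))
}

#' Process the reads of a fixture directory into mapped chimeras
#'
#' Writes \code{chimeras.tsv} (deduplicated mapped chimeras) and
#' \code{fate_summary.tsv} (one row per read fate, counts summing to the
#' input read count) next to the fixtures.
#'
#' @param dir Fixture directory.
#' @param config A [process_config()].
#' @param fixtures Optional in-memory fixture list (as returned by
#'   [read_fixtures()]); when supplied, the directory is only used for
#'   outputs.
#' @return Invisibly, the [process_reads()] result.
#' @export
run_process <- function(dir, config = process_config(), fixtures = NULL) {
  fx <- fixtures %||% tryCatch(read_fixtures(dir), error = function(e)
    data_error(sprintf("cannot read fixtures in %s: %s", dir, conditionMessage(e))))
  pr <- process_reads(fx$reads, fx$catalog, fx$transcriptome, config)
  chim <- pr$chimeras[, c("read_id", "umi", "mirna_id", "transcript_id",
                          "start", "end", "mapping_mismatches")]
  names(chim)[7] <- "mismatches"
  write_tsv(chim, file.path(dir, "chimeras.tsv"))
  write_tsv(pr$fate_summary, file.path(dir, "fate_summary.tsv"))
  for (i in seq_len(nrow(pr$fate_summary)))
    message(sprintf("process: %s = %d", pr$fate_summary$fate[i], pr$fate_summary$n[i]))
  invisible(pr)
}

#' Cluster, filter and rank candidates from processed chimeras
#'
#' Writes \code{clusters.tsv} (cluster geometry, region label and
#' per-miRNA support), \code{candidates.tsv} (the filtered and ranked
#' candidate table) and \code{filter_summary.tsv} (candidate counts
#' entering and failing each criterion).
#'
#' @param dir Fixture directory already processed by [run_process()].
#' @param config A [filter_config()].
#' @param fixtures Optional in-memory fixture list.
#' @return Invisibly, a list with \code{clusters}, \code{candidates} and
#'   \code{filter_summary}.
#' @export
run_nominate <- function(dir, config = filter_config(), fixtures = NULL) {
  fx <- fixtures %||% read_fixtures(dir)
  chim_path <- file.path(dir, "chimeras.tsv")
  if (!file.exists(chim_path)) data_error(sprintf("no chimeras.tsv in %s; run process first", dir))
  chim <- read_tsv(chim_path)

  clusters <- cluster_sites(chim, fx$transcriptome)
  clusters <- annotate_regions(clusters, fx$transcriptome)
  candidates <- find_candidates(clusters, fx$catalog, fx$transcriptome, config)
  candidates <- nominate(candidates, config)

  ## wide cluster report: geometry + one support column per miRNA
  cl <- clusters$clusters
  for (id in fx$catalog$id) {
    s <- clusters$support[clusters$support$mirna_id == id, ]
    cl[[id]] <- s$n[match(cl$cluster_id, s$cluster_id)]
    cl[[id]][is.na(cl[[id]])] <- 0L
  }
  write_tsv(cl[, setdiff(names(cl), "cluster_id")], file.path(dir, "clusters.tsv"))
  write_candidate_table(candidates, file.path(dir, "candidates.tsv"))

  fs <- data.frame(stage = c("candidates_total", paste0("fail_", c("C1", "C2", "C3", "C4", "C5")),
                             "survivors"),
                   n = c(nrow(candidates),
                         vapply(c("C1", "C2", "C3", "C4", "C5"),
                                function(cc) sum(!candidates[[cc]]), integer(1)),
                         sum(!is.na(candidates$rank))),
                   stringsAsFactors = FALSE)
  write_tsv(fs, file.path(dir, "filter_summary.tsv"))
  for (i in seq_len(nrow(fs))) message(sprintf("nominate: %s = %d", fs$stage[i], fs$n[i]))
  invisible(list(clusters = clusters, candidates = candidates, filter_summary = fs))
}

#' Evaluate nominated candidates against the simulation truth
#'
#' Writes \code{recovery.json} (top-1 recovery and per-site outcomes)
#' and \code{recovery_sites.tsv}.
#'
#' @param dir Fixture directory already processed by [run_nominate()].
#' @param fixtures Optional in-memory fixture list.
#' @return Invisibly, the [evaluate_recovery()] result.
#' @export
run_evaluate <- function(dir, fixtures = NULL) {
  fx <- fixtures %||% read_fixtures(dir)
  cand_path <- file.path(dir, "candidates.tsv")
  if (!file.exists(cand_path)) data_error(sprintf("no candidates.tsv in %s; run nominate first", dir))
  candidates <- read_candidate_table(cand_path)
  known_tx <- fx$transcriptome$transcripts$transcript_id
  bad <- setdiff(unique(c(candidates$transcript, fx$truth$transcript_id)), known_tx)
  if (length(bad))
    data_error(paste("identifier mismatch between candidates/truth and transcriptome:",
                     paste(bad, collapse = ", ")))
  if (nrow(fx$truth) &&
      !all(fx$truth$mirna_id %in% fx$catalog$id))
    data_error("truth manifest references miRNAs absent from the catalog")
  rec <- evaluate_recovery(candidates, fx$truth)
  jsonlite::write_json(list(top1_recovery = rec$top1_recovery, n_true = rec$n_true),
                       file.path(dir, "recovery.json"), auto_unbox = TRUE, digits = NA)
  write_tsv(rec$sites, file.path(dir, "recovery_sites.tsv"))
  message(sprintf("evaluate: top-1 recovery %.3f over %d true triggers",
                  rec$top1_recovery, rec$n_true))
  invisible(rec)
}

#' Run the full pipeline end to end
#'
#' @param dir Working directory for fixtures and reports.
#' @param synthetic,process,filter Stage configurations.
#' @param site_specs Optional site architectures (defaults to
#'   [default_site_specs()]).
#' @return Invisibly, a list with \code{sim}, \code{processed},
#'   \code{nominated} and \code{recovery}.
#' @export
run_pipeline <- function(dir, synthetic = synthetic_config(),
                         process = process_config(), filter = filter_config(),
                         site_specs = NULL) {
  sim <- run_simulate(dir, synthetic, site_specs)
  fx <- list(catalog = sim$catalog, transcriptome = sim$transcriptome,
             truth = sim$truth, reads = sim$reads)
  pr <- run_process(dir, process, fixtures = fx)
  nom <- run_nominate(dir, filter, fixtures = fx)
  rec <- run_evaluate(dir, fixtures = fx)
  invisible(list(sim = sim, processed = pr, nominated = nom, recovery = rec))
}

## ---------------------------------------------------------------------
## flat key-value config file with [sections]

#' Read a pipeline configuration file
#'
#' Flat \code{key = value} format with \code{[synthetic]},
#' \code{[process]} and \code{[filter]} sections and \code{#} comments;
#' comma-separated values become vectors.  A fully commented default is
#' shipped at \code{system.file("extdata", "default_config.ini",
#' package = "tdmdscan")}.
#'
#' @param path Config file path.
#' @return A list with elements \code{synthetic}, \code{process} and
#'   \code{filter}, ready to pass to the stage constructors.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) usage_error(sprintf("config file not found: %s", path))
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  out <- list(synthetic = list(), process = list(), filter = list())
  section <- NULL
  for (l in ln) {
    if (grepl("^\\[.+\\]$", l)) {
      section <- sub("^\\[(.+)\\]$", "\\1", l)
      if (!section %in% names(out))
        usage_error(sprintf("unknown config section [%s]", section))
      next
    }
    if (!grepl("=", l, fixed = TRUE) || is.null(section))
      usage_error(sprintf("malformed config line: '%s'", l))
    key <- trimws(sub("=.*$", "", l))
    val <- trimws(sub("^[^=]*=", "", l))
    vals <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    parsed <- if (!anyNA(num)) num else vals
    out[[section]][[key]] <- parsed
  }
  out
}

#' Command-line entry point
#'
#' Thin subcommand wrapper over the pipeline stages, for use from the
#' shipped \code{Rscript} launcher (\code{system.file("scripts",
#' "tdmdscan", package = "tdmdscan")}):
#' \preformatted{
#'   tdmdscan simulate --dir DIR [--config FILE] [--seed N] [--reads-total N]
#'   tdmdscan process  --dir DIR [--config FILE]
#'   tdmdscan nominate --dir DIR [--config FILE] [--top-k N]
#'   tdmdscan evaluate --dir DIR
#' }
#' Flags override config-file keys.  Conventional exit codes: 0 ok,
#' 1 data error, 2 usage error.
#'
#' @param args Character vector of arguments (defaults to the process
#'   command line).
#' @return The exit status, invisibly.
#' @export
tdmd_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  run <- function() {
    if (length(args) < 1L)
      usage_error("usage: tdmdscan <simulate|process|nominate|evaluate> --dir DIR [options]")
    cmd <- args[[1]]
    rest <- args[-1]
    opts <- list()
    i <- 1L
    while (i <= length(rest)) {
      a <- rest[[i]]
      if (grepl("^--[a-z-]+=", a)) {
        opts[[sub("^--([a-z-]+)=.*$", "\\1", a)]] <- sub("^--[a-z-]+=", "", a)
        i <- i + 1L
      } else if (grepl("^--[a-z-]+$", a)) {
        if (i + 1L > length(rest)) usage_error(sprintf("flag %s needs a value", a))
        opts[[sub("^--", "", a)]] <- rest[[i + 1L]]
        i <- i + 2L
      } else usage_error(sprintf("unrecognized argument '%s'", a))
    }
    if (is.null(opts$dir)) usage_error("--dir is required")
    cfg <- if (!is.null(opts$config)) read_run_config(opts$config)
           else list(synthetic = list(), process = list(), filter = list())
    if (!is.null(opts$seed)) cfg$synthetic$rng_seed <- as.integer(opts$seed)
    if (!is.null(opts[["reads-total"]])) cfg$synthetic$reads_total <- as.integer(opts[["reads-total"]])
    if (!is.null(opts[["top-k"]])) cfg$filter$top_k <- as.integer(opts[["top-k"]])

    switch(cmd,
      simulate = run_simulate(opts$dir, do.call(synthetic_config, cfg$synthetic)),
      process = run_process(opts$dir, do.call(process_config, cfg$process)),
      nominate = run_nominate(opts$dir, do.call(filter_config, cfg$filter)),
      evaluate = run_evaluate(opts$dir),
      usage_error(sprintf("unknown subcommand '%s'", cmd)))
    0L
  }
  status <- tryCatch(run(),
    tdmd_usage_error = function(e) { message("error: ", conditionMessage(e)); 2L },
    tdmd_data_error = function(e) { message("error: ", conditionMessage(e)); 1L },
    error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
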