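# Synthetic-data generator: configs, catalogs, site realization, reads,
# fixture round trips.

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(rng_seed = 5, n_mirnas = 10, n_transcripts = 20,
         transcript_length_range = c(300, 600), reads_total = 5000),
    list(...))
  do.call(synthetic_config, args)
}

test_that("config validation names the offending field", {
  expect_error(synthetic_config(chimera_fraction = 1.2), "chimera_fraction")
  expect_error(synthetic_config(chimera_fraction = 0.6, contaminant_fraction = 0.6),
               "chimera_fraction")
  expect_error(synthetic_config(umi_length = 3), "umi_length")
  expect_error(synthetic_config(reads_total = -1), "reads_total")
  expect_error(synthetic_config(adapter_sequence = "AGAUCG"), "adapter_sequence")
})

test_that("miRNA catalogs are deterministic, valid RNA, and honor include_known", {
  cfg <- small_cfg()
  c1 <- build_mirna_catalog(cfg)
  c2 <- build_mirna_catalog(cfg)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 10L)
  expect_false(any(duplicated(c1$id)))
  expect_true(all(grepl("^[ACGU]+$", c1$sequence)))
  expect_true(all(nchar(c1$sequence) >= 20 & nchar(c1$sequence) <= 23))
  expect_true(any(c1$probe_enriched))

  single <- build_mirna_catalog(synthetic_config(rng_seed = 7, n_mirnas = 1))
  expect_equal(nrow(single), 1L)
  expect_true(nchar(single$sequence) >= 20 && nchar(single$sequence) <= 23)

  known <- build_mirna_catalog(small_cfg(),
                               include_known = "let-7a-5p:UGAGGUAGUAGGUUGUAUAGUU")
  expect_true("let-7a-5p" %in% known$id)
  expect_equal(known$sequence[known$id == "let-7a-5p"], "UGAGGUAGUAGGUUGUAUAGUU")
})

test_that("site specs validate the trigger invariants", {
  expect_error(site_spec("m1", seed_class = "none", is_true_trigger = TRUE), "true trigger")
  expect_error(site_spec("m1", region_label = "CDS", is_true_trigger = TRUE), "true trigger")
  expect_error(site_spec("m1", central_bulge_run = 8, is_true_trigger = TRUE), "true trigger")
  expect_error(site_spec("m1", three_prime_run = 5, is_true_trigger = TRUE), "true trigger")
  expect_error(site_spec("m1", three_prime_run = 14), "0..13")
  expect_error(site_spec("m1", seed_class = "9mer"), "seed_class")
})

test_that("realized sites reproduce their requested architecture through the
           package's own classifier and duplex engine", {
  cfg <- small_cfg()
  catalog <- build_mirna_catalog(cfg)
  specs <- default_site_specs(catalog)
  bt <- build_transcriptome(catalog, specs, cfg)
  truth <- bt$truth
  expect_equal(nrow(truth), length(specs))
  for (i in seq_len(nrow(truth))) {
    mseq <- catalog$sequence[match(truth$mirna_id[i], catalog$id)]
    L <- nchar(mseq)
    txseq <- bt$transcriptome$sequences[[truth$transcript_id[i]]]
    ws <- truth$seed_window_start[i]
    win <- substr(txseq, ws + 1, ws + 8)
    if (truth$seed_class[i] == "none") {
      site <- substr(txseq, truth$start[i] + 1, truth$end[i])
      expect_equal(nrow(locate_seed_sites(mseq, site)), 0L)
    } else {
      expect_equal(classify_seed(mseq, win), truth$seed_class[i])
    }
    aln <- predict_duplex(substring(mseq, 9, L),
                          substr(txseq, max(0, ws - 20) + 1, ws), mirna_start = 9L)
    expect_equal(max_unpaired_run_after_seed(aln), truth$central_bulge_run[i])
    expect_equal(max_pair_run(aln, region = c(L - 12, L)), truth$three_prime_run[i])
    # conservation sign over the pairing region
    cons <- bt$transcriptome$conservation[[truth$transcript_id[i]]]
    mu <- mean(cons[(truth$start[i] + 1):truth$end[i]])
    expect_true(abs(mu) >= 0.5)
    expect_equal(sign(mu), if (truth$conservation_sign[i] == "positive") 1 else -1)
  }
})

test_that("empty site specs give a siteless transcriptome and empty manifest", {
  cfg <- small_cfg()
  catalog <- build_mirna_catalog(cfg)
  bt <- build_transcriptome(catalog, list(), cfg)
  expect_equal(nrow(bt$truth), 0L)
})

test_that("unrealizable specs fail with an error identifying the spec", {
  cfg <- small_cfg()
  catalog <- build_mirna_catalog(cfg)
  bad <- site_spec(catalog$id[1], three_prime_run = 13, central_bulge_run = 12)
  expect_error(build_transcriptome(catalog, list(bad), cfg), catalog$id[1])
})

test_that("reads follow [UMI][miRNA][target][adapter] and empirical fractions
           match the binomial model", {
  cfg <- synthetic_config(rng_seed = 9, n_mirnas = 4, n_transcripts = 12,
                          transcript_length_range = c(300, 600),
                          reads_total = 20000, sequencing_error_rate = 0,
                          chimera_fraction = 0.1, contaminant_fraction = 0.05)
  catalog <- build_mirna_catalog(cfg)
  bt <- build_transcriptome(catalog, list(), cfg)
  sim <- simulate_reads(bt$transcriptome, catalog, bt$truth, cfg)
  expect_equal(nrow(sim$reads), 20000L)
  expect_true(all(nchar(sim$reads$sequence) > 10 + nchar(cfg$adapter_sequence)))
  expect_true(all(endsWith(sim$reads$sequence, cfg$adapter_sequence)))

  ## chimera fraction within 3 binomial standard errors
  p_hat <- mean(sim$read_truth$kind == "chimera")
  se <- sqrt(0.1 * 0.9 / 20000)
  expect_lt(abs(p_hat - 0.1), 3 * se)

  ## miRNA-only reads are UMI + miRNA + adapter exactly
  i <- which(sim$read_truth$kind == "mirna_only")[1]
  mid <- sim$read_truth$mirna_id[i]
  mdna <- chartr("U", "T", catalog$sequence[catalog$id == mid])
  expect_equal(substr(sim$reads$sequence[i], 11, 10 + nchar(mdna)), mdna)
})

test_that("probe enrichment skews chimera counts by the configured factor", {
  cfg <- synthetic_config(rng_seed = 13, n_mirnas = 2, n_transcripts = 10,
                          transcript_length_range = c(300, 600),
                          reads_total = 50000, chimera_fraction = 0.5,
                          enrichment_factor = 8, contaminant_fraction = 0,
                          sequencing_error_rate = 0)
  catalog <- build_mirna_catalog(cfg)   # miRNA 1 enriched, miRNA 2 not
  expect_equal(catalog$probe_enriched, c(TRUE, FALSE))
  bt <- build_transcriptome(catalog, list(), cfg)
  sim <- simulate_reads(bt$transcriptome, catalog, bt$truth, cfg)
  ch <- sim$read_truth[sim$read_truth$kind == "chimera", ]
  nA <- sum(ch$mirna_id == catalog$id[1]); nB <- sum(ch$mirna_id == catalog$id[2])
  ## A ~ Binom(n, 8/9): compare observed enriched fraction with 3 SEs
  p0 <- 8 / 9
  se <- sqrt(p0 * (1 - p0) / (nA + nB))
  expect_lt(abs(nA / (nA + nB) - p0), 3 * se)
})

test_that("reads_total = 0 yields an empty library without error", {
  cfg <- small_cfg(reads_total = 0)
  catalog <- build_mirna_catalog(cfg)
  bt <- build_transcriptome(catalog, list(), cfg)
  sim <- simulate_reads(bt$transcriptome, catalog, bt$truth, cfg)
  expect_equal(nrow(sim$reads), 0L)
  expect_equal(nrow(sim$read_truth), 0L)
})

test_that("fixtures round-trip exactly and are byte-identical under a fixed seed", {
  cfg <- synthetic_config(rng_seed = 21, n_mirnas = 8, n_transcripts = 10,
                          transcript_length_range = c(300, 500), reads_total = 500)
  catalog <- build_mirna_catalog(cfg)
  bt <- build_transcriptome(catalog, default_site_specs(catalog), cfg)
  sim <- simulate_reads(bt$transcriptome, catalog, bt$truth, cfg)
  obj <- list(catalog = catalog, transcriptome = bt$transcriptome,
              truth = sim$truth, reads = sim$reads)

  d1 <- file.path(tempfile(), "fx1")  # nested, non-existing: must be created
  paths <- write_fixtures(obj, d1)
  expect_true(all(file.exists(paths)))
  expect_length(paths, 6L)

  back <- read_fixtures(d1)
  expect_equal(back$catalog, obj$catalog)
  expect_equal(back$transcriptome$sequences, obj$transcriptome$sequences)
  expect_equal(back$transcriptome$segments, obj$transcriptome$segments)
  expect_equal(back$transcriptome$transcripts, obj$transcriptome$transcripts)
  expect_equal(back$transcriptome$conservation, obj$transcriptome$conservation)
  expect_equal(back$truth, obj$truth)
  expect_equal(back$reads, obj$reads)

  ## per-base conservation: one data line per transcript base
  bg <- readLines(paths[["conservation"]])
  bg <- bg[!grepl("^track", bg)]
  expect_equal(length(bg), sum(nchar(obj$transcriptome$sequences)))

  ## FASTQ line count = 4 x reads
  expect_equal(length(readLines(paths[["reads"]])), 4L * nrow(obj$reads))

  ## byte-identical regeneration under the same config
  d2 <- tempfile("fx2")
  catalog2 <- build_mirna_catalog(cfg)
  bt2 <- build_transcriptome(catalog2, default_site_specs(catalog2), cfg)
  sim2 <- simulate_reads(bt2$transcriptome, catalog2, bt2$truth, cfg)
  paths2 <- write_fixtures(list(catalog = catalog2, transcriptome = bt2$transcriptome,
                                truth = sim2$truth, reads = sim2$reads), d2)
  for (f in names(paths))
    expect_equal(unname(tools::md5sum(paths[[f]])), unname(tools::md5sum(paths2[[f]])),
                 info = f)
})
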