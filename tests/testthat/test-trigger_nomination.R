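# Criterion evaluation, ranking, candidate table I/O, recovery.

toy_candidates <- function() {
  # six candidates; exactly two pass all criteria
  base <- data.frame(
    mirna = "miR-x", gene = paste0("G", 1:6), transcript = paste0("T", 1:6),
    site_start = 0L, site_end = 28L, region = "3UTR", seed_class = "8mer",
    central_unpaired_run = 2L, three_prime_run = 9L,
    seed_cons_mean = 0.8, three_prime_cons_mean = 0.9,
    three_prime_mfe_kcal_mol = c(-18.2, -12.0, -9.1, -20.0, -15.0, -11.0),
    chimera_support = c(3L, 7L, 2L, 5L, 1L, 4L),
    C1 = TRUE, C2 = TRUE, C3 = TRUE, C4 = TRUE, C5 = TRUE,
    rank = NA_integer_, selected = FALSE, stringsAsFactors = FALSE)
  base$C1[3] <- FALSE  # seed failure
  base$C2[4] <- FALSE  # CDS-like failure
  base$C3[5] <- FALSE  # bulge failure
  base$C4[6] <- FALSE  # 3' run failure
  base                 # rows 1 and 2 survive
}

test_that("survivor ranking sorts by MFE with support then coordinates as tie-breaks", {
  cand <- toy_candidates()
  cand$C1 <- cand$C2 <- cand$C3 <- cand$C4 <- cand$C5 <- TRUE
  cand <- cand[1:3, ]
  cand$three_prime_mfe_kcal_mol <- c(-12.0, -18.2, -9.1)
  out <- nominate(cand, filter_config())
  surv <- out[!is.na(out$rank), ]
  expect_equal(surv$three_prime_mfe_kcal_mol[order(surv$rank)], c(-18.2, -12.0, -9.1))
  # equal MFE: higher support wins
  tie <- cand
  tie$three_prime_mfe_kcal_mol <- -10
  tie$chimera_support <- c(3L, 7L, 5L)
  out2 <- nominate(tie, filter_config())
  expect_equal(out2$chimera_support[out2$rank == 1], 7L)
  # equal MFE and support: lexicographic transcript
  tie$chimera_support <- 2L
  out3 <- nominate(tie, filter_config())
  expect_equal(out3$transcript[order(out3$rank)], c("T1", "T2", "T3"))
  # empty input is fine
  expect_equal(nrow(nominate(toy_candidates()[0, ], filter_config())), 0L)
})

test_that("the survivor set is invariant to the order criteria are applied", {
  cand <- toy_candidates()
  crit <- c("C1", "C2", "C3", "C4", "C5")
  set.seed(701)
  base_surv <- sort(cand$transcript[Reduce(`&`, lapply(crit, function(cc) cand[[cc]]))])
  expect_equal(base_surv, c("T1", "T2"))
  for (k in 1:10) {
    perm <- sample(crit)
    keep <- rep(TRUE, nrow(cand))
    for (cc in perm) keep <- keep & cand[[cc]]
    expect_equal(sort(cand$transcript[keep]), base_surv)
  }
  # nominate agrees
  out <- nominate(cand, filter_config())
  expect_equal(sort(out$transcript[!is.na(out$rank)]), base_surv)
  # ranks are 1..n without gaps and top_k selection is flagged
  expect_setequal(out$rank[!is.na(out$rank)], 1:2)
  expect_equal(sum(out$selected), 2L)
  out1 <- nominate(cand, filter_config(top_k = 1))
  expect_equal(sum(out1$selected), 1L)
})

test_that("evaluate_candidate computes flags from sequence, geometry and conservation", {
  set.seed(702)
  mir <- rand_rna(22)
  region <- substring(mir, 10, 22)
  flank <- chartr("ACGU", "UGCA", paste(rev(strsplit(region, "")[[1]]), collapse = ""))
  window <- paste0(chartr("ACGU", "UGCA",
                          paste(rev(strsplit(substring(mir, 2, 8), "")[[1]]), collapse = "")), "A")
  tx <- paste0(rand_dna(50), chartr("U", "T", flank), chartr("U", "T", window), rand_dna(30))
  ws <- 50L + 13L
  cons <- rep(1, nchar(tx))
  cand <- evaluate_candidate("m", mir, "T", "G", tx, cons, "3UTR", ws, 5L)
  expect_equal(cand$seed_class, "8mer")
  expect_true(all(unlist(cand[, c("C1", "C2", "C3", "C4", "C5")])))
  expect_equal(cand$three_prime_run, 13L)
  expect_lt(cand$three_prime_mfe_kcal_mol, -10)
  # negative conservation flips C5 only
  cand2 <- evaluate_candidate("m", mir, "T", "G", tx, -cons, "3UTR", ws, 5L)
  expect_false(cand2$C5)
  expect_true(all(unlist(cand2[, c("C1", "C2", "C3", "C4")])))
  # CDS region flips C2 only
  cand3 <- evaluate_candidate("m", mir, "T", "G", tx, cons, "CDS", ws, 5L)
  expect_false(cand3$C2)
  # missing conservation warns and fails C5 without crashing
  expect_warning(cand4 <- evaluate_candidate("m", mir, "T", "G", tx, NULL, "3UTR", ws, 5L),
                 "conservation")
  expect_false(cand4$C5)
})

test_that("candidate tables round-trip with two-decimal energies", {
  cand <- nominate(toy_candidates(), filter_config())
  path <- tempfile(fileext = ".tsv")
  write_candidate_table(cand, path)
  lines <- readLines(path)
  expect_equal(length(lines), nrow(cand) + 1L)
  expect_true(any(grepl("-18\\.20", lines)))  # two decimal places
  back <- read_candidate_table(path)
  expect_equal(back, cand)
  # empty table -> header-only file
  p2 <- tempfile(fileext = ".tsv")
  write_candidate_table(cand[0, ], p2)
  expect_equal(length(readLines(p2)), 1L)
  expect_equal(nrow(read_candidate_table(p2)), 0L)
})

test_that("recovery reports ranks for triggers and rejection criteria for decoys", {
  cand <- nominate(toy_candidates(), filter_config())
  truth <- data.frame(
    mirna_id = "miR-x", transcript_id = paste0("T", c(1, 3, 4, 5, 6, 9)),
    start = 0L, end = 28L, seed_window_start = 20L,
    is_true_trigger = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  rec <- evaluate_recovery(cand, truth)
  s <- rec$sites
  expect_equal(s$rank[s$transcript_id == "T1"], 1L)
  expect_equal(s$rejected_at[s$transcript_id == "T3"], "C1")
  expect_equal(s$rejected_at[s$transcript_id == "T4"], "C2")
  expect_equal(s$rejected_at[s$transcript_id == "T5"], "C3")
  expect_equal(s$rejected_at[s$transcript_id == "T6"], "C4")
  # a truth site with no candidate at all counts as a seed (C1) rejection
  expect_equal(s$rejected_at[s$transcript_id == "T9"], "C1")
  expect_equal(rec$top1_recovery, 1)
  # empty candidates -> zero recovery, no error
  rec0 <- evaluate_recovery(cand[0, ], truth)
  expect_equal(rec0$top1_recovery, 0)
})

test_that("fresh UMIs double support but change no criterion flags", {
  set.seed(703)
  cfg <- synthetic_config(rng_seed = 41, n_mirnas = 8, n_transcripts = 15,
                          transcript_length_range = c(300, 600), reads_total = 3000,
                          chimera_fraction = 0.15, sequencing_error_rate = 0)
  catalog <- build_mirna_catalog(cfg)
  bt <- build_transcriptome(catalog, default_site_specs(catalog), cfg)
  sim <- simulate_reads(bt$transcriptome, catalog, bt$truth, cfg)
  pr <- process_reads(sim$reads, catalog, bt$transcriptome)
  run_nom <- function(chim) {
    cl <- annotate_regions(cluster_sites(chim, bt$transcriptome), bt$transcriptome)
    nominate(find_candidates(cl, catalog, bt$transcriptome), filter_config())
  }
  base <- run_nom(pr$chimeras)
  # same UMIs duplicated: dedup upstream would remove them, so the table is
  # unchanged by construction; fresh UMIs double every support count
  dup <- pr$chimeras
  dup$read_id <- paste0("z", dup$read_id)
  dup$umi <- chartr("ACGT", "CAGT", dup$umi)
  doubled <- run_nom(dedup_chimeras(rbind(pr$chimeras, dup)))
  key <- function(df) paste(df$mirna, df$transcript, df$site_end)
  m <- match(key(base), key(doubled))
  expect_false(any(is.na(m)))
  expect_equal(doubled$chimera_support[m], 2L * base$chimera_support)
  for (cc in c("C1", "C2", "C3", "C4", "C5"))
    expect_equal(doubled[[cc]][m], base[[cc]], info = cc)
})
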