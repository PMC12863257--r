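# Read processing: UMI, adapter, contaminants, miRNA calling, mapping,
# deduplication, and the pipeline-conservation invariants.

test_that("UMI extraction splits the prefix and flags short reads", {
  ex <- extract_umi("ACGTACGTACTTTT", 10)
  expect_equal(ex$umi, "ACGTACGTAC")
  expect_equal(ex$remainder, "TTTT")
  ex0 <- extract_umi("ACGTACGTAC", 0)
  expect_equal(ex0$umi, "")
  expect_equal(ex0$remainder, "ACGTACGTAC")
  exs <- extract_umi("ACGTACGTA", 10)  # 9 nt < UMI
  expect_true(is.na(exs$umi))
})

test_that("adapter trimming follows the overlap/mismatch-rate rule", {
  expect_equal(trim_adapter("AAAAGATCGGA", "GATCGGAAGAG"), "AAAA")
  expect_equal(trim_adapter("AAAA", "GATC"), "AAAA")
  # terminal "GA" is below min_overlap, so the read is kept whole
  expect_equal(trim_adapter("AAAAGA", "GATC", min_overlap = 3), "AAAAGA")
  # full internal occurrence truncates at its start, discarding the tail
  expect_equal(trim_adapter("CCCCGATCGGAAGAGTTTT", "GATCGGAAGAG"), "CCCC")
  # one mismatch in a full-length occurrence is within the 0.1 rate
  expect_equal(trim_adapter("CCCCGATCGGAACAG", "GATCGGAAGAG"), "CCCC")
  # but a mismatch in a short overlap is not (floor(0.1 * 5) = 0)
  expect_equal(trim_adapter("CCCCCCGATCG", "GATCGGAAGAG"),
               trim_adapter_ref("CCCCCCGATCG", "GATCGGAAGAG"))
})

test_that("vectorized trimming agrees with the literal scalar rule on random reads", {
  set.seed(501)
  adapter <- "AGATCGGAAGAGC"
  reads <- vapply(1:300, function(i) {
    core <- rand_dna(sample(5:40, 1))
    r <- switch(sample(3, 1),
                paste0(core, adapter),                       # full adapter
                paste0(core, substr(adapter, 1, sample(0:12, 1))),  # partial
                core)                                        # none
    # sprinkle mutations
    if (runif(1) < 0.5 && nchar(r) > 0) {
      p <- sample(nchar(r), 1)
      substr(r, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    r
  }, character(1))
  got <- trim_adapter(reads, adapter)
  ref <- vapply(reads, trim_adapter_ref, character(1), adapter = adapter,
                USE.NAMES = FALSE)
  expect_equal(got, ref)
  # re-trimming agrees with the scalar rule applied afresh (a trimmed core
  # can itself end in adapter-prefix-like bases, which the single-pass
  # rule then legitimately removes, so strict idempotence is not implied)
  expect_equal(trim_adapter(got, adapter),
               vapply(got, trim_adapter_ref, character(1), adapter = adapter,
                      USE.NAMES = FALSE))
})

test_that("contaminant screening is exact against a brute-force scan", {
  set.seed(502)
  contams <- vapply(1:4, function(i) rand_dna(120), character(1))
  expect_false(any(is_contaminant(c("ACGT", rand_dna(30)), character(0))))
  # exact subsequence is dropped
  frag <- substr(contams[2], 31, 60)
  expect_true(is_contaminant(frag, contams))
  # randomized cases incl. 0/1/2-mismatch fragments and random reads
  reads <- character(0)
  for (i in 1:120) {
    if (runif(1) < 0.6) {
      cs <- sample(contams, 1)
      l <- sample(15:60, 1)
      p <- sample(nchar(cs) - l + 1, 1)
      r <- substr(cs, p, p + l - 1)
      nmut <- sample(0:2, 1)
      for (q in sample(l, nmut)) {
        old <- substr(r, q, q)
        substr(r, q, q) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      }
      reads <- c(reads, r)
    } else reads <- c(reads, rand_dna(sample(15:60, 1)))
  }
  got <- is_contaminant(reads, contams, max_mismatches = 1)
  ref <- vapply(reads, is_contaminant_ref, logical(1), contaminants = contams,
                max_mismatches = 1, USE.NAMES = FALSE)
  expect_equal(got, ref)
})

test_that("miRNA segment calling prefers length then mismatches and flags ties", {
  catalog <- data.frame(
    id = c("mirA", "mirB", "mirC"),
    sequence = c("UGAGGUAGUAGGUUGUAUAGUU",        # 22 nt
                 "ACCCGUAGAUCCGAACUUGUGA",        # 22 nt
                 "ACCCGUAGAUCCGAACUUGU"),         # 20 nt, prefix of B's first 20
    stringsAsFactors = FALSE)
  tail <- "CTACCTCAGTTACGTACGTAC"
  read <- paste0("TGAGGTAGTAGGTTGTATAGTT", tail)
  out <- call_mirna_segment(read, catalog)
  expect_equal(out$status, "chimera")
  expect_equal(out$mirna_id, "mirA")
  expect_equal(out$mirna_matched_len, 22L)
  expect_equal(out$target_seq, tail)

  # 12 nt of a miRNA only: below min_mirna_match
  expect_equal(call_mirna_segment(substr(read, 1, 12), catalog)$status, "non_chimera")
  # a full miRNA with no tail is not a chimera
  expect_equal(call_mirna_segment("TGAGGTAGTAGGTTGTATAGTT", catalog)$status, "non_chimera")
  # mirB wins over its own 20-nt prefix twin by matched length
  readB <- paste0("ACCCGTAGATCCGAACTTGTGA", tail)
  outB <- call_mirna_segment(readB, catalog)
  expect_equal(outB$mirna_id, "mirB")
  # identical-prefix catalog entries tie -> ambiguous
  cat2 <- data.frame(id = c("x", "y"),
                     sequence = c("UGAGGUAGUAGGUUGUAUAGUU", "UGAGGUAGUAGGUUGUAUAGUU"),
                     stringsAsFactors = FALSE)
  expect_equal(call_mirna_segment(read, cat2)$status, "ambiguous")
  # one mismatch in the miRNA segment is tolerated and counted
  read1 <- read
  substr(read1, 5, 5) <- "C"  # G -> C inside the miRNA segment
  out1 <- call_mirna_segment(read1, catalog)
  expect_equal(out1$status, "chimera")
  expect_equal(out1$mirna_mismatches, 1L)
})

test_that("target mapping requires a unique best ungapped hit", {
  set.seed(503)
  t1 <- rand_dna(400); t2 <- rand_dna(300)
  shared <- substr(t1, 101, 125)
  t2 <- paste0(substr(t2, 1, 150), shared, substr(t2, 151, 300))
  seqs <- c(TXA = t1, TXB = t2)
  # exact substring at offset 100 (0-based)
  mp <- map_target(substr(t1, 101, 125 + 25), seqs)  # 50-mer unique to TXA
  expect_equal(mp$status, "mapped")
  expect_equal(mp$transcript_id, "TXA")
  expect_equal(mp$start, 100L)
  expect_equal(mp$end, 150L)
  expect_equal(mp$mapping_mismatches, 0L)
  # present identically in both -> multimapped
  expect_equal(map_target(shared, seqs)$status, "multimapped")
  # too short
  expect_equal(map_target(strrep("A", 10), seqs)$status, "too_short")
  # two mismatches tolerated, three not
  frag <- substr(t1, 201, 230)
  for (q in c(5, 15)) substr(frag, q, q) <- chartr("ACGT", "TGCA", substr(frag, q, q))
  mp2 <- map_target(frag, seqs)
  expect_equal(mp2$status, "mapped")
  expect_equal(mp2$mapping_mismatches, 2L)
  substr(frag, 25, 25) <- chartr("ACGT", "TGCA", substr(frag, 25, 25))
  expect_equal(map_target(frag, seqs)$status, "unmapped")
  # repeat exclusion drops overlapping hits
  rep_cat <- data.frame(transcript_id = "TXA", start = 90L, end = 110L,
                        stringsAsFactors = FALSE)
  expect_equal(map_target(substr(t1, 101, 150), seqs, repeat_catalog = rep_cat)$status,
               "repeat")
})

test_that("deduplication keeps one representative per key, deterministically", {
  mk <- function(read_id, umi, mirna, tx, start) {
    data.frame(read_id = read_id, umi = umi, mirna_id = mirna, transcript_id = tx,
               start = start, end = start + 25L, stringsAsFactors = FALSE)
  }
  same <- do.call(rbind, lapply(sprintf("r%02d", 5:1), mk, umi = "AAAA",
                                mirna = "m", tx = "t", start = 10L))
  out <- dedup_chimeras(same)
  expect_equal(nrow(out), 1L)
  expect_equal(out$read_id, "r01")  # lexicographically smallest survives
  # same UMI, different start: both kept
  two <- rbind(mk("r1", "AAAA", "m", "t", 10L), mk("r2", "AAAA", "m", "t", 40L))
  expect_equal(nrow(dedup_chimeras(two)), 2L)
  # idempotence
  expect_equal(dedup_chimeras(out), out)
  # random input vs brute-force group-by
  set.seed(504)
  rnd <- mk(sprintf("r%03d", sample(200)), sample(c("ACGT", "GGCC", "TTAA"), 200, TRUE),
            sample(c("m1", "m2"), 200, TRUE), sample(c("t1", "t2"), 200, TRUE),
            sample(c(5L, 50L, 500L), 200, TRUE))
  got <- dedup_chimeras(rnd)
  ref <- do.call(rbind, lapply(split(rnd, paste(rnd$umi, rnd$mirna_id,
                                                rnd$transcript_id, rnd$start)),
                               function(g) g[order(g$read_id)[1], ]))
  expect_setequal(got$read_id, ref$read_id)
})

test_that("every read gets exactly one fate and counts sum to the input", {
  cfg <- synthetic_config(rng_seed = 31, n_mirnas = 8, n_transcripts = 15,
                          transcript_length_range = c(300, 600), reads_total = 4000,
                          chimera_fraction = 0.1)
  catalog <- build_mirna_catalog(cfg)
  bt <- build_transcriptome(catalog, default_site_specs(catalog), cfg)
  sim <- simulate_reads(bt$transcriptome, catalog, bt$truth, cfg)
  pr <- process_reads(sim$reads, catalog, bt$transcriptome)
  expect_false(any(is.na(pr$fates$fate)))
  n_in <- pr$fate_summary$n[pr$fate_summary$fate == "n_input"]
  expect_equal(sum(pr$fate_summary$n[pr$fate_summary$fate != "n_input"]), n_in)
  expect_equal(n_in, 4000L)
})

test_that("zero-error reads round-trip to the exact truth chimera multiset", {
  cfg <- synthetic_config(rng_seed = 33, n_mirnas = 8, n_transcripts = 15,
                          transcript_length_range = c(300, 600), reads_total = 4000,
                          chimera_fraction = 0.1, sequencing_error_rate = 0)
  catalog <- build_mirna_catalog(cfg)
  bt <- build_transcriptome(catalog, default_site_specs(catalog), cfg)
  sim <- simulate_reads(bt$transcriptome, catalog, bt$truth, cfg)
  pr <- process_reads(sim$reads, catalog, bt$transcriptome)
  truth_ch <- sim$read_truth[sim$read_truth$kind == "chimera", ]
  got <- sort(with(pr$mapped, paste(mirna_id, transcript_id, start, end)))
  want <- sort(with(truth_ch, paste(mirna_id, transcript_id, start, end)))
  expect_identical(got, want)
})

test_that("a single-site, all-chimera, zero-error library parses back perfectly", {
  cfg <- synthetic_config(rng_seed = 35, n_mirnas = 1, n_transcripts = 5,
                          transcript_length_range = c(300, 500), reads_total = 400,
                          chimera_fraction = 1, contaminant_fraction = 0,
                          sequencing_error_rate = 0, site_chimera_bias = 1)
  catalog <- build_mirna_catalog(cfg)
  spec <- site_spec(catalog$id[1], three_prime_run = 13,
                    central_bulge_run = nchar(catalog$sequence[1]) - 21,
                    region_label = "3UTR", is_true_trigger = TRUE)
  bt <- build_transcriptome(catalog, list(spec), cfg)
  sim <- simulate_reads(bt$transcriptome, catalog, bt$truth, cfg)
  pr <- process_reads(sim$reads, catalog, bt$transcriptome)
  expect_equal(nrow(pr$mapped), 400L)
  expect_true(all(pr$mapped$mirna_id == catalog$id[1]))
  expect_true(all(pr$mapped$transcript_id == bt$truth$transcript_id))
  # every fragment covers the embedded site
  expect_true(all(pr$mapped$start <= bt$truth$start & pr$mapped$end >= bt$truth$end))
})
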