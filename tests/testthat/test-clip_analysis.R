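test_that("binning tiles transcripts and conserves assigned reads", {
  m <- transcript_model("g1", "g1", "g1", "+", matrix(c(0, 120), ncol = 2),
                        30, 90)
  mk <- function(pos) data.frame(reference = "g1", strand = "+",
                                 five_prime_pos = pos, length = 30,
                                 mapq = 255, unique = TRUE, sample_id = "x")
  bins <- bin_counts(mk(c(0, 49, 50, 99, 100, 119)), mk(c(10, 60)),
                     list(m), bin_size = 50)
  expect_equal(bins$start, c(0, 50, 100))
  expect_equal(bins$end, c(50, 100, 120))
  expect_equal(bins$clip_count, c(2, 2, 2))
  expect_equal(bins$input_count, c(1, 1, 0))
  expect_equal(sum(bins$clip_count), 6)
})

test_that("binning agrees with a brute-force per-read scan", {
  sim <- generate_transcriptome(15, seed = 61)
  cl <- simulate_clip_reads(sim, 3000, 3000, seed = 62)
  bins <- bin_counts(cl$clip, cl$input, sim$models)
  expect_equal(sum(bins$clip_count), nrow(cl$clip))
  expect_equal(sum(bins$input_count), nrow(cl$input))
  for (k in sample.int(nrow(bins), 25)) {
    b <- bins[k, ]
    expect_equal(b$clip_count,
                 sum(cl$clip$reference == b$reference &
                       cl$clip$five_prime_pos >= b$start &
                       cl$clip$five_prime_pos < b$end))
  }
})

test_that("the peak caller flags strong enrichment and not exchangeable bins", {
  withr::with_seed(63, {
    n <- 2000
    bins <- data.frame(reference = rep(sprintf("t%03d", 1:100), each = 20),
                       start = rep(0:19 * 50, 100))
    bins$end <- bins$start + 50
    bins$input_count <- rpois(n, 20)
    bins$clip_count <- rpois(n, 20)
  })
  hot <- 37
  bins$clip_count[hot] <- 50 * 20
  pk <- call_peaks(bins)
  expect_true(pk$is_peak[pk$start == bins$start[hot] &
                           pk$reference == bins$reference[hot]])
  expect_lt(min(pk$p_value), 1e-6)
  # all bins at the same count: nothing can be a peak
  flat <- bins; flat$clip_count <- 7L; flat$input_count <- 7L
  pf <- call_peaks(flat)
  expect_equal(sum(pf$is_peak), 0)
  expect_error(call_peaks(flat[flat$clip_count < 0, ]), "no bins")
})

test_that("null CLIP/input simulations stay at the nominal peak rate", {
  sim0 <- generate_transcriptome(300, planted_fraction = 0, seed = 65)
  cl0 <- simulate_clip_reads(sim0, 1e5, 1e5, seed = 66)
  p0 <- call_peaks(bin_counts(cl0$clip, cl0$input, sim0$models))
  fpr <- mean(p0$is_peak)
  expect_lte(fpr, 0.01 + 3 * sqrt(0.01 * 0.99 / nrow(p0)))
})

test_that("peak merging follows the center-distance rule with both-replicate support", {
  mk_peak <- function(ref, start, rep_id)
    data.frame(reference = ref, start = start, end = start + 50,
               clip_count = 50, input_count = 5, p_value = 1e-5,
               is_peak = TRUE, replicate_id = rep_id,
               stringsAsFactors = FALSE)
  # centers 125 and 205: distance 80 <= 100 -> one merged peak
  mg <- merge_peaks(mk_peak("t1", 100, "rep1"), mk_peak("t1", 180, "rep2"))
  expect_equal(nrow(mg), 1)
  expect_equal(mg$start, 100)
  expect_equal(mg$end, 230)
  expect_equal(mg$center, 165)
  # distance 120 > 100: no double support anywhere -> nothing merged
  far <- merge_peaks(mk_peak("t1", 100, "rep1"), mk_peak("t1", 220, "rep2"))
  expect_equal(nrow(far), 0)
  expect_equal(attr(far, "n_discarded"), 2L)
  # single-replicate peaks are discarded and counted
  solo <- merge_peaks(mk_peak("t1", 100, "rep1"),
                      mk_peak("t2", 100, "rep2"))
  expect_equal(nrow(solo), 0)
  expect_equal(attr(solo, "n_discarded"), 2L)
})

test_that("merging matches brute-force transitive closure and is symmetric", {
  withr::with_seed(67, {
    mk <- function(rep_id, n) data.frame(
      reference = sample(c("a", "b", "c"), n, TRUE),
      start = sample.int(3000, n), replicate_id = rep_id,
      clip_count = 20, input_count = 2, p_value = 1e-4, is_peak = TRUE,
      stringsAsFactors = FALSE)
    p1 <- mk("rep1", 40); p1$end <- p1$start + 50
    p2 <- mk("rep2", 40); p2$end <- p2$start + 50
  })
  mg <- merge_peaks(p1, p2)
  # brute force: group pooled peaks, keep dual-support groups
  pool <- rbind(p1, p2)
  centers <- (pool$start + pool$end) / 2
  grp <- brute_force_merge_groups(pool$reference, centers, 100)
  dual <- vapply(split(pool$replicate_id, grp),
                 function(r) length(unique(r)) > 1, TRUE)
  spans <- lapply(split(seq_len(nrow(pool)), grp)[dual], function(i)
    c(min(pool$start[i]), max(pool$end[i])))
  expect_equal(nrow(mg), sum(dual))
  got <- mg[order(mg$reference, mg$start), c("start", "end")]
  want <- do.call(rbind, spans)
  want <- want[order(vapply(split(pool$reference, grp)[dual], `[`, "", 1),
                     want[, 1]), , drop = FALSE]
  expect_equal(unname(as.matrix(got)), unname(want))
  # symmetric in replicate order; idempotent grouping on its own output
  mg2 <- merge_peaks(p2, p1)
  expect_equal(mg[order(mg$reference, mg$start), c("reference", "start", "end")],
               mg2[order(mg2$reference, mg2$start), c("reference", "start", "end")],
               ignore_attr = TRUE)
})

test_that("peak annotation uses region precedence and percentages sum to 100", {
  sim <- generate_transcriptome(40, planted_fraction = 0.5, seed = 69)
  ti <- transcript_index(sim$models)
  pk <- data.frame(reference = c(ti$reference[1], ti$reference[1],
                                 ti$reference[2], "nowhere"),
                   start = 0, end = 0)
  pk$start <- c(ti$cds_tx_end[1] + 5,          # 3'UTR
                2,                              # 5'UTR
                ti$cds_tx_start[2] + 9,         # CDS
                10)
  pk$end <- pk$start + 10
  pk$center <- pk$start + 5
  ann <- annotate_peaks(pk, sim$models)
  expect_equal(ann$region, c("3'UTR", "5'UTR", "CDS", "intergenic"))
  expect_equal(sum(attr(ann, "percentages")), 100, tolerance = 0.1)
  expect_true(is.na(ann$gene_id[4]))
})

test_that("CLIP reproducibility separates replicates from RNA profiles", {
  sim <- generate_transcriptome(150, planted_fraction = 0.5, seed = 71)
  cl1 <- simulate_clip_reads(sim, 1e5, 1e5, seed = 72)
  cl2 <- simulate_clip_reads(sim, 1e5, 1e5, seed = 73)
  rna <- simulate_rna_reads(sim, 1e5, seed = 74)
  g1 <- gene_read_counts(cl1$clip, sim$models)
  g2 <- gene_read_counts(cl2$clip, sim$models)
  gr <- gene_read_counts(rna, sim$models)
  cc <- clip_reproducibility(g1, g2, gr)
  expect_equal(unname(clip_reproducibility(g1, g1, gr)["rep1_rep2"]), 1)
  expect_gt(cc["rep1_rep2"], cc["rep1_rna"])
  expect_gt(cc["rep1_rep2"], 0.9)
  expect_error(clip_reproducibility(g1[1:2], g2[1:2], gr[1:2]),
               "fewer than 3")
})

test_that("EM motif discovery recovers planted and degenerate motifs", {
  # identical sequences equal to a repeated 8-mer: PWM snaps to its indicator
  seqs <- stats::setNames(rep(strrep("UAUUUAUU", 3), 12), paste0("r", 1:12))
  d <- discover_motif(seqs, width = 8, n_restarts = 2, n_null = 0, seed = 1)
  expect_equal(d$consensus, "UAUUUAUU")
  expect_true(all(apply(d$motif$matrix, 2, max) > 0.9))
  # planted consensus in random sequences
  seqs2 <- random_rna_seqs(120, 50, planted_fraction = 0.8, seed = 2)
  d2 <- discover_motif(seqs2, width = 8, n_null = 0, seed = 3)
  expect_lte(hamming(d2$consensus, "UAUUUAUU"), 1)
  # the EM objective never decreases
  expect_true(all(diff(d2$loglik_trace) >= -1e-9))
  expect_error(discover_motif(seqs2[1:5]), "at least 10")
  expect_error(discover_motif(c(seqs2, stats::setNames("AC", "tiny"))),
               "at least")
})

test_that("motif discovery significance is calibrated on random sequences", {
  ps <- vapply(1:5, function(s) {
    seqs <- random_rna_seqs(30, 40, planted_fraction = 0, seed = 90 + s)
    discover_motif(seqs, width = 8, n_restarts = 5, n_null = 19,
                   seed = s)$p_value
  }, 0)
  expect_gte(mean(ps > 0.05), 0.6)
  # and a strongly planted motif is significant
  seqs <- random_rna_seqs(60, 40, planted_fraction = 0.9, seed = 99)
  dp <- discover_motif(seqs, width = 8, n_restarts = 5, n_null = 19,
                       seed = 100)
  expect_lte(dp$p_value, 0.05)
})
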