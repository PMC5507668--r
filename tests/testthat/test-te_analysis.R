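test_that("count_reads assigns by 5'-end region membership in union mode", {
  m1 <- transcript_model("gA", "gA.t", "chr1", "+",
                         matrix(c(0, 300), ncol = 2), 30, 270)
  m2 <- transcript_model("gB", "gB.t", "chr1", "+",
                         matrix(c(250, 550), ncol = 2), 280, 520)
  aln <- data.frame(
    reference = "chr1", strand = "+",
    five_prime_pos = c(50, 60, 70,   # gA CDS x3
                       260,          # gA CDS and gB 5'UTR: ambiguous only
                                     # when counting exons, not CDS
                       400,          # gB CDS
                       600),         # outside both
    length = 28, mapq = 255, unique = TRUE, sample_id = "x")
  cds <- count_reads(aln, list(m1, m2), region = "CDS")
  expect_equal(unname(cds["gA"]), 4L)
  expect_equal(unname(cds["gB"]), 1L)
  expect_equal(attr(cds, "n_ambiguous"), 0L)
  ex <- count_reads(aln, list(m1, m2), region = "exons")
  # position 260 is exonic in both genes: ambiguous, unassigned
  expect_equal(attr(ex, "n_ambiguous"), 1L)
  expect_equal(unname(ex["gA"]), 3L)
  # non-unique reads never count
  aln$unique <- FALSE
  expect_equal(sum(count_reads(aln, list(m1, m2))), 0L)
})

test_that("count_reads equals the brute-force per-read scan", {
  sim <- generate_transcriptome(20, seed = 31)
  gm <- project_genomic(sim$models, gap = 50, seed = 32)  # some near-overlaps
  withr::with_seed(33, {
    aln <- data.frame(
      reference = "chrS", strand = sample(c("+", "-"), 400, TRUE),
      five_prime_pos = sample.int(60000, 400), length = 28,
      mapq = sample(c(0, 255), 400, TRUE, prob = c(0.2, 0.8)),
      sample_id = "x")
  })
  aln$unique <- aln$mapq >= 10
  for (region in c("CDS", "exons")) {
    fast <- count_reads(aln, gm, region = region)
    slow <- brute_force_counts(aln, gm, region = region)
    expect_equal(as.integer(fast), as.integer(slow), ignore_attr = TRUE)
    expect_equal(attr(fast, "n_ambiguous"), attr(slow, "n_ambiguous"))
  }
})

test_that("RPKM follows its closed form and scale invariance", {
  ct <- count_table(matrix(c(10, 0, 4), 3, 1,
                           dimnames = list(c("a", "b", "c"), "s1")),
                    lengths = c(1000, 500, 2000), totals = 1e6,
                    assay = "RNA")
  r <- rpkm(ct)
  expect_equal(unname(r[, 1]), c(10, 0, 2))
  # doubling counts and totals preserves RPKM
  ct2 <- count_table(ct$counts * 2L, ct$lengths, ct$totals * 2,
                     assay = "RNA")
  expect_equal(rpkm(ct2), r)
  # independent spreadsheet-style recomputation on random tables
  withr::with_seed(2, {
    cc <- matrix(rpois(60, 40), 20, 3,
                 dimnames = list(sprintf("g%02d", 1:20), c("x", "y", "z")))
    len <- sample(200:2000, 20)
    tot <- colSums(cc) + sample(100:200, 3)
  })
  ct3 <- count_table(cc, len, tot, assay = "RPF")
  manual <- t(t(cc * 1e9 / len) / tot)
  expect_equal(rpkm(ct3), manual)
  expect_error(count_table(cc, len, colSums(cc) - 1, assay = "RPF"),
               "totals")
  expect_error(rpkm(count_table(matrix(0, 1, 1), 10, 0, "RNA")), "zero total")
})

test_that("the expression filter keeps genes above threshold at every stage", {
  sim <- generate_transcriptome(200, seed = 35)
  tc <- simulate_timecourse(sim, depth = 30, seed = 36)
  keep <- filter_expressed(tc$rpf, tc$rna, threshold = 10)
  a <- stage_rpkm_for_test(tc$rpf); b <- stage_rpkm_for_test(tc$rna)
  manual <- rownames(a)[apply(a > 10, 1, all) & apply(b > 10, 1, all)]
  expect_identical(keep, manual)
  # a gene at RPKM <= 10 at a single stage is excluded
  low <- rownames(a)[apply(a > 10, 1, sum) == 4 & apply(a > 10, 1, all) == FALSE]
  expect_true(all(!low %in% keep))
})

test_that("apparent TE is the RPF/RNA RPKM ratio with zero-centered rows", {
  counts_rpf <- matrix(20L, 2, 10)
  counts_rna <- matrix(10L, 2, 10)
  rownames(counts_rpf) <- rownames(counts_rna) <- c("g1", "g2")
  colnames(counts_rpf) <- paste0("r", 1:10)
  colnames(counts_rna) <- paste0("n", 1:10)
  st <- rep(c(0, 1, 2, 4, 6), each = 2)
  rpf <- count_table(counts_rpf, c(1000, 1000), rep(1e3, 10), "RPF",
                     stage = st, replicate = rep(1:2, 5))
  rna <- count_table(counts_rna, c(1000, 1000), rep(1e3, 10), "RNA",
                     stage = st, replicate = rep(1:2, 5))
  te <- apparent_te(rpf, rna, c("g1", "g2"))
  expect_equal(unname(te$te), matrix(2, 2, 5))
  expect_equal(unname(te$log2_te), matrix(1, 2, 5))
  expect_equal(rowSums(te$centered), c(g1 = 0, g2 = 0))
})

test_that("differential TE p-values have exact bootstrap granularity", {
  sim <- generate_transcriptome(150, shift_fraction = 0, seed = 37)
  tc <- simulate_timecourse(sim, depth = 50, seed = 38)
  keep <- filter_expressed(tc$rpf, tc$rna)
  B <- 200
  dt <- differential_te(subset_count_table(tc$rpf, c(0, 1)),
                        subset_count_table(tc$rna, c(0, 1)),
                        keep, B = B, seed = 39)
  p <- dt$p_hr0_hr1
  expect_true(all(p > 0))
  expect_gte(min(p), 1 / (B + 1))
  expect_lte(max(p), 1)
  # granularity exactly 1/(B+1)
  expect_equal(p * (B + 1), round(p * (B + 1)), tolerance = 1e-9)
  expect_error(differential_te(tc$rpf, tc$rna, keep, B = 50), "B must")
})

test_that("doubling sequencing depth preserves the sign of the statistic", {
  sim <- generate_transcriptome(200, shift_fraction = 0.3, seed = 41)
  tc <- simulate_timecourse(sim, depth = 60, seed = 42)
  keep <- filter_expressed(tc$rpf, tc$rna)
  r1 <- subset_count_table(tc$rpf, c(0, 1))
  n1 <- subset_count_table(tc$rna, c(0, 1))
  r2 <- r1; r2$counts <- r2$counts * 2L; r2$totals <- r2$totals * 2
  n2 <- n1; n2$counts <- n2$counts * 2L; n2$totals <- n2$totals * 2
  d1 <- differential_te(r1, n1, keep, B = 200, seed = 43)
  d2 <- differential_te(r2, n2, keep, B = 200, seed = 43)
  big <- abs(d1$D_hr0_hr1) > 1  # genes with a clear signal
  expect_true(all(sign(d1$D_hr0_hr1[big]) == sign(d2$D_hr0_hr1[big])))
})

test_that("planted shifts are detected with the right direction", {
  sim <- generate_transcriptome(400, shift_fraction = 0.25, shift_log2 = 2,
                                abundance_sdlog = 0.3, seed = 45)
  tc <- simulate_timecourse(sim, depth = 80, seed = 46)
  keep <- filter_expressed(tc$rpf, tc$rna)
  dt <- differential_te(subset_count_table(tc$rpf, c(0, 1)),
                        subset_count_table(tc$rna, c(0, 1)),
                        keep, B = 500, seed = 47)
  m <- merge(dt, sim$truth$genes, by = "gene_id")
  sh <- m$shift & m$shift_stage == 2
  expect_gt(mean(m$significant[sh]), 0.7)
  hit <- sh & m$significant
  expect_gt(mean(m$direction[hit] ==
                   ifelse(m$shift_log2[hit] > 0, "up", "down")), 0.95)
  expect_lt(mean(m$significant[!m$shift]), 0.12)
})

test_that("TE clustering groups directions purely and ignores input order", {
  # two clean cohorts: strong up-shift and strong down-shift profiles
  withr::with_seed(3, {
    up <- matrix(rep(c(-1, -1, 1, 1, 1), each = 10), 10) +
      matrix(rnorm(50, sd = 0.05), 10)
    dn <- -up + matrix(rnorm(50, sd = 0.05), 10)
  })
  m <- rbind(up, dn)
  rownames(m) <- sprintf("g%02d", 1:20)
  colnames(m) <- paste0("hr", c(0, 1, 2, 4, 6))
  cen <- m - rowMeans(m)
  te_prof <- structure(list(centered = cen), class = "te_profile")
  diff_res <- data.frame(
    gene_id = rownames(m),
    min_p = 0.001, significant = TRUE,
    direction = rep(c("up", "down"), each = 10),
    stringsAsFactors = FALSE)
  cl <- cluster_te(te_prof, diff_res)
  expect_identical(cl$direction[1:10], rep("up", 10), ignore_attr = TRUE)
  expect_identical(cl$direction[11:20], rep("down", 10), ignore_attr = TRUE)
  # permuting the input row order leaves the final ordering unchanged
  perm <- withr::with_seed(4, sample(20))
  te_perm <- structure(list(centered = cen[perm, ]), class = "te_profile")
  cl2 <- cluster_te(te_perm, diff_res[perm, ])
  expect_identical(cl$row_order, cl2$row_order)
  # identical profiles are adjacent with merge height 0
  dup <- te_prof; dup$centered[2, ] <- dup$centered[1, ]
  cld <- cluster_te(dup, diff_res)
  i1 <- which(cld$row_order == "g01"); i2 <- which(cld$row_order == "g02")
  expect_equal(abs(i1 - i2), 1)
  expect_equal(min(cld$heights$up), 0)
  expect_error(cluster_te(te_prof, diff_res[1, ]), "fewer than 2")
})
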