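# small local helpers
gtools_rdirichlet <- function() {
  g <- stats::rgamma(4, shape = 2)
  g / sum(g)
}
rna_letters_t <- function() c("A", "C", "G", "U")

test_that("zero-order background matches hand counts with pseudocounts", {
  bg <- background_model(c("AACG", "UUU", "GG"))
  # counts A2 C1 G3 U3 plus +1 each over 9+4 letters
  expect_equal(unname(bg), c(3, 2, 4, 4) / 13)
  expect_equal(sum(bg), 1)
  expect_gt(background_model("UUUUUUUUUU")[["U"]], 0.7)
  u <- background_model(strrep("ACGU", 100))
  expect_equal(unname(u), rep(0.25, 4), tolerance = 1e-2)
})

test_that("3'UTRs come from the longest-CDS isoform in sense orientation", {
  # two isoforms of one gene: CDS 300 vs 450 nt
  iso1 <- transcript_model("g1", "g1.short", "g1.short", "+",
                           matrix(c(0, 500), ncol = 2), 50, 350)
  iso2 <- transcript_model("g1", "g1.long", "g1.long", "+",
                           matrix(c(0, 700), ncol = 2), 50, 500)
  seqs <- c(g1.short = strrep("A", 500),
            g1.long = paste0(strrep("C", 50), "AUG", strrep("C", 444),
                             strrep("G", 203)))
  utr <- extract_3utrs(list(iso1, iso2), seqs)
  expect_equal(unname(utr["g1"]), strrep("G", 200))
  # minus-strand genomic model: sequence reverse-complemented to sense
  gm <- transcript_model("g2", "g2.t", "chr1", "-",
                         matrix(c(0, 300), ncol = 2), 100, 250)
  chrom <- paste0(strrep("A", 100),   # genomic 0-99 -> sense 3'UTR U*100
                  "UUA",              # genomic 100-102 -> sense stop UAA
                  strrep("A", 144),
                  "CAU",              # genomic 247-249 -> sense AUG
                  strrep("G", 50))    # genomic 250-299 -> sense 5'UTR C*50
  utr2 <- extract_3utrs(list(gm), c(chr1 = chrom))
  expect_equal(unname(utr2["g2"]), strrep("U", 100))
  # inconsistent sequence length is an error naming the transcript
  expect_error(extract_3utrs(list(iso2), c(g1.long = "AUGCC")), "g1.long")
})

test_that("PWM scan finds planted sites and respects the width", {
  bg <- c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)
  mo <- consensus_motif("UAUUUAUU", "are", peak = 0.9)
  s <- c(one = paste0(strrep("C", 20), "UAUUUAUU", strrep("G", 20)),
         short = "UAUU",
         none = strrep("CG", 30))
  occ <- scan_pwm(s, mo, bg)
  expect_equal(nrow(occ), 1)
  expect_equal(occ$sequence_id, "one")
  expect_equal(occ$start, 20L)
  expect_true(all(occ$p_value <= 1e-4))
  # a zero-probability motif is pseudocounted, not an error
  m0 <- matrix(0, 4, 6); m0[cbind(c(1, 2, 3, 4, 1, 2), 1:6)] <- 1
  mz <- motif_matrix("z", "z", m0)
  expect_message(riboclip:::pwm_score_dist(mz, bg), "pseudocount")
})

test_that("the DP score distribution equals exhaustive enumeration", {
  withr::with_seed(9, {
    for (w in c(4, 5, 6)) {
      bg <- as.numeric(stats::setNames(gtools_rdirichlet(), rna_letters_t()))
      bg <- bg / sum(bg)
      names(bg) <- rna_letters_t()
      m <- matrix(stats::runif(4 * w, 0.05, 1), 4, w)
      m <- sweep(m, 2, colSums(m), "/")
      mo <- motif_matrix(sprintf("w%d", w), "x", m)
      sd <- riboclip:::pwm_score_dist(mo, bg)
      expect_equal(sum(sd$dist), 1, tolerance = 1e-9)
      words <- as.matrix(expand.grid(rep(list(1:4), w)))
      wsc <- rowSums(sapply(seq_len(w), function(i) sd$intmat[words[, i], i]))
      wpr <- apply(sapply(seq_len(w), function(i) bg[words[, i]]), 1, prod)
      p_enum <- vapply(wsc, function(s) sum(wpr[wsc >= s]), 0)
      p_dp <- riboclip:::pwm_score_pvalue(sd, wsc)
      expect_lt(max(abs(p_dp - p_enum)), 1e-6)
    }
  })
})

test_that("shuffling preserves per-sequence letter multisets", {
  seqs <- random_rna_seqs(10, 40, seed = 21)
  shuf <- shuffle_sequences(seqs, copies = 10, seed = 22)
  expect_length(shuf, 100)
  sorted <- function(x) vapply(strsplit(x, ""), function(ch)
    paste(sort(ch), collapse = ""), "")
  expect_identical(unname(sorted(shuf)), unname(rep(sorted(seqs), 10)))
  # homopolymers are unchanged
  expect_identical(unname(shuffle_sequences(c(h = strrep("U", 30)), 3,
                                            seed = 1)),
                   rep(strrep("U", 30), 3))
  # dinucleotide frequencies converge to the mononucleotide product
  long <- random_rna_seqs(1, 40, seed = 23)
  many <- shuffle_sequences(long, copies = 400, seed = 24)
  aa <- sum(vapply(many, function(s)
    lengths(regmatches(s, gregexpr("(?=AA)", s, perl = TRUE))), 0))
  na <- sum(vapply(strsplit(paste(many, collapse = ""), ""), function(x)
    sum(x == "A"), 0))
  p_a <- na / sum(nchar(many))
  exp_aa <- p_a^2 * sum(nchar(many) - 1)
  expect_lt(abs(aa - exp_aa) / exp_aa, 0.2)
})

test_that("Fisher enrichment equals the hypergeometric tail", {
  withr::with_seed(31, {
    for (k in 1:100) {
      a <- sample(0:30, 1); b <- sample(0:30, 1)
      c_ <- sample(0:300, 1); d <- sample(0:300, 1)
      if (a + c_ == 0) next
      p_pkg <- stats::fisher.test(matrix(c(a, b, c_, d), 2),
                                  alternative = "greater")$p.value
      # tail of the hypergeometric: draws = first column margin
      p_hyp <- stats::phyper(a - 1, a + b, c_ + d, a + c_,
                             lower.tail = FALSE)
      expect_equal(p_pkg, p_hyp, tolerance = 1e-12)
    }
  })
  # equal proportions: odds ratio 1 and no evidence of enrichment
  mo <- consensus_motif("AAAA", "m1")
  occ <- data.frame(sequence_id = c("r1", "s1"), start = 0L,
                    motif_id = "m1", score = 1, p_value = 1e-5)
  fe <- fisher_enrichment(occ[1, ], occ[2, ], 10, 10, list(mo))
  expect_equal(fe$odds_ratio, 1)
  expect_gt(fe$p_value, 0.5)
  # empty scans on both sides: p exactly 1 with the odds ratio flagged
  none <- occ[0, ]
  f0 <- fisher_enrichment(none, none, 10, 10, list(mo))
  expect_equal(f0$p_value, 1)
  expect_true(f0$or_undefined)
  # adjusted p never below raw p
  expect_true(all(fe$adj_p >= fe$p_value))
})

test_that("planted consensus outranks decoys in enriched 3'UTRs", {
  sim <- generate_transcriptome(200, planted_fraction = 0.5, seed = 51)
  utrs <- extract_3utrs(sim$models, sim$sequences)
  bg <- background_model(utrs)
  motifs <- c(list(consensus_motif("UAUUUAUU", "planted", "Zfp36")),
              random_decoy_motifs(19, seed = 52))
  shuf <- shuffle_sequences(utrs, copies = 10, seed = 53)
  ro <- do.call(rbind, lapply(motifs, function(m) scan_pwm(utrs, m, bg)))
  so <- do.call(rbind, lapply(motifs, function(m) scan_pwm(shuf, m, bg)))
  fe <- fisher_enrichment(ro, so, length(utrs), length(shuf), motifs)
  expect_equal(fe$motif_id[1], "planted")
  expect_lt(fe$adj_p[1], 1e-20)
})

test_that("motif report filters to expressed RBPs and flags the extreme tier", {
  res <- data.frame(motif_id = c("m1", "m2", "m3"),
                    rbp_name = c("Zfp36", "Lowexp", "Mystery"),
                    odds_ratio = c(50, 40, 30),
                    p_value = c(1e-120, 1e-30, 1e-10),
                    adj_p = c(3e-120, 2e-30, 1e-10),
                    stringsAsFactors = FALSE)
  expr_tab <- data.frame(rbp_name = c("Zfp36", "Lowexp"), rpkm = c(50, 3))
  expect_warning(rep <- report_top_motifs(res, expr_tab, top_n = 10),
                 "Mystery")
  expect_equal(rep$motif_id, "m1")          # Lowexp excluded, Mystery unknown
  expect_true(rep$stringent[1])             # adj p < 1e-100 tier
  expect_identical(attr(rep, "unknown_rbps"), "Mystery")
  # top_n larger than survivors returns the full list without padding
  expect_equal(nrow(rep), 1)
})

test_that("under the complete null, motif enrichment stays calibrated", {
  raw_frac <- numeric(0); discoveries <- integer(0)
  for (s in 1:5) {
    sim <- generate_transcriptome(80, planted_fraction = 0, seed = 60 + s)
    utrs <- extract_3utrs(sim$models, sim$sequences)
    bg <- background_model(utrs)
    motifs <- random_decoy_motifs(20, seed = 70 + s)
    shuf <- shuffle_sequences(utrs, copies = 10, seed = 80 + s)
    ro <- do.call(rbind, lapply(motifs, function(m) scan_pwm(utrs, m, bg)))
    so <- do.call(rbind, lapply(motifs, function(m) scan_pwm(shuf, m, bg)))
    fe <- fisher_enrichment(ro, so, length(utrs), length(shuf), motifs)
    raw_frac <- c(raw_frac, mean(fe$p_value < 0.05))
    discoveries <- c(discoveries, sum(fe$adj_p < 0.05))
  }
  n <- 20 * 5
  expect_lte(mean(raw_frac), 0.05 + 3 * sqrt(0.05 * 0.95 / n))
  expect_gte(mean(discoveries == 0), 0.8)
})
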