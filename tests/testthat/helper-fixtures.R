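# shared fixtures: all synthetic, built in code at test time

# a tiny two-exon model: exons (100,200)+(300,400), coding span 150-352,
# so the spliced regions are 5'UTR 50 / CDS 102 / 3'UTR 48 nt (plus strand)
tiny_model <- function(strand = "+") {
  transcript_model("g1", "g1.t1", "chr1", strand,
                   matrix(c(100, 200, 300, 400), ncol = 2, byrow = TRUE),
                   150, 352)
}

# random RNA sequences with an optional planted consensus
random_rna_seqs <- function(n, len, planted_fraction = 0,
                            consensus = "UAUUUAUU", seed = 1) {
  withr::with_seed(seed, {
    s <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
            collapse = ""), "")
    if (planted_fraction > 0) {
      idx <- sample(n, round(planted_fraction * n))
      for (i in idx) {
        p <- sample(len - nchar(consensus) + 1, 1)
        substr(s[i], p, p + nchar(consensus) - 1) <- consensus
      }
    }
  })
  stats::setNames(s, paste0("s", seq_len(n)))
}

# brute-force per-read counting oracle: 5'-end membership in region intervals
brute_force_counts <- function(aln, models, region = "CDS") {
  aln <- aln[aln$unique, , drop = FALSE]
  counts <- stats::setNames(integer(length(models)),
                            vapply(models, `[[`, "", "gene_id"))
  ambiguous <- 0L
  for (r in seq_len(nrow(aln))) {
    hits <- integer(0)
    for (gi in seq_along(models)) {
      m <- models[[gi]]
      if (m$reference != aln$reference[r]) next
      if (m$strand != aln$strand[r]) next
      pos <- aln$five_prime_pos[r]
      iv <- if (region == "CDS") {
        s <- pmax(m$exons[, 1], m$cds_start)
        e <- pmin(m$exons[, 2], m$cds_end)
        cbind(s[e > s], e[e > s])
      } else m$exons
      if (nrow(iv) && any(pos >= iv[, 1] & pos < iv[, 2]))
        hits <- c(hits, gi)
    }
    if (length(hits) == 1) counts[hits] <- counts[hits] + 1L
    else if (length(hits) > 1) ambiguous <- ambiguous + 1L
  }
  attr(counts, "n_ambiguous") <- ambiguous
  counts
}

# brute-force single-linkage transitive closure of peak centers
brute_force_merge_groups <- function(ref, center, max_dist = 100) {
  n <- length(center)
  group <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (ref[i] == ref[j] && abs(center[i] - center[j]) <= max_dist &&
          group[i] != group[j]) {
        group[group == group[j]] <- group[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(group, unique(group))
}

hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

# replicate-averaged RPKM per stage for tests
stage_rpkm_for_test <- function(ct) {
  r <- rpkm(ct)
  stages <- sort(unique(ct$samples$stage))
  sapply(stages, function(s) rowMeans(r[, ct$samples$stage == s, drop = FALSE]))
}
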