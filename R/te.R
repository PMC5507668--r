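#' Expression filter on replicate-averaged RPKM
#'
#' A gene is retained iff its replicate-averaged RPKM exceeds `threshold`
#' in both assays at every stage (the "RPKM > 10 at all stages in both
#' Ribo-seq and RNA-seq" rule).
#'
#' @param rpf_ct,rna_ct [count_table()]s with matching genes and stages.
#' @param threshold RPKM threshold (strictly greater; default 10).
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(rpf_ct, rna_ct, threshold = 10) {
  a <- stage_rpkm(rpf_ct); b <- stage_rpkm(rna_ct)
  stopifnot(identical(rownames(a), rownames(b)))
  keep <- apply(a > threshold, 1, all) & apply(b > threshold, 1, all)
  rownames(a)[keep]
}

#' Apparent translation efficiency profile
#'
#' Apparent TE is the ratio of replicate-averaged RPF RPKM (CDS length) to
#' replicate-averaged RNA RPKM (exon-union length) per gene per stage — a
#' CDS ribosome-density contrast. Returns the raw, log2 and row-mean-centered
#' log2 views; each centered row sums to zero.
#'
#' @inheritParams filter_expressed
#' @param retained gene ids passing [filter_expressed()].
#' @return object of class `te_profile` with elements `te`, `log2_te`,
#'   `centered` (genes x stages matrices).
#' @export
apparent_te <- function(rpf_ct, rna_ct, retained) {
  a <- stage_rpkm(rpf_ct)[retained, , drop = FALSE]
  b <- stage_rpkm(rna_ct)[retained, , drop = FALSE]
  stopifnot(all(b > 0))  # guaranteed by the expression filter
  te <- a / b
  l2 <- log2(te)
  structure(list(te = te, log2_te = l2, centered = l2 - rowMeans(l2)),
            class = "te_profile")
}

#' Empirical differential-TE test across adjacent stages
#'
#' For each adjacent stage pair, the RPF count of each gene is judged
#' against the expectation implied by its RNA count: per sample a robust
#' log-linear trend `E[RPF] = exp(a + b log(RNA + 0.5))` is fitted across
#' genes, a gene-level translation factor `t_g` (ratio of the gene's summed
#' RPF to its summed trend expectation over the pair) defines the per-gene
#' null mean, and a negative-binomial dispersion is estimated by method of
#' moments within deciles of the null mean. The translation score of each
#' observation is its mid-p quantile residual under NB(null mean,
#' dispersion); the statistic `D` is the replicate-averaged score difference
#' between the two stages. Its null distribution comes from a joint
#' parametric bootstrap from the per-gene null: RNA counts are resampled
#' from their own fitted negative binomial and propagated through the
#' trend (so the noise of the RNA-implied expectation enters the null),
#' RPF counts are drawn around the propagated expectation with the
#' RNA-noise-adjusted residual dispersion, and `t_g` is re-estimated inside
#' each draw. This gives a two-sided empirical p-value
#' `(1 + #{|D*| >= |D|}) / (B + 1)`; the smallest achievable p is
#' `1/(B+1)` and no p-value is zero. A gene is significant if any adjacent
#' pair has p < `alpha`; its direction is the sign of `D` at the minimum-p
#' pair (`"up"` = TE increases at the later stage).
#'
#' @inheritParams filter_expressed
#' @param retained gene ids passing [filter_expressed()].
#' @param B bootstrap replicates (>= 100).
#' @param alpha per-pair significance level (default 0.05).
#' @param seed integer seed for the bootstrap.
#' @return data.frame (one row per gene): per-pair `D` and `p` columns,
#'   `min_p`, `min_p_pair`, `direction`, `significant`.
#' @export
differential_te <- function(rpf_ct, rna_ct, retained, B = 10000,
                            alpha = 0.05, seed = 1) {
  if (B < 100) stop("B must be >= 100")
  if (any(rpf_ct$counts != round(rpf_ct$counts)) ||
      any(rna_ct$counts != round(rna_ct$counts)))
    stop("counts must be integers")
  stages <- sort(unique(rpf_ct$samples$stage))
  stopifnot(length(stages) >= 2,
            identical(stages, sort(unique(rna_ct$samples$stage))))
  y <- rpf_ct$counts[retained, , drop = FALSE]
  x <- rna_ct$counts[retained, , drop = FALSE]
  n <- length(retained)
  pairs <- cbind(stages[-length(stages)], stages[-1])
  res <- data.frame(gene_id = retained, stringsAsFactors = FALSE)
  D_mat <- p_mat <- matrix(NA_real_, n, nrow(pairs))

  mid_p_score <- function(obs, mu, size) {
    u <- stats::pnbinom(obs - 1, mu = mu, size = size) +
      0.5 * stats::dnbinom(obs, mu = mu, size = size)
    stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
  }

  withr::with_seed(seed, for (pi in seq_len(nrow(pairs))) {
    sel_rpf <- which(rpf_ct$samples$stage %in% pairs[pi, ])
    # match RNA samples to RPF samples by stage + replicate
    key <- paste(rpf_ct$samples$stage[sel_rpf], rpf_ct$samples$replicate[sel_rpf])
    sel_rna <- match(key, paste(rna_ct$samples$stage, rna_ct$samples$replicate))
    if (anyNA(sel_rna)) stop("RNA samples do not match RPF stage/replicate design")
    ys <- y[, sel_rpf, drop = FALSE]
    xs <- x[, sel_rna, drop = FALSE]
    ns <- ncol(ys)
    stage_of <- rpf_ct$samples$stage[sel_rpf]

    # (1) per-sample robust trend
    coefs <- matrix(0, 2, ns)
    mu_trend <- sapply(seq_len(ns), function(j) {
      fit <- MASS::rlm(log(ys[, j] + 0.5) ~ log(xs[, j] + 0.5), maxit = 50)
      coefs[, j] <<- stats::coef(fit)
      pmax(exp(unname(stats::fitted(fit))), 1e-6)
    })
    # (2) gene-level translation factor and per-gene null mean
    t_g <- pmax(rowSums(ys), 0.5) / rowSums(mu_trend)
    mu0 <- mu_trend * t_g
    # (3) decile method-of-moments dispersions from within-stage replicate
    # variability (between-stage TE shifts cannot contaminate them)
    sf <- colSums(xs) / mean(colSums(xs))
    lam <- rowMeans(sweep(xs, 2, sf, "/")) %o% sf        # RNA null means
    lam <- pmax(lam, 1e-6)
    within_disp <- function(m) {
      # per-decile NB dispersion from residuals against per-stage gene means
      stage_mean <- sapply(unique(stage_of), function(s)
        rowMeans(m[, stage_of == s, drop = FALSE]))
      mu_hat <- stage_mean[, match(stage_of, unique(stage_of)), drop = FALSE]
      nrep <- ns / length(unique(stage_of))
      sq <- (m - mu_hat)^2 * nrep / (nrep - 1)
      dec <- cut(rank(rowMeans(mu_hat), ties.method = "first"), 10,
                 labels = FALSE)
      phi <- vapply(1:10, function(d) {
        r <- dec == d
        max(1e-4, sum(sq[r, ] - mu_hat[r, ]) / sum(pmax(mu_hat[r, ], 1e-6)^2))
      }, 0)
      phi[dec]
    }
    phi_x <- within_disp(xs)
    phi_y <- within_disp(ys)
    size_x <- 1 / phi_x
    size_y <- 1 / phi_y
    # scoring variance: RPF dispersion plus the delta-method RNA-propagated
    # variance of the trend expectation
    size_tot_of <- function(mu0m, xm, j) {
      # rows are genes, so lam[, j] and the dispersions recycle correctly
      var_m <- (mu0m / (xm + 0.5))^2 * coefs[2, j]^2 *
        (lam[, j] + phi_x * lam[, j]^2)
      var_tot <- mu0m + phi_y * mu0m^2 + var_m
      mu0m^2 / pmax(var_tot - mu0m, 1e-8)
    }
    # (4) observed statistic: mid-p quantile residuals vs the total null
    z <- sapply(seq_len(ns), function(j)
      mid_p_score(ys[, j], mu0[, j], size_tot_of(mu0[, j], xs[, j], j)))
    later <- stage_of == pairs[pi, 2]
    D <- rowMeans(z[, later, drop = FALSE]) - rowMeans(z[, !later, drop = FALSE])
    # (5) joint parametric bootstrap from the per-gene null: RPF generated
    # at the trend of the noise-free RNA mean but scored against the trend
    # of a freshly resampled RNA count, so the RNA-propagated noise enters
    # the null statistic as it does in the observed data; the translation
    # factor is re-estimated inside each draw
    mu_true <- t_g * sapply(seq_len(ns), function(j)
      pmax(exp(coefs[1, j] + coefs[2, j] * log(lam[, j] + 0.5)), 1e-6))
    exceed <- .boot_te_exceed(lam, 1 / phi_x, mu_true, 1 / phi_y,
                              coefs[1, ], coefs[2, ], phi_x, phi_y,
                              later, D, as.integer(B))
    D_mat[, pi] <- D
    p_mat[, pi] <- (1 + exceed) / (B + 1)
  })

  pair_lab <- sprintf("hr%g_hr%g", pairs[, 1], pairs[, 2])
  colnames(D_mat) <- paste0("D_", pair_lab)
  colnames(p_mat) <- paste0("p_", pair_lab)
  min_i <- apply(p_mat, 1, which.min)
  res <- cbind(res, D_mat, p_mat)
  res$min_p <- p_mat[cbind(seq_len(n), min_i)]
  res$min_p_pair <- pair_lab[min_i]
  res$significant <- apply(p_mat < alpha, 1, any)
  res$direction <- ifelse(res$significant,
                          ifelse(D_mat[cbind(seq_len(n), min_i)] > 0,
                                 "up", "down"), NA_character_)
  res
}

#' Direction-grouped hierarchical clustering of TE profiles
#'
#' Significant genes are grouped by direction ("up" then "down"); within
#' each group rows are ordered by complete-linkage hierarchical clustering
#' (Euclidean distance) of the row-centered log2 TE profiles. Rows are
#' canonically sorted by gene id before clustering so the result does not
#' depend on input order.
#'
#' @param te_profile an [apparent_te()] result.
#' @param diff_results a [differential_te()] result.
#' @return list with `matrix` (ordered centered log2 TE), `row_order`,
#'   `direction` labels, and per-group dendrogram `heights`.
#' @export
cluster_te <- function(te_profile, diff_results) {
  sig <- diff_results[diff_results$significant, ]
  if (nrow(sig) < 2) stop("fewer than 2 significant genes")
  sig <- sig[order(sig$gene_id), ]
  m <- te_profile$centered[sig$gene_id, , drop = FALSE]
  ord <- character(0); heights <- list()
  for (dir in c("up", "down")) {
    ids <- sig$gene_id[sig$direction == dir]
    if (length(ids) == 0) next
    if (length(ids) == 1) { ord <- c(ord, ids); next }
    hc <- stats::hclust(stats::dist(m[ids, , drop = FALSE]),
                        method = "complete")
    ord <- c(ord, ids[hc$order])
    heights[[dir]] <- hc$height
  }
  list(matrix = m[ord, , drop = FALSE], row_order = ord,
       direction = stats::setNames(sig$direction, sig$gene_id)[ord],
       heights = heights)
}
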