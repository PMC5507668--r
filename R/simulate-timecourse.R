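#' Simulate a five-stage RPF/RNA count time course
#'
#' Per gene, stage and replicate, counts are negative binomial with mean
#' proportional to abundance x transcript length (RNA) or
#' abundance x TE x CDS length (RPF), scaled so the per-stage mean count
#' equals `depth`. TE-shift genes change their RPF means by their planted
#' log2 effect from the shift stage onward (already encoded in the truth TE
#' matrix); replicates are i.i.d. As `dispersion` approaches zero the counts
#' become Poisson.
#'
#' @param sim a transcriptome from [generate_transcriptome()].
#' @param depth target mean count per gene per sample.
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); default from the simulation truth.
#' @param n_reps replicates per stage.
#' @param seed integer seed.
#' @return list with `rpf` and `rna` [count_table()]s
#'   (5 stages x `n_reps` replicates each).
#' @export
simulate_timecourse <- function(sim, depth = 50, dispersion = NULL,
                                n_reps = 2, seed = 1) {
  p <- sim$truth$params
  if (is.null(dispersion)) dispersion <- p$nb_dispersion
  g <- sim$truth$genes
  stages <- p$stages
  n <- nrow(g)
  draw <- function(mu) {
    if (dispersion < 1e-12) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  withr::with_seed(seed, {
    build <- function(kind) {
      cols <- list(); stage_v <- numeric(0); rep_v <- integer(0)
      for (s in seq_along(stages)) {
        w <- if (kind == "RPF")
          sim$truth$abundance[, s] * sim$truth$te[, s] * g$cds_length
        else sim$truth$abundance[, s] * g$tx_length
        mu <- depth * w / mean(w)
        for (r in seq_len(n_reps)) {
          cols[[length(cols) + 1]] <- draw(mu)
          stage_v <- c(stage_v, stages[s]); rep_v <- c(rep_v, r)
        }
      }
      m <- do.call(cbind, cols)
      rownames(m) <- g$gene_id
      colnames(m) <- sprintf("%s_hr%g_r%d", tolower(kind), stage_v, rep_v)
      lengths <- if (kind == "RPF") g$cds_length else g$tx_length
      count_table(m, stats::setNames(lengths, g$gene_id),
                  totals = ceiling(1.05 * colSums(m)), assay = kind,
                  stage = stage_v, replicate = rep_v)
    }
    rpf <- build("RPF")
    rna <- build("RNA")
  })
  list(rpf = rpf, rna = rna)
}
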