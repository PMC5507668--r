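#' Pairwise reproducibility of CLIP replicates versus RNA
#'
#' Pearson correlations of log(count + 1) per gene among the two CLIP
#' replicates and an RNA-seq profile.
#'
#' @param clip_rep1,clip_rep2,rna named per-gene count vectors on a common
#'   gene set.
#' @return named vector of three correlations (rep1_rep2, rep1_rna,
#'   rep2_rna).
#' @export
clip_reproducibility <- function(clip_rep1, clip_rep2, rna) {
  genes <- Reduce(intersect, list(names(clip_rep1), names(clip_rep2),
                                  names(rna)))
  if (length(genes) < 3) stop("fewer than 3 genes in common")
  l <- function(x) log(x[genes] + 1)
  c(rep1_rep2 = stats::cor(l(clip_rep1), l(clip_rep2)),
    rep1_rna = stats::cor(l(clip_rep1), l(rna)),
    rep2_rna = stats::cor(l(clip_rep2), l(rna)))
}

#' Per-gene unique-read counts of an alignment set
#'
#' @param aln alignment data.frame.
#' @param models list of `transcript_model`s (defines the gene universe).
#' @return named numeric vector of per-gene read counts.
#' @export
gene_read_counts <- function(aln, models) {
  ti <- transcript_index(models)
  tb <- table(factor(aln$reference[aln$unique], levels = ti$reference))
  stats::setNames(as.numeric(tb), ti$gene_id)
}

#' Bin CLIP and input read counts along transcripts
#'
#' Non-overlapping `bin_size`-nt bins are tiled 5' to 3' along each
#' transcript (the terminal bin may be shorter); reads are assigned to the
#' bin containing their 5' end. Only unique alignments are counted.
#'
#' @param clip_aln,input_aln alignment data.frames in transcript
#'   coordinates.
#' @param models list of `transcript_model`s (or a [transcript_index()]).
#' @param bin_size bin width in nt (default 50).
#' @return data.frame with reference, start, end, clip_count, input_count.
#' @export
bin_counts <- function(clip_aln, input_aln, models, bin_size = 50) {
  ti <- if (is.data.frame(models)) models else transcript_index(models)
  nb <- ceiling(ti$tx_length / bin_size)
  bins <- data.frame(
    reference = rep(ti$reference, nb),
    start = unlist(lapply(nb, function(k) (seq_len(k) - 1) * bin_size)),
    stringsAsFactors = FALSE)
  bins$end <- pmin(bins$start + bin_size,
                   rep(ti$tx_length, nb))
  key <- paste(bins$reference, bins$start %/% bin_size)
  tally <- function(aln) {
    aln <- aln[aln$unique & aln$reference %in% ti$reference, , drop = FALSE]
    k <- paste(aln$reference, aln$five_prime_pos %/% bin_size)
    tb <- table(factor(k, levels = key))
    as.numeric(tb)
  }
  bins$clip_count <- tally(clip_aln)
  bins$input_count <- tally(input_aln)
  bins
}

# negative log-likelihood of a zero-truncated NB regression on log(input+1)
ztnb_negll <- function(par, y, lx) {
  mu <- exp(par[1] + par[2] * lx)
  size <- exp(par[3])
  ll <- stats::dnbinom(y, mu = mu, size = size, log = TRUE) -
    log1p(-stats::dnbinom(0, mu = mu, size = size))
  -sum(ll)
}

#' Call CLIP peaks by zero-truncated negative binomial over input
#'
#' Bins with at least one CLIP read enter a zero-truncated negative
#' binomial regression with mean `exp(b0 + b1 * log(scaled_input + 1))`,
#' where the input covariate of a bin is its expected input count under the
#' gene's input rate (gene input total scaled by bin width over transcript
#' length) scaled by the CLIP/input library-size ratio. Gene-level
#' smoothing matters: the raw per-bin input count is itself a noisy
#' estimate of the local background, and conditioning on it directly makes
#' bins whose input fluctuates low spuriously significant. `b0`, `b1` and
#' the dispersion are estimated by direct maximization of the
#' zero-truncated likelihood.
#' Each bin's p-value is the upper tail of its fitted
#' zero-truncated distribution at the observed count
#' (`P(Y >= y | Y >= 1)`); bins below `p_threshold` are peaks. The fit is
#' two-pass: bins called at the first pass (signal) are excluded and the
#' null refitted on the remainder, so strong peaks do not inflate the null
#' dispersion. On non-convergence the fit falls back to method-of-moments
#' NB with a warning.
#'
#' @param bins a [bin_counts()] table.
#' @param p_threshold peak p-value threshold (default 0.01).
#' @param replicate_id label attached to the peaks.
#' @return data.frame of all fitted bins with `p_value` and `is_peak`;
#'   attribute `"fit"` records the fitted parameters.
#' @export
call_peaks <- function(bins, p_threshold = 0.01, replicate_id = "rep1") {
  fit_bins <- bins[bins$clip_count >= 1, , drop = FALSE]
  if (nrow(fit_bins) == 0) stop("no bins with CLIP reads")
  scale <- sum(bins$clip_count) / max(sum(bins$input_count), 1)
  if (sum(bins$input_count) == 0) {
    warning("all-zero input: using constant offset")
    lx <- rep(0, nrow(fit_bins))
  } else {
    # per-gene smoothed expected input per bin
    widths <- bins$end - bins$start
    gene_input <- tapply(bins$input_count, bins$reference, sum)
    gene_len <- tapply(widths, bins$reference, sum)
    exp_input <- as.numeric(gene_input[bins$reference]) * widths /
      as.numeric(gene_len[bins$reference])
    lx <- log(scale * exp_input[bins$clip_count >= 1] + 1)
  }
  y <- fit_bins$clip_count
  fit_ztnb <- function(y, lx) {
    start <- c(log(max(mean(y / exp(lx)), 1e-3)), 1, 0)
    opt <- try(stats::optim(start, ztnb_negll, y = y, lx = lx,
                            method = "BFGS"), silent = TRUE)
    if (inherits(opt, "try-error") || opt$convergence != 0) {
      warning("ZTNB fit did not converge; falling back to method-of-moments NB")
      r <- y / exp(lx)
      mu_hat <- mean(r)
      v <- stats::var(r)
      list(b0 = log(mu_hat), b1 = 1,
           size = if (v > mu_hat) mu_hat^2 / (v - mu_hat) else 100)
    } else list(b0 = opt$par[1], b1 = opt$par[2], size = exp(opt$par[3]))
  }
  pvals <- function(fit, y, lx) {
    mu <- exp(fit$b0 + fit$b1 * lx)
    p0 <- stats::dnbinom(0, mu = mu, size = fit$size)
    p <- (1 - stats::pnbinom(y - 1, mu = mu, size = fit$size)) / (1 - p0)
    pmin(pmax(p, .Machine$double.xmin), 1)
  }
  fit <- fit_ztnb(y, lx)
  p <- pvals(fit, y, lx)
  # second pass: refit the null without decisively significant bins, so
  # strong peaks cannot inflate the null dispersion; the exclusion cutoff
  # is far below p_threshold so near-null bins stay in the fit and the
  # refit is unbiased on signal-free data
  null_set <- p >= min(p_threshold, 1e-4)
  if (any(!null_set) && sum(null_set) >= 10) {
    fit <- fit_ztnb(y[null_set], lx[null_set])
    p <- pvals(fit, y, lx)
  }
  fit_bins$p_value <- p
  fit_bins$is_peak <- fit_bins$p_value < p_threshold
  fit_bins$replicate_id <- replicate_id
  structure(fit_bins, fit = c(fit, scale = scale))
}

#' Merge peaks across replicates by center distance
#'
#' Peaks from both replicates are pooled per reference and grouped by
#' single-linkage: peaks whose centers are within `max_center_distance` nt
#' (directly or through intermediates) form one group. Groups supported by
#' both replicates become merged peaks spanning the union of their members;
#' others are discarded and counted.
#'
#' @param peaks_rep1,peaks_rep2 [call_peaks()] outputs (only `is_peak` rows
#'   are used).
#' @param max_center_distance maximum center-to-center distance (nt,
#'   inclusive; default 100).
#' @return data.frame of merged peaks (reference, start, end, center,
#'   n_rep1, n_rep2, clip_count, input_count); attribute
#'   `"n_discarded"` counts single-replicate groups.
#' @export
merge_peaks <- function(peaks_rep1, peaks_rep2, max_center_distance = 100) {
  pool <- rbind(peaks_rep1[peaks_rep1$is_peak, , drop = FALSE],
                peaks_rep2[peaks_rep2$is_peak, , drop = FALSE])
  if (nrow(pool) == 0)
    return(structure(data.frame(), n_discarded = 0L))
  pool$center <- (pool$start + pool$end) / 2
  pool <- pool[order(pool$reference, pool$center), ]
  new_group <- c(TRUE, pool$reference[-1] != pool$reference[-nrow(pool)] |
                   diff(pool$center) > max_center_distance)
  pool$group <- cumsum(new_group)
  labs <- sort(unique(pool$replicate_id))
  merged <- lapply(split(pool, pool$group), function(g) {
    if (length(unique(g$replicate_id)) < 2) return(NULL)
    data.frame(reference = g$reference[1], start = min(g$start),
               end = max(g$end), center = (min(g$start) + max(g$end)) / 2,
               n_rep1 = sum(g$replicate_id == labs[1]),
               n_rep2 = sum(g$replicate_id == labs[2]),
               n_members = nrow(g),
               clip_count = sum(g$clip_count),
               input_count = sum(g$input_count),
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(merged, is.null, TRUE)
  out <- do.call(rbind, merged[keep])
  if (is.null(out)) out <- data.frame()
  structure(out, n_discarded = sum(!keep))
}

#' Annotate merged peaks with gene regions
#'
#' The label is the region containing the peak center on the gene's
#' selected isoform, with precedence 3'UTR > 5'UTR > CDS > intron on
#' ambiguity; peaks outside any gene are labelled intergenic and excluded
#' from the percentages.
#'
#' @param merged_peaks a [merge_peaks()] table.
#' @param models list of `transcript_model`s.
#' @return the peak table with `gene_id` and `region` columns; attribute
#'   `"percentages"` gives region percentages over annotated peaks
#'   (summing to 100).
#' @export
annotate_peaks <- function(merged_peaks, models) {
  ti <- transcript_index(select_isoforms(models))
  i <- match(merged_peaks$reference, ti$reference)
  pos <- merged_peaks$center
  region <- rep("intergenic", nrow(merged_peaks))
  ok <- !is.na(i) & pos >= 0 & pos < ti$tx_length[i]
  region[ok] <- ifelse(pos[ok] >= ti$cds_tx_end[i[ok]], "3'UTR",
                       ifelse(pos[ok] < ti$cds_tx_start[i[ok]], "5'UTR",
                              "CDS"))
  merged_peaks$gene_id <- ifelse(ok, ti$gene_id[i], NA_character_)
  merged_peaks$region <- region
  ann <- region[region != "intergenic"]
  pct <- 100 * table(factor(ann, levels = c("3'UTR", "5'UTR", "CDS",
                                            "intron"))) / max(length(ann), 1)
  if (any(region == "intergenic"))
    log_info("annotate_peaks: %d intergenic peak(s) excluded",
             sum(region == "intergenic"))
  structure(merged_peaks, percentages = pct)
}

#' Extract peak sequences for motif discovery
#'
#' @param peaks annotated peak table (needs reference, start, end).
#' @param sequences named character vector of transcript sequences.
#' @param pad nt added on both sides (default 0), clipped to the transcript.
#' @return named character vector of peak sequences.
#' @export
peak_sequences <- function(peaks, sequences, pad = 0) {
  out <- character(nrow(peaks))
  for (k in seq_len(nrow(peaks))) {
    s <- sequences[[peaks$reference[k]]]
    a <- max(0, peaks$start[k] - pad)
    b <- min(nchar(s), peaks$end[k] + pad)
    out[k] <- substr(s, a + 1, b)
  }
  stats::setNames(out, sprintf("%s_%d_%d", peaks$reference,
                               peaks$start, peaks$end))
}

#' Write peaks as BED6 (score column = -log10 p)
#'
#' @param peaks peak or merged-peak table.
#' @param path output file.
#' @export
write_peaks_bed6 <- function(peaks, path) {
  score <- if ("p_value" %in% names(peaks))
    round(pmin(-log10(peaks$p_value), 1000), 2) else 0
  df <- data.frame(peaks$reference, peaks$start, peaks$end,
                   sprintf("peak%d", seq_len(nrow(peaks))), score, "+")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
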