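#' Metagene profile of read 5' ends around start or stop codons
#'
#' Sums, over transcripts, the density of unique read 5' ends at each
#' position of a -50..+50 nt window anchored at the first base of the start
#' codon (`anchor = "start"`) or of the stop codon (`anchor = "stop"`).
#' Only unique alignments of exactly `read_length` nt contribute; density is
#' reads per million uniquely mapped reads (RPM), so duplicating the input
#' leaves the profile unchanged. Transcripts whose window overhangs their
#' ends contribute only in-bounds positions.
#'
#' @param aln alignment data.frame in transcript coordinates.
#' @param models list of `transcript_model`s (or a [transcript_index()]).
#' @param anchor `"start"` or `"stop"`.
#' @param read_length footprint length used for the profile (default 28).
#' @param window half-width of the window (nt).
#' @return object of class `metagene_profile`: data.frame with `position`
#'   (relative to the anchor codon's first base) and `density` (RPM).
#' @export
metagene_profile <- function(aln, models, anchor = c("start", "stop"),
                             read_length = 28, window = 50) {
  anchor <- match.arg(anchor)
  ti <- if (is.data.frame(models)) models else transcript_index(models)
  aln <- aln[aln$unique, , drop = FALSE]
  total_unique <- nrow(aln)
  aln <- aln[aln$length == read_length, , drop = FALSE]
  i <- match(aln$reference, ti$reference)
  keep <- !is.na(i)
  aln <- aln[keep, , drop = FALSE]; i <- i[keep]
  if (nrow(aln) == 0) stop("empty profile: no qualifying reads")
  anchor_pos <- if (anchor == "start") ti$cds_tx_start[i] else
    ti$cds_tx_end[i] - 3
  rel <- aln$five_prime_pos - anchor_pos
  in_win <- rel >= -window & rel <= window
  tb <- table(factor(rel[in_win], levels = -window:window))
  prof <- data.frame(position = -window:window,
                     density = as.numeric(tb) * 1e6 / total_unique)
  structure(prof, class = c("metagene_profile", "data.frame"),
            anchor = anchor, read_length = read_length,
            total_unique = total_unique)
}

#' Estimate P- and A-site offsets from metagene profiles
#'
#' The P-site offset is minus the argmax position of the start-anchored
#' profile over window positions -40..-1; the stop-anchored (A-site) offset
#' is defined the same way on the stop profile. Peak prominence is the peak
#' density divided by the median density of the search window; prominence
#' below 2 triggers a weak-signal warning, and a tie at the maximum is an
#' error reporting the tied positions.
#'
#' @param start_profile,stop_profile [metagene_profile()]s anchored at start
#'   and stop codons.
#' @return list with `p_site_offset`, `a_site_offset` (nt) and their
#'   prominences.
#' @export
estimate_offsets <- function(start_profile, stop_profile) {
  peak <- function(prof, label) {
    w <- prof[prof$position >= -40 & prof$position <= -1, ]
    if (nrow(w) == 0 || all(w$density == 0))
      stop("ambiguous peak (", label, "): flat profile")
    top <- which(w$density == max(w$density))
    if (length(top) > 1)
      stop("ambiguous peak (", label, "): tie at positions ",
           paste(w$position[top], collapse = ", "))
    med <- stats::median(w$density)
    prom <- if (med > 0) w$density[top] / med else Inf
    if (prom < 2)
      warning("weak signal (", label, "): peak prominence ",
              format(prom, digits = 3), " < 2")
    list(offset = -w$position[top], prominence = prom)
  }
  p <- peak(start_profile, "start")
  a <- peak(stop_profile, "stop")
  list(p_site_offset = p$offset, a_site_offset = a$offset,
       p_site_prominence = p$prominence, a_site_prominence = a$prominence)
}

#' Codon periodicity of CDS-internal read 5' ends
#'
#' Counts unique `read_length`-nt read 5' ends in the three CDS frames
#' (frame = (position - CDS start) mod 3), excluding reads within
#' `boundary_exclude` nt of the CDS start or stop to keep initiation and
#' termination spikes out of the frame statistics, and computes the
#' mean-removed positional autocorrelation of the pooled CDS 5'-end density
#' at lags 1..9. Pooling over transcripts of unequal CDS length and unequal
#' expression induces a smooth positional trend that is not periodicity; the
#' autocorrelation is therefore computed on the residual of the pooled
#' density against its expression-weighted expected coverage (each
#' transcript contributing its own mean read rate over the offsets it
#' covers), over CDS offsets up to the `coverage_quantile` of CDS lengths.
#'
#' @inheritParams metagene_profile
#' @param boundary_exclude nt excluded at both CDS ends (default 15).
#' @param max_lag largest autocorrelation lag examined.
#' @param coverage_quantile CDS-length quantile bounding the positional
#'   window of the autocorrelation.
#' @return list with `frame_counts` (length 3), `chi_square` statistic and
#'   p-value against a uniform 1/3 split, `autocorrelation` (lags 1..max_lag),
#'   and `dominant_period` (nt).
#' @export
frame_periodicity <- function(aln, models, read_length = 28,
                              boundary_exclude = 15, max_lag = 9,
                              coverage_quantile = 0.7) {
  ti <- if (is.data.frame(models)) models else transcript_index(models)
  aln <- aln[aln$unique & aln$length == read_length, , drop = FALSE]
  i <- match(aln$reference, ti$reference)
  keep <- !is.na(i)
  aln <- aln[keep, , drop = FALSE]; i <- i[keep]
  rel <- aln$five_prime_pos - ti$cds_tx_start[i]
  internal <- rel >= boundary_exclude &
    rel < ti$cds_length[i] - boundary_exclude
  rel <- rel[internal]; i_int <- i[internal]
  if (length(rel) < 100) stop("insufficient reads: ", length(rel),
                              " CDS-internal 5' ends (>=100 required)")
  frame_counts <- as.integer(table(factor(rel %% 3, levels = 0:2)))
  chi <- stats::chisq.test(frame_counts, p = rep(1 / 3, 3))
  # residual autocorrelation against expression-weighted expected coverage
  cap <- floor(stats::quantile(ti$cds_length, coverage_quantile)) -
    boundary_exclude
  upper <- pmin(ti$cds_length - boundary_exclude, cap)  # per-tx window end
  in_win <- rel < upper[i_int]
  relw <- rel[in_win]; iw <- i_int[in_win]
  n_t <- as.numeric(table(factor(iw, levels = seq_len(nrow(ti)))))
  len_t <- pmax(upper - boundary_exclude, 0)
  rate_t <- ifelse(len_t > 0, n_t / len_t, 0)
  pos <- boundary_exclude:(cap - 1)
  d <- as.numeric(table(factor(relw, levels = pos)))
  # expected[pos] = sum of rates of transcripts whose window covers pos
  expected <- vapply(pos, function(p0) sum(rate_t[upper > p0]), 0)
  resid <- d - expected
  denom <- sum(resid^2)
  ac <- vapply(seq_len(max_lag), function(l)
    sum(resid[seq_len(length(resid) - l)] * resid[-seq_len(l)]) / denom, 0)
  list(frame_counts = frame_counts,
       chi_square = unname(chi$statistic), chi_p = chi$p.value,
       autocorrelation = ac, dominant_period = which.max(ac),
       n_reads = length(rel))
}

#' Read density of UTRs and introns relative to the CDS
#'
#' For each transcript, density is unique reads per nt of region, a read
#' being assigned to the region containing its (5' end + `psite_offset`)
#' position; the table reports 5'UTR, 3'UTR and intron densities divided by
#' the CDS density. For footprints, passing the P-site offset estimated
#' from the metagene profiles keeps initiation footprints (whose 5' ends
#' protrude 12 nt into the 5'UTR) assigned to the CDS they translate;
#' leave it 0 for RNA fragments. Transcripts with zero CDS density are
#' excluded; zero-length regions give missing ratios.
#'
#' @inheritParams metagene_profile
#' @param psite_offset nt added to 5' ends before region assignment
#'   (default 0).
#' @return data.frame (one row per transcript with CDS reads) with columns
#'   `utr5_ratio`, `utr3_ratio`, `intron_ratio`; summary quartiles in
#'   attribute `"quartiles"`.
#' @export
region_density_ratios <- function(aln, models, psite_offset = 0) {
  if (is.data.frame(models))
    stop("region_density_ratios needs the full transcript models")
  ti <- transcript_index(models)
  intron_len <- vapply(models, function(m)
    if (nrow(m$introns)) sum(m$introns[, 2] - m$introns[, 1]) else 0, 0)
  aln <- aln[aln$unique, , drop = FALSE]
  i <- match(aln$reference, ti$reference)
  keep <- !is.na(i)
  aln <- aln[keep, , drop = FALSE]; i <- i[keep]
  pos <- pmin(aln$five_prime_pos + psite_offset, ti$tx_length[i] - 1)
  region <- ifelse(pos < ti$cds_tx_start[i], "utr5",
                   ifelse(pos < ti$cds_tx_end[i], "cds", "utr3"))
  cnt <- function(r) {
    tb <- table(factor(i[region == r], levels = seq_len(nrow(ti))))
    as.numeric(tb)
  }
  n5 <- cnt("utr5"); nc <- cnt("cds"); n3 <- cnt("utr3")
  dens <- function(n, len) ifelse(len > 0, n / len, NA_real_)
  cds_d <- dens(nc, ti$cds_length)
  out <- data.frame(
    transcript_id = ti$transcript_id,
    utr5_ratio = dens(n5, ti$utr5_length) / cds_d,
    utr3_ratio = dens(n3, ti$utr3_length) / cds_d,
    intron_ratio = dens(0, intron_len) / cds_d,  # transcript-space reads never intronic
    stringsAsFactors = FALSE)
  out <- out[!is.na(cds_d) & cds_d > 0, ]
  q <- apply(out[, -1], 2, stats::quantile,
             probs = c(0.25, 0.5, 0.75), na.rm = TRUE)
  structure(out, quartiles = q)
}

#' Pairwise Pearson correlation of replicates on log2 RPM
#'
#' Genes are retained only if their count exceeds `min_reads` in every
#' sample; counts are normalized to reads per million mapped (RPM) and
#' log2-transformed before correlation.
#'
#' @param ct a [count_table()].
#' @param min_reads retention threshold (default 10, strictly greater).
#' @return symmetric correlation matrix with unit diagonal; attribute
#'   `"n_genes"` gives the retained gene count.
#' @export
replicate_correlation <- function(ct, min_reads = 10) {
  stopifnot(inherits(ct, "count_table"))
  keep <- apply(ct$counts, 1, function(x) all(x > min_reads))
  if (sum(keep) < 3) stop("fewer than 3 genes pass the min_reads filter")
  rpm <- sweep(ct$counts[keep, , drop = FALSE] * 1e6, 2, ct$totals, "/")
  structure(stats::cor(log2(rpm)), n_genes = sum(keep))
}

#' @export
#' @rdname metagene_profile
#' @param x a `metagene_profile`.
#' @param ... passed to [plot()].
plot.metagene_profile <- function(x, ...) {
  graphics::plot(x$position, x$density, type = "h", lwd = 2,
                 xlab = sprintf("position relative to %s codon (nt)",
                                attr(x, "anchor")),
                 ylab = "5'-end density (RPM)", ...)
  invisible(x)
}

#' Bar plot of CDS frame counts
#'
#' @param spectrum a [frame_periodicity()] result.
#' @param ... passed to [graphics::barplot()].
#' @export
plot_frame_counts <- function(spectrum, ...) {
  graphics::barplot(spectrum$frame_counts, names.arg = 0:2,
                    xlab = "reading frame of 5' end",
                    ylab = "CDS-internal reads", ...)
  invisible(spectrum)
}
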