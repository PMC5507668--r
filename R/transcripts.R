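#' Transcript model with CDS-defined regions
#'
#' A `transcript_model` holds the exon structure and coding span of one
#' transcript and exposes the derived 5'UTR / CDS / 3'UTR / intron
#' decomposition. All coordinates are 0-based half-open; for minus-strand
#' transcripts, transcript coordinate 0 is the exonic base with the largest
#' genomic coordinate.
#'
#' @param gene_id,transcript_id identifiers.
#' @param reference chromosome (or transcript) name the exons live on.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix of (start, end) genomic intervals,
#'   0-based half-open, sorted and non-overlapping.
#' @param cds_start,cds_end genomic coordinates of the coding span
#'   (0-based half-open; the span includes the stop codon).
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, transcript_id, reference, strand,
                             exons, cds_start, cds_end) {
  exons <- matrix(as.numeric(exons), ncol = 2)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (nrow(exons) == 0) stop("transcript needs at least one exon")
  if (any(exons[, 2] <= exons[, 1])) stop("empty or inverted exon interval")
  o <- order(exons[, 1])
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("overlapping exons")
  widths <- exons[, 2] - exons[, 1]
  tx_length <- sum(widths)
  if (cds_end <= cds_start) stop("empty CDS span")
  m <- list(gene_id = gene_id, transcript_id = transcript_id,
            reference = reference, strand = strand, exons = exons,
            cds_start = cds_start, cds_end = cds_end,
            tx_length = tx_length)
  class(m) <- "transcript_model"
  # CDS boundaries must be exonic
  if (is.na(genomic_to_transcript(m, cds_start)) ||
      is.na(genomic_to_transcript(m, cds_end - 1)))
    stop("CDS boundaries fall outside the exon union")
  sp <- cds_tx_span(m)
  cds_length <- sp[2] - sp[1]
  if (cds_length %% 3 != 0)
    stop(sprintf("CDS length %d not divisible by 3", cds_length))
  m$cds_tx_start <- sp[1]
  m$cds_tx_end <- sp[2]
  m$cds_length <- cds_length
  m$utr5_length <- sp[1]
  m$utr3_length <- tx_length - sp[2]
  m$introns <- if (nrow(exons) > 1)
    cbind(exons[-nrow(exons), 2], exons[-1, 1]) else
    matrix(numeric(0), ncol = 2)
  m
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model %s (%s) %s:%s %d exon(s), 5'UTR %d / CDS %d / 3'UTR %d nt>\n",
              x$transcript_id, x$gene_id, x$reference, x$strand,
              nrow(x$exons), x$utr5_length, x$cds_length, x$utr3_length))
  invisible(x)
}

#' Map genomic positions to transcript coordinates
#'
#' @param model a `transcript_model`.
#' @param pos vector of genomic positions (0-based). Non-exonic positions map
#'   to `NA`.
#' @return transcript coordinates (0-based), strand-aware.
#' @export
genomic_to_transcript <- function(model, pos) {
  ex <- model$exons
  cum <- cumsum(c(0, ex[, 2] - ex[, 1]))
  out <- rep(NA_real_, length(pos))
  for (i in seq_len(nrow(ex))) {
    in_ex <- !is.na(pos) & pos >= ex[i, 1] & pos < ex[i, 2]
    out[in_ex] <- cum[i] + (pos[in_ex] - ex[i, 1])
  }
  if (model$strand == "-") out <- model$tx_length - 1 - out
  out
}

#' Map transcript positions to genomic coordinates
#'
#' Inverse of [genomic_to_transcript()]; exact round-trip for every exonic
#' position.
#' @inheritParams genomic_to_transcript
#' @param pos vector of transcript positions (0-based).
#' @export
transcript_to_genomic <- function(model, pos) {
  ex <- model$exons
  cum <- cumsum(c(0, ex[, 2] - ex[, 1]))
  p <- if (model$strand == "-") model$tx_length - 1 - pos else pos
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p >= 0 & p < model$tx_length
  idx <- findInterval(p[ok], cum, rightmost.closed = FALSE)
  out[ok] <- ex[idx, 1] + (p[ok] - cum[idx])
  out
}

# transcript-coordinate half-open CDS span (includes the stop codon)
cds_tx_span <- function(model) {
  if (model$strand == "+") {
    c(genomic_to_transcript(model, model$cds_start),
      genomic_to_transcript(model, model$cds_end - 1) + 1)
  } else {
    c(genomic_to_transcript(model, model$cds_end - 1),
      genomic_to_transcript(model, model$cds_start) + 1)
  }
}

#' Select one representative isoform per gene
#'
#' The isoform with the longest CDS is kept; ties are broken by longest
#' transcript, then lexicographic transcript id.
#'
#' @param models list of `transcript_model`s.
#' @return named list of models, one per gene.
#' @export
select_isoforms <- function(models) {
  df <- data.frame(
    i = seq_along(models),
    gene = vapply(models, `[[`, "", "gene_id"),
    cds = vapply(models, `[[`, 0, "cds_length"),
    len = vapply(models, `[[`, 0, "tx_length"),
    tid = vapply(models, `[[`, "", "transcript_id"),
    stringsAsFactors = FALSE)
  df <- df[order(df$gene, -df$cds, -df$len, df$tid), ]
  keep <- df$i[!duplicated(df$gene)]
  out <- models[sort(keep)]
  names(out) <- vapply(out, `[[`, "", "gene_id")
  out
}

#' Tabulate transcript models for vectorized analytics
#'
#' Builds a data frame keyed by the alignment reference name. For
#' transcript-space alignments (the simulator default) the reference is the
#' transcript id and all region boundaries are transcript coordinates.
#'
#' @param models list of `transcript_model`s (typically one per gene,
#'   see [select_isoforms()]).
#' @return data.frame with one row per model.
#' @export
transcript_index <- function(models) {
  if (inherits(models, "transcript_model")) models <- list(models)
  data.frame(
    reference = vapply(models, function(m)
      if (identical(m$reference, m$transcript_id)) m$reference else m$transcript_id,
      ""),
    gene_id = vapply(models, `[[`, "", "gene_id"),
    transcript_id = vapply(models, `[[`, "", "transcript_id"),
    tx_length = vapply(models, `[[`, 0, "tx_length"),
    utr5_length = vapply(models, `[[`, 0, "utr5_length"),
    cds_length = vapply(models, `[[`, 0, "cds_length"),
    utr3_length = vapply(models, `[[`, 0, "utr3_length"),
    cds_tx_start = vapply(models, `[[`, 0, "cds_tx_start"),
    cds_tx_end = vapply(models, `[[`, 0, "cds_tx_end"),
    stringsAsFactors = FALSE)
}

#' Extract the spliced transcript sequence in sense orientation
#'
#' @param model a `transcript_model`.
#' @param sequences named character vector of reference sequences (RNA
#'   alphabet). If it contains the transcript id, that entry is returned
#'   directly; otherwise the exon substrings of `sequences[[reference]]` are
#'   concatenated and reverse-complemented for minus-strand models.
#' @export
transcript_sequence <- function(model, sequences) {
  if (model$transcript_id %in% names(sequences))
    return(unname(sequences[[model$transcript_id]]))
  if (!model$reference %in% names(sequences))
    stop(sprintf("no sequence for reference '%s' (transcript %s)",
                 model$reference, model$transcript_id))
  chrom <- sequences[[model$reference]]
  parts <- apply(model$exons, 1, function(e) substr(chrom, e[1] + 1, e[2]))
  s <- paste(parts, collapse = "")
  if (model$strand == "-") s <- revcomp_rna(s)
  s
}
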