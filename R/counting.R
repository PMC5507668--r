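#' Gene-by-sample count table
#'
#' @param counts genes x samples matrix of non-negative integer counts
#'   (rownames = gene ids, colnames = sample ids).
#' @param lengths per-gene counting length (nt), named or in row order.
#' @param totals per-sample total mapped reads (>= column sums).
#' @param assay `"RPF"` or `"RNA"`.
#' @param stage per-sample stage (hours), parallel to columns.
#' @param replicate per-sample replicate label, parallel to columns.
#' @return object of class `count_table`.
#' @export
count_table <- function(counts, lengths, totals, assay = c("RPF", "RNA"),
                        stage = rep(NA_real_, ncol(counts)),
                        replicate = rep(1L, ncol(counts))) {
  assay <- match.arg(assay)
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  if (any(totals < colSums(counts)))
    stop("per-sample totals must be >= column sums")
  structure(list(counts = counts, lengths = lengths, totals = totals,
                 assay = assay,
                 samples = data.frame(sample = colnames(counts),
                                      stage = stage, replicate = replicate,
                                      stringsAsFactors = FALSE)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table %s: %d genes x %d samples, stages %s>\n",
              x$assay, nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$stage), collapse = ",")))
  invisible(x)
}

#' Count reads per gene by 5'-end region membership (union mode)
#'
#' A read is assigned to a gene if its 5' end falls inside the gene's
#' counting region on the matching strand. Reads overlapping no gene, or
#' more than one gene, are left unassigned (union-mode ambiguity) and
#' tallied. Only alignments flagged `unique` are counted.
#'
#' @param aln alignment data.frame (see [read_alignments()]).
#' @param models list of `transcript_model`s (one per gene).
#' @param region `"CDS"` (footprints) or `"exons"` (RNA fragments).
#' @return named integer vector of per-gene counts, with attributes
#'   `n_unassigned` and `n_ambiguous`.
#' @export
count_reads <- function(aln, models, region = c("CDS", "exons")) {
  region <- match.arg(region)
  aln <- aln[aln$unique, , drop = FALSE]
  gene_ids <- vapply(models, `[[`, "", "gene_id")
  reg <- lapply(models, function(m) {
    ex <- m$exons
    if (region == "CDS") {
      s <- pmax(ex[, 1], m$cds_start); e <- pmin(ex[, 2], m$cds_end)
      keep <- e > s
      ex <- cbind(s[keep], e[keep])
    }
    GenomicRanges::GRanges(m$reference,
                           IRanges::IRanges(ex[, 1] + 1, ex[, 2]),
                           strand = m$strand)
  })
  flat <- unlist(GenomicRanges::GRangesList(reg))
  flat$gene <- rep(seq_along(models),
                   lengths(lapply(reg, BiocGenerics::start)))
  counts <- integer(length(models))
  names(counts) <- gene_ids
  n_unassigned <- 0L; n_ambiguous <- 0L
  if (nrow(aln) > 0) {
    reads <- GenomicRanges::GRanges(aln$reference,
                                    IRanges::IRanges(aln$five_prime_pos + 1,
                                                     width = 1),
                                    strand = aln$strand)
    hits <- GenomicRanges::findOverlaps(reads, flat, ignore.strand = FALSE)
    hit_gene <- flat$gene[S4Vectors::subjectHits(hits)]
    per_read <- split(hit_gene, S4Vectors::queryHits(hits))
    genes_per_read <- vapply(per_read, function(x) length(unique(x)), 0L)
    one <- genes_per_read == 1L
    assigned <- vapply(per_read[one], `[[`, 0L, 1L)
    tb <- table(factor(assigned, levels = seq_along(models)))
    counts <- as.integer(tb)
    names(counts) <- gene_ids
    n_ambiguous <- sum(genes_per_read > 1L)
    n_unassigned <- nrow(aln) - length(per_read) + n_ambiguous
  }
  attr(counts, "n_unassigned") <- n_unassigned
  attr(counts, "n_ambiguous") <- n_ambiguous
  counts
}

#' Reads Per Kilobase of transcript per Million mapped reads
#'
#' `RPKM(g, s) = count * 1e9 / (length_nt * total_mapped)`; zero counts give
#' zero RPKM. Doubling all counts and totals leaves RPKM unchanged.
#'
#' @param ct a [count_table()].
#' @return genes x samples matrix of RPKM values.
#' @export
rpkm <- function(ct) {
  stopifnot(inherits(ct, "count_table"))
  if (any(ct$totals == 0)) stop("zero total mapped reads in a sample")
  sweep(ct$counts * 1e9 / ct$lengths, 2, ct$totals, "/")
}

#' Restrict a count table to a subset of stages
#'
#' @param ct a [count_table()].
#' @param stages stage values (hours) to keep.
#' @return a `count_table` with only the matching samples.
#' @export
subset_count_table <- function(ct, stages) {
  sel <- ct$samples$stage %in% stages
  if (!any(sel)) stop("no samples at the requested stages")
  count_table(ct$counts[, sel, drop = FALSE], ct$lengths, ct$totals[sel],
              assay = ct$assay, stage = ct$samples$stage[sel],
              replicate = ct$samples$replicate[sel])
}

# replicate-averaged RPKM per stage: genes x stages matrix
stage_rpkm <- function(ct) {
  r <- rpkm(ct)
  stages <- sort(unique(ct$samples$stage))
  out <- sapply(stages, function(s)
    rowMeans(r[, ct$samples$stage == s, drop = FALSE]))
  colnames(out) <- paste0("hr", stages)
  out
}
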