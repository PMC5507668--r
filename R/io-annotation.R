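#' Read transcript annotation from BED12 or GTF
#'
#' Builds one [transcript_model()] per transcript. BED12 `thickStart` /
#' `thickEnd` or GTF `CDS` features define the coding span (which, by the
#' package convention, includes the stop codon). Transcript names of the form
#' `gene|transcript` carry the gene id; otherwise the name serves as both.
#' Transcripts violating the model invariants (e.g. CDS length not divisible
#' by 3) are skipped with a warning and counted, never silently dropped.
#'
#' @param path BED12 (`.bed`) or GTF (`.gtf`) file.
#' @param format `"auto"` (by extension), `"bed12"` or `"gtf"`.
#' @return list of `transcript_model`s; attribute `n_skipped` counts skipped
#'   transcripts.
#' @export
read_annotation <- function(path, format = c("auto", "bed12", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed12", gtf = "gtf", gff = "gtf",
                     stop("cannot infer annotation format from '", ext, "'"))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    warning("empty annotation file: ", path)
    return(structure(list(), n_skipped = 0L))
  }
  if (format == "bed12") {
    nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
    if (any(nf != 12))
      stop(sprintf("parse error: line %d of %s has %d fields (12 expected)",
                   which(nf != 12)[1], path, nf[nf != 12][1]))
    gr <- rtracklayer::import(path, format = "BED")
    specs <- lapply(seq_along(gr), function(i) {
      b <- rtracklayer::blocks(gr)[[i]]
      list(name = gr$name[i],
           reference = as.character(GenomicRanges::seqnames(gr)[i]),
           strand = as.character(GenomicRanges::strand(gr)[i]),
           exons = cbind(BiocGenerics::start(b) - 1, BiocGenerics::end(b)),
           cds_start = BiocGenerics::start(gr$thick)[i] - 1,
           cds_end = BiocGenerics::end(gr$thick)[i])
    })
  } else {
    gr <- rtracklayer::import(path, format = "GTF")
    if (!all(c("type", "transcript_id") %in% names(S4Vectors::mcols(gr))))
      stop("GTF lacks type/transcript_id attributes: ", path)
    tx_ids <- unique(gr$transcript_id[gr$type %in% c("exon", "CDS")])
    specs <- lapply(tx_ids, function(tid) {
      sub <- gr[gr$transcript_id == tid]
      ex <- sub[sub$type == "exon"]
      cds <- sub[sub$type == "CDS"]
      if (length(ex) == 0 || length(cds) == 0) return(NULL)
      gid <- if ("gene_id" %in% names(S4Vectors::mcols(sub)) &&
                 !is.na(sub$gene_id[1])) sub$gene_id[1] else tid
      list(name = paste0(gid, "|", tid),
           reference = as.character(GenomicRanges::seqnames(ex)[1]),
           strand = as.character(GenomicRanges::strand(ex)[1]),
           exons = cbind(BiocGenerics::start(ex) - 1, BiocGenerics::end(ex)),
           cds_start = min(BiocGenerics::start(cds)) - 1,
           cds_end = max(BiocGenerics::end(cds)))
    })
    specs <- specs[!vapply(specs, is.null, TRUE)]
  }
  models <- list()
  skipped <- 0L
  for (sp in specs) {
    ids <- strsplit(sp$name, "|", fixed = TRUE)[[1]]
    gene_id <- ids[1]
    tx_id <- if (length(ids) > 1) ids[2] else ids[1]
    m <- tryCatch(
      transcript_model(gene_id, tx_id, sp$reference, sp$strand, sp$exons,
                       sp$cds_start, sp$cds_end),
      error = function(e) {
        warning(sprintf("skipping transcript %s: %s", tx_id,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (is.null(m)) skipped <- skipped + 1L else models[[length(models) + 1]] <- m
  }
  if (skipped > 0) log_info("read_annotation: skipped %d invalid transcript(s)", skipped)
  structure(models, n_skipped = skipped)
}

#' Write transcript models as BED12
#'
#' @param models list of `transcript_model`s.
#' @param path output file.
#' @export
write_annotation_bed12 <- function(models, path) {
  lines <- vapply(models, function(m) {
    ex <- m$exons
    chromStart <- min(ex[, 1])
    name <- if (identical(m$gene_id, m$transcript_id)) m$transcript_id else
      paste0(m$gene_id, "|", m$transcript_id)
    paste(m$reference, format(chromStart, scientific = FALSE),
          format(max(ex[, 2]), scientific = FALSE), name, 0, m$strand,
          format(m$cds_start, scientific = FALSE),
          format(m$cds_end, scientific = FALSE), "0", nrow(ex),
          paste0(paste(ex[, 2] - ex[, 1], collapse = ","), ","),
          paste0(paste(ex[, 1] - chromStart, collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write transcript models as GTF (exon + CDS features)
#'
#' The CDS features span the full coding interval including the stop codon,
#' so the GTF and BED12 writers describe identical models.
#' @inheritParams write_annotation_bed12
#' @export
write_annotation_gtf <- function(models, path) {
  out <- unlist(lapply(models, function(m) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     m$gene_id, m$transcript_id)
    ex_lines <- apply(m$exons, 1, function(e)
      paste(m$reference, "riboclip", "exon",
            format(e[1] + 1, scientific = FALSE),
            format(e[2], scientific = FALSE),
            ".", m$strand, ".", attrs, sep = "\t"))
    # CDS features: intersect the coding span with each exon
    cds <- apply(m$exons, 1, function(e) {
      s <- max(e[1], m$cds_start); en <- min(e[2], m$cds_end)
      if (en <= s) return(NA_character_)
      paste(m$reference, "riboclip", "CDS",
            format(s + 1, scientific = FALSE),
            format(en, scientific = FALSE),
            ".", m$strand, ".", attrs, sep = "\t")
    })
    c(ex_lines, cds[!is.na(cds)])
  }))
  writeLines(out, path)
  invisible(path)
}
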