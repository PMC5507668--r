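#' Read aligned reads as strand-aware 5'-end records
#'
#' Each alignment is reduced to (reference, strand, 5'-end coordinate,
#' length, MAPQ, uniqueness). The 5' end is the 5'-most aligned base on the
#' read's strand, 0-based: for minus-strand reads it is the rightmost
#' aligned base. Reads with MAPQ below `min_mapq` are flagged
#' `unique = FALSE` (the uniqueness proxy mirroring an HTSeq `-a 10` style
#' filter) but are kept in the stream.
#'
#' @param path SAM/BAM or 6-column BED file (BED score column = MAPQ).
#' @param min_mapq MAPQ threshold for the uniqueness flag (default 10).
#' @param sample_id sample label attached to every record.
#' @param known_references optional character vector; references outside it
#'   raise an error naming the offenders.
#' @param format `"auto"`, `"sam"`, `"bam"` or `"bed6"`.
#' @return data.frame with columns reference, strand, five_prime_pos,
#'   length, mapq, unique, sample_id.
#' @export
read_alignments <- function(path, min_mapq = 10, sample_id = basename(path),
                            known_references = NULL,
                            format = c("auto", "sam", "bam", "bed6")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sam = "sam", bam = "bam", bed = "bed6",
                     stop("cannot infer alignment format from '", ext, "'"))
  }
  if (format == "bed6") {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "start", "end", "name",
                                          "score", "strand"),
                            colClasses = c("character", "numeric", "numeric",
                                           "character", "numeric", "character"))
    aln <- data.frame(
      reference = df$chrom,
      strand = df$strand,
      five_prime_pos = ifelse(df$strand == "-", df$end - 1, df$start),
      length = as.integer(df$end - df$start),
      mapq = as.integer(df$score),
      stringsAsFactors = FALSE)
  } else {
    bam <- path
    if (format == "sam") {
      bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                              indexDestination = FALSE)
    }
    ga <- GenomicAlignments::readGAlignments(
      bam, param = Rsamtools::ScanBamParam(what = "mapq"))
    st <- as.character(GenomicAlignments::strand(ga))
    aln <- data.frame(
      reference = as.character(GenomicAlignments::seqnames(ga)),
      strand = st,
      five_prime_pos = ifelse(st == "-",
                              BiocGenerics::end(ga) - 1,
                              BiocGenerics::start(ga) - 1),
      length = GenomicAlignments::qwidth(ga),
      mapq = S4Vectors::mcols(ga)$mapq,
      stringsAsFactors = FALSE)
  }
  if (!is.null(known_references)) {
    bad <- setdiff(unique(aln$reference), known_references)
    if (length(bad) > 0)
      stop("unknown reference name(s): ", paste(bad, collapse = ", "))
  }
  aln$unique <- !is.na(aln$mapq) & aln$mapq >= min_mapq
  aln$sample_id <- sample_id
  aln
}

#' Write alignment records as BED6 (score column = MAPQ)
#'
#' @param aln alignment data.frame (see [read_alignments()]).
#' @param path output file.
#' @export
write_alignments_bed6 <- function(aln, path) {
  start <- ifelse(aln$strand == "-",
                  aln$five_prime_pos - aln$length + 1,
                  aln$five_prime_pos)
  df <- data.frame(aln$reference, format(start, scientific = FALSE, trim = TRUE),
                   format(start + aln$length, scientific = FALSE, trim = TRUE),
                   sprintf("read%d", seq_len(nrow(aln))),
                   aln$mapq, aln$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write alignment records as SAM (ungapped, CIGAR `<len>M`)
#'
#' @inheritParams write_alignments_bed6
#' @param reference_lengths named vector of reference sequence lengths for
#'   the `@SQ` header lines.
#' @export
write_alignments_sam <- function(aln, path, reference_lengths) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(reference_lengths),
                     as.integer(reference_lengths)), con)
  start <- ifelse(aln$strand == "-",
                  aln$five_prime_pos - aln$length + 1,
                  aln$five_prime_pos)
  flag <- ifelse(aln$strand == "-", 16L, 0L)
  seq_field <- vapply(aln$length, function(n)
    paste(rep("N", n), collapse = ""), "")
  writeLines(paste(sprintf("read%d", seq_len(nrow(aln))), flag,
                   aln$reference, format(start + 1, scientific = FALSE, trim = TRUE),
                   as.integer(aln$mapq), paste0(aln$length, "M"),
                   "*", 0, 0, seq_field, "*", sep = "\t"), con)
  invisible(path)
}
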