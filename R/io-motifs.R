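#' Construct an RBP position weight matrix
#'
#' @param motif_id motif identifier.
#' @param rbp_name RNA-binding protein name.
#' @param matrix 4 x width matrix of probabilities, rows A, C, G, U.
#' @param renormalize_tol columns whose sums deviate from 1 by at most this
#'   are renormalized; larger deviations are an error.
#' @return object of class `motif_matrix`.
#' @export
motif_matrix <- function(motif_id, rbp_name, matrix, renormalize_tol = 1e-4) {
  m <- base::matrix(as.numeric(matrix), nrow = 4,
                    dimnames = list(c("A", "C", "G", "U"), NULL))
  if (ncol(m) < 4) stop("motif width must be >= 4")
  if (any(m < 0)) stop("negative probability in motif ", motif_id)
  cs <- colSums(m)
  if (any(abs(cs - 1) > renormalize_tol))
    stop(sprintf("motif %s: column sum %.6f deviates from 1 by more than %g",
                 motif_id, cs[which.max(abs(cs - 1))], renormalize_tol))
  m <- sweep(m, 2, cs, "/")
  structure(list(motif_id = motif_id, rbp_name = rbp_name,
                 width = ncol(m), matrix = m),
            class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("<motif_matrix %s (%s) width %d, consensus %s>\n",
              x$motif_id, x$rbp_name, x$width, motif_consensus(x)))
  invisible(x)
}

#' Column-wise argmax consensus of a PWM
#' @param motif a `motif_matrix`.
#' @export
motif_consensus <- function(motif) {
  paste(rownames(motif$matrix)[apply(motif$matrix, 2, which.max)],
        collapse = "")
}

#' Read motifs from a MEME minimal-format file
#'
#' Accepts ACGU or ACGT alphabets (T is mapped to U). Each motif's
#' letter-probability matrix is validated and lightly renormalized; column
#' sums off by more than 1e-4 are a parse error.
#'
#' @param path MEME minimal motif file.
#' @return list of [motif_matrix()] objects.
#' @export
read_meme_motifs <- function(path) {
  lines <- readLines(path)
  motif_at <- grep("^MOTIF\\b", lines)
  if (length(motif_at) == 0) stop("no MOTIF blocks in ", path)
  out <- vector("list", length(motif_at))
  for (k in seq_along(motif_at)) {
    hdr <- strsplit(trimws(lines[motif_at[k]]), "\\s+")[[1]]
    motif_id <- hdr[2]
    rbp_name <- if (length(hdr) >= 3) hdr[3] else hdr[2]
    lp <- grep("^letter-probability matrix", lines[motif_at[k]:length(lines)])[1]
    if (is.na(lp)) stop("motif ", motif_id, " lacks a letter-probability matrix")
    lp <- motif_at[k] + lp - 1
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[lp]))
    rows <- lines[(lp + 1):(lp + w)]
    vals <- lapply(strsplit(trimws(rows), "\\s+"), as.numeric)
    if (any(lengths(vals) != 4))
      stop("motif ", motif_id, ": matrix row without 4 probabilities")
    m <- t(do.call(rbind, vals))  # rows A C G U/T in file column order
    out[[k]] <- motif_matrix(motif_id, rbp_name, m)
  }
  out
}

#' Write motifs in MEME minimal format
#'
#' @param motifs list of `motif_matrix` objects (or a single one).
#' @param path output file.
#' @param background optional background frequencies (A, C, G, U).
#' @export
write_meme_motifs <- function(motifs, path, background = rep(0.25, 4)) {
  if (inherits(motifs, "motif_matrix")) motifs <- list(motifs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGU", "", "strands: +", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f U %.5f", background[1],
                       background[2], background[3], background[4]), ""), con)
  for (mo in motifs) {
    writeLines(sprintf("MOTIF %s %s", mo$motif_id, mo$rbp_name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       mo$width), con)
    writeLines(apply(mo$matrix, 2, function(col)
      paste(sprintf("%.6f", col), collapse = "  ")), con)
    writeLines("", con)
  }
  invisible(path)
}
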