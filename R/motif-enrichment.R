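#' Extract 3'UTR sequences of a gene set
#'
#' One sequence per gene, from the isoform with the longest CDS
#' (see [select_isoforms()]); minus-strand models are returned in sense
#' orientation. The transcript sequence length is checked against the model
#' and the CDS is required to start with AUG; inconsistencies raise an error
#' naming the transcript.
#'
#' @param models list of `transcript_model`s.
#' @param sequences named character vector of transcript or chromosome
#'   sequences (see [transcript_sequence()]).
#' @param gene_set gene ids to extract (default all).
#' @return named character vector of 3'UTR sequences (names = gene ids);
#'   genes with zero-length 3'UTRs are dropped with a warning.
#' @export
extract_3utrs <- function(models, sequences, gene_set = NULL) {
  sel <- select_isoforms(models)
  if (!is.null(gene_set)) sel <- sel[names(sel) %in% gene_set]
  out <- vapply(sel, function(m) {
    s <- transcript_sequence(m, sequences)
    if (nchar(s) != m$tx_length)
      stop(sprintf("sequence/annotation inconsistency for transcript %s: %d nt vs %d nt",
                   m$transcript_id, nchar(s), m$tx_length))
    if (substr(s, m$cds_tx_start + 1, m$cds_tx_start + 3) != "AUG")
      stop(sprintf("CDS of transcript %s does not start with AUG",
                   m$transcript_id))
    substr(s, m$cds_tx_end + 1, m$tx_length)
  }, "")
  empty <- nchar(out) == 0
  if (any(empty))
    warning(sum(empty), " gene(s) with zero-length 3'UTR dropped")
  out[!empty]
}

#' Fisher enrichment of motif occurrences against a shuffled null
#'
#' For each motif, sequences containing at least one occurrence are counted
#' in the real and shuffled sets, and a one-sided (enrichment) Fisher exact
#' test of the 2x2 table is computed, with Benjamini-Hochberg adjustment
#' across motifs. Odds ratios use a 0.5 continuity correction when any cell
#' is zero.
#'
#' @param real_occ,shuffled_occ occurrence tables from [scan_pwm()]
#'   (rows from any number of motifs).
#' @param n_real_seqs,n_shuffled_seqs total numbers of scanned sequences.
#' @param motifs list of [motif_matrix()] (supplies motif ids and RBP names).
#' @return data.frame per motif: counts, odds_ratio, p_value, adj_p,
#'   sorted by adjusted p.
#' @export
fisher_enrichment <- function(real_occ, shuffled_occ, n_real_seqs,
                              n_shuffled_seqs, motifs) {
  rows <- lapply(motifs, function(mo) {
    a <- length(unique(real_occ$sequence_id[real_occ$motif_id == mo$motif_id]))
    c_ <- length(unique(shuffled_occ$sequence_id[shuffled_occ$motif_id == mo$motif_id]))
    b <- n_real_seqs - a
    d <- n_shuffled_seqs - c_
    tab <- matrix(c(a, b, c_, d), 2)
    if (a + c_ == 0) {
      p <- 1; or <- 1; flag <- TRUE
    } else {
      p <- stats::fisher.test(tab, alternative = "greater")$p.value
      flag <- FALSE
      or <- if (any(tab == 0)) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
            else (a * d) / (b * c_)
    }
    data.frame(motif_id = mo$motif_id, rbp_name = mo$rbp_name,
               real_with = a, real_without = b,
               shuffled_with = c_, shuffled_without = d,
               odds_ratio = or, p_value = p, or_undefined = flag,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$adj_p <- stats::p.adjust(res$p_value, method = "BH")
  res[order(res$adj_p, res$p_value, res$motif_id), ]
}

#' Rank enriched motifs of expressed RBPs
#'
#' Filters enrichment results to RBPs expressed above `rpkm_threshold`,
#' ranks by adjusted p, and flags the extreme tier (adjusted p below
#' `stringent_p`). RBPs absent from the expression table are flagged
#' `unknown expression` and excluded.
#'
#' @param results a [fisher_enrichment()] table.
#' @param rbp_expression data.frame with columns `rbp_name` and `rpkm`.
#' @param rpkm_threshold expression cutoff (default 10, `>=`).
#' @param top_n number of motifs reported (default 10; fewer if fewer pass).
#' @param stringent_p threshold of the stringent tier (default 1e-100).
#' @return data.frame of at most `top_n` rows with a `stringent` flag;
#'   attribute `"unknown_rbps"` lists RBPs lacking expression data.
#' @export
report_top_motifs <- function(results, rbp_expression, rpkm_threshold = 10,
                              top_n = 10, stringent_p = 1e-100) {
  expr <- rbp_expression$rpkm[match(results$rbp_name, rbp_expression$rbp_name)]
  unknown <- unique(results$rbp_name[is.na(expr)])
  if (length(unknown))
    warning("unknown expression for RBP(s): ", paste(unknown, collapse = ", "))
  keep <- !is.na(expr) & expr >= rpkm_threshold
  out <- results[keep, , drop = FALSE]
  out$rbp_rpkm <- expr[keep]
  out <- out[order(out$adj_p, out$p_value, out$motif_id), , drop = FALSE]
  out <- utils::head(out, top_n)
  out$stringent <- out$adj_p < stringent_p
  structure(out, unknown_rbps = unknown)
}

#' Generate decoy PWMs for enrichment benchmarking
#'
#' Random sharply-peaked PWMs (one dominant base per column drawn uniformly)
#' used as decoys alongside a planted consensus motif.
#'
#' @param n number of decoys.
#' @param width motif width.
#' @param peak probability of the dominant base per column.
#' @param seed integer seed.
#' @return list of [motif_matrix()] objects.
#' @export
random_decoy_motifs <- function(n, width = 8, peak = 0.85, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n), function(k) {
    dom <- sample.int(4, width, replace = TRUE)
    m <- matrix((1 - peak) / 3, 4, width)
    m[cbind(dom, seq_len(width))] <- peak
    motif_matrix(sprintf("decoy%02d", k), sprintf("DECOY%02d", k), m)
  }))
}

#' PWM with a given consensus and per-column peak probability
#'
#' @param consensus RNA consensus string.
#' @param motif_id,rbp_name identifiers.
#' @param peak probability of the consensus base per column.
#' @return a [motif_matrix()].
#' @export
consensus_motif <- function(consensus, motif_id = "consensus",
                            rbp_name = motif_id, peak = 0.85) {
  code <- encode_rna(consensus)
  m <- matrix((1 - peak) / 3, 4, length(code))
  m[cbind(code, seq_along(code))] <- peak
  motif_matrix(motif_id, rbp_name, m)
}
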