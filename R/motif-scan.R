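#' Zero-order background model of a sequence set
#'
#' Mononucleotide frequencies over A, C, G, U pooled across all sequences,
#' with a +1 pseudocount per base.
#'
#' @param sequences character vector of RNA sequences.
#' @return named numeric vector of four frequencies summing to 1.
#' @export
background_model <- function(sequences) {
  codes <- unlist(lapply(sequences, encode_rna), use.names = FALSE)
  counts <- tabulate(codes, nbins = 4) + 1
  stats::setNames(counts / sum(counts), rna_letters)
}

# integer log-odds matrix and exact null score distribution of a PWM under
# a zero-order background, discretized at `granularity` bits
pwm_score_dist <- function(motif, background, granularity = 1e-3) {
  m <- motif$matrix
  if (any(m == 0)) {
    log_info("motif %s contains zero probabilities; adding 1e-3 pseudocount",
             motif$motif_id)
    m <- sweep(m + 1e-3, 2, colSums(m + 1e-3), "/")
  }
  if (any(background <= 0)) stop("background must be strictly positive")
  intmat <- round(log2(m / background) / granularity)
  lo <- sum(apply(intmat, 2, min))
  hi <- sum(apply(intmat, 2, max))
  # DP convolution of per-column score distributions under the background
  dist <- numeric(hi - lo + 1)       # index = score - lo + 1
  off <- 0
  dist[1] <- 1
  cur_lo <- 0
  for (i in seq_len(ncol(intmat))) {
    new <- numeric(length(dist))
    new_lo <- cur_lo + min(intmat[, i])
    for (b in 1:4) {
      sh <- intmat[b, i] - min(intmat[, i])
      idx <- which(dist > 0)
      new[idx + sh] <- new[idx + sh] + dist[idx] * background[b]
    }
    dist <- new
    cur_lo <- new_lo
  }
  tail_p <- rev(cumsum(rev(dist)))
  list(intmat = intmat, lo = lo, hi = hi, dist = dist, tail_p = tail_p,
       granularity = granularity)
}

# p-value of integer scores under a pwm_score_dist (P(S >= s))
pwm_score_pvalue <- function(sd, scores) {
  idx <- pmin(pmax(scores - sd$lo + 1, 1), length(sd$tail_p))
  p <- sd$tail_p[idx]
  p[scores > sd$hi] <- 0
  p[scores < sd$lo] <- 1
  pmin(p, 1)
}

#' Scan sequences with a PWM using exact score p-values
#'
#' Per position, the score is the summed log2 odds of the motif versus the
#' zero-order background; the null score distribution is computed exactly by
#' dynamic programming over scores discretized at 1/1000 bit, and positions
#' with `P(S >= s) <= p_threshold` are reported as occurrences. Only the
#' sense strand is scanned.
#'
#' @param sequences named character vector of RNA sequences.
#' @param motif a [motif_matrix()].
#' @param background zero-order frequencies from [background_model()].
#' @param p_threshold occurrence p-value threshold (default 1e-4).
#' @return data.frame with columns sequence_id, start (0-based), motif_id,
#'   score (bits), p_value.
#' @export
scan_pwm <- function(sequences, motif, background, p_threshold = 1e-4) {
  sd <- pwm_score_dist(motif, background)
  w <- motif$width
  cutoff_i <- which(sd$tail_p <= p_threshold)
  cutoff <- if (length(cutoff_i)) sd$lo + cutoff_i[1] - 1 else Inf
  out <- vector("list", length(sequences))
  ids <- names(sequences)
  if (is.null(ids)) ids <- as.character(seq_along(sequences))
  for (s in seq_along(sequences)) {
    code <- encode_rna(sequences[[s]])
    L <- length(code)
    if (L < w) next
    npos <- L - w + 1
    sc <- integer(npos)
    for (i in seq_len(w))
      sc <- sc + sd$intmat[code[i:(i + npos - 1)], i]
    hit <- which(sc >= cutoff)
    if (length(hit))
      out[[s]] <- data.frame(sequence_id = ids[s], start = hit - 1L,
                             motif_id = motif$motif_id,
                             score = sc[hit] * sd$granularity,
                             p_value = pwm_score_pvalue(sd, sc[hit]),
                             stringsAsFactors = FALSE)
  }
  occ <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(occ))
    occ <- data.frame(sequence_id = character(0), start = integer(0),
                      motif_id = character(0), score = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  occ
}

#' Shuffle sequences preserving per-sequence base composition and length
#'
#' Each copy is an independent uniform permutation of each sequence's
#' letters, so the letter multiset of every sequence is preserved exactly.
#'
#' @param sequences named character vector.
#' @param copies number of shuffled copies (default 10).
#' @param seed integer seed.
#' @return named character vector of `length(sequences) * copies` shuffled
#'   sequences (names suffixed `_shufK`).
#' @export
shuffle_sequences <- function(sequences, copies = 10, seed = 1) {
  ids <- names(sequences)
  if (is.null(ids)) ids <- as.character(seq_along(sequences))
  withr::with_seed(seed, {
    out <- character(length(sequences) * copies)
    nm <- character(length(out))
    k <- 0
    for (cp in seq_len(copies)) {
      for (s in seq_along(sequences)) {
        k <- k + 1
        ch <- strsplit(sequences[[s]], "", fixed = TRUE)[[1]]
        out[k] <- paste(sample(ch), collapse = "")
        nm[k] <- sprintf("%s_shuf%d", ids[s], cp)
      }
    }
  })
  stats::setNames(out, nm)
}
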