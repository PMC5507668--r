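#' De novo single-motif discovery by one-occurrence-per-sequence EM
#'
#' Fits a `width`-column PWM under the OOPS model: each sequence carries
#' exactly one motif occurrence at an unknown start position (uniform
#' prior), the rest of the sequence following the zero-order background.
#' The E-step computes the posterior over start positions from the current
#' PWM/background odds; the M-step re-estimates the PWM from
#' posterior-weighted base counts with 0.25 pseudocounts. The EM objective
#' (relative log-likelihood versus the pure-background model) is
#' non-decreasing across iterations. `n_restarts` random restarts are run
#' (each seeded from a random sequence window smoothed toward the
#' background) and the best final log-likelihood is kept. Significance is
#' the empirical p-value of the fitted motif's information content against
#' `n_null` identical fits on shuffled copies of the sequences.
#'
#' @param sequences named character vector (>= 10 sequences, each >= width
#'   nt).
#' @param width motif width (default 8).
#' @param n_restarts EM restarts (default 20).
#' @param n_null shuffled-sequence refits for the empirical p (default 100;
#'   0 skips significance).
#' @param max_iter,tol EM stopping rule.
#' @param seed integer seed.
#' @return list with `motif` ([motif_matrix()]), `consensus`,
#'   `information_content` (bits), `log_likelihood`, `loglik_trace` of the
#'   best restart, `converged`, and `p_value` (NA if `n_null = 0`).
#' @export
discover_motif <- function(sequences, width = 8, n_restarts = 20,
                           n_null = 100, max_iter = 200, tol = 1e-8,
                           seed = 1) {
  if (length(sequences) < 10) stop("need at least 10 sequences")
  if (any(nchar(sequences) < width))
    stop("every sequence must be at least `width` nt")
  bg <- background_model(sequences)
  withr::with_seed(seed, {
    best <- em_oops_restarts(sequences, width, bg, n_restarts, max_iter, tol)
    p_val <- NA_real_
    if (n_null > 0) {
      ic_null <- vapply(seq_len(n_null), function(k) {
        shuf <- shuffle_sequences(sequences, copies = 1,
                                  seed = sample.int(.Machine$integer.max, 1))
        fit <- em_oops_restarts(shuf, width, bg, n_restarts, max_iter, tol)
        pwm_information_content(fit$pwm, bg)
      }, 0)
      ic <- pwm_information_content(best$pwm, bg)
      p_val <- (1 + sum(ic_null >= ic)) / (n_null + 1)
    }
  })
  motif <- motif_matrix("discovered", "discovered", best$pwm)
  list(motif = motif, consensus = motif_consensus(motif),
       information_content = pwm_information_content(best$pwm, bg),
       log_likelihood = best$loglik, loglik_trace = best$trace,
       converged = best$converged, p_value = p_val)
}

#' Information content of a PWM relative to a background (bits)
#' @param pwm 4 x width probability matrix.
#' @param background length-4 frequencies.
#' @export
pwm_information_content <- function(pwm, background) {
  sum(pwm * log2(pmax(pwm, 1e-12) / background))
}

# run n_restarts EM fits, return the best
em_oops_restarts <- function(sequences, width, bg, n_restarts, max_iter, tol) {
  codes <- lapply(sequences, encode_rna)
  Ls <- lengths(codes)
  npos <- Ls - width + 1L
  # padded code matrix: rows sequences, columns positions
  n <- length(codes)
  Lmax <- max(Ls)
  cm <- matrix(NA_integer_, n, Lmax)
  for (s in seq_len(n)) cm[s, seq_len(Ls[s])] <- codes[[s]]
  maxpos <- max(npos)
  pos_ok <- outer(seq_len(n), seq_len(maxpos),
                  function(s, p) p <= npos[s])
  # loop-invariant structures: per motif column, the code block aligned to
  # every candidate start, and per (column, base) the valid index sets
  blocks <- lapply(seq_len(width), function(i)
    cm[, i:(i + maxpos - 1), drop = FALSE])
  midx <- lapply(seq_len(width), function(i) {
    lapply(1:4, function(b)
      which(!is.na(blocks[[i]]) & blocks[[i]] == b & pos_ok))
  })
  pre <- list(blocks = blocks, midx = midx, pos_ok = pos_ok, npos = npos,
              n = n, maxpos = maxpos, width = width, bg = bg)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    s0 <- sample.int(n, 1)
    p0 <- sample.int(npos[s0], 1)
    seed_word <- cm[s0, p0:(p0 + width - 1)]
    pwm <- matrix(rep(bg, width) * 0.3, 4, width)
    pwm[cbind(seed_word, seq_len(width))] <- 0.7 + pwm[cbind(seed_word, seq_len(width))]
    pwm <- sweep(pwm, 2, colSums(pwm), "/")
    fit <- em_oops(pre, pwm, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  # phase-shift refinement: a shifted register is a common EM local optimum;
  # retry the best PWM shifted by +/-1..2 columns (vacated columns filled
  # with the background) and keep any likelihood improvement
  repeat {
    improved <- FALSE
    for (sh in c(-2L, -1L, 1L, 2L)) {
      shifted <- shift_pwm(best$pwm, sh, bg)
      fit <- em_oops(pre, shifted, max_iter, tol)
      if (fit$loglik > best$loglik + 1e-9) {
        best <- fit
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  best
}

# shift PWM columns by `sh` (positive = motif moves right), filling vacated
# columns with the background distribution
shift_pwm <- function(pwm, sh, bg) {
  w <- ncol(pwm)
  out <- matrix(bg, 4, w)
  if (sh > 0) out[, (sh + 1):w] <- pwm[, 1:(w - sh), drop = FALSE]
  else out[, 1:(w + sh)] <- pwm[, (1 - sh):w, drop = FALSE]
  out
}

# OOPS EM core on precomputed padded blocks
em_oops <- function(pre, pwm, max_iter, tol) {
  n <- pre$n; maxpos <- pre$maxpos; width <- pre$width
  log_bg <- log(pre$bg)
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    log_odds <- log(pwm) - log_bg   # 4 x width, column-major
    sc <- matrix(0, n, maxpos)
    for (i in seq_len(width)) {
      v <- log_odds[pre$blocks[[i]] + 4L * (i - 1L)]
      v[is.na(v)] <- 0
      sc <- sc + v
    }
    sc[!pre$pos_ok] <- -Inf
    mx <- apply(sc, 1, max)
    w <- exp(sc - mx)
    rs <- rowSums(w, na.rm = TRUE)
    post <- w / rs
    ll <- sum(mx + log(rs) - log(pre$npos))  # relative to background model
    trace <- c(trace, ll)
    # M-step: posterior-weighted base counts with 0.25 pseudocounts
    new_pwm <- matrix(0.25, 4, width)
    for (i in seq_len(width))
      for (b in 1:4)
        new_pwm[b, i] <- new_pwm[b, i] + sum(post[pre$midx[[i]][[b]]])
    new_pwm <- sweep(new_pwm, 2, colSums(new_pwm), "/")
    if (is.finite(ll_prev) && ll - ll_prev < tol * max(1, abs(ll))) {
      converged <- TRUE
      pwm <- new_pwm
      break
    }
    ll_prev <- ll
    pwm <- new_pwm
  }
  list(pwm = pwm, loglik = ll, trace = trace, converged = converged)
}
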