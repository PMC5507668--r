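#' Derive a stage-specific seed from a master seed
#'
#' Every random procedure in the package consumes a seed derived
#' deterministically from the master seed and a stage label, so that a single
#' master seed fixes the whole run while stages remain independent streams.
#'
#' @param master_seed integer master seed.
#' @param stage character stage label (e.g. `"simulate_ribo"`).
#' @return an integer seed `< 2^31`.
#' @export
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 99991L
  as.integer((abs(as.integer(master_seed)) %% 21473L) * 99991L + h)
}

log_info <- function(...) message("[riboclip] ", sprintf(...))

#' @keywords internal
rna_letters <- c("A", "C", "G", "U")

# encode an RNA/DNA string to integer codes 1..4 (A,C,G,U; T treated as U)
encode_rna <- function(x) {
  v <- utf8ToInt(chartr("acgutT", "ACGUUU", x))
  code <- integer(length(v))
  code[v == utf8ToInt("A")] <- 1L
  code[v == utf8ToInt("C")] <- 2L
  code[v == utf8ToInt("G")] <- 3L
  code[v == utf8ToInt("U")] <- 4L
  if (any(code == 0L)) stop("non-ACGU(T) character in sequence")
  code
}

decode_rna <- function(code) paste(rna_letters[code], collapse = "")

#' Reverse complement an RNA character string
#' @keywords internal
revcomp_rna <- function(x) {
  chartr("ACGU", "UGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}
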