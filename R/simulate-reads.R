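#' Simulate ribosome footprint alignments
#'
#' Footprints are assigned to genes proportionally to
#' abundance x TE x CDS length. Within a gene, the P-site codon is drawn
#' uniformly over the sense codons, with initiation and termination spikes
#' (`spike_mult` times the per-codon rate) at the start codon and the last
#' sense codon (whose A-site is the stop codon). The 5' end is placed
#' `psite_offset` nt upstream of the P-site first base with probability
#' `frame_fidelity`, else shifted +/-1 nt. A small fraction of reads is
#' placed uniformly in the UTRs as background.
#'
#' @param sim a transcriptome from [generate_transcriptome()].
#' @param total_reads number of footprints.
#' @param stage time-course stage index (1-5) whose abundance/TE to use.
#' @param frame_fidelity,psite_offset,read_length,spike_mult,utr_background
#'   geometry parameters; defaults come from the simulation truth.
#' @param seed integer seed.
#' @param sample_id sample label.
#' @return alignment data.frame in transcript coordinates (all `+` strand,
#'   MAPQ 255, `unique = TRUE`).
#' @export
simulate_ribo_reads <- function(sim, total_reads = 5e5, stage = 1,
                                frame_fidelity = NULL, psite_offset = NULL,
                                read_length = NULL, spike_mult = NULL,
                                utr_background = NULL, seed = 1,
                                sample_id = "ribo") {
  if (total_reads <= 0) stop("total_reads must be positive")
  p <- sim$truth$params
  if (is.null(frame_fidelity)) frame_fidelity <- p$frame_fidelity
  if (is.null(psite_offset)) psite_offset <- p$psite_offset
  if (is.null(read_length)) read_length <- p$footprint_length
  if (is.null(spike_mult)) spike_mult <- p$spike_mult
  if (is.null(utr_background)) utr_background <- p$utr_background
  g <- sim$truth$genes
  w <- sim$truth$abundance[, stage] * sim$truth$te[, stage] * g$cds_length
  withr::with_seed(seed, {
    gi <- sample.int(nrow(g), total_reads, replace = TRUE, prob = w)
    m <- g$cds_length[gi] / 3            # codons incl. stop
    n_psite <- m - 1                     # sense codons 0..m-2
    tot_w <- (n_psite - 2) + 2 * spike_mult
    u <- stats::runif(total_reads) * tot_w
    k <- ifelse(u < spike_mult, 0,
                ifelse(u < 2 * spike_mult, n_psite - 1,
                       1 + floor(u - 2 * spike_mult)))
    five <- g$utr5_length[gi] + 3 * k - psite_offset
    jitter_on <- stats::runif(total_reads) >= frame_fidelity
    five[jitter_on] <- five[jitter_on] +
      sample(c(-1L, 1L), sum(jitter_on), replace = TRUE)
    # UTR background reads
    bg <- stats::runif(total_reads) < utr_background
    if (any(bg)) {
      a <- g$utr5_length[gi[bg]]
      cds_end <- g$utr5_length[gi[bg]] + g$cds_length[gi[bg]]
      b <- pmax(0, g$tx_length[gi[bg]] - read_length + 1 - cds_end)
      ub <- floor(stats::runif(sum(bg)) * (a + b))
      five[bg] <- ifelse(ub < a, ub, cds_end + (ub - a))
    }
    five <- pmin(pmax(five, 0), g$tx_length[gi] - read_length)
  })
  data.frame(reference = g$gene_id[gi], strand = "+", five_prime_pos = five,
             length = read_length, mapq = 255, unique = TRUE,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

#' Simulate RNA-seq fragment alignments
#'
#' Fragments are assigned to genes proportionally to
#' abundance x transcript length; 5' ends are uniform over the transcript,
#' so they carry no frame structure.
#'
#' @inheritParams simulate_ribo_reads
#' @param read_length fragment length (nt).
#' @export
simulate_rna_reads <- function(sim, total_reads = 5e5, stage = 1,
                               read_length = 30, seed = 1,
                               sample_id = "rna") {
  if (total_reads <= 0) return(empty_alignments())
  g <- sim$truth$genes
  if (read_length > min(g$tx_length))
    stop("read_length exceeds the shortest transcript")
  w <- sim$truth$abundance[, stage] * g$tx_length
  withr::with_seed(seed, {
    gi <- sample.int(nrow(g), total_reads, replace = TRUE, prob = w)
    five <- floor(stats::runif(total_reads) * (g$tx_length[gi] - read_length + 1))
  })
  data.frame(reference = g$gene_id[gi], strand = "+", five_prime_pos = five,
             length = read_length, mapq = 255, unique = TRUE,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

empty_alignments <- function() {
  data.frame(reference = character(0), strand = character(0),
              five_prime_pos = numeric(0), length = numeric(0),
              mapq = numeric(0), unique = logical(0),
              sample_id = character(0), stringsAsFactors = FALSE)
}

#' Simulate CLIP-seq and input-control alignments
#'
#' CLIP reads are a mixture of peak reads — 5' ends Normal(center, `peak_sd`),
#' truncated to the transcript, around the planted 3'UTR motif sites, with
#' per-peak intensity `peak_intensity` times the expected background of one
#' `bin_size` window, scaled by the gamma intensity factor stored in the
#' simulation truth (shared across replicate libraries, giving the
#' negative-binomial marginal intensity) — and background reads
#' proportional to abundance, uniform over the transcript. The input
#' library contains background only.
#'
#' @inheritParams simulate_ribo_reads
#' @param n_clip,n_input library sizes.
#' @param peak_intensity mean peak enrichment over the local background of a
#'   50-nt bin.
#' @param peak_sd standard deviation (nt) of peak read 5' ends.
#' @param read_length CLIP read length (nt).
#' @param bin_size window used to scale peak intensity to local background.
#' @param stage stage whose abundance drives the background.
#' @return list with `clip` and `input` alignment data.frames.
#' @export
simulate_clip_reads <- function(sim, n_clip = 2e5, n_input = 2e5,
                                peak_intensity = 10, peak_sd = NULL,
                                read_length = 30,
                                bin_size = 50, stage = 4, seed = 1) {
  p <- sim$truth$params
  if (is.null(peak_sd)) peak_sd <- p$clip_peak_sd
  g <- sim$truth$genes
  pk <- sim$truth$planted
  bg_w <- sim$truth$abundance[, stage]
  withr::with_seed(seed, {
    draw_background <- function(n, label) {
      gi <- sample.int(nrow(g), n, replace = TRUE, prob = bg_w)
      five <- floor(stats::runif(n) * (g$tx_length[gi] - read_length + 1))
      data.frame(reference = g$gene_id[gi], strand = "+",
                 five_prime_pos = five, length = read_length, mapq = 255,
                 unique = TRUE, sample_id = label, stringsAsFactors = FALSE)
    }
    if (nrow(pk) > 0) {
      pg <- match(pk$gene_id, g$gene_id)
      pk_w <- peak_intensity * bg_w[pg] * (bin_size / g$tx_length[pg]) *
        pk$intensity
      all_w <- c(bg_w, pk_w)
      cat_i <- sample.int(length(all_w), n_clip, replace = TRUE, prob = all_w)
      is_pk <- cat_i > nrow(g)
      clip <- empty_alignments()[0, ]
      gi <- integer(n_clip); five <- numeric(n_clip)
      gi[!is_pk] <- cat_i[!is_pk]
      five[!is_pk] <- floor(stats::runif(sum(!is_pk)) *
                              (g$tx_length[gi[!is_pk]] - read_length + 1))
      pj <- cat_i[is_pk] - nrow(g)
      gi[is_pk] <- pg[pj]
      five[is_pk] <- round(stats::rnorm(sum(is_pk), pk$peak_center_tx[pj],
                                        peak_sd))
      five <- pmin(pmax(five, 0), g$tx_length[gi] - read_length)
      clip <- data.frame(reference = g$gene_id[gi], strand = "+",
                         five_prime_pos = five, length = read_length,
                         mapq = 255, unique = TRUE, sample_id = "clip",
                         stringsAsFactors = FALSE)
    } else {
      clip <- draw_background(n_clip, "clip")
    }
    input <- draw_background(n_input, "input")
  })
  list(clip = clip, input = input)
}
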