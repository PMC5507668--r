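#' Generate a synthetic transcriptome with known ground truth
#'
#' Builds `n_genes` intronless transcript models in transcript coordinates
#' (one reference per transcript), their RNA sequences, and a truth record
#' fixing every downstream expectation: per-gene RNA abundance and
#' translation efficiency (TE) over a five-point time course, TE-shift genes
#' with stage and log2 effect size, planted 3'UTR motif instances, and the
#' footprint geometry (28-nt footprints, 12-nt 5'-end-to-P-site offset).
#'
#' Every CDS starts AUG and ends with a stop codon; internal codons are drawn
#' uniformly from the 61 sense codons; UTR bases are i.i.d. with
#' `base_freqs`. A `planted_fraction` of genes receive one exact copy of
#' `motif_consensus` at a uniform 3'UTR position; those positions double as
#' the planted CLIP peak centers.
#'
#' @param n_genes number of genes (one transcript each).
#' @param utr5_range,utr3_range inclusive length ranges (nt); minima 30 and
#'   100 respectively.
#' @param cds_codon_range inclusive range of CDS codons (incl. start/stop);
#'   minimum 50 codons so CDS >= 150 nt.
#' @param base_freqs UTR base composition over A, C, G, U.
#' @param abundance_meanlog,abundance_sdlog log-normal parameters of the
#'   per-gene RNA abundance (arbitrary units); `abundance_sdlog = 0` gives
#'   equally expressed genes, useful for power studies at a fixed count
#'   level.
#' @param motif_consensus consensus sequence planted into 3'UTRs
#'   (default the AU-rich element `UAUUUAUU`).
#' @param planted_fraction fraction of genes with one planted instance.
#' @param shift_fraction fraction of genes whose TE shifts during the course.
#' @param shift_log2 absolute log2 TE effect size of shift genes.
#' @param frame_fidelity probability a simulated footprint 5' end falls at
#'   the exact P-site offset (else +/-1 nt).
#' @param clip_intensity_dispersion gamma dispersion of the per-peak CLIP
#'   intensity factors stored in the truth (shared by all replicate
#'   libraries); 0 gives every peak exactly the nominal intensity.
#' @param nb_dispersion negative-binomial dispersion of simulated counts.
#' @param seed integer seed; fixes every output byte.
#' @return list with `models` (transcript_model list), `sequences` (named
#'   character, RNA alphabet), and `truth` (see Details).
#' @export
generate_transcriptome <- function(n_genes = 2000,
                                   utr5_range = c(30, 150),
                                   cds_codon_range = c(60, 400),
                                   utr3_range = c(100, 500),
                                   base_freqs = c(A = 0.25, C = 0.25,
                                                  G = 0.25, U = 0.25),
                                   motif_consensus = "UAUUUAUU",
                                   planted_fraction = 0.5,
                                   abundance_meanlog = log(50),
                                   abundance_sdlog = 1,
                                   shift_fraction = 0.1,
                                   shift_log2 = 2,
                                   frame_fidelity = 0.9,
                                   nb_dispersion = 0.1,
                                   clip_intensity_dispersion = 0.5,
                                   seed = 1) {
  stopifnot(n_genes >= 1)
  if (utr5_range[1] < 30 || cds_codon_range[1] < 50 || utr3_range[1] < 100)
    stop("infeasible length parameters: need utr5 >= 30, cds >= 150 nt, utr3 >= 100")
  width <- nchar(motif_consensus)
  withr::with_seed(seed, {
    utr5 <- sample(utr5_range[1]:utr5_range[2], n_genes, replace = TRUE)
    codons <- sample(cds_codon_range[1]:cds_codon_range[2], n_genes,
                     replace = TRUE)
    utr3 <- sample(utr3_range[1]:utr3_range[2], n_genes, replace = TRUE)
    cds <- 3L * codons
    tx_len <- utr5 + cds + utr3

    # sequences: UTR bases i.i.d., CDS = AUG + sense codons + stop
    all_codons <- apply(expand.grid(rna_letters, rna_letters, rna_letters)[, 3:1],
                        1, paste, collapse = "")
    sense <- setdiff(all_codons, c("UAA", "UAG", "UGA"))
    stops <- c("UAA", "UAG", "UGA")
    utr_chars <- sample(rna_letters, sum(utr5) + sum(utr3), replace = TRUE,
                        prob = base_freqs)
    gene_f <- factor(rep.int(seq_len(n_genes), times = utr5 + utr3),
                     levels = seq_len(n_genes))
    utr_seq <- vapply(split(utr_chars, gene_f), paste, "", collapse = "")
    utr5_seq <- substr(utr_seq, 1, utr5)
    utr3_seq <- substr(utr_seq, utr5 + 1, utr5 + utr3)
    body <- sample(sense, sum(codons - 2L), replace = TRUE)
    body_f <- factor(rep.int(seq_len(n_genes), times = codons - 2L),
                     levels = seq_len(n_genes))
    cds_seq <- paste0("AUG", vapply(split(body, body_f), paste, "", collapse = ""),
                      sample(stops, n_genes, replace = TRUE))

    # planted 3'UTR motif instances
    n_planted <- round(planted_fraction * n_genes)
    planted_genes <- sort(sample.int(n_genes, n_planted))
    motif_start <- integer(0)
    if (n_planted > 0) {
      motif_start <- vapply(planted_genes, function(g)
        sample.int(utr3[g] - width + 1L, 1L) - 1L, 0L)
      for (k in seq_len(n_planted)) {
        g <- planted_genes[k]
        substr(utr3_seq[g], motif_start[k] + 1, motif_start[k] + width) <-
          motif_consensus
      }
    }
    seqs <- paste0(utr5_seq, cds_seq, utr3_seq)
    gene_ids <- sprintf("gene%04d", seq_len(n_genes))
    names(seqs) <- gene_ids

    # expression truth: stages 0,1,2,4,6 hr
    stages <- c(0, 1, 2, 4, 6)
    abundance <- stats::rlnorm(n_genes, meanlog = abundance_meanlog,
                               sdlog = abundance_sdlog)
    abundance <- matrix(abundance, n_genes, 5)
    base_te <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 0.5)
    n_shift <- round(shift_fraction * n_genes)
    shift_gene <- rep(FALSE, n_genes)
    shift_stage <- rep(NA_integer_, n_genes)
    shift_sign <- rep(NA_real_, n_genes)
    if (n_shift > 0) {
      idx <- sample.int(n_genes, n_shift)
      shift_gene[idx] <- TRUE
      shift_stage[idx] <- sample(2:5, n_shift, replace = TRUE)
      shift_sign[idx] <- sample(c(-1, 1), n_shift, replace = TRUE)
    }
    te <- matrix(base_te, n_genes, 5)
    for (s in 2:5) {
      on <- shift_gene & !is.na(shift_stage) & shift_stage <= s
      te[on, s] <- base_te[on] * 2^(shift_sign[on] * shift_log2)
    }
    colnames(te) <- colnames(abundance) <- paste0("hr", stages)
    peak_intensity_factor <- if (clip_intensity_dispersion > 0)
      stats::rgamma(n_planted, shape = 1 / clip_intensity_dispersion,
                    scale = clip_intensity_dispersion)
    else rep(1, n_planted)
  })

  models <- lapply(seq_len(n_genes), function(g)
    transcript_model(gene_ids[g], gene_ids[g], gene_ids[g], "+",
                     matrix(c(0, tx_len[g]), ncol = 2),
                     utr5[g], utr5[g] + cds[g]))
  names(models) <- gene_ids

  planted <- data.frame(
    gene_id = gene_ids[planted_genes],
    motif_id = rep("planted", length(planted_genes)),
    motif_start_utr3 = motif_start,
    motif_start_tx = utr5[planted_genes] + cds[planted_genes] + motif_start,
    peak_center_tx = utr5[planted_genes] + cds[planted_genes] + motif_start +
      floor(width / 2),
    intensity = peak_intensity_factor,
    stringsAsFactors = FALSE)

  truth <- list(
    genes = data.frame(gene_id = gene_ids, tx_length = tx_len,
                       utr5_length = utr5, cds_length = cds,
                       utr3_length = utr3, base_te = base_te,
                       shift = shift_gene, shift_stage = shift_stage,
                       shift_log2 = shift_sign * shift_log2,
                       stringsAsFactors = FALSE),
    abundance = abundance,
    te = te,
    planted = planted,
    params = list(stages = stages, footprint_length = 28L, psite_offset = 12L,
                  frame_fidelity = frame_fidelity,
                  nb_dispersion = nb_dispersion, spike_mult = 5,
                  utr_background = 0.02, clip_peak_sd = 15,
                  motif_consensus = motif_consensus, seed = seed))
  list(models = models, sequences = seqs, truth = truth)
}

#' Project transcript-space models onto a virtual genome
#'
#' Re-expresses each intronless transcript-space model as a spliced genomic
#' model on a single chromosome, with 1-3 exons, random intron lengths and
#' random strand, preserving all region lengths. Used to exercise
#' genomic/transcript coordinate mapping and genomic-mode counting.
#'
#' @param models list of transcript-space `transcript_model`s.
#' @param chrom virtual chromosome name.
#' @param intron_range inclusive intron length range (nt).
#' @param gap intergenic gap (nt).
#' @param seed integer seed.
#' @return list of genomic `transcript_model`s (same ids and region lengths).
#' @export
project_genomic <- function(models, chrom = "chrS",
                            intron_range = c(100, 500), gap = 500, seed = 1) {
  withr::with_seed(seed, {
    offset <- 0
    lapply(models, function(m) {
      L <- m$tx_length
      n_ex <- sample(1:3, 1)
      cuts <- sort(sample.int(L - 1, n_ex - 1))
      bounds <- c(0, cuts, L)                     # exon widths in tx space
      widths <- diff(bounds)
      introns <- if (n_ex > 1)
        sample(intron_range[1]:intron_range[2], n_ex - 1, replace = TRUE)
        else integer(0)
      starts <- offset + cumsum(c(0, widths[-n_ex] + introns))
      exons <- cbind(starts, starts + widths)
      strand <- sample(c("+", "-"), 1)
      # map transcript-space CDS bounds (strand-aware) to genomic
      tmp <- list(exons = exons, strand = strand, tx_length = L)
      class(tmp) <- "transcript_model"
      cds_g <- transcript_to_genomic(tmp, c(m$cds_tx_start, m$cds_tx_end - 1))
      offset <<- max(exons[, 2]) + gap
      transcript_model(m$gene_id, m$transcript_id, chrom, strand, exons,
                       min(cds_g), max(cds_g) + 1)
    })
  })
}
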