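#' Pipeline run configuration
#'
#' Collects stage parameters (defaults mirroring the study conventions:
#' expression threshold 10 RPKM, 28-nt footprints, 10 shuffled copies,
#' 50-nt CLIP bins, peak p 0.01, 100-nt merge distance, motif width 8) and
#' a master seed from which every stage derives its own seed via
#' [derive_seed()], so a serialized configuration reloads to an identical
#' run.
#'
#' @param outdir output directory.
#' @param seed master seed.
#' @param n_genes,ribo_reads,rna_reads,clip_reads synthetic-mode sizes.
#' @param expression_threshold,footprint_length,shuffle_copies,bin_size
#'   stage parameters.
#' @param peak_p,merge_distance,motif_width,bootstrap_B stage parameters.
#' @param stages which stages to run (subset of qc, te, motifs, clip).
#' @param inputs optional named list of input paths (annotation, sequences,
#'   alignments, motifs); `NULL` means synthetic mode.
#' @return object of class `run_config`.
#' @export
run_config <- function(outdir = "results", seed = 1,
                       n_genes = 500, ribo_reads = 2e5, rna_reads = 2e5,
                       clip_reads = 2e5,
                       expression_threshold = 10, footprint_length = 28,
                       shuffle_copies = 10, bin_size = 50, peak_p = 0.01,
                       merge_distance = 100, motif_width = 8,
                       bootstrap_B = 1000,
                       stages = c("qc", "te", "motifs", "clip"),
                       inputs = NULL) {
  cfg <- as.list(environment())
  bad <- setdiff(stages, c("qc", "te", "motifs", "clip"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!is.null(inputs) && "clip" %in% stages &&
      (is.null(inputs$clip1) || is.null(inputs$clip2) || is.null(inputs$input)))
    stop("configuration error: CLIP stage requested but CLIP/input alignments missing")
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order (QC, TE, motif enrichment, with
#' the CLIP branch independent), writes tabular outputs under
#' `config$outdir` and returns (and writes) a JSON manifest recording
#' parameters, per-stage seeds and record counts. In synthetic mode
#' (`inputs = NULL`) the run starts by generating a transcriptome and read
#' sets with the bundled simulator; a fixed master seed makes every output
#' byte-identical across runs.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(parameters = config[setdiff(names(config), "inputs")],
                   stages = list())
  out <- function(name) file.path(config$outdir, name)
  wtsv <- function(df, name) {
    utils::write.table(df, out(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$stages[[name]] <<- list(file = name, rows = nrow(df))
    invisible(df)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed (seed %d): %s", stage,
                   derive_seed(config$seed, stage), conditionMessage(e)),
           call. = FALSE))
  }

  if (is.null(config$inputs)) {
    sim <- run_stage("simulate", generate_transcriptome(
      config$n_genes, seed = derive_seed(config$seed, "simulate")))
    models <- sim$models
    sequences <- sim$sequences
    ribo <- simulate_ribo_reads(sim, config$ribo_reads,
                                seed = derive_seed(config$seed, "ribo"))
    rna <- simulate_rna_reads(sim, config$rna_reads,
                              seed = derive_seed(config$seed, "rna"))
    tc <- simulate_timecourse(sim, seed = derive_seed(config$seed, "tc"))
    clip1 <- simulate_clip_reads(sim, config$clip_reads, config$clip_reads,
                                 seed = derive_seed(config$seed, "clip1"))
    clip2 <- simulate_clip_reads(sim, config$clip_reads, config$clip_reads,
                                 seed = derive_seed(config$seed, "clip2"))
    wtsv(sim$truth$genes, "truth_genes.tsv")
  } else {
    models <- run_stage("load", read_annotation(config$inputs$annotation))
    sequences <- read_fasta_rna(config$inputs$sequences)
    ribo <- read_alignments(config$inputs$ribo, sample_id = "ribo")
    rna <- read_alignments(config$inputs$rna, sample_id = "rna")
    tc <- NULL
    if ("clip" %in% config$stages) {
      c1 <- read_alignments(config$inputs$clip1, sample_id = "clip1")
      c2 <- read_alignments(config$inputs$clip2, sample_id = "clip2")
      ci <- read_alignments(config$inputs$input, sample_id = "input")
      clip1 <- list(clip = c1, input = ci)
      clip2 <- list(clip = c2, input = ci)
    }
  }

  if ("qc" %in% config$stages) run_stage("qc", {
    ps <- metagene_profile(ribo, models, "start", config$footprint_length)
    pe <- metagene_profile(ribo, models, "stop", config$footprint_length)
    off <- estimate_offsets(ps, pe)
    fp <- frame_periodicity(ribo, models, config$footprint_length)
    rdr <- region_density_ratios(ribo, models)
    wtsv(as.data.frame(ps), "metagene_start.tsv")
    wtsv(as.data.frame(pe), "metagene_stop.tsv")
    wtsv(data.frame(p_site_offset = off$p_site_offset,
                    a_site_offset = off$a_site_offset,
                    dominant_period = fp$dominant_period,
                    frame0 = fp$frame_counts[1], frame1 = fp$frame_counts[2],
                    frame2 = fp$frame_counts[3]), "qc_summary.tsv")
    wtsv(rdr, "region_density_ratios.tsv")
    log_info("qc: offsets %d/%d, dominant period %d",
             off$p_site_offset, off$a_site_offset, fp$dominant_period)
  })

  diff_res <- NULL; retained <- NULL
  if ("te" %in% config$stages && !is.null(tc)) run_stage("te", {
    retained <- filter_expressed(tc$rpf, tc$rna, config$expression_threshold)
    te <- apparent_te(tc$rpf, tc$rna, retained)
    diff_res <- differential_te(tc$rpf, tc$rna, retained,
                                 B = config$bootstrap_B,
                                 seed = derive_seed(config$seed, "te"))
    wtsv(cbind(gene_id = rownames(te$te), as.data.frame(te$te)), "te.tsv")
    wtsv(diff_res, "differential_te.tsv")
    if (sum(diff_res$significant) >= 2) {
      cl <- cluster_te(te, diff_res)
      wtsv(cbind(gene_id = rownames(cl$matrix), direction = cl$direction,
                 as.data.frame(cl$matrix)), "te_clusters.tsv")
    }
    log_info("te: %d retained, %d significant", length(retained),
             sum(diff_res$significant))
  })

  if ("motifs" %in% config$stages && !is.null(diff_res)) run_stage("motifs", {
    genes <- diff_res$gene_id[diff_res$significant]
    if (length(genes) >= 5) {
      utrs <- extract_3utrs(models, sequences, genes)
      bg <- background_model(utrs)
      motifs <- if (!is.null(config$inputs$motifs))
        read_meme_motifs(config$inputs$motifs)
      else c(list(consensus_motif("UAUUUAUU", "ARE", "Zfp36")),
             random_decoy_motifs(19, seed = derive_seed(config$seed, "decoys")))
      shuf <- shuffle_sequences(utrs, config$shuffle_copies,
                                seed = derive_seed(config$seed, "shuffle"))
      ro <- do.call(rbind, lapply(motifs, function(m) scan_pwm(utrs, m, bg)))
      so <- do.call(rbind, lapply(motifs, function(m) scan_pwm(shuf, m, bg)))
      fe <- fisher_enrichment(ro, so, length(utrs), length(shuf), motifs)
      wtsv(ro, "motif_occurrences.tsv")
      wtsv(fe, "motif_enrichment.tsv")
      log_info("motifs: top motif %s (adj p %.3g)", fe$motif_id[1], fe$adj_p[1])
    } else log_info("motifs: skipped (<5 significant genes)")
  })

  if ("clip" %in% config$stages) run_stage("clip", {
    pk1 <- call_peaks(bin_counts(clip1$clip, clip1$input, models,
                                 config$bin_size),
                      config$peak_p, "rep1")
    pk2 <- call_peaks(bin_counts(clip2$clip, clip2$input, models,
                                 config$bin_size),
                      config$peak_p, "rep2")
    mg <- merge_peaks(pk1, pk2, config$merge_distance)
    ann <- annotate_peaks(mg, models)
    wtsv(pk1[pk1$is_peak, ], "peaks_rep1.tsv")
    wtsv(pk2[pk2$is_peak, ], "peaks_rep2.tsv")
    wtsv(ann, "peaks_merged.tsv")
    write_peaks_bed6(ann, out("peaks_merged.bed"))
    pct <- attr(ann, "percentages")
    wtsv(data.frame(region = names(pct), percent = as.numeric(pct)),
         "peak_regions.tsv")
    if (nrow(ann) >= 10) {
      seqs <- peak_sequences(ann, sequences)
      seqs <- seqs[nchar(seqs) >= config$motif_width]
      dm <- discover_motif(seqs, config$motif_width, n_null = 0,
                           seed = derive_seed(config$seed, "motif_em"))
      write_meme_motifs(dm$motif, out("discovered_motif.meme"))
      log_info("clip: %d merged peaks, discovered consensus %s",
               nrow(ann), dm$consensus)
    }
  })

  manifest$seed <- config$seed
  manifest$package_version <- as.character(utils::packageVersion("riboclip"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Read an RNA FASTA file as a named character vector (T mapped to U)
#' @param path FASTA file.
#' @export
read_fasta_rna <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(chartr("Tt", "Uu", toupper(as.character(x))), names(x))
}

#' Write RNA sequences as FASTA
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta_rna <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(sequences), path)
  invisible(path)
}
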