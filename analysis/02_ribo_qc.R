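#!/usr/bin/env Rscript
# Stage 2: footprint quality control. Reads the stage-1 alignments back
# from BED, builds start-/stop-anchored metagene profiles, estimates the
# P- and A-site offsets, measures codon periodicity, region specificity
# and replicate correlation.

library(riboclip)

ddir <- "results/data"
outdir <- "results/qc"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

models <- read_annotation(file.path(ddir, "transcripts.bed"))
ribo <- read_alignments(file.path(ddir, "ribo.bed"), sample_id = "ribo")
rna <- read_alignments(file.path(ddir, "rna.bed"), sample_id = "rna")

start_prof <- metagene_profile(ribo, models, "start")
stop_prof <- metagene_profile(ribo, models, "stop")
off <- estimate_offsets(start_prof, stop_prof)
cat(sprintf("metagene offsets: P-site %d nt (prominence %.0f), A-site %d nt (prominence %.0f)\n",
            off$p_site_offset, off$p_site_prominence,
            off$a_site_offset, off$a_site_prominence))

fp_ribo <- frame_periodicity(ribo, models)
fp_rna <- frame_periodicity(rna, models, read_length = 30)
cat(sprintf("periodicity: footprints dominant period %d nt (frame split %s); RNA period %d, max acf %.3f\n",
            fp_ribo$dominant_period,
            paste(round(fp_ribo$frame_counts / sum(fp_ribo$frame_counts), 2),
                  collapse = "/"),
            fp_rna$dominant_period, max(fp_rna$autocorrelation)))

ratios <- region_density_ratios(ribo, models, psite_offset = off$p_site_offset)
q <- attr(ratios, "quartiles")
cat(sprintf("region specificity: median UTR/CDS density ratios 5'UTR %.3f, 3'UTR %.3f\n",
            q["50%", "utr5_ratio"], q["50%", "utr3_ratio"]))

counts <- read.delim(file.path(ddir, "counts_rpf.tsv"), row.names = 1)
samp <- read.delim(file.path(ddir, "samples_rpf.tsv"))
ct <- count_table(as.matrix(counts), lengths = setNames(
  vapply(models, `[[`, 0, "cds_length"),
  vapply(models, `[[`, "", "gene_id"))[rownames(counts)],
  totals = samp$total, assay = "RPF",
  stage = samp$stage, replicate = samp$replicate)
cm <- replicate_correlation(ct)
cat(sprintf("replicate correlation (log2 RPM, %d genes): same-stage r = %.3f\n",
            attr(cm, "n_genes"), cm[1, 2]))

write.table(as.data.frame(start_prof), file.path(outdir, "metagene_start.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(as.data.frame(stop_prof), file.path(outdir, "metagene_stop.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ratios, file.path(outdir, "region_ratios.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(round(cm, 4), file.path(outdir, "replicate_correlation.tsv"),
            sep = "\t", quote = FALSE)
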