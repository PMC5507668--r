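#!/usr/bin/env Rscript
# Stage 5: CLIP-seq. Checks replicate reproducibility, calls peaks per
# replicate with the zero-truncated NB model over the input control
# (50-nt bins, p < 0.01), merges peaks across replicates (centers within
# 100 nt), annotates merged peaks by gene region, and runs de novo
# width-8 motif discovery on the peak sequences.

library(riboclip)

ddir <- "results/data"
outdir <- "results/clip"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
seed <- 7

models <- read_annotation(file.path(ddir, "transcripts.bed"))
seqs <- read_fasta_rna(file.path(ddir, "transcripts.fa"))
clip1 <- read_alignments(file.path(ddir, "clip_rep1.bed"), sample_id = "rep1")
clip2 <- read_alignments(file.path(ddir, "clip_rep2.bed"), sample_id = "rep2")
input <- read_alignments(file.path(ddir, "clip_input.bed"), sample_id = "input")
rna <- read_alignments(file.path(ddir, "rna.bed"), sample_id = "rna")

cc <- clip_reproducibility(gene_read_counts(clip1, models),
                           gene_read_counts(clip2, models),
                           gene_read_counts(rna, models))
cat(sprintf("reproducibility (log counts/gene): rep1-rep2 r = %.3f; rep-RNA r = %.3f / %.3f\n",
            cc["rep1_rep2"], cc["rep1_rna"], cc["rep2_rna"]))

pk1 <- call_peaks(bin_counts(clip1, input, models), replicate_id = "rep1")
pk2 <- call_peaks(bin_counts(clip2, input, models), replicate_id = "rep2")
mg <- merge_peaks(pk1, pk2)
ann <- annotate_peaks(mg, models)
pct <- attr(ann, "percentages")
cat(sprintf("peaks: %d rep1, %d rep2 -> %d merged (both replicates); regions: %s\n",
            sum(pk1$is_peak), sum(pk2$is_peak), nrow(ann),
            paste(sprintf("%s %.1f%%", names(pct), pct), collapse = ", ")))

peak_seqs <- peak_sequences(ann, seqs)
peak_seqs <- peak_seqs[nchar(peak_seqs) >= 8]
dm <- discover_motif(peak_seqs, width = 8, n_null = 20,
                     seed = derive_seed(seed, "motif_em"))
cat(sprintf("discovered motif: %s (information content %.1f bits, empirical p %.3g)\n",
            dm$consensus, dm$information_content, dm$p_value))

write_peaks_bed6(ann, file.path(outdir, "peaks_merged.bed"))
write.table(ann, file.path(outdir, "peaks_merged.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(region = names(pct), percent = round(as.numeric(pct), 2)),
            file.path(outdir, "peak_regions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_meme_motifs(dm$motif, file.path(outdir, "discovered_motif.meme"))
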