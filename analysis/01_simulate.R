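#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study - a transcriptome with known truth
# (TE time course, planted 3'UTR ARE sites), ribosome footprints, RNA-seq
# fragments, a five-stage count time course and duplicate CLIP + input
# libraries - and write everything in the standard formats the later stages
# read back (BED12, FASTA, BED6, TSV).

library(riboclip)

seed <- 7
outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

sim <- generate_transcriptome(1000, seed = derive_seed(seed, "simulate"))
write_annotation_bed12(sim$models, file.path(outdir, "transcripts.bed"))
write_fasta_rna(sim$sequences, file.path(outdir, "transcripts.fa"))
write.table(sim$truth$genes, file.path(outdir, "truth_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth$planted, file.path(outdir, "truth_planted.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

ribo <- simulate_ribo_reads(sim, 5e5, seed = derive_seed(seed, "ribo"))
rna <- simulate_rna_reads(sim, 5e5, seed = derive_seed(seed, "rna"))
write_alignments_bed6(ribo, file.path(outdir, "ribo.bed"))
write_alignments_bed6(rna, file.path(outdir, "rna.bed"))

tc <- simulate_timecourse(sim, depth = 50, seed = derive_seed(seed, "tc"))
for (assay in c("rpf", "rna")) {
  ct <- tc[[assay]]
  df <- cbind(gene_id = rownames(ct$counts), as.data.frame(ct$counts))
  write.table(df, file.path(outdir, sprintf("counts_%s.tsv", assay)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cbind(ct$samples, total = ct$totals),
              file.path(outdir, sprintf("samples_%s.tsv", assay)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

clip1 <- simulate_clip_reads(sim, 2e5, 2e5, seed = derive_seed(seed, "clip1"))
clip2 <- simulate_clip_reads(sim, 2e5, 2e5, seed = derive_seed(seed, "clip2"))
write_alignments_bed6(clip1$clip, file.path(outdir, "clip_rep1.bed"))
write_alignments_bed6(clip2$clip, file.path(outdir, "clip_rep2.bed"))
write_alignments_bed6(clip1$input, file.path(outdir, "clip_input.bed"))

# RBP motif collection: the ARE consensus of Zfp36 plus random decoys, with
# a small expression table gating the enrichment report
motifs <- c(list(consensus_motif("UAUUUAUU", "ARE_Zfp36", "Zfp36")),
            random_decoy_motifs(19, seed = derive_seed(seed, "decoys")))
write_meme_motifs(motifs, file.path(outdir, "motifs.meme"))
set.seed(derive_seed(seed, "rbp_expr"))
rbp_expr <- data.frame(
  rbp_name = vapply(motifs, `[[`, "", "rbp_name"),
  rpkm = c(120, round(runif(19, 0, 40), 1)))
write.table(rbp_expr, file.path(outdir, "rbp_expression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d genes (%d with a planted ARE site), %s\n",
            nrow(sim$truth$genes), nrow(sim$truth$planted), outdir))
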