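#!/usr/bin/env Rscript
# Stage 4: RBP motif enrichment. Scans the 3'UTRs of differentially
# translated genes with the motif collection against a zero-order
# background, builds a 10x shuffled null, ranks motifs by one-sided Fisher
# enrichment with BH correction, and reports the enriched motifs of
# expressed RBPs.

library(riboclip)

ddir <- "results/data"
outdir <- "results/motifs"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
seed <- 7

models <- read_annotation(file.path(ddir, "transcripts.bed"))
seqs <- read_fasta_rna(file.path(ddir, "transcripts.fa"))
sig <- read.delim("results/te/significant_genes.tsv")$gene_id
motifs <- read_meme_motifs(file.path(ddir, "motifs.meme"))
rbp_expr <- read.delim(file.path(ddir, "rbp_expression.tsv"))

utrs <- extract_3utrs(models, seqs, sig)
cat(sprintf("scanning %d 3'UTRs of differentially translated genes with %d motifs\n",
            length(utrs), length(motifs)))

bg <- background_model(utrs)
shuf <- shuffle_sequences(utrs, copies = 10,
                          seed = derive_seed(seed, "shuffle"))
real_occ <- do.call(rbind, lapply(motifs, function(m) scan_pwm(utrs, m, bg)))
shuf_occ <- do.call(rbind, lapply(motifs, function(m) scan_pwm(shuf, m, bg)))
fe <- fisher_enrichment(real_occ, shuf_occ, length(utrs), length(shuf),
                        motifs)
top <- report_top_motifs(fe, rbp_expr, rpkm_threshold = 10, top_n = 10)

cat("top enriched motifs of expressed RBPs:\n")
print(top[, c("motif_id", "rbp_name", "odds_ratio", "adj_p", "stringent")],
      row.names = FALSE)

write.table(real_occ, file.path(outdir, "occurrences.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(fe, file.path(outdir, "enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(top, file.path(outdir, "top_motifs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
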