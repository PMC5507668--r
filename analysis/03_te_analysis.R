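#!/usr/bin/env Rscript
# Stage 3: translation-efficiency dynamics. Filters to expressed genes
# (RPKM > 10 in both assays at all five stages), computes apparent TE,
# runs the empirical differential-TE test across adjacent stages, groups
# significant genes by direction and clusters their centered log2 TE
# profiles.

library(riboclip)

ddir <- "results/data"
outdir <- "results/te"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
seed <- 7

truth <- read.delim(file.path(ddir, "truth_genes.tsv"))
load_ct <- function(assay) {
  counts <- as.matrix(read.delim(
    file.path(ddir, sprintf("counts_%s.tsv", assay)), row.names = 1))
  samp <- read.delim(file.path(ddir, sprintf("samples_%s.tsv", assay)))
  lengths <- if (assay == "rpf") truth$cds_length else truth$tx_length
  count_table(counts, setNames(lengths, truth$gene_id)[rownames(counts)],
              totals = samp$total, assay = toupper(sub("rpf", "RPF", assay)),
              stage = samp$stage, replicate = samp$replicate)
}
rpf <- load_ct("rpf")
rna <- load_ct("rna")

retained <- filter_expressed(rpf, rna, threshold = 10)
cat(sprintf("%d of %d genes pass the RPKM > 10 filter at all stages\n",
            length(retained), nrow(truth)))

te <- apparent_te(rpf, rna, retained)
dt <- differential_te(rpf, rna, retained, B = 2000, seed = derive_seed(seed, "te"))
sig <- dt[dt$significant, ]
cat(sprintf("%d genes differentially translated (empirical p < 0.05 at any adjacent pair): %d up, %d down\n",
            nrow(sig), sum(sig$direction == "up"),
            sum(sig$direction == "down")))

# recovery against the simulation truth
m <- merge(dt, truth, by = "gene_id")
cat(sprintf("truth check: %.0f%% of planted TE shifts detected; %.1f%% of null genes called\n",
            100 * mean(m$significant[m$shift]),
            100 * mean(m$significant[!m$shift])))

cl <- cluster_te(te, dt)
write.table(cbind(gene_id = rownames(cl$matrix), direction = cl$direction,
                  round(as.data.frame(cl$matrix), 4)),
            file.path(outdir, "te_clusters.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cbind(gene_id = rownames(te$te), round(as.data.frame(te$te), 4)),
            file.path(outdir, "te.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(dt, file.path(outdir, "differential_te.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(gene_id = sig$gene_id),
            file.path(outdir, "significant_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
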