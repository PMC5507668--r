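# riboclip

Analysis of translational regulation from parallel ribosome profiling
(Ribo-seq) and RNA-seq time courses, with an independent CLIP-seq branch —
the computational workflow of an LPS-stimulated macrophage study: footprint
quality control, translation-efficiency (TE) dynamics with an empirical
differential test, AU-rich-element (ARE) motif enrichment in 3'UTRs, and
CLIP peak calling with de novo motif discovery. A synthetic-data module
generates transcriptomes and read sets with fully known ground truth, so
every stage is validated against what was planted.

**Who it is for.** Computational biologists analysing Ribo-seq/RNA-seq
time courses (translational control during stimulation responses) or
RBP CLIP-seq data, and anyone who wants a fully seeded, tested pipeline to
benchmark such analyses against simulated truth.

## The models at the core

- **Footprint QC.** 28-nt ribosome-protected fragments have fixed geometry:
  the distance from the footprint 5' end to the P-site codon is 12 nt, and
  to the A-site codon at termination 15 nt. Metagene profiles of read 5'
  ends (RPM) around start/stop codons recover these offsets as profile
  argmaxes; elongating ribosomes give a 3-nt codon periodicity of
  CDS-internal 5' ends (positional autocorrelation over lags 1–9 plus a
  frame chi-square), which RNA-seq fragments lack.
- **Differential TE.** Apparent TE is RPF RPKM / RNA RPKM per gene and
  stage. For each adjacent stage pair, RPF counts are scored against the
  expectation implied by the matched RNA counts (robust trend
  `E[RPF] = exp(a + b log RNA)`, gene-level translation factor, decile NB
  dispersion from within-stage replicates); the statistic is the
  replicate-averaged difference of mid-p quantile-residual scores and its
  p-value comes from a joint parametric bootstrap (p granularity exactly
  1/(B+1)). Genes with p < 0.05 at any pair are differentially translated,
  grouped by the direction at their minimum-p pair.
- **Motif enrichment.** 3'UTRs of differentially translated genes (longest
  CDS isoform) scanned with RBP PWMs against a zero-order background, with
  *exact* score p-values by dynamic programming (1/1000-bit grid), a
  10×-shuffled sequence null, one-sided Fisher tests with BH correction,
  and an expressed-RBP (RPKM ≥ 10) filter on the report.
- **CLIP-seq.** 50-nt bins, zero-truncated negative binomial regression of
  CLIP counts on the scaled input control, peaks at p < 0.01, merged across
  replicates when centers are ≤ 100 nt apart (both replicates required),
  annotated 3'UTR > 5'UTR > CDS > intron; one-occurrence-per-sequence EM
  (width 8, 20 restarts, shift refinement) discovers the binding motif with
  an empirical shuffled-null significance.

## Worked example

The `analysis/` scripts run the whole study on simulated data
(`Rscript analysis/01_simulate.R` … `05_clip_analysis.R`), writing tables
under `results/`. The same flow in a session:

```r
library(riboclip)

sim  <- generate_transcriptome(1000, seed = 7)     # truth: TE course + planted AREs
ribo <- simulate_ribo_reads(sim, 5e5, seed = 7)

off <- estimate_offsets(metagene_profile(ribo, sim$models, "start"),
                        metagene_profile(ribo, sim$models, "stop"))
frame_periodicity(ribo, sim$models)$dominant_period
#> [1] 3
c(off$p_site_offset, off$a_site_offset)
#> [1] 12 15

tc   <- simulate_timecourse(sim, depth = 50, seed = 8)
keep <- filter_expressed(tc$rpf, tc$rna)           # RPKM > 10, both assays, all stages
dt   <- differential_te(tc$rpf, tc$rna, keep, B = 2000, seed = 9)
sum(dt$significant)
#> [1] 234
```

The QC stage prints `P-site 12 nt, A-site 15 nt` and a 0.90/0.05/0.05
frame split; the motif stage ranks the planted ARE (`UAUUUAUU`, Zfp36)
first among 19 decoys at an adjusted p below 1e-100; the CLIP stage merges
replicate-supported peaks (≈96–99% in 3'UTRs) and rediscovers `UAUUUAUU`
from the peak sequences. Each number is the package reading back what the
simulator planted — the point of the exercise.

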