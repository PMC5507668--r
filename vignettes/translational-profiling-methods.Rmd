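---
title: "Methods: ribosome profiling QC, differential translation efficiency, and CLIP-seq analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ribosome profiling QC, differential translation efficiency, and CLIP-seq analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

riboclip analyses parallel ribosome-profiling (Ribo-seq) and RNA-seq time
courses, with an independent CLIP-seq branch, as they arise in studies of
translational regulation during inflammatory responses: macrophages
stimulated with LPS and sampled at 0, 1, 2, 4 and 6 hr, each sample split
into a footprint library and an RNA library. This vignette describes the
models behind each stage, the tunable parameters and why their defaults are
what they are, what the bundled simulator does and does not emulate, and the
numerical choices a maintainer would want written down.

## Coordinates and data model

All internal coordinates are 0-based half-open, matching BED. A read is
reduced to its strand-aware 5' end: for a minus-strand alignment this is the
rightmost aligned base. "Uniquely mapped" is operationalized as MAPQ >= 10
(the HTSeq `-a 10` convention); multimappers are flagged and excluded from
all counting. Where a gene has several isoforms, region-level analyses use
the isoform with the longest CDS (ties: longest transcript, then
lexicographic id). The coding span convention includes the stop codon, so a
CDS length is always a multiple of 3 and ends on a stop.

The simulator emits alignments directly in transcript coordinates (one
reference per transcript). All the analyses here are transcript-relative, so
this removes spliced-alignment bookkeeping from the statistical questions;
`project_genomic()` exists to exercise the genomic/transcript mapping and
genomic-mode counting against the same truth.

## The synthetic study and its ground truth

`generate_transcriptome()` fixes, per gene: 5'UTR length uniform on 30-150
nt, CDS 60-400 codons (AUG start, stop end, sense codons uniform), 3'UTR
100-500 nt with i.i.d. uniform base composition; RNA abundance log-normal
(meanlog log 50, sdlog 1, constant over the course); baseline TE log-normal
(sdlog 0.5); a 10% subset of genes shifts TE by +/-2 log2 units at one of
the four later stages and keeps the new level; half the genes carry one
exact `UAUUUAUU` AU-rich element (ARE) at a uniform 3'UTR position, and
those positions double as CLIP peak centers with gamma intensity factors
(dispersion 0.5) stored in the truth so the two CLIP replicates share them.
Footprints are 28 nt with a 12-nt 5'-end-to-P-site offset; the 5' end lands
exactly on the P-site grid with probability 0.9 (else +/-1 nt), initiation
and termination spikes are 5x the per-codon rate, and 2% of footprints are
uniform UTR background. These spike/background values are simulator
conveniences chosen so the metagene profiles and region ratios look like
real libraries; they are recorded in the truth, not claims about data.

What the simulator does **not** emulate: sequencing errors, adapter
artifacts, PCR duplicates, mappability structure, codon-specific dwell
times, transcriptional change over the course, isoform switching, or
crosslink-site truncations in CLIP. Passing tests therefore demonstrate
that each method recovers what it models under clean sampling noise - not
that it is robust to every artifact of real libraries.

## Footprint QC

Metagene profiles sum unique 28-nt read 5' ends over a -50..+50 window
anchored at the first base of the start or stop codon, in reads per million
uniquely mapped (RPM) so duplicating a library changes nothing. The P-site
offset is minus the argmax of the start profile over window positions
-40..-1, and the stop-anchored (A-site) offset likewise; with the footprint
geometry above these are 12 and 15 nt (the termination peak sits at the
stop minus offset-plus-3 because the stop codon occupies the A site). The
argmax is the simplest estimator consistent with reading the peak off a
metagene plot; a tie is an error, and a peak less than 2x the window median
warns of weak signal.

Periodicity is measured two ways: a chi-square of the three CDS frame
counts against uniform, and the positional autocorrelation (lags 1-9) of
pooled CDS 5'-end density. Reads within 15 nt of the CDS ends are excluded
so initiation/termination spikes cannot bias the frames. Pooling transcripts
of unequal length and expression induces a smooth positional trend that is
not periodicity, so the autocorrelation is computed on the residual of the
pooled density against its expression-weighted expected coverage (each
transcript contributes its own mean rate over the offsets it covers), over
offsets up to the 70% quantile of CDS lengths. On simulated RNA-seq this
residual is pure multinomial noise and no lag dominates; on footprints lag
3 carries nearly all the signal.

Region specificity divides per-nt read density in 5'UTR, 3'UTR and introns
by CDS density, assigning each read by its P-site-shifted position (5' end
+ estimated offset): initiation footprints protrude 12 nt into the 5'UTR
and would otherwise be misattributed. Replicate correlation is Pearson on
log2 RPM over genes with more than 10 reads in every sample.

## Differential translation efficiency

Apparent TE is the ratio of replicate-averaged RPF RPKM (CDS length) to
RNA RPKM (exon-union length) - a CDS ribosome-density contrast. Genes enter
the analysis only if replicate-averaged RPKM exceeds 10 in both assays at
all five stages (the filter is applied to replicate-averaged values; the
alternative per-replicate reading of the rule is stricter but changes little
at these depths).

The differential test judges RPF counts against the expectation implied by
the matched RNA counts, per adjacent stage pair (0-1, 1-2, 2-4, 4-6):

1. Per sample, a robust log-linear trend `E[RPF] = exp(a + b log(RNA+0.5))`
   is fitted across genes (`MASS::rlm`).
2. A gene-level translation factor `t_g` - the ratio of the gene's summed
   RPF to its summed trend expectation over the pair's four samples -
   defines the per-gene null mean `t_g * trend(RNA)`. This factor is
   essential: genes carry stable gene-specific TE, and a trend-only null
   mistakes that biology for between-stage change.
3. Negative-binomial dispersions are estimated by method of moments within
   deciles of the null mean, from *within-stage replicate residuals* (with
   an `n/(n-1)` degrees-of-freedom correction), separately for RNA and RPF.
   Using within-stage variability makes the dispersions immune to
   contamination by genuinely shifting genes, which would otherwise inflate
   the null and cost power.
4. Each observation's translation score is its mid-p quantile residual
   `qnorm(P(Y < y) + 0.5 P(Y = y))` under NB(null mean, total variance),
   where the total variance adds the delta-method RNA-propagated variance
   of the trend expectation to the RPF dispersion. The statistic `D` is the
   replicate-averaged score difference between the two stages.
5. The null distribution of `D` comes from a joint parametric bootstrap:
   RNA counts are resampled from their fitted NB and pushed through the
   trend (so the noise of the RNA-implied expectation enters the null
   exactly as it does in the observed statistic), RPF counts are drawn
   around the trend of the noise-free RNA mean with the RPF dispersion,
   and `t_g` is re-estimated inside every draw. The empirical two-sided
   p-value is `(1 + #{|D*| >= |D|})/(B+1)`; its granularity is exactly
   `1/(B+1)` and no p-value is zero. The bootstrap inner loop is compiled
   (Rcpp) and uses R's RNG, so a seed fixes the result.

A gene is differentially translated if any adjacent pair has p < 0.05; its
direction is the sign of `D` at the minimum-p pair ("up" = TE rises at the
later stage). Two design points deserve emphasis because they were learned
the hard way: conditioning the null on the *observed* RNA counts (instead
of resampling them) makes low-expression genes anti-conservative, because
the observed statistic contains RNA noise the null then lacks; and
generating bootstrap RPF around the resampled (rather than noise-free) RNA
expectation cancels that same noise and is anti-conservative in the other
direction. With the scheme above, the per-pair type-I error sits at ~0.05
across pooled null simulations, and a 2-log2 shift at mean count 50 is
detected in >80% of genes.

Clustering of significant genes groups rows by direction, then orders each
group by complete-linkage hierarchical clustering (Euclidean) of
row-mean-centered log2 TE; rows are canonically sorted by gene id first so
the result is invariant to input order.

## 3'UTR motif enrichment

The 3'UTRs of differentially translated genes (longest-CDS isoform, sense
strand) are scanned with each RBP position weight matrix against the
zero-order background of the scanned set (+1 pseudocount per base; sense
strand only). Scores are summed log2 odds; the null score distribution is
computed *exactly* by dynamic programming over scores discretized at 1/1000
bit - positions are scored with the same discretized integers, so the
p-values are exact for the scored quantity and agree with brute-force
enumeration of all 4^w words to machine precision. The occurrence threshold
is p <= 1e-4 (the FIMO default); motifs containing zeros get a 1e-3
pseudocount with a logged message.

The null is ten shuffled copies of each sequence (uniform letter
permutations, preserving composition and length exactly), pooled into one
contingency per motif: sequences-with-at-least-one-occurrence in real
versus shuffled, one-sided Fisher exact test, BH adjustment across motifs.
Counting sequences rather than occurrences avoids the position
non-independence of overlapping hits. The report keeps motifs of RBPs
expressed at RPKM >= 10, ranks by adjusted p, and flags the extreme tier
(adjusted p < 1e-100) separately. Under a complete null the raw p < 0.05
fraction stays at its nominal level and BH at 0.05 almost always returns
zero discoveries.

## CLIP-seq peak calling and motif discovery

CLIP and input reads are binned by 5' end into 50-nt windows tiled along
each transcript. Bins with at least one CLIP read enter a zero-truncated
negative binomial regression with mean `exp(b0 + b1 log(scaled_input + 1))`,
fitted by direct likelihood maximization; per-bin p-values are the upper
tail of the fitted zero-truncated distribution at the observed count, and
bins below p = 0.01 are peaks (raw threshold, as peak callers conventionally
apply; the threshold is an argument).

Two choices depart from the most literal "offset on the per-bin input
count" formulation, both because the literal version is miscalibrated:

- The input covariate is the *gene-level smoothed* expected input of the
  bin (gene input total x bin width / transcript length). A raw per-bin
  input count is itself a noisy estimate of local background; conditioning
  on it directly makes every bin whose input fluctuated to 0-2 reads look
  enriched, concentrating false positives exactly where the background
  estimate is worst (~2x the nominal rate in null simulations).
- The input coefficient `b1` is free rather than fixed at 1, absorbing
  residual attenuation between the smoothed covariate and the CLIP mean.

The fit is two-pass: bins decisively significant at first pass (p < 1e-4)
are excluded and the null refitted, so strong peaks cannot inflate the null
dispersion; the exclusion cutoff sits far below the calling threshold so
the refit is unbiased when there is no signal. With these choices the null
peak rate is at or below nominal and 10x-background peaks are recovered
with ~0.95-0.98 sensitivity at the default depths.

Peaks from the two replicates are pooled and grouped by single-linkage on
centers (<= 100 nt, per reference); only groups containing peaks from both
replicates survive, spanning their members' union. Merged peaks are
annotated by the region containing their center on the selected isoform,
with precedence 3'UTR > 5'UTR > CDS > intron on ambiguity (the binding
biology of interest is 3'UTR-centric); intergenic peaks are excluded from
the percentages, which sum to 100.

Motif discovery on peak sequences is a one-occurrence-per-sequence EM with
a width-8 PWM: uniform prior over start positions, posterior from PWM vs
zero-order background odds, M-step with 0.25 pseudocounts, convergence at a
relative log-likelihood change of 1e-8 (cap 200 iterations; the EM
objective is provably non-decreasing and tested as such). Twenty restarts
are seeded from random data windows, and the best fit is refined by
trying +/-1 and +/-2 column shifts (a shifted register is the most common
EM local optimum; the refinement recovers the exact register essentially
always in simulations). Significance is the empirical p of the fitted
motif's information content against the same fit on shuffled copies of the
sequences (default 100; the E-value of a motif-discovery suite is replaced
by this calibrated, data-local null).

## Problem sizes, seeds, determinism

Every stochastic routine takes an explicit seed; stage seeds derive from
one master seed (`derive_seed()`), and the full pipeline is byte-identical
across runs at a fixed seed (tested). The validation suite runs the QC
recovery at the study scale (2,000 transcripts, 500,000 footprints, 20
seeds), differential-TE calibration pooled over 20 null simulations of
1,000 genes at bootstrap depth B = 2,000 (one adjacent pair per simulation;
the p-value is a per-pair quantity), power at the fixed operating point of
mean count 50 on the full course, and the CLIP and motif stacks at 150-500
genes - sizes chosen so each property is measured with useful precision on
a single CPU. `scripts/acceptance.R` re-runs the footprint-geometry
recovery from scratch at the full default conditions and writes the
estimated offsets and dominant period as JSON.

## Known limitations

The differential-TE test assumes replicates are exchangeable within stage
and at least two per stage for the within-stage dispersion; with a single
replicate the dispersion would need an external estimate. The peak caller
models a transcript-uniform background within gene; strong within-gene
input structure (mappability, local biases) would be smoothed away. Motif
enrichment uses a zero-order null; dinucleotide-preserving shuffles would
be stricter for composition-driven motifs. Region annotation resolves
ambiguous peaks by precedence, not by read evidence. The 724/280-gene
headline lists of the motivating study require its deposited raw data and
era-specific aligners and are out of scope here.
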