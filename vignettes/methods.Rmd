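---
title: "Methods: differential transcriptome-epigenome analysis with epidiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential transcriptome-epigenome analysis with epidiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

epidiff compares a cancer-derived cell line against a normal-derived
reference across matched RNA-seq and ChIP-seq data and prioritizes
candidate genes where the transcriptome and the epigenome move together.
This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic-data module does and does not
emulate.

## Coordinates and interval arithmetic

All coordinates are 0-based half-open internally, BED-native. TSV readers
accept `one_based = TRUE` for tables produced with 1-based inclusive
conventions; since public island tables rarely state their convention,
both conversions are supported rather than guessed. Distance between
intervals is the gap in bp, with overlap and adjacency both at distance 0
— this makes "within 5 kb" a closed predicate (`distance <= 5000`) — and
an infinite sentinel across chromosomes so proximity tests need no
special-casing.

## Differential expression

Expression is RPKM (`count * 1e9 / (exon_length * library_size)`); genes
above 1 RPKM in at least one line are retained. The trimmed mean of
M-values factor is computed on raw counts — genes zero in either sample
excluded, the extreme 30% per tail by M and 5% per tail by A removed,
inverse-variance weights `1/(1/t + 1/r)` — so the factor absorbs both
depth and composition (an exactly doubled library gives factor 2.0). The
trim fractions and weights follow the method's standard formulation; they
are exposed as arguments. With fewer than 10 surviving genes the factor
falls back to the untrimmed weighted mean with a warning.

Per-gene testing is the two-sided Fisher exact test of the gene's counts
against the TMM-scaled effective libraries, evaluated directly on the
hypergeometric support (summing probabilities no larger than the observed
table's, with the conventional `1 + 1e-7` relative slack), which is exact
and cheap even with multi-million margins. A gene is called differential
iff BH FDR < 0.05 and fold change >= 3; the fold change uses a 0.5
pseudo-count for zero counts in the ratio only, never in the test, so
ranking stays finite while inference stays exact. miRNA-style tables are
tested with a Pearson chi-square without continuity correction (counts
are large; the correction would be conservative), falling back to the
Fisher exact test when any expected cell is below 1, with Bonferroni
correction across tested genes.

Worth knowing: at fixed counts, growing both libraries does *not* shrink
the Fisher p — it converges to the binomial limit from below. Power comes
from scaling counts with depth, and the tests assert exactly that.

### Length-bias-aware enrichment

Long genes are over-detected as differential. The probability-weighting
function is an isotonic regression of the DE indicator on gene length
over up to 40 equal-occupancy bins, with the monotonicity direction taken
from the sign of the bin-level Spearman correlation and weights floored
at 1e-4. Each category's odds is the ratio of mean weights inside versus
outside, and the enrichment p is the upper tail of the Wallenius
noncentral hypergeometric distribution with those odds. The Wallenius pmf
is evaluated from its exact integral representation with adaptive
quadrature and renormalized over the support; `odds = 1` is special-cased
to the central hypergeometric so the reduction is exact rather than
merely numerical. Tests validate the biased case against brute Monte
Carlo urn sampling (sequential weighted draws without replacement are
exactly the Wallenius urn).

## Island calling

Parameters follow the broad-domain caller convention: 200-bp windows,
gap 200 bp (600 bp for H3K27me3), 81% effective genome, island FDR
<= 0.001, differential fold >= 3 at FDR < 0.05. A window is eligible when
its count exceeds the smallest k with upper-tail Poisson mass below 0.20
under the genome-wide background rate; eligible windows bridged by at
most one gap of ineligible sequence merge. The island-level score is an
upper-tail Poisson p of the island's total ChIP count against the
input-scaled expectation, floored at the background expectation so thin
input coverage cannot inflate significance; BH then controls the FDR over
islands. This is a fully specified stand-in for aggregate window-score
callers: same window/gap/genome-fraction parameters, but a defined,
testable island-level statistic. Tags are counted at their 5' position
without fragment extension (short single-end tags; no extension length is
assumed).

Differential islands are called on regions defined from the pooled
samples, so one symmetric region set serves both directions — swapping
samples inverts fold and direction and leaves p unchanged, which the
tests assert. The per-region test is exact binomial on the count split
against the library-size split; readcounts are reported per million tags.
Published tables of this design sometimes print folds that are not the
ratio of their printed readcounts; epidiff's fold is always the ratio of
its library-normalized readcounts, documented here as the package's own
normalization.

Annotation assigns each island one category from its midpoint with
precedence promoter (3 kb upstream of a TSS) > 5' UTR > 3' UTR > coding
exon > intron > downstream > distal intergenic; the midpoint rule is
unambiguous where partial-overlap rules would need tie-breaking.

## TSS metagene profiles

Genes are ranked by RPKM and split into four groups of equal size (±1),
ties broken by gene id so membership is deterministic. Offsets are
strand-oriented (upstream is always negative); bins are 25 bp over ±5 kb;
genes whose flank crosses a chromosome edge are skipped and counted. The
profile is the mean (not the sum) over genes so quartiles of slightly
unequal size are comparable.

Per-gene, per-bin counts are capped at the smallest k with Poisson
upper-tail mass below alpha = 1e-5 under a global lambda (the mean bin
count of the mark/sample). This removes tower artifacts while preserving
shape *in the sparse regime* — when typical per-gene bin counts are a few
tags, the cap sits an order of magnitude above the signal. At the depths
real libraries reach (~10-20 M tags over a mammalian genome), promoter
bins of individual genes hold single-digit counts, which is that regime.
The lambda scope (global) and alpha are documented defaults of this
implementation, not claims about any particular published analysis.

## Copy-number controls

Adjacent same-state segments merge when the gap is strictly below 1 Mb
(the boundary case stays unmerged); merging is idempotent and absorbs the
gap. Islands whose midpoint lies in a lost region are excluded, and both
the excluded count and the fraction of all differential islands are
reported — the fraction's denominator is this package's own definition.
Per-chromosome islands-per-Mb densities are computed for gain, CNLOH and
neutral footprints (neutral = chromosome minus all events), and gain and
CNLOH are each compared to neutral with a two-sided Mann-Whitney U test:
exact when `min(n, m) <= 8`, `n + m <= 25` and no ties, otherwise the
tie-corrected normal approximation with continuity correction. At
`n = m = 8` the two branches agree to about 0.01-0.02 in p, which is the
documented accuracy of the switch.

## Candidate prioritization and qPCR statistics

The three criteria (Pol II island up in cancer within 5 kb; H3K27me3
island up in normal within 5 kb; expression up >= 3-fold) are measured
from the gene body, not the TSS — the inclusive reading of "within 5 kb
of" a gene — with the window exposed as configuration. Criterion (iii)
inherits the DE FDR gate by default because the candidate set should be a
subset of the reported DE table; `require_fdr = FALSE` relaxes this.

ddCt normalizes the target Cq to the arithmetic mean of two housekeeping
Cq values — identically the geometric mean of the linear quantities —
then to the reference-group mean, so reference samples average to 1 on
the log scale and any per-sample plate shift cancels exactly (asserted as
an invariance test). Group comparison reports the fold change of
arithmetic means and the same Mann-Whitney implementation used by the
copy-number control.

## The synthetic-data module

Every generator is a pure function of its parameters and seed. Defaults
define the toy study: 2 chromosomes of 3 Mb, 200 non-overlapping stranded
genes with 1-10 exons and CDS bounds inside the terminal exons; 40
planted DE genes with fold changes uniform in [4, 9] (half up, half
down), negative-binomial counts at dispersion 0.02 — the low biological
variability of cell-line replicates; the 5% least-expressed genes are
made near-silent to exercise the RPKM filter. ChIP signal follows the
canonical promoter geometry: H3K4me3 bimodal at ±350 bp (sd 70),
H3K4me1 at −700/+1300 bp (sd 140), Pol II at the TSS (sd 80), H3K27me3
broad over gene bodies with a small peak 250 bp downstream, intensities
tied to expression quartile (positively for the active marks, negatively
for H3K27me3). The cancer-like sample carries a TSS depletion of
H3K27me3 over top-quartile genes and a global 0.85 H3K27me3 deflation.

Signal budgets are per-mark (7k/15k/20k/40k tags for
H3K4me3/H3K4me1/PolII/H3K27me3, plus 60k uniform background and 100k
input per sample): sharp marks concentrate their tags in few bins, so
their budgets are smaller, keeping per-gene 25-bp bin counts in the
single digits — the sparse regime real libraries occupy and the one in
which Poisson trimming is shape-preserving. Candidate genes (4 by
default, drawn from strongly up-regulated planted DE genes outside lost
regions) receive planted islands whose *realized* library-normalized
region fold equals the planted factor (6, twice every threshold): the
generator adds favored-sample tags until the expected region ratio —
background and the opposing sample's content included — hits the target.
This makes the truth table's enrichment factor the quantity the pipeline
actually estimates.

CNA segments tile part of the genome with at least one gain/loss/CNLOH
each, a same-state pair about 0.5 Mb apart (exercising the merge rule)
and a loss segment (exercising exclusion). qPCR plates are generated as
`Cq = baseline − log2(expression) + sample shift + noise` (noise 0.25
cycles by default, 10 samples per group, triplicates), with constant
housekeeping expression, so the ddCt chain recovers the planted ratio
exactly at zero noise.

What the generator does **not** emulate: mappability structure and
blacklist artifacts, duplicate-read towers, fragment-length effects,
GC bias, transcript isoforms, and biological replicate variability
beyond the NB dispersion. Passing the planted-truth suites therefore
demonstrates internal correctness of the statistics and the plumbing,
not robustness to those real-data pathologies.

## Problem sizes and determinism

The default demo (200 genes, 6 Mb, ~1.3 M tags across all marks, inputs
and samples) runs the full pipeline in well under a minute on one CPU;
the Monte-Carlo suites (50-seed island null calibration, 50-seed
copy-number bias calibration, 1e6-draw Wallenius urn check) are sized to
keep the whole validation suite in a few minutes. Reruns with the same
config are byte-identical (the manifest records parameters and input
hashes; it contains no timestamps by design).
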