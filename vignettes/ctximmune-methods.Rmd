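---
title: "Methods: models, parameters and design choices"
author: "ctximmune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctximmune)
```

ctximmune implements the analysis arms of a context-specific immune
profiling study of a two-group cohort (cases vs. healthy controls):
co-expression network modules with a jackknife stability screen,
signature-based immune deconvolution with a marker-removal sensitivity
protocol, lncRNA discovery and genomic-context annotation, site-to-pair
miRNA binding statistics, and cytometry gating with per-event
KNN group-enrichment mapping. Every arm runs end to end on synthetic data
with planted, recoverable ground truth; this vignette explains the models,
the tunables, and the choices that were genuinely open.

## Preprocessing

Counts are normalized with median-of-ratios size factors: for the genes
with all-positive counts, each gene's geometric mean across samples is the
reference, and a sample's factor is the median ratio of its counts to the
reference. Factors are rescaled to geometric mean 1 — the scale is not
identified otherwise, and the rescaling makes factors comparable across
runs. Expression is `log2(count / s + pseudocount)` (default pseudocount
1). Dispersion-model variance-stabilizing transforms are deliberately not
reproduced: the downstream consumer is a correlation network, which needs
only a monotone, finite transform, and the original use of those
transforms was visual QC.

The low-count filter keeps genes with at least `min_count` (10) reads in
at least `min_samples` samples, defaulting to the smaller group size so
that a gene expressed in only one full group survives.

Sample QC flags a sample when (a) its merge height in average-linkage
clustering of Euclidean sample distances exceeds the median height plus
`z_height` MADs, or (b) its distance from the centroid in the first two
principal components exceeds the mean plus `z_pca` standard deviations.
`z_pca` is the conventional 3. `z_height` defaults to 5: leaf merge
heights are right-skewed even for perfectly homogeneous cohorts (some
sample is always last to join a cluster), and a 3-MAD cut fires in roughly
a quarter of clean simulated cohorts at 12–14 samples, which would
routinely discard good samples. At 5 MADs clean cohorts are flag-free in
over 95% of simulations while a sample shifted by a few standard
deviations on all genes sits far beyond the threshold. Samples with
genuinely extreme global module activation can still be flagged — that is
the intended behaviour of a "discordant global expression" screen, not an
error, but it is worth knowing when interpreting the QC report on strongly
modular data.

## Co-expression networks and modules

The network is signed: adjacency `a_ij = ((1 + cor_ij) / 2)^beta`, so
anti-correlated genes get adjacency near zero rather than being folded
onto positively correlated ones. The topological overlap measure

$$\mathrm{TOM}_{ij} = \frac{\sum_{u \neq i,j} a_{iu} a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}}, \qquad k_i = \sum_{u \neq i} a_{iu}$$

is used as clustering similarity; `1 - TOM` feeds average-linkage
hierarchical clustering. The soft threshold `beta` is the smallest
candidate (default 1–20) whose scale-free fit — the R² of the regression
of log10 p(k) on log10 k over connectivity bins, signed so only a
decreasing degree distribution counts — reaches 0.8, else the candidate
maximizing the fit. Block-structured synthetic data does not always admit
a 0.8 fit at small sample sizes; the fallback keeps the selection total
and deterministic.

Module detection is a static cut of the dendrogram (default cut height:
the 0.75 quantile of merge heights, i.e. one quarter from the top),
removal of clusters below `min_module_size` (30), a membership refinement,
and eigengene merging. The refinement strips members whose correlation
with their module eigengene is not significantly positive (Student test at
`kme_alpha = 0.01`) and re-checks the size floor. It is the
sample-size-adaptive analogue of the usual fixed module-membership (kME)
cutoff, and it is what keeps a static cut honest: wherever the cut lands
inside the band of noise merges, loose genes attach to real modules and
chance clumps of noise pass the size floor; the refinement removes both,
and in simulations it is the difference between recovering planted modules
at Jaccard 0.6–0.8 and recovering them at 0.98–1.0. On pure-noise data it
empties the module set entirely, which downstream code treats as "nothing
to report", not an error.

The eigengene is the first principal component of the standardized member
expression, scaled to unit variance and sign-oriented so its mean
correlation with members is positive — without the orientation the PC sign
is arbitrary, and sign-preservation scoring would be meaningless. Modules
whose eigengenes correlate above `1 - merge_cut` (default 0.75) are merged
iteratively, closest pair first. Module–trait association is the Pearson
correlation of eigengene with the 0/1 condition with the Student transform
`t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom.

## Leave-one-out stability

Small immune cohorts make module claims fragile; the stability screen asks
whether each full-network module survives the removal of any single
sample. Each of the n jackknife iterations rebuilds the network and
re-detects modules with identical parameters — the power is not re-selected
and the full run's data-driven cut height is frozen — then matches each
full module to the leave-one-out module maximizing Jaccard similarity of
gene composition (ties: larger module, then lower label; the unassigned
label never participates). A module is `stable` iff its eigengene–trait
correlation keeps its full-network sign in every iteration *and* its
minimum matched Jaccard reaches `jaccard_threshold`. The default 0.5 is
the weakest defensible reading of "consistent composition" — majority
overlap — and is exposed in the configuration. Raising the threshold can
only demote modules, never promote them.

## Signature deconvolution and the sensitivity protocol

The enrichment scorer is deliberately simple: per sample, genes are ranked
ascending and

$$\mathrm{score} = \frac{\overline{\mathrm{rank}}_{sig} - (G+1)/2}{G-1}
\in [-0.5, 0.5],$$

zero-mean under random ranks and invariant to any monotone transform of a
sample's expression. The enrichment engine is deliberately replaceable —
any per-sample signature scorer could stand here; the substance of this
arm is the reference-overlap filter (keep a cell type only if
strictly more than 90% of its signature genes are measured), Welch tests
with Benjamini–Hochberg correction across retained types, and the
sensitivity protocol: delete a list of canonical markers from both the
matrix and the signatures, rerun everything, and compare. The shipped
25-gene neutrophil removal list contains the ten canonical granule and
lineage markers plus fifteen well-established completions and is plain
data — any list can be passed.

## lncRNA discovery and genomic context

Consensus between two assembly routes uses intron-chain identity (the
gffcompare "=" idiom): a route-A transcript is kept iff some route-B
transcript on the same chromosome and strand has the identical ordered
intron chain; terminal exon ends are free, and single-exon transcripts
never match (the next filter removes them anyway). The filter cascade then
applies, in order: spliced length ≥ 200 nt (a 199 nt candidate dies, a
200 nt one survives), ≥ 2 exons, no same-strand exonic overlap with the
normal-tissue set, no same-strand exonic overlap with known noncoding
annotation, and coding probability strictly greater than 0.99 (a
probability of exactly 0.99 is removed). The probability is a consumed
input column — no coding-potential model is fitted here. "Detected in
normal tissues" is operationalized as same-strand exonic overlap, the
bedtools-style reading of that filter.

Context classification is strand-aware with a fixed precedence:
same-strand exonic overlap with a coding gene → `sense_overlapping`;
full containment in one intron of a same-strand coding transcript →
`sense_intronic`; span overlap with an opposite-strand coding gene →
`antisense`; no overlap but a head-to-head (divergent) opposite-strand
coding TSS within `bidir_window` (1000 nt, the conventional bidirectional
promoter distance) → `bidirectional`; else `intergenic`. The precedence
makes the classes mutually exclusive and exhaustive. The nearest coding
gene on either strand is reported with its gap (0 when overlapping), left
blank beyond `nearest_window` (1 Mb) — matching the convention of leaving
the column empty for isolated intergenic transcripts. Antisense requires
only span overlap because antisense calls in practice annotate the host
gene without exon-level detail. Target prioritization sorts candidate
interactions by relevance-flag count (cancer pathway, immune pathway) and
then ascending interaction score — more negative hybridization energy is
stronger — and keeps the top three per lncRNA.

## miRNA site-to-pair statistics

Site-level evidence is an add-one empirical upper-tail p-value against a
null sample of −logKd values: `p = (1 + #{null ≥ obs}) / (N + 1)`. The
add-one form never returns 0 and equals `1/(N+1)` at best, which imposes a
real design constraint: with m sites tested, BH at level α can only retain
a site if `1/(N+1)` is below `α·rank/m`, so the null sample must be large
relative to the site count (the generator defaults to N = 10⁴).

The default null when none is supplied is the pooled observed −logKd
values — the label-shuffle null, since shuffling (miRNA, transcript)
assignments leaves the pooled distribution unchanged. This is fine when
true signal is sparse but contaminates badly when a large fraction of
sites carry signal; a clean external null sample can and should be passed
in that case, and the site generator emits one.

Site retention uses covariate-weighted BH with cross-fitted quantile-bin
weights: sites are binned by covariate quantiles, each fold's per-bin
weights are estimated from the other folds only (the floored excess of
small p-values per bin), normalized to mean 1, and BH is applied to
`p/w`. With one bin, a constant covariate, or unit weights this is
element-wise plain BH. Two properties matter and are both tested: the
weighting gains power when signal concentrates in a covariate bin, and
loses almost none when the covariate is uninformative (the cross-fitting
floor keeps weights near 1). The covariate must be independent of the
p-value under the null; binning on the site's own score rank would tilt
weights toward small p-values and void FDR control, which is why the
pipeline's default covariate is the per-transcript site count, not any
function of −logKd itself.

Retained sites are combined per (miRNA, transcript) pair with the
aggregated Cauchy method,

$$T = \frac{\sum_i w_i \tan((0.5 - p_i)\pi)}{\sum_i w_i}, \qquad
p_{comb} = \frac{1}{2} - \frac{\arctan T}{\pi},$$

on the *raw* p-values of the retained sites (combining adjusted quantities
is statistically invalid; the correction acts only as the retention gate),
clipped to `[1e-15, 1 - 1e-15]`. BH across pairs with at least one
retained site gives pair-level q-values; pairs with no retained site are
reported non-significant with a retained-site count of zero.

## Cytometry

Positivity thresholds come from fluorescence-minus-one controls: the
threshold for marker m is the 99th percentile of m's FMO distribution.
"HLA-DR low" is operationalized as below that threshold. The default gate
tree is the standard human MDSC strategy — total MDSC =
Lin⁻ HLA-DR⁻/low CD33⁺ CD11b⁺, split into PMN-MDSC (CD15⁺CD14⁻), M-MDSC
(CD14⁺CD15⁻) and e-MDSC (CD14⁻CD15⁻) — with per-sample percentages of the
parent gate and checkpoint positivity (CD47, SIRPα, Gal-9, CD73, PD-L1)
within each subset. Group comparison defaults to Mann–Whitney and
switches to Welch when an F test rejects variance homogeneity at 0.05
(`auto` mode), with stars at 0.05/0.01/0.001.

KNN enrichment scores each event by the fraction f of its k nearest
neighbours (Euclidean, self excluded) from the case group, after the two
groups are subsampled to equal event counts with the configured seed —
unequal group sizes would bias every neighbourhood. Events with f ≥ τ are
case-enriched, f ≤ 1 − τ control-enriched; τ defaults to the printed 95%
cut and k to 60, the convention of the T-REX-style per-event comparison
this follows. Distances are computed in z-scaled marker space by default;
a precomputed 2-D embedding can be supplied instead, but no embedding
algorithm is implemented here — the KNN structure, not the projection,
carries the statistic.

## What the generators emulate, and what they do not

`simulate_counts` draws negative binomial counts whose log2 means share a
per-module latent factor; the loading is chosen per gene so the expected
pairwise within-module correlation of log2 counts equals the target ρ,
with the NB sampling noise folded in by a delta-method approximation at
the gene's baseline mean. The disease module's latent factor is shifted
by `group_effect` in case samples, so the module moves coherently — the
same structure a disease-associated program shows in a real cohort. Library
depth is a lognormal multiplier (`libsize_sd`, default 0 for equal depth).
Not emulated: gene-length effects, GC bias, batch structure, count
outliers, and any correlation between modules; passing tests on this
generator shows the machinery recovers planted structure under clean
assumptions, not that real cohorts behave this cleanly.

`simulate_events` draws per-sample Gaussian mixtures over an 11-marker
panel on an arcsinh-like scale with one cluster given zero mixing weight
in controls; FMO tables redraw the mixture with the target marker's stain
absent. Real cytometry adds spillover, autofluorescence and acquisition
drift, none of which is modelled. `simulate_annotation` constructs one
toy locus per genomic-context class, each planted to satisfy exactly its
class definition under the classifier's precedence. `simulate_sites`
draws null −logKd values from Gaussian(2, 0.5) — any smooth null works
because the empirical p-values are distribution-free — and shifts true
pairs' sites upward by `effect_shift`.

All generators are pure functions of their arguments including the seed;
nothing in the package touches the global RNG state (seeded operations use
scoped seeds).

## Problem sizes and numerical choices

The test-suite and acceptance simulations use cohorts of 12–14 samples and
150–600 genes (the scale of a small discovery cohort),
cytometry runs of 10–27 samples at 120–400 events per sample, and site
tables of 40–50 pairs; jackknife screens run 25 independent seeds, null
calibrations 100–2000 replicates. These sizes were chosen once, as the
package's study conditions. Numerical conventions: TOM is symmetrized
(`(T + T')/2`) to cancel floating-point asymmetry and its diagonal set to
1; ACAT inputs are clipped at 1e-15; the empirical-p add-one convention
bounds p away from 0; eigengene sign is fixed by mean member correlation;
Jaccard of two empty sets is 1 by convention; all interval arithmetic is
0-based half-open internally with conversions only at the GTF/BED
boundaries.

## Known limitations

The module detector is a deterministic static-cut procedure, not the full
dynamic-hybrid tree cutter; it is the inner engine the stability screen
needs, with every parameter exposed, but it will fragment nested module
structure that the adaptive algorithm could resolve. The deconvolution
scorer makes no attempt at absolute cell fractions or spillover
correction. The weighted-FDR scheme is a transparent, cross-fitted
simplification of covariate-weighted hypothesis testing, not the original
convex-optimized weighting. Pair-level BH treats pairs as independent;
the ACAT combination inside a pair is valid under dependence, but
correlated pairs (shared miRNAs) are not modelled. KNN enrichment
reports per-event flags; it does not segment flagged events into connected
regions.
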