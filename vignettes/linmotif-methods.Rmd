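---
title: "Methods: lineage-specific TF-miRNA co-regulation in linmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage-specific TF-miRNA co-regulation in linmotif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`linmotif` implements a complete analysis chain for studying how
transcription factors (TFs) and microRNAs (miRNAs) jointly regulate the
genes that mark developmental lineages, with hematopoiesis as the
motivating system. This vignette documents the statistical models, the
tunable parameters, the synthetic-data generator that the tests run
against, and the numerical choices made where the design was open.

## Expression classes

Genes are grouped into three canonical expression patterns along
differentiation: high in embryonic stem cells (ESC) and monotonically
decreasing (class 1), peaking in intermediate progenitors (class 2), and
peaking in terminally differentiated cells (class 3). `assign_classes()`
computes per-gene profiles of **cell-type mean** expression (averaging
replicates makes the result invariant to sample permutations within a
cell type), standardizes each profile to zero mean and unit variance,
and applies average-linkage agglomerative clustering on Euclidean
distance, cutting the tree at `k = 3`. Clustering cell-type means rather
than raw samples was an open design point; means were chosen because the
class notion is about the trajectory shape, not replicate noise.
Clusters are relabeled 1..k by descending mean ESC expression, so labels
are reproducible, and genes are sorted lexicographically before
clustering so merge-order ties cannot depend on input order.

## SimScore

The similarity of a gene to a reference gene set (e.g. the pluripotent
genes) is

$$\mathrm{SimScore}(g) = \sum_{s} \varphi(x_{g,s};\,\mu_s,\sigma_s)\; x_{g,s},$$

where $(\mu_s, \sigma_s)$ is the maximum-likelihood Gaussian (mean, sd
with $n$ denominator) fitted per sample to the reference set's
expression values. The density value plays the role of a bin count of
reference genes near $x_{g,s}$: the Gaussian fit is the continuous limit
of binning and removes bin width as a free parameter. A zero-variance
reference in any sample is an error (the density would be degenerate);
the message advises jittering or excluding the sample.

Three significance tests ask whether a focal set (e.g. imprinted genes)
scores higher than the background of all other scored genes:

* **Mann–Whitney U**, one-sided (focal greater), normal approximation
  with tie correction; when both groups have at most 50 members and no
  ties, the exact p-value is reported alongside.
* **Top-fraction hypergeometric**: the overlap of the focal set with the
  top 10% of ranked genes, upper-tail, with the universe equal to all
  scored genes (the chip universe is not available to the package, and
  using scored genes keeps the test self-contained). Score ties at the
  decile cut are broken by lexicographic gene identifier.
* **Label permutation**: `n_perm = 1000` same-size gene sets are redrawn
  uniformly and the mean focal score compared to the null means, with
  add-one smoothing, $p = (\#\{\text{null} \ge \text{obs}\} + 1)/(n+1)$.
  Redrawing gene labels (rather than shuffling expression values within
  genes) preserves the empirical score distribution exactly.

Scores are computed per dataset, not pooled, since the per-sample
densities are dataset-specific.

## Lineage markers

Within each dataset and lineage, stages are compared with an
empirical-Bayes moderated t-statistic. For a two-stage contrast with
per-gene pooled variance $s_g^2$ on $d_g$ degrees of freedom, the
posterior variance is

$$\tilde s^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},
\qquad \tilde t = \frac{\hat\beta}{\tilde s \sqrt{1/n_1 + 1/n_2}},$$

on $d_0 + d_g$ degrees of freedom. The prior $(d_0, s_0^2)$ is estimated
by the standard moment-matching on $\log s_g^2$ (digamma/trigamma
inversion; the trigamma inverse is a Newton iteration started at
$0.5 + 1/y$, converged to $10^{-10}$ relative). $d_0 = 0$ recovers the
classical pooled t-test and $d_0 = \infty$ a constant-variance
statistic; both limits are verified in the tests, and the whole
machinery is cross-checked against an independent empirical-Bayes
implementation (limma) on a shared fixture.

With three stages, both consecutive contrasts (early vs intermediate,
intermediate vs terminal) are run and a gene is significant for the
lineage if either contrast passes Benjamini–Hochberg at 5% — the weakest
assumption that still encodes "differences between the three stages";
an F-test across stages would be the main alternative but reports no
direction. Two-stage datasets use on/off calling instead: a gene is
"on" in a stage iff **all** its replicates there exceed the threshold
(conservative; the all-replicates rule was an open point), and is a
marker iff on in exactly one stage. The default threshold is the
matrix-wide median log-expression, a scale-free choice, and is
configurable.

A gene is **confirmed** for a lineage iff it is significant there in at
least two datasets, and **exclusive** if it is confirmed for exactly one
lineage; exclusive markers are what downstream stages consume. Genes
following the global class patterns are differentially expressed across
stages in *every* lineage, so exclusivity — not significance alone — is
what isolates lineage identity.

## miRNA enrichment and ORA

For each miRNA, two upper-tail hypergeometric families are tested and
BH-adjusted separately across miRNAs: its target genes against the
marker set (universe: genes shared by the expression matrix and the
catalog, a declared choice since no chip universe is available), and the
TFs linked to it (regulating or regulated) against the marker TFs
(universe: the catalog's TF census). A miRNA is selected when either
family's adjusted p-value is at most 0.001. The two-family union mirrors
the idea that a miRNA is implicated either through its targets or
through its regulators; the exact formulation of the regulator-TF test
is a declared package choice, kept behind the `tf_test` flag.
`fisher_ora()` provides the generic category version: one-sided Fisher
exact tests for categories with at least 2 query genes, at level 0.05.

## Networks, hubs, motifs

The lineage network is the catalog subgraph induced on the exclusive
markers plus selected miRNAs, keeping edges whose evidence
(experimental/predicted) passes the filter; isolated nodes are dropped.
Degree centrality counts incident links in both directions over all
(deduplicated) edge types. TFs/genes and miRNAs are ranked separately
and the top `ceiling(0.10 × class size)` reported, ties at the cut
broken by higher degree then lexicographic identifier.

Three-node motifs are enumerated by their edge patterns — TF-FFL
(TF→miRNA, TF→target, miRNA→target), miRNA-FFL (miRNA→TF, miRNA→target,
TF→target) and composite-FFL (mutual TF↔miRNA regulation plus both
regulator→target edges) — each triple reported once per satisfied type.
Significance is empirical: `N_r = 100` degree-preserving randomizations,
$p = N_h/N_r$ where $N_h$ counts randomized networks with at least the
observed count of the type. $p$ can be exactly 0, so the
add-one-smoothed value is always reported alongside. Significance is
assessed at the type level (p < 0.05) and instances inherit their
type's call.

Randomization rewires each edge type independently by double-edge swaps
(default 100 attempted swaps per edge), which preserves per-node,
per-type in- and out-degrees exactly and therefore respects the
node-class bipartite structure; swaps creating self-loops or duplicate
edges are rejected and degree preservation is asserted on every call.
Two numerical caveats discovered while calibrating the test and worth
knowing about: motif counts are integers, so count ties between the
observed network and randomizations make $p = N_h/N_r$ conservative on
small dense networks; and on *very* small networks (a handful of TFs and
miRNAs) the swap space is so constrained that the null cannot
discriminate at all. The calibration test therefore uses a typed network
of 15 TFs, 15 miRNAs and 30 genes with 50/90/90 edges, large enough that
counts spread and ties are rare.

## GO semantic validation

Gene-level semantic similarity uses best-match averaging over term
pairs. The default Wang measure scores a term pair by summed
shared-ancestor contributions with per-edge factors 0.8 (is_a) and 0.6
(part_of; excluded by default); Resnik-BMA uses max-normalized
information content of the most informative common ancestor, with IC
computed from annotation frequencies propagated over the DAG. Wang is
the default because it needs no annotation corpus beyond the input and
satisfies similarity 1 on identical annotation sets; with Resnik's
max-IC normalization, self-similarity equals $IC(t)/IC_{max}$ and only
reaches 1 for maximally specific terms — a known property of that
measure, so the identity invariant is asserted for Wang. Unannotated
genes are dropped (not scored 0), which would otherwise deflate observed
and null distributions asymmetrically. OBO (is_a, optional part_of) and
GAF 2.x readers are included; annotations default to the
biological-process aspect.

The functional-homogeneity test compares pairwise similarities among a
motif's co-regulated genes (the union of targets of its TF and miRNA,
pairwise) with 100 same-size random draws from all annotated genes, pair
scores pooled, via a one-sided two-sample Kolmogorov–Smirnov test of
whether observed scores are stochastically larger. One statistical
subtlety is documented rather than hidden: pair scores within a draw
share genes and are positively dependent, so the analytic KS p-value —
which assumes independent observations — is anti-conservative under the
null. The package therefore reports, alongside the analytic `ks_p`, an
`empirical_p`: the add-one-smoothed rank of the observed KS statistic
among the null draws' own KS statistics, which is calibrated by
exchangeability. Calibration tests assert uniformity of `empirical_p`;
planted-homogeneity detection is asserted for the analytic `ks_p`.

## The synthetic-data generator

The generator emulates the statistical structure of a multi-dataset
hematopoiesis microarray compendium; its defaults are the study
conditions of the test suite:

* two lineages of 12 cell types each (4 per stage: early, intermediate,
  terminal), profiled in three datasets — one two-stage (early +
  terminal, analysed by on/off calling) and two three-stage — with 2
  replicates per cell type, plus ESC control samples;
* 1000 background genes in the three classes with proportions
  0.5/0.25/0.25 and piecewise-linear log2 stage profiles
  (class 1: 10→8→6→4; class 2: 5→7→10→6; class 3: 4→5→7→10), i.i.d.
  Gaussian noise with sd 0.5 — magnitudes typical of log2 microarray
  intensities; no effect-size or noise values were given to emulate, so
  these are config parameters, not claims;
* 25 planted markers per lineage: flat at baseline 5 everywhere except
  their own lineage, where stage means ramp by `marker_effect = 1.0`
  (= 2 × noise sd) per stage step — a deliberately modest effect that
  exercises the moderated-t power envelope;
* gene sets sampled with class weights (imprinted 0.70/0.15/0.15,
  pluripotent 0.80/0.10/0.10, hematopoietic 0.10/0.20/0.70), so the
  imprinted set genuinely leans towards the ESC-high class;
* an interaction catalog of 40 TFs, 20 miRNAs and all expression genes
  with 60/300/300/40 random edges per type, plus planted TF-FFLs whose
  three edges are always present. In the pipeline, 8 markers per lineage
  double as TFs, 6 miRNAs per lineage target 6 of its markers each, and
  16 FFLs per lineage are planted among those nodes. These counts were
  fixed by power reasoning: the miRNA target sets must overlap the
  markers enough for hypergeometric enrichment at adjusted 0.001 over a
  1000-gene universe, yet stay sparse enough within the induced network
  (roughly a quarter of the marker pool) that degree-preserving
  randomization can actually dilute the planted alignment;
* a toy is_a ontology (random DAG, 50 terms) in which each lineage's
  marker set shares one dedicated deep term, planting detectable
  functional homogeneity.

What the generator deliberately does **not** emulate: probe-level array
artifacts and normalization (inputs are assumed normalized,
log-scale), miRNA expression values (miRNAs appear only as catalog
nodes), correlated noise or batch structure, dataset-specific platform
effects, and the breadth of real regulatory databases. Passing tests
therefore demonstrate that the statistical machinery is correct and
calibrated under its stated model — not that the biological conclusions
of any particular real-data analysis are reproduced.

## Problem sizes used by the test suite

Oracle-equivalence checks run exact brute-force reimplementations
(triple scans, combinatorial enumeration, double loops, hand-evaluated
recursions) on 8–50 random instances of up to 60 nodes, universes up to
N = 12, and vectors up to n = 1000. Calibration checks use 200
replicates (motif p-values on the 15/15/30 fixture with 100
randomizations each; permutation and Mann–Whitney p with 199
permutations; KS empirical p with 40 draws), planted-recovery checks 40
seeds (FFLs) and 50 simulations (markers at effect 2 × noise sd), and
the determinism check runs the full default pipeline twice. These sizes
keep each property at the scale where its exact oracle is feasible while
leaving the statistics enough replicates to be binding.

## Known limitations

* The randomization null is per edge type; cross-type degree
  correlations are preserved only through the fixed node set.
* The hypergeometric universes are package choices (scored genes;
  matrix ∩ catalog genes); with a real chip annotation the universe
  should be supplied explicitly.
* On/off calling has no error control; it is a thresholding device for
  designs where only two stages exist.
* The analytic KS p-value for functional homogeneity inherits the
  dependence problem described above; prefer `empirical_p` when the
  decision matters.
* Wang similarity treats all is_a edges identically (factor 0.8); no
  term-specificity weighting beyond the DAG topology is attempted.
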