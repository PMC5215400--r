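# linmotif

Lineage-specific TF–miRNA co-regulatory networks and feed-forward-loop
(FFL) motifs, with every statistical step testable on synthetic data.

## The problem

During hematopoietic differentiation, cells descend from stem cells
through progenitor stages to terminally differentiated blood cells, and
the hand-off is steered jointly by transcription factors (TFs) and
microRNAs (miRNAs). A recurring question is whether particular gene
classes — for instance imprinted genes, which are expressed from only one
parental allele — track the expression programs of pluripotency or of
blood development, and which TF–miRNA circuits regulate the genes that
mark each lineage. `linmotif` implements the full computational chain
for this kind of study, for analysts working with normalized expression
matrices, gene-set files and regulatory interaction catalogs:

1. **Expression classes** — genes are grouped into three canonical
   patterns along ESC → progenitor → differentiated samples by
   average-linkage hierarchical clustering of standardized cell-type mean
   profiles (`assign_classes()`).
2. **SimScore** — a per-gene similarity to a reference gene set:

   `SimScore(g) = Σ_s φ(x_{g,s}; μ_s, σ_s) · x_{g,s}`

   where (μ_s, σ_s) is the maximum-likelihood Gaussian fitted to the
   reference set's expression in sample *s*. Significance by one-sided
   Mann–Whitney U, a top-10% hypergeometric overlap test, and a
   1000-draw label-permutation test (`simscore_tests()`).
3. **Lineage markers** — empirical-Bayes moderated t-statistics
   (`t̃ = effect / (s̃ √(1/n₁+1/n₂))` with
   `s̃² = (d₀s₀² + d_g s_g²)/(d₀+d_g)`) across consecutive developmental
   stages, Benjamini–Hochberg control at 5%, on/off thresholding for
   two-stage designs, and a ≥2-dataset consensus rule
   (`call_markers()`, `consensus_markers()`).
4. **miRNA enrichment** — upper-tail hypergeometric tests of each
   miRNA's target genes and regulator TFs within the marker set, BH
   cutoff 0.001 (`enrich_mirnas()`); a generic Fisher-exact ORA is also
   provided (`fisher_ora()`).
5. **Networks and motifs** — induced TF–miRNA regulatory networks with
   top-10% degree-centrality hubs (`build_network()`, `degree_hubs()`);
   enumeration of 3-node TF-FFL / miRNA-FFL / composite-FFL motifs and
   empirical significance `p = N_h / N_r` from `N_r = 100`
   degree-preserving double-edge-swap randomizations
   (`motif_significance()`).
6. **Functional validation** — GO semantic similarity (Wang or
   Resnik best-match-average) of co-regulated gene pairs against a
   100-draw resampled null with a one-sided Kolmogorov–Smirnov decision
   (`functional_homogeneity_test()`).

A first-class synthetic-data module (`simulate_expression()`,
`simulate_catalog()`, `simulate_ontology()`) generates all inputs with
known ground truth — planted expression classes, planted lineage
markers, planted FFLs, planted functional homogeneity — so the whole
chain runs and is verified without any external download.

## Worked example

```r
library(linmotif)

cfg <- simulation_config(rng_seed = 1)
sim <- simulate_expression(cfg)
ref <- sim$gene_sets$gene[sim$gene_sets$set == "pluripotent"]
foc <- sim$gene_sets$gene[sim$gene_sets$set == "imprinted"]
samples <- sim$annotations$sample[sim$annotations$dataset == "DS2"]
sub <- dplyr::select(sim$expression, dplyr::all_of(c("gene", samples)))
dens <- fit_reference_density(sub, ref)
simscore_tests(simscore(sub, dens), foc, n_perm = 1000, seed = 1)
#> SimScore result: 1050 genes, 30 focal, top fraction 0.10
#> # A tibble: 4 × 3
#>   test              statistic         p
#>   <chr>                 <dbl>     <dbl>
#> 1 mannwhitney            NA    0.00535
#> 2 mannwhitney_exact      NA   NA
#> 3 hypergeometric          3    0.592
#> 4 permutation            80.8  0.000999
```

The simulated imprinted set leans towards the ESC-high class, so its
mean SimScore against the pluripotent reference beats 999 of 1000
size-matched random gene sets (permutation p ≈ 0.001) and the
Mann–Whitney test agrees (p ≈ 0.005); the top-decile overlap (3 of 30)
is unremarkable here.

```r
cs <- simulate_catalog(simulation_config(
  n_planted_ffls = 20,
  edges_per_type = c("TF->miRNA" = 20, "TF->gene" = 60,
                     "miRNA->gene" = 60, "miRNA->TF" = 10),
  rng_seed = 1))
motif_significance(cs$catalog, n_rand = 100, swaps_per_edge = 20, seed = 1)
#> Motif significance over 100 degree-preserving randomizations:
#> # A tibble: 3 × 7
#>   motif_type    observed   n_h   n_r     p p_smoothed significant
#>   <chr>            <int> <int> <dbl> <dbl>      <dbl> <lgl>
#> 1 TF-FFL              20     0   100     0    0.00990 TRUE
#> 2 miRNA-FFL            0   100   100     1    1       FALSE
#> 3 composite-FFL        0   100   100     1    1       FALSE
```

All 20 planted TF-FFLs are recovered, and no degree-preserving
randomization of the sparse background reproduces that count
(p = 0/100; the add-one-smoothed value 0.0099 is reported alongside).

`run_pipeline(pipeline_config(out_dir, seed))` chains all stages —
simulation, classes, SimScore, markers, enrichment, networks, motifs,
GO validation — writes TSV/GMT/JSON/SIF/GraphML outputs and an MD5
run manifest, and is bit-reproducible for a fixed seed.

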