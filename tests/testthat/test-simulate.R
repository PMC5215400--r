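test_that("simulation is bit-identical under a fixed seed", {
  cfg <- simulation_config(n_genes = 120, rng_seed = 42)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$gene_sets, b$gene_sets)
  expect_identical(a$ground_truth, b$ground_truth)
  ca <- simulate_catalog(cfg)
  cb <- simulate_catalog(cfg)
  expect_identical(ca$catalog, cb$catalog)
  expect_identical(ca$ground_truth, cb$ground_truth)
})

test_that("zero-noise matrices reproduce the configured class means exactly", {
  cfg <- simulation_config(n_genes = 60, noise_sd = 0,
                           n_planted_markers_per_lineage = 2, rng_seed = 3)
  sim <- simulate_expression(cfg)
  m <- as.matrix(sim$expression[, -1])
  rownames(m) <- sim$expression$gene
  truth <- sim$ground_truth$class_of_gene
  profiles <- cfg$class_mean_profiles
  ann <- sim$annotations
  for (g in sample(truth$gene, 10)) {
    cl <- truth$class[truth$gene == g]
    expected <- profiles[cl, match(ann$stage, colnames(profiles))]
    expect_equal(unname(m[g, ann$sample]), unname(expected))
  }
  # class-1 stage means strictly decrease from ESC to terminal
  g1 <- truth$gene[truth$class == 1][1]
  stage_means <- tapply(m[g1, ann$sample], ann$stage, mean)
  expect_true(all(diff(stage_means[c("ESC", "early", "intermediate",
                                     "terminal")]) < 0))
  # planted markers sit at baseline outside their lineage and ramp inside
  mk <- sim$ground_truth$planted_markers[1, ]
  other <- ann$sample[!is.na(ann$lineage) & ann$lineage != mk$lineage]
  expect_true(all(m[mk$gene, other] == cfg$marker_baseline))
  own_term <- ann$sample[!is.na(ann$lineage) & ann$lineage == mk$lineage &
                           ann$stage == "terminal"]
  expect_true(all(m[mk$gene, own_term] ==
                    cfg$marker_baseline + 2 * cfg$marker_effect))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_genes = 0), "n_genes")
  expect_error(simulation_config(class_proportions = c(0.5, 0.3, 0.3)),
               "summing to 1")
  expect_error(simulation_config(marker_effect = 0), "marker_effect")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  cfg <- simulation_config(n_planted_ffls = 10)
  expect_error(
    simulate_catalog(cfg, genes = "g1", tfs = "t1", mirnas = "m1"),
    "planted FFLs")
})

test_that("hierarchical clustering recovers the planted classes without noise", {
  cfg <- simulation_config(n_genes = 300,
                           class_proportions = c(0.5, 0.25, 0.25),
                           noise_sd = 0, n_planted_markers_per_lineage = 1,
                           rng_seed = 11)
  sim <- simulate_expression(cfg)
  truth <- sim$ground_truth$class_of_gene
  cl <- assign_classes(sim$expression, sim$annotations, k = 3)
  merged <- merge(cl, truth, by = "gene")
  expect_equal(rand_index(merged$class.x, merged$class.y), 1.0)
  # deterministic relabeling reproduces the ground-truth labels themselves
  expect_true(all(merged$class.x == merged$class.y))
})

test_that("planted FFL edges are always present and the catalog is clean", {
  for (seed in c(1, 5, 9)) {
    cfg <- simulation_config(n_planted_ffls = 15, rng_seed = seed)
    cs <- simulate_catalog(cfg)
    edges <- cs$catalog
    expect_false(any(edges$source == edges$target))
    expect_false(any(duplicated(edges[, c("source", "target", "type")])))
    pl <- cs$ground_truth$planted_ffls
    expect_equal(nrow(pl), 15)
    has <- function(s, t, ty)
      any(edges$source == s & edges$target == t & edges$type == ty)
    for (i in seq_len(nrow(pl))) {
      expect_true(has(pl$tf[i], pl$mirna[i], "TF->miRNA"))
      expect_true(has(pl$tf[i], pl$target[i], "TF->gene"))
      expect_true(has(pl$mirna[i], pl$target[i], "miRNA->gene"))
    }
  }
})

test_that("a planted-only catalog yields exactly the planted TF-FFLs", {
  cfg <- simulation_config(
    n_planted_ffls = 5,
    edges_per_type = c("TF->miRNA" = 0, "TF->gene" = 0,
                       "miRNA->gene" = 0, "miRNA->TF" = 0),
    rng_seed = 21)
  cs <- simulate_catalog(cfg)
  found <- enumerate_motifs(cs$catalog)
  tf_ffl <- found[found$motif_type == "TF-FFL", ]
  pl <- cs$ground_truth$planted_ffls
  expect_equal(nrow(tf_ffl), nrow(pl))
  expect_equal(
    tf_ffl[order(tf_ffl$tf, tf_ffl$mirna, tf_ffl$target),
           c("tf", "mirna", "target")],
    pl[order(pl$tf, pl$mirna, pl$target), ],
    ignore_attr = TRUE)
  expect_equal(nrow(found[found$motif_type == "composite-FFL", ]), 0)
})

test_that("simulated ontologies are valid DAGs with planted annotations", {
  genes <- sprintf("g%02d", 1:30)
  onto <- simulate_ontology(genes, n_terms = 20,
                            planted_sets = list(core = genes[1:5]),
                            seed = 2)
  expect_s3_class(onto, "ontology_graph")
  planted_term <- onto$terms$id[startsWith(onto$terms$id, "GO:P")]
  ann <- onto$annotations
  expect_true(all(genes[1:5] %in% ann$gene[ann$term == planted_term]))
  # same seed, same ontology
  onto2 <- simulate_ontology(genes, n_terms = 20,
                             planted_sets = list(core = genes[1:5]),
                             seed = 2)
  expect_identical(onto$edges, onto2$edges)
})
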