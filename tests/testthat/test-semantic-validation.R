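# Five-term toy DAG: root <- A <- B and root <- C (is_a only).
toy_dag <- function() {
  ontology(
    terms = tibble::tibble(id = c("root", "A", "B", "C"),
                           name = c("root", "a", "b", "c"),
                           namespace = "biological_process"),
    edges = tibble::tibble(child = c("A", "B", "C"),
                           parent = c("root", "A", "root"),
                           relation = "is_a"),
    annotations = tibble::tibble(gene = c("g1", "g2", "g3"),
                                 term = c("B", "C", "B")))
}

test_that("Wang similarity matches direct evaluation of its definition", {
  onto <- toy_dag()
  got <- pairwise_semantic_similarity(c("g1", "g2"), onto)
  # hand computation: S_B = {B:1, A:0.8, root:0.64}, S_C = {C:1, root:0.8}
  # shared mass 0.64 + 0.8 over totals 2.44 + 1.8
  expect_equal(got$similarity, 1.44 / 4.24, tolerance = 1e-12)
  parent_list <- split(onto$edges$parent, onto$edges$child)
  expect_equal(got$similarity, oracle_wang_sim("B", "C", parent_list),
               tolerance = 1e-12)
  # identical annotation sets score exactly 1
  ident <- pairwise_semantic_similarity(c("g1", "g3"), onto)
  expect_equal(ident$similarity, 1.0)
  # root-only vs leaf annotation: strictly inside (0, 1)
  onto2 <- attach_annotations(onto, tibble::tibble(
    gene = c("ga", "gb"), term = c("root", "B")))
  mid <- pairwise_semantic_similarity(c("ga", "gb"), onto2)
  expect_gt(mid$similarity, 0)
  expect_lt(mid$similarity, 1)
})

test_that("similarity is symmetric and bounded for both measures", {
  genes <- sprintf("g%02d", 1:12)
  onto <- simulate_ontology(genes, n_terms = 25, seed = 5)
  for (measure in c("Wang", "Resnik")) {
    ps <- pairwise_semantic_similarity(genes[1:6], onto, measure = measure)
    expect_true(all(ps$similarity >= 0 & ps$similarity <= 1))
    # symmetry: reversing the input order reproduces every pair score
    ps2 <- pairwise_semantic_similarity(rev(genes[1:6]), onto,
                                        measure = measure)
    expect_equal(dplyr::arrange(ps, gene1, gene2),
                 dplyr::arrange(ps2, gene1, gene2))
  }
  # unannotated genes are dropped, not scored
  expect_message(
    pairwise_semantic_similarity(c(genes[1:3], "ghost"), onto),
    "unannotated")
  expect_error(pairwise_semantic_similarity(c("ghost1", "ghost2"), onto),
               "at least 2")
})

test_that("OBO and GAF readers parse the standard dialects", {
  obo <- c("format-version: 1.2", "",
           "[Term]", "id: GO:0000001", "name: root",
           "namespace: biological_process", "",
           "[Term]", "id: GO:0000002", "name: mid",
           "namespace: biological_process",
           "is_a: GO:0000001 ! root",
           "relationship: part_of GO:0000001 ! root", "",
           "[Term]", "id: GO:0000003", "name: gone",
           "namespace: biological_process", "is_obsolete: true",
           "[Typedef]", "id: part_of")
  op <- withr::local_tempfile(fileext = ".obo")
  writeLines(obo, op)
  onto <- read_obo(op)
  expect_equal(sort(onto$terms$id), c("GO:0000001", "GO:0000002"))
  expect_equal(onto$edges$relation, "is_a")
  onto_po <- read_obo(op, include_part_of = TRUE)
  expect_setequal(onto_po$edges$relation, c("is_a", "part_of"))

  gaf <- c("!gaf-version: 2.1",
           paste("MGI", "MGI:1", "Axl", "", "GO:0000002", "PMID:1", "IDA",
                 "", "P", "", "", "protein", "taxon:10090", "20160101",
                 "MGI", sep = "\t"),
           paste("MGI", "MGI:2", "Ndn", "", "GO:0000002", "PMID:1", "IEA",
                 "", "C", "", "", "protein", "taxon:10090", "20160101",
                 "MGI", sep = "\t"))
  gp <- withr::local_tempfile(fileext = ".gaf")
  writeLines(gaf, gp)
  ann <- read_gaf(gp)
  expect_equal(ann$gene, "Axl")   # aspect filter keeps P only
  ann_all <- read_gaf(gp, aspects = c("P", "C"))
  expect_equal(sort(ann_all$gene), c("Axl", "Ndn"))
  with_ann <- attach_annotations(onto, ann)
  expect_equal(nrow(with_ann$annotations), 1)
})

test_that("cyclic ontologies and dangling annotations are rejected", {
  terms <- tibble::tibble(id = c("a", "b"), name = c("a", "b"),
                          namespace = "biological_process")
  cyc <- tibble::tibble(child = c("a", "b"), parent = c("b", "a"),
                        relation = "is_a")
  expect_error(ontology(terms, cyc), "cycle")
  ok_edges <- tibble::tibble(child = "b", parent = "a", relation = "is_a")
  expect_error(ontology(terms, ok_edges,
                        annotations = tibble::tibble(gene = "g",
                                                     term = "zz")),
               "unknown terms")
})

test_that("planted functional homogeneity is detected, degenerate sets handled", {
  genes <- sprintf("g%03d", 1:80)
  onto <- simulate_ontology(genes, n_terms = 30,
                            planted_sets = list(core = genes[1:10]),
                            seed = 44)
  rep <- suppressMessages(
    functional_homogeneity_test(genes[1:10], onto, n_perm = 60, seed = 45))
  expect_lt(rep$ks_p, 0.05)
  expect_lt(rep$empirical_p, 0.05)
  expect_s3_class(autoplot(rep), "ggplot")
  gl <- glance(rep)
  expect_gt(gl$mean_similarity, gl$null_mean)
  # two genes with identical annotations: observed degenerate at 1, and
  # the KS statistic equals the null CDF just below 1
  onto2 <- attach_annotations(
    onto, dplyr::bind_rows(onto$annotations,
                           tibble::tibble(gene = c("tw1", "tw2"),
                                          term = onto$terms$id[5])))
  rep2 <- suppressMessages(
    functional_homogeneity_test(c("tw1", "tw2"), onto2, n_perm = 40,
                                seed = 46))
  expect_equal(nrow(rep2$pair_scores), 1)
  expect_equal(rep2$pair_scores$similarity, 1.0)
  expect_equal(rep2$ks_statistic, mean(rep2$null_scores < 1),
               tolerance = 1e-12)
  expect_error(functional_homogeneity_test(genes[1:60], onto),
               "too small")
})

test_that("cross-set similarity separates planted sets from background", {
  genes <- sprintf("g%03d", 1:60)
  onto <- simulate_ontology(genes, n_terms = 25,
                            planted_sets = list(ab = genes[1:14]),
                            seed = 50)
  res <- geneset_class_similarity(genes[1:7], genes[8:14], onto,
                                  n_background = 40, seed = 51)
  expect_gt(res$observed_mean, mean(res$background_means))
  expect_lt(res$p, 0.05)
  # identical-annotation sets give mean similarity 1
  onto3 <- ontology(
    terms = tibble::tibble(id = c("r", "x"), name = c("r", "x"),
                           namespace = "biological_process"),
    edges = tibble::tibble(child = "x", parent = "r", relation = "is_a"),
    annotations = tibble::tibble(gene = c("p", "q", "s"), term = "x"))
  res3 <- geneset_class_similarity(c("p", "q"), c("q", "s"), onto3,
                                   n_background = 5, seed = 52)
  expect_equal(res3$observed_mean, 1.0)
})
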