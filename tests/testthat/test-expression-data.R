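test_that("expression TSV round-trip preserves values and metadata", {
  cfg <- simulation_config(n_genes = 40, rng_seed = 4)
  sim <- simulate_expression(cfg)
  mp <- withr::local_tempfile(fileext = ".tsv")
  ap <- withr::local_tempfile(fileext = ".tsv")
  write_expression(sim, mp, ap)
  back <- read_expression(mp, ap)
  expect_equal(back$expression$gene, sim$expression$gene)
  expect_equal(as.matrix(back$expression[, -1]),
               as.matrix(sim$expression[, -1]), tolerance = 1e-12)
})

test_that("malformed expression inputs fail loudly", {
  fx <- small_expression()
  mp <- withr::local_tempfile(fileext = ".tsv")
  ap <- withr::local_tempfile(fileext = ".tsv")
  dup <- rbind(fx$expression, fx$expression[1, ])
  readr::write_tsv(dup, mp)
  readr::write_tsv(fx$annotations, ap)
  expect_error(read_expression(mp, ap), "G001")
  # unannotated sample is a hard error
  readr::write_tsv(fx$expression, mp)
  readr::write_tsv(fx$annotations[-1, ], ap)
  expect_error(read_expression(mp, ap), "without annotation")
  # genes with missing values are dropped with a warning
  holey <- fx$expression
  holey[2, 3] <- NA
  readr::write_tsv(holey, mp)
  readr::write_tsv(fx$annotations, ap)
  expect_warning(res <- read_expression(mp, ap), "Dropping")
  expect_equal(nrow(res$expression), nrow(fx$expression) - 1)
})

test_that("GMT, catalog and lineage-plan files round-trip", {
  gs <- tibble::tibble(set = rep(c("alpha", "beta"), c(3, 2)),
                       gene = c("g1", "g2", "g3", "g2", "g9"))
  gp <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, gp)
  back <- read_gmt(gp)
  expect_equal(sort(back$gene[back$set == "alpha"]), c("g1", "g2", "g3"))
  expect_equal(nrow(back), 5)

  cfg <- simulation_config(rng_seed = 8)
  cs <- simulate_catalog(cfg)
  cp <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(cs$catalog, cp)
  expect_equal(read_catalog(cp), cs$catalog)
  bad <- cs$catalog
  bad$type[1] <- "gene->TF"
  readr::write_tsv(bad, cp)
  expect_error(read_catalog(cp), "Unknown edge types")

  plan <- default_lineage_plan()
  pp <- withr::local_tempfile(fileext = ".json")
  write_lineage_plan(plan, pp)
  back_plan <- read_lineage_plan(pp)
  expect_equal(back_plan$cells, plan$cells)
  expect_equal(back_plan$datasets, plan$datasets)
})

test_that("network export writes SIF and round-trips through GraphML", {
  catalog <- tibble::tibble(
    source = c("m1", "TF1", "TF1"),
    target = c("A", "A", "m1"),
    type = c("miRNA->gene", "TF->gene", "TF->miRNA"),
    evidence = "experimental")
  net <- suppressMessages(build_network(c("A", "TF1"), "m1", catalog))
  sp <- withr::local_tempfile(fileext = ".sif")
  write_network_sif(net, sp)
  expect_equal(readLines(sp),
               c("TF1\tTF_gene\tA", "TF1\tTF_miRNA\tm1", "m1\tmiRNA_gene\tA"))
  gp <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, gp)
  back <- read_network_graphml(gp)
  expect_equal(dplyr::arrange(back$edges, source, target),
               dplyr::arrange(net$edges, source, target))
  expect_equal(dplyr::arrange(back$nodes, node), net$nodes)
})

test_that("class assignment is order-invariant and handles edge cases", {
  cfg <- simulation_config(n_genes = 90, noise_sd = 0.3, rng_seed = 13,
                           n_planted_markers_per_lineage = 1)
  sim <- simulate_expression(cfg)
  cl <- assign_classes(sim$expression, sim$annotations, k = 3)
  shuffled <- sim$expression[sample(nrow(sim$expression)), ]
  cl2 <- assign_classes(shuffled, sim$annotations, k = 3)
  expect_equal(cl, cl2[match(cl$gene, cl2$gene), ], ignore_attr = TRUE)
  # permuting samples within a cell type changes nothing
  ann <- sim$annotations
  perm <- unlist(lapply(split(ann$sample, ann$cell_type), sample))
  permuted <- sim$expression[, c("gene", perm)]
  cl3 <- assign_classes(permuted, sim$annotations, k = 3)
  expect_equal(cl, cl3)
  # k = 1 puts everything in class 1
  cl1 <- assign_classes(sim$expression, sim$annotations, k = 1)
  expect_true(all(cl1$class == 1L))
  # identical profiles share a label
  fx <- small_expression(n_genes = 6)
  fx$expression[2, -1] <- fx$expression[1, -1]
  cl4 <- assign_classes(fx$expression, fx$annotations, k = 3)
  expect_equal(cl4$class[cl4$gene == fx$expression$gene[1]],
               cl4$class[cl4$gene == fx$expression$gene[2]])
  expect_error(assign_classes(fx$expression, fx$annotations, k = 99),
               "between 1")
})
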