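#' Pipeline configuration
#'
#' Bundles the synthetic-data configuration, all stage parameters (at their
#' conventional defaults: BH 5% for markers, adjusted 0.001 for miRNA
#' enrichment, top fraction 10%, 1000 score permutations, 100 network
#' randomizations, 100 ontology permutations) and stage toggles.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; every stage derives its own stream from it.
#' @param sim_config A [simulation_config()].
#' @param alpha_markers BH level for marker calling.
#' @param alpha_mirna Adjusted-p cutoff for miRNA enrichment.
#' @param top_fraction Top fraction for the SimScore hypergeometric test.
#' @param n_perm_simscore SimScore permutations.
#' @param n_rand Network randomizations N_r.
#' @param swaps_per_edge Attempted swaps per edge per randomization.
#' @param n_perm_go Ontology-null permutations.
#' @param alpha_motif Motif-type significance threshold.
#' @param stages Named logical vector toggling stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("linmotif_run_"),
                            seed = 1L,
                            sim_config = simulation_config(rng_seed = seed),
                            alpha_markers = 0.05,
                            alpha_mirna = 0.001,
                            top_fraction = 0.10,
                            n_perm_simscore = 1000,
                            n_rand = 100,
                            swaps_per_edge = 100,
                            n_perm_go = 100,
                            alpha_motif = 0.05,
                            stages = c(classes = TRUE, simscore = TRUE,
                                       markers = TRUE, enrichment = TRUE,
                                       network = TRUE, motifs = TRUE,
                                       validation = TRUE)) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 sim_config = sim_config, alpha_markers = alpha_markers,
                 alpha_mirna = alpha_mirna, top_fraction = top_fraction,
                 n_perm_simscore = n_perm_simscore, n_rand = n_rand,
                 swaps_per_edge = swaps_per_edge, n_perm_go = n_perm_go,
                 alpha_motif = alpha_motif, stages = stages),
            class = "pipeline_config")
}

# Simulate the full linked input bundle for a pipeline run: expression with
# planted markers, a catalog whose planted miRNAs target those markers and
# whose planted FFLs live among marker TFs / planted miRNAs / marker
# genes, and a toy ontology with planted functional homogeneity per
# lineage marker set.
simulate_pipeline_inputs <- function(sim_config) {
  sim <- simulate_expression(sim_config)
  truth <- sim$ground_truth
  genes <- sim$expression$gene
  lineages <- unique(truth$planted_markers$lineage)

  with_seed(derive_seed(sim_config$rng_seed, 11L), {
    background <- setdiff(genes, truth$planted_markers$gene)
    n_tfs <- sim_config$n_tfs
    # a handful of each lineage's markers double as TFs, so FFLs can live
    # entirely inside the induced lineage network
    tfs_per_lineage <- min(8L, sim_config$n_planted_markers_per_lineage)
    marker_tfs <- truth$planted_markers |>
      group_by(.data$lineage) |>
      dplyr::slice_head(n = tfs_per_lineage) |>
      ungroup()
    tfs <- sort(c(marker_tfs$gene,
                  sample(background, max(n_tfs - nrow(marker_tfs), 1))))
    mirnas <- sprintf("mmu-miR-%03d", seq_len(sim_config$n_mirnas))
    # six planted miRNAs per lineage, each targeting a small subset of its
    # markers: enough overlap for hypergeometric enrichment, sparse enough
    # that the randomization null is not saturated
    mirnas_per_lineage <- 6L
    targets_per_mirna <- function(mk) min(6L, length(mk))
    planted_mirnas <- map_dfr(seq_along(lineages), function(i) {
      mk <- truth$planted_markers$gene[truth$planted_markers$lineage ==
                                         lineages[i]]
      map_dfr(seq_len(mirnas_per_lineage), function(j) {
        mi <- mirnas[mirnas_per_lineage * (i - 1) + j]
        tibble(lineage = lineages[i], mirna = mi,
               target = sample(mk, targets_per_mirna(mk)))
      })
    })
    extra_edges <- planted_mirnas |>
      mutate(source = .data$mirna, type = "miRNA->gene",
             evidence = "experimental") |>
      select("source", "target", "type", "evidence")
    # plant FFLs within one lineage each, with targets drawn from the
    # planted miRNA's own target set (so no extra miRNA->gene edges)
    per_lineage <- max(1L, sim_config$n_planted_ffls %/% length(lineages))
    ffl_triples <- map_dfr(lineages, function(ln) {
      pool_tf <- marker_tfs$gene[marker_tfs$lineage == ln]
      cand <- planted_mirnas |>
        filter(.data$lineage == ln) |>
        select("mirna", "target") |>
        tidyr::expand_grid(tf = pool_tf) |>
        filter(.data$tf != .data$target) |>
        select("tf", "mirna", "target")
      cand[sample.int(nrow(cand), min(per_lineage, nrow(cand))), ]
    })
    cat_sim <- simulate_catalog(sim_config, genes = genes, tfs = tfs,
                                mirnas = mirnas, extra_edges = extra_edges,
                                planted_ffls = ffl_triples)
    planted_sets <- split(truth$planted_markers$gene,
                          truth$planted_markers$lineage)
    onto <- simulate_ontology(genes, n_terms = 50,
                              planted_sets = planted_sets,
                              seed = derive_seed(sim_config$rng_seed, 13L))
    list(sim = sim, catalog = cat_sim$catalog, tfs = tfs, mirnas = mirnas,
         planted_mirnas = planted_mirnas,
         planted_ffls = cat_sim$ground_truth$planted_ffls,
         ontology = onto)
  })
}

#' Run the full synthetic analysis pipeline
#'
#' Executes, in dependency order: input simulation, expression-class
#' assignment, SimScore with its three tests (imprinted focal set vs the
#' pluripotent reference, per dataset), lineage marker calling with the
#' cross-dataset consensus rule, miRNA enrichment per lineage, network
#' assembly with degree hubs, FFL motif significance, and GO
#' functional-homogeneity validation. Every stage output is written under
#' `config$out_dir` and hashed (MD5) into a JSON run manifest together
#' with the parameters and seeds; re-running the same config reproduces
#' identical hashes.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory stage results and the
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  st <- config$stages
  results <- list()
  files <- character(0)
  log <- list()

  fail <- function(stage, msg) abort(sprintf("Stage '%s' failed: %s",
                                             stage, msg))

  # --- simulate ------------------------------------------------------
  inputs <- simulate_pipeline_inputs(config$sim_config)
  sim <- inputs$sim
  write_expression(sim, out("expression.tsv"), out("annotations.tsv"))
  write_gmt(sim$gene_sets, out("gene_sets.gmt"))
  write_catalog(inputs$catalog, out("catalog.tsv"))
  write_lineage_plan(config$sim_config$lineage_plan, out("lineage_plan.json"))
  jsonlite::write_json(
    list(class_of_gene = sim$ground_truth$class_of_gene,
         planted_markers = sim$ground_truth$planted_markers,
         planted_ffls = inputs$planted_ffls),
    out("ground_truth.json"), dataframe = "rows")
  files <- c(files, "expression.tsv", "annotations.tsv", "gene_sets.gmt",
             "catalog.tsv", "lineage_plan.json", "ground_truth.json")
  results$inputs <- inputs
  log$simulate <- list(n_genes = nrow(sim$expression),
                       n_samples = nrow(sim$annotations),
                       n_edges = nrow(inputs$catalog))

  # --- classes -------------------------------------------------------
  if (isTRUE(st[["classes"]])) {
    classes <- assign_classes(sim$expression, sim$annotations, k = 3)
    readr::write_tsv(classes, out("classes.tsv"), progress = FALSE)
    files <- c(files, "classes.tsv")
    results$classes <- classes
    log$classes <- as.list(table(classes$class))
  }

  # --- simscore ------------------------------------------------------
  if (isTRUE(st[["simscore"]])) {
    focal <- sim$gene_sets$gene[sim$gene_sets$set == "imprinted"]
    reference <- sim$gene_sets$gene[sim$gene_sets$set == "pluripotent"]
    datasets <- setdiff(unique(sim$annotations$dataset), character(0))
    simscore_res <- map(setNames(datasets, datasets), function(ds) {
      samples <- sim$annotations$sample[sim$annotations$dataset == ds]
      sub <- sim$expression |> select(all_of(c("gene", samples)))
      dens <- fit_reference_density(sub, reference)
      sc <- simscore(sub, dens)
      simscore_tests(sc, focal, n_perm = config$n_perm_simscore,
                     top_fraction = config$top_fraction,
                     seed = derive_seed(config$seed, 21L))
    })
    summary_tbl <- map_dfr(simscore_res, glance, .id = "dataset")
    readr::write_tsv(map_dfr(simscore_res, tidy, .id = "dataset"),
                     out("simscore.tsv"), progress = FALSE)
    jsonlite::write_json(summary_tbl, out("simscore_tests.json"),
                         dataframe = "rows", digits = NA)
    files <- c(files, "simscore.tsv", "simscore_tests.json")
    results$simscore <- simscore_res
    log$simscore <- list(datasets = length(datasets))
  }

  # --- markers -------------------------------------------------------
  if (isTRUE(st[["markers"]])) {
    calls <- call_markers(sim$expression, sim$annotations,
                          alpha = config$alpha_markers)
    consensus <- consensus_markers(calls)
    readr::write_tsv(calls, out("marker_calls.tsv"), progress = FALSE)
    readr::write_tsv(consensus, out("markers.tsv"), progress = FALSE)
    files <- c(files, "marker_calls.tsv", "markers.tsv")
    results$marker_calls <- calls
    results$markers <- consensus
    log$markers <- list(
      n_consensus = sum(consensus$consensus),
      n_exclusive = sum(consensus$exclusive))
  }

  # --- enrichment ----------------------------------------------------
  if (isTRUE(st[["enrichment"]])) {
    if (is.null(results$markers)) fail("enrichment", "markers stage disabled")
    universe <- intersect(sim$expression$gene,
                          unique(c(inputs$catalog$source,
                                   inputs$catalog$target)))
    enr <- results$markers |>
      filter(.data$exclusive) |>
      group_by(.data$lineage) |>
      summarise(markers = list(.data$gene), .groups = "drop")
    enrichment <- map2(enr$lineage, enr$markers, function(ln, mk) {
      enrich_mirnas(intersect(mk, universe), inputs$catalog, universe,
                    alpha_adj = config$alpha_mirna)
    })
    names(enrichment) <- enr$lineage
    enr_tbl <- map_dfr(enrichment, identity, .id = "lineage")
    readr::write_tsv(enr_tbl, out("mirna_enrichment.tsv"), progress = FALSE)
    files <- c(files, "mirna_enrichment.tsv")
    results$enrichment <- enrichment
    log$enrichment <- list(
      selected = sum(vapply(enrichment, function(e)
        length(attr(e, "selected_mirnas")), numeric(1))))
  }

  # --- network -------------------------------------------------------
  if (isTRUE(st[["network"]])) {
    if (is.null(results$enrichment)) fail("network", "enrichment disabled")
    networks <- imap(results$enrichment, function(e, ln) {
      mk <- results$markers$gene[results$markers$exclusive &
                                   results$markers$lineage == ln]
      build_network(mk, attr(e, "selected_mirnas"), inputs$catalog,
                    lineage = ln)
    })
    hubs <- map(networks, function(net) {
      if (nrow(net$nodes) == 0) return(NULL)
      degree_hubs(net, fraction = 0.10)
    })
    for (ln in names(networks)) {
      if (nrow(networks[[ln]]$edges) == 0) next
      write_network_sif(networks[[ln]], out(sprintf("network_%s.sif", ln)))
      write_network_graphml(networks[[ln]],
                            out(sprintf("network_%s.graphml", ln)))
      files <- c(files, sprintf("network_%s.sif", ln),
                 sprintf("network_%s.graphml", ln))
    }
    hub_tbl <- map_dfr(keep(hubs, Negate(is.null)), as_tibble,
                       .id = "lineage")
    readr::write_tsv(hub_tbl, out("hubs.tsv"), progress = FALSE)
    files <- c(files, "hubs.tsv")
    results$networks <- networks
    results$hubs <- hubs
    log$network <- map(networks, function(n)
      list(nodes = nrow(n$nodes), edges = nrow(n$edges)))
  }

  # --- motifs --------------------------------------------------------
  if (isTRUE(st[["motifs"]])) {
    if (is.null(results$networks)) fail("motifs", "network stage disabled")
    motifs <- imap(results$networks, function(net, ln) {
      if (nrow(net$edges) == 0) return(NULL)
      motif_significance(net, n_rand = config$n_rand,
                         swaps_per_edge = config$swaps_per_edge,
                         seed = derive_seed(config$seed, 31L),
                         alpha = config$alpha_motif)
    })
    motif_tbl <- map_dfr(keep(motifs, Negate(is.null)),
                         function(m) m$summary, .id = "lineage")
    inst_tbl <- map_dfr(keep(motifs, Negate(is.null)),
                        function(m) m$instances, .id = "lineage")
    readr::write_tsv(inst_tbl, out("motif_instances.tsv"), progress = FALSE)
    jsonlite::write_json(motif_tbl, out("motif_significance.json"),
                         dataframe = "rows", digits = NA)
    files <- c(files, "motif_instances.tsv", "motif_significance.json")
    results$motifs <- motifs
    log$motifs <- list(n_significant_types = sum(motif_tbl$significant))
  }

  # --- validation ----------------------------------------------------
  if (isTRUE(st[["validation"]])) {
    if (is.null(results$motifs))
      fail("validation", "motif stage disabled (validation depends on it)")
    validation <- imap(keep(results$motifs, Negate(is.null)),
                       function(m, ln) {
      sig <- m$instances |> filter(.data$significant)
      if (nrow(sig) == 0) return(NULL)
      net <- results$networks[[ln]]
      coreg <- unique(net$edges$target[
        net$edges$type %in% c("TF->gene", "miRNA->gene") &
          (net$edges$source %in% sig$tf | net$edges$source %in% sig$mirna)])
      if (length(coreg) < 2) return(NULL)
      functional_homogeneity_test(coreg, inputs$ontology,
                                  n_perm = config$n_perm_go,
                                  seed = derive_seed(config$seed, 41L))
    })
    val_tbl <- map_dfr(keep(validation, Negate(is.null)), glance,
                       .id = "lineage")
    jsonlite::write_json(val_tbl, out("validation.json"),
                         dataframe = "rows", digits = NA)
    files <- c(files, "validation.json")
    results$validation <- validation
    log$validation <- list(n_lineages_tested =
                             length(keep(validation, Negate(is.null))))
  }

  # --- manifest ------------------------------------------------------
  hashes <- tools::md5sum(file.path(config$out_dir, files))
  names(hashes) <- files
  manifest <- list(
    seed = config$seed,
    parameters = list(alpha_markers = config$alpha_markers,
                      alpha_mirna = config$alpha_mirna,
                      top_fraction = config$top_fraction,
                      n_perm_simscore = config$n_perm_simscore,
                      n_rand = config$n_rand,
                      swaps_per_edge = config$swaps_per_edge,
                      n_perm_go = config$n_perm_go,
                      alpha_motif = config$alpha_motif),
    stages = as.list(st),
    log = log,
    files = as.list(hashes))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
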