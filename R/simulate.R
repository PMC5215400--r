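#' Default multi-dataset lineage plan
#'
#' Builds the lineage plan the simulator uses by default: two lineages
#' (one lymphoid-like, one myeloid-like), each a chain of 12 cell types
#' grouped into the three developmental stages (early progenitors,
#' intermediate progenitors, terminally differentiated cells), profiled in
#' three datasets. Dataset `DS1` carries only the early and terminal stages
#' (the two-stage design analysed by on/off thresholding); `DS2` and `DS3`
#' carry all three stages.
#'
#' @param lineages Character vector of lineage names.
#' @param cell_types_per_stage Number of cell types per stage per lineage.
#' @param replicates Unused here; kept in [simulation_config()].
#' @return A `lineage_plan` object: a list with `cells` (tibble: lineage,
#'   cell_type, order, stage) and `datasets` (tibble: dataset, lineage,
#'   stage) describing which stages each dataset profiles.
#' @export
default_lineage_plan <- function(lineages = c("lymphoid", "myeloid"),
                                 cell_types_per_stage = 4) {
  stages <- c("early", "intermediate", "terminal")
  cells <- map_dfr(lineages, function(ln) {
    n <- 3 * cell_types_per_stage
    tibble(
      lineage = ln,
      cell_type = sprintf("%s_ct%02d", substr(ln, 1, 2), seq_len(n)),
      order = seq_len(n),
      stage = rep(stages, each = cell_types_per_stage)
    )
  })
  datasets <- bind_rows(
    tidyr::expand_grid(dataset = "DS1", lineage = lineages,
                       stage = c("early", "terminal")),
    tidyr::expand_grid(dataset = c("DS2", "DS3"), lineage = lineages,
                       stage = stages)
  )
  structure(list(cells = cells, datasets = datasets), class = "lineage_plan")
}

#' Validate a lineage plan
#' @param plan A `lineage_plan`.
#' @return The plan, invisibly; errors on violation.
#' @export
validate_lineage_plan <- function(plan) {
  stopifnot(inherits(plan, "lineage_plan"))
  cells <- plan$cells
  bad <- cells |> group_by(.data$lineage) |>
    summarise(dup = anyDuplicated(.data$cell_type) > 0,
              nstage = dplyr::n_distinct(.data$stage))
  if (any(bad$dup)) abort("Duplicated cell types within a lineage.")
  if (any(bad$nstage < 2)) abort("Every lineage needs >= 2 distinct stages.")
  invisible(plan)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with validated
#' defaults. The defaults define the study conditions used throughout the
#' package's tests: three expression-pattern classes across
#' ESC/progenitor/differentiated samples, two 12-cell-type lineages in three
#' datasets with two replicates per cell type, Gaussian noise of 0.5 on the
#' log2 scale, and planted lineage markers whose per-stage effect equals
#' twice the noise standard deviation.
#'
#' @param n_genes Number of background (class-patterned) genes.
#' @param n_samples_per_celltype Replicates per cell type per dataset.
#' @param lineage_plan A `lineage_plan`; see [default_lineage_plan()].
#' @param class_proportions Length-3 fractions summing to 1.
#' @param class_mean_profiles 3 x 4 matrix of mean log2 expression, rows =
#'   classes 1..3, columns = ESC/early/intermediate/terminal stage means.
#' @param noise_sd I.i.d. Gaussian noise sd (log2 units); may be 0 for
#'   noise-free checks.
#' @param n_planted_markers_per_lineage Planted lineage-restricted DE genes.
#' @param marker_effect Per-consecutive-stage log2 effect of planted
#'   markers (> 0).
#' @param marker_baseline Baseline log2 expression of markers outside their
#'   lineage.
#' @param geneset_sizes Named counts for the imprinted / pluripotent /
#'   hematopoietic sets.
#' @param geneset_class_weights Named list of length-3 sampling weights over
#'   the classes for each gene set.
#' @param n_tfs,n_mirnas,n_catalog_genes Interaction-catalog node counts.
#' @param edges_per_type Named counts of random edges per edge type.
#' @param n_planted_ffls Number of planted TF-FFL triples.
#' @param rng_seed Integer seed; all outputs are deterministic given it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 1000,
                              n_samples_per_celltype = 2,
                              lineage_plan = default_lineage_plan(),
                              class_proportions = c(0.5, 0.25, 0.25),
                              class_mean_profiles = default_class_profiles(),
                              noise_sd = 0.5,
                              n_planted_markers_per_lineage = 25,
                              marker_effect = 1.0,
                              marker_baseline = 5,
                              geneset_sizes = c(imprinted = 30,
                                                pluripotent = 40,
                                                hematopoietic = 50),
                              geneset_class_weights = list(
                                imprinted = c(0.70, 0.15, 0.15),
                                pluripotent = c(0.80, 0.10, 0.10),
                                hematopoietic = c(0.10, 0.20, 0.70)),
                              n_tfs = 40,
                              n_mirnas = 20,
                              n_catalog_genes = 200,
                              edges_per_type = c("TF->miRNA" = 60,
                                                 "TF->gene" = 300,
                                                 "miRNA->gene" = 300,
                                                 "miRNA->TF" = 40),
                              n_planted_ffls = 32,
                              rng_seed = 1L) {
  assert_count(n_genes, "n_genes")
  assert_count(n_samples_per_celltype, "n_samples_per_celltype")
  validate_lineage_plan(lineage_plan)
  if (length(class_proportions) != 3 ||
      abs(sum(class_proportions) - 1) > 1e-12 || any(class_proportions <= 0))
    abort("`class_proportions` must be 3 positive fractions summing to 1.")
  stopifnot(is.matrix(class_mean_profiles),
            nrow(class_mean_profiles) == 3, ncol(class_mean_profiles) == 4)
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0.")
  assert_count(n_planted_markers_per_lineage, "n_planted_markers_per_lineage",
               min = 0)
  if (marker_effect <= 0) abort("`marker_effect` must be > 0.")
  assert_count(n_tfs, "n_tfs"); assert_count(n_mirnas, "n_mirnas")
  assert_count(n_catalog_genes, "n_catalog_genes")
  if (is.null(names(edges_per_type)) ||
      !all(names(edges_per_type) %in% EDGE_TYPES))
    abort("`edges_per_type` must be named by the four edge types.")
  if (any(edges_per_type < 0)) abort("Edge counts must be >= 0.")
  assert_count(n_planted_ffls, "n_planted_ffls", min = 0)
  structure(
    list(n_genes = as.integer(n_genes),
         n_samples_per_celltype = as.integer(n_samples_per_celltype),
         lineage_plan = lineage_plan,
         class_proportions = class_proportions,
         class_mean_profiles = class_mean_profiles,
         noise_sd = noise_sd,
         n_planted_markers_per_lineage =
           as.integer(n_planted_markers_per_lineage),
         marker_effect = marker_effect,
         marker_baseline = marker_baseline,
         geneset_sizes = geneset_sizes,
         geneset_class_weights = geneset_class_weights,
         n_tfs = as.integer(n_tfs), n_mirnas = as.integer(n_mirnas),
         n_catalog_genes = as.integer(n_catalog_genes),
         edges_per_type = edges_per_type,
         n_planted_ffls = as.integer(n_planted_ffls),
         rng_seed = as.integer(rng_seed)),
    class = "simulation_config")
}

#' Default class mean trajectories
#'
#' Piecewise-linear stage trajectories on the log2 scale for the three
#' expression-pattern classes: class 1 high in ESC and monotonically
#' decreasing towards terminal cells, class 2 peaking in intermediate
#' progenitors, class 3 peaking in terminally differentiated cells.
#' @return 3 x 4 numeric matrix (rows classes, columns
#'   ESC/early/intermediate/terminal).
#' @export
default_class_profiles <- function() {
  m <- rbind(c(10, 8, 6, 4),
             c(5, 7, 10, 6),
             c(4, 5, 7, 10))
  dimnames(m) <- list(paste0("class", 1:3),
                      c("ESC", "early", "intermediate", "terminal"))
  m
}

# Sample annotation table implied by a config: one row per (dataset,
# lineage, cell type, replicate), plus ESC control samples in dataset DS0.
sim_annotations <- function(config) {
  plan <- config$lineage_plan
  reps <- config$n_samples_per_celltype
  ann <- plan$datasets |>
    inner_join(plan$cells, by = c("lineage", "stage"),
               relationship = "many-to-many") |>
    tidyr::expand_grid(replicate = seq_len(reps)) |>
    mutate(sample = sprintf("%s_%s_r%d", .data$dataset, .data$cell_type,
                            .data$replicate)) |>
    select("sample", "dataset", "lineage", "cell_type", "stage",
           "order", "replicate") |>
    arrange(.data$sample)
  esc <- tibble(sample = sprintf("DS0_ESC_r%d", seq_len(reps)),
                dataset = "DS0", lineage = NA_character_,
                cell_type = "ESC", stage = "ESC", order = 0L,
                replicate = seq_len(reps))
  bind_rows(esc, ann)
}

#' Simulate a log-scale expression matrix with known ground truth
#'
#' Generates genes in three expression-pattern classes across
#' ESC/early/intermediate/terminal samples, plus planted lineage-restricted
#' marker genes (class-3-style trajectories confined to one lineage's cell
#' types), and samples the imprinted / pluripotent / hematopoietic gene sets
#' across the classes with configurable class weights. Noise is i.i.d.
#' Gaussian on the log2 scale. Fully deterministic given `config$rng_seed`.
#'
#' @param config A [simulation_config()].
#' @return A list with `expression` (tibble: gene + one column per sample),
#'   `annotations` (tibble: sample, dataset, lineage, cell_type, stage,
#'   order, replicate), `gene_sets` (tibble: set, gene, origin),
#'   `ground_truth` (list: `class_of_gene`, `planted_markers`) and the
#'   `config`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$rng_seed, {
    ann <- sim_annotations(config)
    stages <- c("ESC", "early", "intermediate", "terminal")
    stage_idx <- match(ann$stage, stages)

    n <- config$n_genes
    counts <- floor(n * config$class_proportions)
    counts[1] <- counts[1] + (n - sum(counts))
    class_of <- rep(1:3, counts)
    genes <- sprintf("G%04d", seq_len(n))

    # class-pattern genes: mean depends only on (class, stage)
    mu <- config$class_mean_profiles[class_of, stage_idx, drop = FALSE]
    rownames(mu) <- genes

    # planted markers: flat baseline everywhere except their own lineage,
    # where stage means ramp baseline, +effect, +2*effect (early/int/term)
    lineages <- unique(config$lineage_plan$cells$lineage)
    nm <- config$n_planted_markers_per_lineage
    marker_tbl <- tibble(lineage = character(), gene = character())
    if (nm > 0) {
      marker_tbl <- tidyr::expand_grid(lineage = lineages, idx = seq_len(nm)) |>
        mutate(gene = sprintf("MK_%s_%02d", .data$lineage, .data$idx)) |>
        select("lineage", "gene")
      ramp <- c(ESC = 0, early = 0, intermediate = 1, terminal = 2)
      mk_mu <- matrix(config$marker_baseline, nrow(marker_tbl), nrow(ann),
                      dimnames = list(marker_tbl$gene, ann$sample))
      for (i in seq_len(nrow(marker_tbl))) {
        own <- !is.na(ann$lineage) & ann$lineage == marker_tbl$lineage[i]
        mk_mu[i, own] <- config$marker_baseline +
          ramp[ann$stage[own]] * config$marker_effect
      }
      mu <- rbind(mu, mk_mu)
    }
    colnames(mu) <- ann$sample

    values <- mu
    if (config$noise_sd > 0)
      values <- values + matrix(rnorm(length(mu), 0, config$noise_sd),
                                nrow(mu), ncol(mu))

    gene_sets <- map_dfr(names(config$geneset_sizes), function(nm_set) {
      w <- config$geneset_class_weights[[nm_set]]
      size <- min(config$geneset_sizes[[nm_set]], n)
      members <- sample(genes, size, prob = w[class_of])
      tibble(set = nm_set, gene = sort(members))
    })
    gene_sets$origin <- NA_character_
    imp <- gene_sets$set == "imprinted"
    if (any(imp))
      gene_sets$origin[imp] <- sample(c("maternal", "paternal"), sum(imp),
                                      replace = TRUE)

    list(expression = matrix_to_tibble(values),
         annotations = ann,
         gene_sets = gene_sets,
         ground_truth = list(
           class_of_gene = tibble(gene = genes, class = class_of),
           planted_markers = marker_tbl),
         config = config)
  })
}

#' Simulate a typed regulatory interaction catalog with planted FFLs
#'
#' Emits random typed edges among TF, miRNA and gene nodes plus
#' `n_planted_ffls` complete feed-forward-loop triples (edges TF->miRNA,
#' TF->gene, miRNA->gene). No duplicate edges, no self loops; deterministic
#' given the config seed (offset so the catalog is independent of the
#' expression draw).
#'
#' @param config A [simulation_config()].
#' @param genes,tfs,mirnas Optional node pools; synthetic identifiers are
#'   generated when omitted. TFs may overlap the gene pool (TFs are genes).
#' @param ffl_pools Optional list with elements `tfs`, `mirnas`, `targets`:
#'   pools the planted triples are drawn from (defaults to the full pools).
#' @param planted_ffls Optional tibble (tf, mirna, target) of explicit
#'   triples to plant, overriding the sampled ones.
#' @param extra_edges Optional tibble (source, target, type, evidence) of
#'   edges to plant verbatim (deduplicated against the rest).
#' @return A list with `catalog` (tibble: source, target, type, evidence),
#'   the node pools (`tfs`, `mirnas`, `genes`) and `ground_truth` (list with
#'   `planted_ffls`: tibble tf, mirna, target).
#' @export
simulate_catalog <- function(config, genes = NULL, tfs = NULL, mirnas = NULL,
                             ffl_pools = NULL, extra_edges = NULL,
                             planted_ffls = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(derive_seed(config$rng_seed, 7L), {
    genes <- genes %||% sprintf("CG%04d", seq_len(config$n_catalog_genes))
    tfs <- tfs %||% sprintf("TF%03d", seq_len(config$n_tfs))
    mirnas <- mirnas %||% sprintf("mmu-miR-%03d", seq_len(config$n_mirnas))
    pools <- list(
      tfs = (ffl_pools$tfs %||% tfs),
      mirnas = (ffl_pools$mirnas %||% mirnas),
      targets = (ffl_pools$targets %||% genes))
    capacity <- length(pools$tfs) * length(pools$mirnas) *
      length(setdiff(pools$targets, NA))
    if (config$n_planted_ffls > capacity)
      abort(sprintf(
        "Requested %d planted FFLs but only %d distinct triples available.",
        config$n_planted_ffls, capacity))

    planted <- tibble(tf = character(), mirna = character(),
                      target = character())
    if (!is.null(planted_ffls)) {
      planted <- as_tibble(planted_ffls) |>
        distinct(.data$tf, .data$mirna, .data$target)
    } else if (config$n_planted_ffls > 0) {
      seen <- character(0)
      while (nrow(planted) < config$n_planted_ffls) {
        need <- config$n_planted_ffls - nrow(planted)
        cand <- tibble(
          tf = sample(pools$tfs, need, replace = TRUE),
          mirna = sample(pools$mirnas, need, replace = TRUE),
          target = sample(pools$targets, need, replace = TRUE)) |>
          filter(.data$tf != .data$target)
        key <- paste(cand$tf, cand$mirna, cand$target)
        cand <- cand[!duplicated(key) & !(key %in% seen), , drop = FALSE]
        seen <- c(seen, paste(cand$tf, cand$mirna, cand$target))
        planted <- bind_rows(planted, cand)
      }
    }
    planted_edges <- bind_rows(
      tibble(source = planted$tf, target = planted$mirna, type = "TF->miRNA"),
      tibble(source = planted$tf, target = planted$target, type = "TF->gene"),
      tibble(source = planted$mirna, target = planted$target,
             type = "miRNA->gene")) |>
      mutate(evidence = "experimental") |>
      distinct(.data$source, .data$target, .data$type, .keep_all = TRUE)

    src_pool <- list("TF->miRNA" = tfs, "TF->gene" = tfs,
                     "miRNA->gene" = mirnas, "miRNA->TF" = mirnas)
    tgt_pool <- list("TF->miRNA" = mirnas, "TF->gene" = genes,
                     "miRNA->gene" = genes, "miRNA->TF" = tfs)
    random_edges <- map_dfr(names(config$edges_per_type), function(ty) {
      n_edges <- config$edges_per_type[[ty]]
      if (n_edges == 0) return(NULL)
      have <- tibble(source = character(), target = character())
      forbidden <- planted_edges |> filter(.data$type == ty)
      while (nrow(have) < n_edges) {
        need <- n_edges - nrow(have)
        cand <- tibble(source = sample(src_pool[[ty]], 2 * need + 4,
                                       replace = TRUE),
                       target = sample(tgt_pool[[ty]], 2 * need + 4,
                                       replace = TRUE)) |>
          filter(.data$source != .data$target) |>
          anti_join(forbidden, by = c("source", "target")) |>
          distinct()
        have <- bind_rows(have, cand) |> distinct() |> head(n_edges)
      }
      have |> mutate(type = ty,
                     evidence = sample(c("experimental", "predicted"),
                                       nrow(have), replace = TRUE))
    })

    catalog <- bind_rows(planted_edges, extra_edges, random_edges) |>
      distinct(.data$source, .data$target, .data$type, .keep_all = TRUE) |>
      arrange(.data$type, .data$source, .data$target)

    list(catalog = catalog, tfs = tfs, mirnas = mirnas, genes = genes,
         ground_truth = list(planted_ffls = planted |>
                               arrange(.data$tf, .data$mirna, .data$target)))
  })
}

#' Simulate a small is_a ontology with annotations
#'
#' Builds a random acyclic term DAG rooted at a single term and annotates
#' genes to terms. Optional `planted_sets` each receive a dedicated deep
#' term annotated to all their genes, creating functional homogeneity that
#' downstream semantic-similarity tests should detect.
#'
#' @param genes Character vector of genes to annotate.
#' @param n_terms Number of ontology terms (>= 5).
#' @param annotations_per_gene Random term annotations per gene.
#' @param planted_sets Optional named list of gene vectors.
#' @param seed Integer seed.
#' @return An `ontology_graph` (see [ontology()]) with annotations attached.
#' @export
simulate_ontology <- function(genes, n_terms = 50, annotations_per_gene = 3,
                              planted_sets = NULL, seed = 1L) {
  assert_count(n_terms, "n_terms", min = 5)
  with_seed(seed, {
    ids <- sprintf("GO:%07d", seq_len(n_terms))
    terms <- tibble(id = ids,
                    name = sprintf("term %d", seq_len(n_terms)),
                    namespace = "biological_process")
    # term i > 1 gets 1-2 parents among earlier terms -> acyclic by design
    edges <- map_dfr(2:n_terms, function(i) {
      k <- sample(1:2, 1)
      tibble(child = ids[i],
             parent = sample(ids[seq_len(i - 1)], min(k, i - 1)),
             relation = "is_a")
    })
    ann <- tibble(
      gene = rep(genes, each = annotations_per_gene),
      term = sample(ids[-1], length(genes) * annotations_per_gene,
                    replace = TRUE)) |> distinct()
    if (!is.null(planted_sets)) {
      extra_ids <- sprintf("GO:P%06d", seq_along(planted_sets))
      deep_parents <- sample(ids[(n_terms %/% 2):n_terms],
                             length(planted_sets), replace = TRUE)
      terms <- bind_rows(terms, tibble(id = extra_ids,
                                       name = paste0("planted ",
                                                     names(planted_sets)),
                                       namespace = "biological_process"))
      edges <- bind_rows(edges, tibble(child = extra_ids,
                                       parent = deep_parents,
                                       relation = "is_a"))
      ann <- bind_rows(ann, map_dfr(seq_along(planted_sets), function(i) {
        tibble(gene = planted_sets[[i]], term = extra_ids[i])
      })) |> distinct()
    }
    ontology(terms, edges, annotations = ann)
  })
}
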