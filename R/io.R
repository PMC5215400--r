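#' Read an expression matrix with sample annotations
#'
#' Reads a TSV matrix (first column `gene`, one column per sample, header
#' row of sample identifiers) together with a sample-annotation TSV that
#' must contain at least `sample`, `cell_type` and `dataset` columns.
#' Genes with any missing value are dropped with a warning; duplicated gene
#' or sample identifiers, or samples without annotation, are hard errors.
#'
#' @param matrix_path Path to the expression TSV.
#' @param annotation_path Path to the annotation TSV.
#' @return A list with `expression` (wide tibble) and `annotations`.
#' @export
read_expression <- function(matrix_path, annotation_path) {
  expression <- readr::read_tsv(matrix_path, show_col_types = FALSE,
                                progress = FALSE)
  if (names(expression)[1] != "gene")
    names(expression)[1] <- "gene"
  annotations <- readr::read_tsv(annotation_path, show_col_types = FALSE,
                                 progress = FALSE)
  need <- c("sample", "cell_type", "dataset")
  if (!all(need %in% names(annotations)))
    abort(paste("Annotation file must contain columns:",
                paste(need, collapse = ", ")))
  m <- expr_matrix(expression)  # errors on duplicate gene/sample ids
  if (!all(is.finite(m))) {
    bad <- rownames(m)[!complete.cases(m) | rowSums(!is.finite(m)) > 0]
    warn(sprintf("Dropping %d gene(s) with missing/non-finite values: %s",
                 length(bad), paste(head(bad, 5), collapse = ", ")))
    m <- m[!(rownames(m) %in% bad), , drop = FALSE]
    expression <- expression |> filter(!.data$gene %in% bad)
  }
  missing_ann <- setdiff(colnames(m), annotations$sample)
  if (length(missing_ann) > 0)
    abort(sprintf("Samples without annotation: %s",
                  paste(missing_ann, collapse = ", ")))
  list(expression = expression, annotations = annotations)
}

#' Write an expression matrix and annotations as TSV
#' @param sim Output of [simulate_expression()] or a list with `expression`
#'   and `annotations` tibbles.
#' @param matrix_path,annotation_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(sim, matrix_path, annotation_path) {
  readr::write_tsv(sim$expression, matrix_path, progress = FALSE)
  readr::write_tsv(sim$annotations, annotation_path, progress = FALSE)
  invisible(c(matrix_path, annotation_path))
}

#' Read gene sets from a GMT file
#'
#' Standard 2-leading-column GMT dialect: set name, description, then one
#' gene per remaining field.
#' @param path Path to the GMT file.
#' @return Tidy tibble (set, description, gene).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- map_dfr(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) abort("Malformed GMT line (need >= 3 fields).")
    tibble(set = f[1], description = f[2], gene = f[-(1:2)])
  })
  if (anyDuplicated(unique(out[, c("set", "description")])$set))
    abort("Duplicate set names in GMT file.")
  out
}

#' Write gene sets to a GMT file
#' @param gene_sets Tibble with `set` and `gene` columns (and optionally
#'   `description`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- gene_sets |>
    group_by(.data$set) |>
    summarise(line = paste(c(.data$set[1],
                             if ("description" %in% names(gene_sets))
                               .data$description[1] else "na",
                             .data$gene), collapse = "\t")) |>
    arrange(.data$set)
  writeLines(lines$line, path)
  invisible(path)
}

#' Read a typed regulatory interaction catalog
#'
#' Four-column TSV: source, target, type, evidence. Edge types must be one
#' of `TF->miRNA`, `TF->gene`, `miRNA->gene`, `miRNA->TF`.
#' @param path Path to the TSV.
#' @return Tibble (source, target, type, evidence), deduplicated on
#'   (source, target, type).
#' @export
read_catalog <- function(path) {
  cat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("source", "target", "type", "evidence")
  if (!all(need %in% names(cat)))
    abort(paste("Catalog must contain columns:", paste(need, collapse = ", ")))
  bad <- setdiff(unique(cat$type), EDGE_TYPES)
  if (length(bad) > 0)
    abort(sprintf("Unknown edge types: %s", paste(bad, collapse = ", ")))
  cat |> distinct(.data$source, .data$target, .data$type, .keep_all = TRUE)
}

#' Write an interaction catalog as TSV
#' @param catalog Tibble (source, target, type, evidence).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_catalog <- function(catalog, path) {
  readr::write_tsv(catalog, path, progress = FALSE)
  invisible(path)
}

#' Read / write a lineage plan as JSON
#' @param path JSON path.
#' @return A `lineage_plan`.
#' @export
read_lineage_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  plan <- structure(list(cells = as_tibble(x$cells),
                         datasets = as_tibble(x$datasets)),
                    class = "lineage_plan")
  validate_lineage_plan(plan)
  plan
}

#' @rdname read_lineage_plan
#' @param plan A `lineage_plan`.
#' @export
write_lineage_plan <- function(plan, path) {
  validate_lineage_plan(plan)
  jsonlite::write_json(list(cells = plan$cells, datasets = plan$datasets),
                       path, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Export a regulatory network
#'
#' `write_network_sif()` writes the Cytoscape SIF dialect
#' (source &lt;tab&gt; edge-type &lt;tab&gt; target); `write_network_graphml()`
#' writes GraphML via igraph, carrying node class and edge type/evidence
#' attributes.
#' @param net A `reg_network` (see [build_network()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_network_sif <- function(net, path) {
  stopifnot(inherits(net, "reg_network"))
  e <- net$edges
  writeLines(sprintf("%s\t%s\t%s", e$source, gsub("->", "_", e$type,
                                                  fixed = TRUE), e$target),
             path)
  invisible(path)
}

#' @rdname write_network_sif
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "reg_network"))
  g <- igraph::graph_from_data_frame(
    net$edges |> select("source", "target", "type", "evidence"),
    directed = TRUE,
    vertices = net$nodes |> select("node", "class"))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a regulatory network from GraphML
#' @param path GraphML path.
#' @param lineage Optional lineage label to attach.
#' @return A `reg_network`.
#' @export
read_network_graphml <- function(path, lineage = NA_character_) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- tibble(node = igraph::vertex_attr(g, "name"),
                  class = igraph::vertex_attr(g, "class"))
  ed <- igraph::as_data_frame(g, what = "edges")
  edges <- tibble(source = ed$from, target = ed$to, type = ed$type,
                  evidence = ed$evidence)
  new_reg_network(nodes, edges, lineage)
}
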