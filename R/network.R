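# Internal constructor; validates endpoint classes against edge types.
new_reg_network <- function(nodes, edges, lineage = NA_character_) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  edges <- edges |> distinct(.data$source, .data$target, .data$type,
                             .keep_all = TRUE)
  cls <- setNames(nodes$class, nodes$node)
  src_class <- sub("->.*", "", edges$type)
  tgt_class <- sub(".*->", "", edges$type)
  # a TF is a gene, so "gene" endpoints accept TF-classed nodes
  src_ok <- cls[edges$source] == src_class |
    (src_class == "gene" & cls[edges$source] == "TF")
  tgt_ok <- cls[edges$target] == tgt_class |
    (tgt_class == "gene" & cls[edges$target] == "TF")
  bad <- which(!src_ok | !tgt_ok)
  if (length(bad) > 0)
    abort(sprintf("Edge type inconsistent with endpoint classes in %d edge(s).",
                  length(bad)))
  structure(list(nodes = as_tibble(nodes), edges = as_tibble(edges),
                 lineage = lineage),
            class = "reg_network")
}

#' @export
print.reg_network <- function(x, ...) {
  cat(sprintf("Regulatory network%s: %d nodes (%s), %d edges\n",
              if (is.na(x$lineage)) "" else paste0(" [", x$lineage, "]"),
              nrow(x$nodes),
              paste(sprintf("%d %s", table(x$nodes$class),
                            names(table(x$nodes$class))), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' Assemble a lineage-specific TF-miRNA regulatory network
#'
#' Induces the subnetwork of an interaction catalog on the selected nodes
#' (marker genes/TFs plus enriched miRNAs), keeping edges whose both
#' endpoints are selected and whose evidence passes the filter. Nodes left
#' without any edge are dropped (logged). Marker genes that appear in the
#' catalog's TF census are classed as TFs.
#'
#' @param markers Character vector of marker genes (TFs included).
#' @param mirnas Character vector of selected miRNAs.
#' @param catalog Interaction catalog tibble.
#' @param evidence_filter Evidence labels to keep (default both
#'   experimental and predicted; "planted"/other labels pass only if
#'   listed).
#' @param lineage Optional lineage name carried on the network.
#' @return A `reg_network`: list with `nodes` (node, class), `edges`
#'   (source, target, type, evidence) and `lineage`.
#' @export
build_network <- function(markers, mirnas, catalog,
                          evidence_filter = c("experimental", "predicted"),
                          lineage = NA_character_) {
  if (length(markers) == 0 || nrow(catalog) == 0)
    abort("`markers` and `catalog` must be non-empty.")
  selected <- union(markers, mirnas)
  tf_census <- unique(c(catalog$source[catalog$type %in%
                                         c("TF->miRNA", "TF->gene")],
                        catalog$target[catalog$type == "miRNA->TF"]))
  edges <- catalog |>
    filter(.data$evidence %in% evidence_filter,
           .data$source %in% selected, .data$target %in% selected)
  if (nrow(edges) == 0) {
    warn("Induced edge set is empty; returning an empty network.")
    return(new_reg_network(tibble(node = character(), class = character()),
                           tibble(source = character(), target = character(),
                                  type = character(), evidence = character()),
                           lineage))
  }
  used <- union(edges$source, edges$target)
  dropped <- setdiff(selected, used)
  if (length(dropped) > 0)
    inform(sprintf("Dropping %d isolated node(s) from the network.",
                   length(dropped)))
  nodes <- tibble(node = sort(used)) |>
    mutate(class = dplyr::case_when(
      .data$node %in% mirnas ~ "miRNA",
      .data$node %in% tf_census ~ "TF",
      TRUE ~ "gene"))
  new_reg_network(nodes, edges |> arrange(.data$type, .data$source,
                                          .data$target), lineage)
}

#' Degree-centrality hubs of a regulatory network
#'
#' Degree = number of links incident upon a node (in + out, all edge types,
#' deduplicated edges). TFs/genes and miRNAs are ranked separately and the
#' top `ceiling(fraction * class size)` of each returned; ties at the cut
#' are broken by higher degree first, then lexicographic identifier.
#'
#' @param net A `reg_network`.
#' @param fraction Hub fraction (default 0.10).
#' @return A `hub_report`: tibble (node, class, class_group, degree, rank,
#'   hub).
#' @export
degree_hubs <- function(net, fraction = 0.10) {
  stopifnot(inherits(net, "reg_network"))
  assert_fraction(fraction, "fraction")
  if (nrow(net$nodes) == 0) abort("Network is empty.")
  inc <- c(net$edges$source, net$edges$target)
  deg <- table(factor(inc, levels = net$nodes$node))
  out <- net$nodes |>
    mutate(degree = as.integer(deg[.data$node]),
           class_group = ifelse(.data$class == "miRNA", "miRNA", "TF/gene")) |>
    group_by(.data$class_group) |>
    arrange(dplyr::desc(.data$degree), .data$node, .by_group = TRUE) |>
    mutate(rank = row_number(),
           hub = .data$rank <= ceiling(fraction * n())) |>
    ungroup() |>
    arrange(.data$class_group, .data$rank)
  structure(out, class = c("hub_report", class(out)), fraction = fraction)
}

#' @export
glance.hub_report <- function(x, ...) {
  x |> group_by(.data$class_group) |>
    summarise(n_nodes = n(), n_hubs = sum(.data$hub),
              max_degree = max(.data$degree), .groups = "drop")
}

#' @export
autoplot.hub_report <- function(object, ...) {
  top <- object |> filter(.data$hub)
  ggplot(top, aes(x = stats::reorder(.data$node, .data$degree),
                  y = .data$degree, fill = .data$class_group)) +
    geom_col() +
    ggplot2::coord_flip() +
    facet_wrap(~class_group, scales = "free_y") +
    labs(x = NULL, y = "degree", title = "Top-decile degree hubs") +
    theme_minimal()
}
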