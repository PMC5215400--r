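# Upper-tail hypergeometric probability P(X >= k) for an overlap of k
# between a size-n query and a size-K unit set in a size-N universe.
hyper_upper_tail <- function(k, K, n, N) {
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric miRNA enrichment within a marker gene set
#'
#' Selects the miRNAs associated with a marker gene set by two upper-tail
#' hypergeometric test families, each BH-adjusted across miRNAs:
#' \itemize{
#' \item `targets`: the miRNA's target genes (miRNA->gene edges) versus the
#'   markers, over the declared gene universe;
#' \item `regulator_tfs`: the TFs linked to the miRNA (sources of
#'   TF->miRNA edges plus targets of its miRNA->TF edges) versus the marker
#'   TFs, over all TFs in the catalog.
#' }
#' A miRNA is selected if its BH-adjusted p-value is at most `alpha_adj`
#' in either family. miRNAs with an empty unit set in a family are skipped
#' for that family (logged).
#'
#' @param markers Character vector of marker genes (must lie in `universe`).
#' @param catalog Interaction catalog tibble (source, target, type,
#'   evidence).
#' @param universe Character vector: the gene universe.
#' @param alpha_adj Adjusted-p cutoff (default 0.001).
#' @param tf_test Run the regulator-TF family (default TRUE).
#' @return Tibble (mirna, family, k, K, n, N, p, p_adj, selected); an
#'   attribute `selected_mirnas` carries the union of selections.
#' @export
enrich_mirnas <- function(markers, catalog, universe, alpha_adj = 0.001,
                          tf_test = TRUE) {
  markers <- unique(markers)
  universe <- unique(universe)
  offenders <- setdiff(markers, universe)
  if (length(offenders) > 0)
    abort(sprintf("Marker genes absent from the universe: %s",
                  paste(head(offenders, 10), collapse = ", ")))
  if (nrow(catalog) == 0) abort("`catalog` must be non-empty.")

  mg <- catalog |> filter(.data$type == "miRNA->gene",
                          .data$target %in% universe)
  mirnas <- sort(unique(c(catalog$target[catalog$type == "TF->miRNA"],
                          catalog$source[catalog$type %in%
                                           c("miRNA->gene", "miRNA->TF")])))
  tf_census <- sort(unique(c(catalog$source[catalog$type %in%
                                              c("TF->miRNA", "TF->gene")],
                             catalog$target[catalog$type == "miRNA->TF"])))

  target_family <- map_dfr(mirnas, function(mi) {
    targets <- unique(mg$target[mg$source == mi])
    if (length(targets) == 0) {
      inform(sprintf("miRNA %s has no targets in the universe; skipped.", mi))
      return(NULL)
    }
    k <- length(intersect(targets, markers))
    tibble(mirna = mi, family = "targets", k = k, K = length(targets),
           n = length(intersect(markers, universe)), N = length(universe),
           p = hyper_upper_tail(k, length(targets),
                                length(intersect(markers, universe)),
                                length(universe)))
  })
  if (nrow(target_family) > 0)
    target_family$p_adj <- p.adjust(target_family$p, method = "BH")

  tf_family <- NULL
  if (tf_test && length(tf_census) > 0) {
    marker_tfs <- intersect(markers, tf_census)
    tf_family <- map_dfr(mirnas, function(mi) {
      linked <- unique(c(
        catalog$source[catalog$type == "TF->miRNA" & catalog$target == mi],
        catalog$target[catalog$type == "miRNA->TF" & catalog$source == mi]))
      if (length(linked) == 0) return(NULL)
      k <- length(intersect(linked, marker_tfs))
      tibble(mirna = mi, family = "regulator_tfs", k = k, K = length(linked),
             n = length(marker_tfs), N = length(tf_census),
             p = hyper_upper_tail(k, length(linked), length(marker_tfs),
                                  length(tf_census)))
    })
    if (!is.null(tf_family) && nrow(tf_family) > 0)
      tf_family$p_adj <- p.adjust(tf_family$p, method = "BH")
  }

  out <- bind_rows(target_family, tf_family)
  if (nrow(out) == 0)
    return(structure(tibble(mirna = character(), family = character(),
                            k = integer(), K = integer(), n = integer(),
                            N = integer(), p = numeric(), p_adj = numeric(),
                            selected = logical()),
                     selected_mirnas = character(0)))
  out <- out |>
    mutate(selected = .data$p_adj <= alpha_adj) |>
    arrange(.data$family, .data$mirna)
  structure(out,
            selected_mirnas = sort(unique(out$mirna[out$selected])))
}

#' Fisher-exact over-representation analysis
#'
#' Generic one-sided (enrichment) Fisher exact test of a query gene set
#' against annotation categories, keeping categories with at least
#' `min_genes` query members. Reports raw p-values against `alpha` (with a
#' BH-adjusted column alongside).
#'
#' @param query Character vector of genes (subset of `universe`).
#' @param categories Named list of gene vectors, or tibble (set, gene).
#' @param universe Character vector: the background gene universe.
#' @param min_genes Minimum query members per category (default 2).
#' @param alpha Significance level on the raw p-value (default 0.05).
#' @return Tibble (category, k, K, n, N, p, p_adj, significant).
#' @export
fisher_ora <- function(query, categories, universe, min_genes = 2,
                       alpha = 0.05) {
  query <- unique(query); universe <- unique(universe)
  offenders <- setdiff(query, universe)
  if (length(offenders) > 0)
    abort(sprintf("Query genes absent from the universe: %s",
                  paste(head(offenders, 10), collapse = ", ")))
  if (is.data.frame(categories))
    categories <- split(categories$gene, categories$set)
  out <- imap(categories, function(members, nm) {
    members <- intersect(unique(members), universe)
    k <- length(intersect(members, query))
    if (k < min_genes) return(NULL)
    K <- length(members); n <- length(query); N <- length(universe)
    tab <- matrix(c(k, n - k, K - k, N - K - n + k), nrow = 2)
    p <- fisher.test(tab, alternative = "greater")$p.value
    tibble(category = nm, k = k, K = K, n = n, N = N, p = p)
  }) |> bind_rows()
  if (nrow(out) == 0)
    return(tibble(category = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), p = numeric(),
                  p_adj = numeric(), significant = logical()))
  out |>
    mutate(p_adj = p.adjust(.data$p, method = "BH"),
           significant = .data$p <= alpha) |>
    arrange(.data$p, .data$category)
}
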