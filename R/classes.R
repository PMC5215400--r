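#' Assign expression-pattern classes by hierarchical clustering
#'
#' Reproduces the three-class view of gene expression along differentiation:
#' per-gene profiles of cell-type mean expression are standardized (z-score
#' per gene), clustered by average-linkage agglomerative clustering on
#' Euclidean distance, and the tree is cut into `k` clusters. Clusters are
#' relabeled 1..k by descending mean ESC expression, so that with the
#' default profiles class 1 is the ESC-high/decreasing pattern, class 2
#' peaks in intermediate progenitors and class 3 in terminal cells.
#'
#' Genes are sorted lexicographically before clustering so that merge-order
#' ties are broken deterministically and labels do not depend on input
#' order. Averaging over replicates makes the result invariant to sample
#' permutations within a cell type.
#'
#' @param expression Wide expression tibble (`gene` + sample columns).
#' @param annotations Sample annotations (`sample`, `cell_type`).
#' @param k Number of classes (default 3).
#' @return Tibble (gene, class).
#' @export
assign_classes <- function(expression, annotations, k = 3) {
  m <- expr_matrix(expression)
  if (k < 1 || k > nrow(m))
    abort("`k` must be between 1 and the number of genes.")
  m <- m[order(rownames(m)), , drop = FALSE]
  ct <- annotations$cell_type[match(colnames(m), annotations$sample)]
  if (anyNA(ct)) abort("Every sample must be annotated with a cell type.")
  # per-gene cell-type mean profile
  prof <- t(apply(m, 1, function(x) tapply(x, ct, mean)))
  colnames(prof) <- sort(unique(ct))
  if (k == 1) return(tibble(gene = rownames(prof), class = 1L))
  z <- t(scale(t(prof)))
  z[!is.finite(z)] <- 0  # constant-profile genes
  hc <- hclust(dist(z), method = "average")
  cl <- cutree(hc, k = k)
  # relabel clusters by descending mean ESC expression (fallback: overall)
  esc_samples <- annotations$sample[annotations$cell_type == "ESC"]
  esc_cols <- intersect(colnames(m), esc_samples)
  ref <- if (length(esc_cols) > 0)
    rowMeans(m[, esc_cols, drop = FALSE]) else rowMeans(m)
  cluster_ref <- tapply(ref, cl, mean)
  relabel <- rank(-cluster_ref, ties.method = "first")
  tibble(gene = rownames(prof), class = as.integer(relabel[as.character(cl)]))
}

#' Adjusted Rand index between two labelings
#'
#' Agreement between two partitions of the same genes, corrected for
#' chance; 1 means identical partitions.
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
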