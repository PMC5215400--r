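#' Fit per-sample Gaussian reference densities
#'
#' For each sample, fits a maximum-likelihood Gaussian (mean, sd with n
#' denominator) to the expression values of a reference gene set (e.g. the
#' pluripotent or hematopoietic genes). These densities summarise where the
#' reference set's expression mass lies in each sample, the continuous
#' analogue of binning reference genes by expression value.
#'
#' @param expression Wide expression tibble (`gene` + sample columns).
#' @param reference Character vector of reference genes (>= 2 must be
#'   present in the matrix).
#' @return A `reference_density` tibble (sample, mean, sd, n_genes).
#' @export
fit_reference_density <- function(expression, reference) {
  m <- expr_matrix(expression)
  ref <- intersect(reference, rownames(m))
  if (length(ref) < 2)
    abort("Need at least 2 reference genes present in the matrix.")
  sub <- m[ref, , drop = FALSE]
  mu <- colMeans(sub)
  n <- nrow(sub)
  sdev <- sqrt(colMeans(sweep(sub, 2, mu)^2))  # MLE (n denominator)
  if (any(sdev == 0))
    abort(paste("Zero variance of reference genes in sample(s):",
                paste(names(sdev)[sdev == 0], collapse = ", "),
                "- jitter the values or exclude these samples."))
  structure(tibble(sample = colnames(m), mean = unname(mu),
                   sd = unname(sdev), n_genes = n),
            class = c("reference_density", class(tibble())))
}

#' Gene-set expression similarity score
#'
#' For each gene g, SimScore(g) = sum over samples s of
#' `dnorm(x[g,s]; mu_s, sigma_s) * x[g,s]`, where (mu_s, sigma_s) are the
#' per-sample Gaussian parameters of the reference set. Genes whose
#' expression tracks the reference set's expression distribution in every
#' sample accumulate large scores.
#'
#' @param expression Wide expression tibble.
#' @param density A [fit_reference_density()] result covering every sample
#'   of `expression`.
#' @return Tibble (gene, score).
#' @export
simscore <- function(expression, density) {
  m <- expr_matrix(expression)
  idx <- match(colnames(m), density$sample)
  if (anyNA(idx))
    abort("`density` must cover every sample of the expression matrix.")
  mu <- density$mean[idx]
  sdev <- density$sd[idx]
  phi <- dnorm(sweep(sweep(m, 2, mu), 2, sdev, "/")) |>
    sweep(2, sdev, "/")
  tibble(gene = rownames(m), score = unname(rowSums(phi * m)))
}

#' Significance tests for a focal gene set's similarity scores
#'
#' Three tests of whether a focal set (e.g. imprinted genes) scores higher
#' than the background of all other scored genes:
#' \itemize{
#' \item one-sided Mann-Whitney U (focal greater), normal approximation with
#'   tie correction; the exact p-value is also reported when both groups
#'   have <= 50 members and there are no ties;
#' \item upper-tail hypergeometric test of the focal overlap with the top
#'   `top_fraction` of ranked genes (universe = all scored genes; the
#'   top-decile cut breaks score ties by lexicographic gene identifier);
#' \item a label-permutation test: `n_perm` same-size random gene sets are
#'   drawn and the mean focal score compared to the null means, with
#'   add-one smoothing: p = (#\{null >= observed\} + 1) / (n_perm + 1).
#' }
#'
#' @param scores Tibble (gene, score) from [simscore()].
#' @param focal Character vector, a subset of the scored genes.
#' @param n_perm Number of permutations (default 1000).
#' @param top_fraction Fraction of top-ranked genes (default 0.10).
#' @param seed Integer seed for the permutation draw.
#' @return A `simscore_result` list: `scores` (gene, score, rank,
#'   in_top_fraction, in_focal), `tests` (tibble) and parameters.
#' @export
simscore_tests <- function(scores, focal, n_perm = 1000, top_fraction = 0.10,
                           seed = 1L) {
  stopifnot(is.data.frame(scores), all(c("gene", "score") %in% names(scores)))
  assert_fraction(top_fraction, "top_fraction")
  assert_count(n_perm, "n_perm")
  focal <- unique(focal)
  if (length(focal) == 0) abort("`focal` must be non-empty.")
  if (!all(focal %in% scores$gene))
    abort("All focal genes must be present among the scored genes.")
  if (length(focal) >= nrow(scores))
    warn("Focal set covers all scored genes; tests are degenerate.")

  n <- nrow(scores)
  in_focal <- scores$gene %in% focal
  x <- scores$score[in_focal]
  y <- scores$score[!in_focal]

  mw_approx <- if (length(y) > 0)
    wilcox.test(x, y, alternative = "greater", exact = FALSE,
                correct = FALSE)$p.value else NA_real_
  mw_exact <- if (length(y) > 0 && length(x) <= 50 && length(y) <= 50 &&
                  !any(duplicated(c(x, y))))
    wilcox.test(x, y, alternative = "greater", exact = TRUE)$p.value
  else NA_real_

  # top-fraction cut: rank by descending score, ties by gene id
  ord <- order(-scores$score, scores$gene)
  rank_of <- integer(n); rank_of[ord] <- seq_len(n)
  n_top <- ceiling(top_fraction * n)
  in_top <- rank_of <= n_top
  k <- sum(in_top & in_focal)
  hyper_p <- phyper(k - 1, length(focal), n - length(focal), n_top,
                    lower.tail = FALSE)

  observed <- mean(x)
  null_means <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      mean(scores$score[sample.int(n, length(focal))])
    }, numeric(1))
  })
  perm_p <- (sum(null_means >= observed) + 1) / (n_perm + 1)

  structure(list(
    scores = scores |>
      mutate(rank = rank_of, in_top_fraction = in_top, in_focal = in_focal),
    tests = tibble(
      test = c("mannwhitney", "mannwhitney_exact", "hypergeometric",
               "permutation"),
      statistic = c(NA_real_, NA_real_, k, observed),
      p = c(mw_approx, mw_exact, hyper_p, perm_p)),
    null_means = null_means,
    focal = focal, n_perm = n_perm, top_fraction = top_fraction,
    seed = seed),
    class = "simscore_result")
}

#' @export
print.simscore_result <- function(x, ...) {
  cat(sprintf("SimScore result: %d genes, %d focal, top fraction %.2f\n",
              nrow(x$scores), length(x$focal), x$top_fraction))
  print(x$tests)
  invisible(x)
}

#' @export
tidy.simscore_result <- function(x, ...) x$scores

#' @export
glance.simscore_result <- function(x, ...) {
  p <- setNames(x$tests$p, x$tests$test)
  tibble(n_genes = nrow(x$scores), n_focal = length(x$focal),
         mannwhitney_p = p[["mannwhitney"]],
         hypergeom_p = p[["hypergeometric"]],
         permutation_p = p[["permutation"]],
         mean_focal_score = x$tests$statistic[x$tests$test == "permutation"])
}

#' @export
autoplot.simscore_result <- function(object, ...) {
  df <- object$scores |>
    mutate(group = ifelse(.data$in_focal, "focal", "background"))
  ggplot(df, aes(x = .data$score, colour = .data$group)) +
    geom_density() +
    labs(x = "SimScore", y = "density",
         title = "Similarity-score distributions") +
    theme_minimal()
}
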