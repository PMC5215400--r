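# Newton inversion of the trigamma function (standard numeric method used
# for empirical-Bayes variance-shrinkage hyperparameter estimation).
trigamma_inverse <- function(y) {
  out <- y
  ok <- is.finite(y) & y > 0
  out[!ok & !is.na(y) & y <= 0] <- Inf
  x <- 0.5 + 1 / y[ok]
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y[ok]) / psigamma(x, deriv = 2)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  out[ok] <- x
  out
}

# Moment-matching estimation of the scaled inverse-chi-square prior
# (d0, s0^2) from per-gene residual variances s2 on df degrees of freedom,
# via the distribution of log s2 (digamma/trigamma inversion).
estimate_variance_prior <- function(s2, df) {
  keep <- is.finite(s2) & s2 > 0
  if (sum(keep) < 2)
    return(list(d0 = 0, s0_sq = if (any(keep)) mean(s2[keep]) else 1))
  z <- log(s2[keep])
  dfk <- rep_len(df, length(s2))[keep]
  e <- z - digamma(dfk / 2) + log(dfk / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - mean(trigamma(dfk / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderated t-test for a two-stage contrast
#'
#' Per-gene two-sample comparison of stage means with variance shrinkage:
#' the pooled within-stage variance s_g^2 (d_g df) is shrunk towards a
#' prior s_0^2 estimated from all genes, giving the posterior variance
#' `s~^2 = (d0*s0^2 + d_g*s_g^2) / (d0 + d_g)` and the moderated statistic
#' `t~ = effect / (s~ * sqrt(1/n1 + 1/n2))` on `d0 + d_g` degrees of
#' freedom. The prior (d0, s0^2) is estimated by moment matching on
#' log s_g^2; `d0 = 0` recovers the classical pooled t-test and
#' `d0 = Inf` a constant-variance statistic.
#'
#' @param expression Wide expression tibble.
#' @param groups Tibble (sample, stage) or named character vector
#'   sample -> stage.
#' @param contrast Length-2 character vector of stages; effect is
#'   mean(contrast[2]) - mean(contrast[1]).
#' @param d0 Optional prior df override (e.g. `0` for no shrinkage,
#'   `Inf` for full shrinkage); default `NULL` estimates it from the data.
#' @return Tibble (gene, effect, s2, s2_post, df_residual, df_total, t, p)
#'   with two-sided p-values; attributes `d0` and `s0_sq` carry the prior.
#' @export
moderated_t <- function(expression, groups, contrast, d0 = NULL) {
  m <- expr_matrix(expression)
  if (is.data.frame(groups))
    groups <- setNames(groups$stage, groups$sample)
  stage <- groups[colnames(m)]
  if (length(contrast) != 2) abort("`contrast` must name exactly two stages.")
  i1 <- which(stage == contrast[1]); i2 <- which(stage == contrast[2])
  for (s in seq_along(contrast)) {
    if (length(list(i1, i2)[[s]]) < 2)
      abort(sprintf("Stage '%s' has fewer than 2 samples.", contrast[s]))
  }
  n1 <- length(i1); n2 <- length(i2)
  x1 <- m[, i1, drop = FALSE]; x2 <- m[, i2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  dg <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dg
  effect <- m2 - m1

  if (is.null(d0)) {
    prior <- estimate_variance_prior(s2, dg)
    d0 <- prior$d0; s0_sq <- prior$s0_sq
  } else {
    s0_sq <- estimate_variance_prior(s2, dg)$s0_sq
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
  else (d0 * s0_sq + dg * s2) / (d0 + dg)
  df_total <- d0 + dg
  tstat <- effect / sqrt(s2_post * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(tstat), df = df_total)
  out <- tibble(gene = rownames(m), effect = unname(effect),
                s2 = unname(s2), s2_post = unname(s2_post),
                df_residual = dg, df_total = df_total,
                t = unname(tstat), p = unname(p))
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

#' Benjamini-Hochberg adjustment with rejection calls
#'
#' Step-up BH adjustment with enforced monotonicity; `reject[i]` is TRUE
#' iff `p_adj[i] <= alpha`.
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return Tibble (p, p_adj, reject).
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    abort("All p-values must lie in [0, 1].")
  assert_fraction(alpha, "alpha")
  p_adj <- p.adjust(p, method = "BH")
  tibble(p = p, p_adj = p_adj, reject = p_adj <= alpha)
}

#' On/off expression calls for two-stage designs
#'
#' A gene is called "on" in a stage iff every one of its samples in that
#' stage exceeds the threshold; it is a marker iff it is on in exactly one
#' of the two stages (uniquely expressed there).
#'
#' @param expression Wide expression tibble.
#' @param groups Tibble (sample, stage) or named vector; exactly two stages.
#' @param threshold On/off log-expression threshold; default is the
#'   matrix-wide median.
#' @return Tibble (gene, on_&lt;stage1&gt;, on_&lt;stage2&gt;, marker,
#'   marker_stage).
#' @export
onoff_markers <- function(expression, groups, threshold = NULL) {
  m <- expr_matrix(expression)
  if (is.data.frame(groups))
    groups <- setNames(groups$stage, groups$sample)
  stage <- groups[colnames(m)]
  stages <- sort(unique(stage[!is.na(stage)]))
  if (length(stages) != 2)
    abort("on/off calling needs exactly two stages; use moderated_t() for >2.")
  threshold <- threshold %||% median(m)
  on1 <- apply(m[, stage == stages[1], drop = FALSE] > threshold, 1, all)
  on2 <- apply(m[, stage == stages[2], drop = FALSE] > threshold, 1, all)
  marker <- xor(on1, on2)
  out <- tibble(gene = rownames(m), on1 = unname(on1), on2 = unname(on2),
                marker = unname(marker),
                marker_stage = unname(ifelse(marker,
                                             ifelse(on1, stages[1],
                                                    stages[2]),
                                             NA_character_)))
  names(out)[2:3] <- paste0("on_", stages)
  attr(out, "threshold") <- threshold
  out
}

#' Per-dataset lineage marker calls
#'
#' For every (dataset, lineage) with at least two stages present, tests
#' stage-wise differential expression. Three-stage designs run both
#' consecutive moderated-t contrasts (early vs intermediate, intermediate
#' vs terminal) with BH control at `alpha` per contrast and take the union
#' of significant genes; two-stage designs use on/off thresholding.
#'
#' @param expression Wide expression tibble.
#' @param annotations Tibble with sample, dataset, lineage, stage.
#' @param alpha BH level for the moderated-t path (default 0.05).
#' @param onoff_threshold Threshold for the on/off path (default matrix
#'   median).
#' @return Tibble of per-call rows (dataset, lineage, gene, method,
#'   contrast, statistic, p, p_adj, significant).
#' @export
call_markers <- function(expression, annotations, alpha = 0.05,
                         onoff_threshold = NULL) {
  stage_order <- c("early", "intermediate", "terminal")
  combos <- annotations |>
    filter(!is.na(.data$lineage), .data$stage %in% stage_order) |>
    distinct(.data$dataset, .data$lineage, .data$stage) |>
    group_by(.data$dataset, .data$lineage) |>
    summarise(stages = list(intersect(stage_order, .data$stage)),
              .groups = "drop")
  m_all <- expr_matrix(expression)
  onoff_threshold <- onoff_threshold %||% median(m_all)

  pmap(list(combos$dataset, combos$lineage, combos$stages),
       function(ds, ln, stages) {
         samples <- annotations |>
           filter(.data$dataset == ds, !is.na(.data$lineage),
                  .data$lineage == ln, .data$stage %in% stages)
         sub <- expression |>
           select(all_of(c("gene", samples$sample)))
         groups <- samples |> select("sample", "stage")
         if (length(stages) == 2) {
           oo <- onoff_markers(sub, groups, threshold = onoff_threshold)
           tibble(dataset = ds, lineage = ln, gene = oo$gene,
                  method = "onoff", contrast = paste(stages, collapse = "|"),
                  statistic = NA_real_, p = NA_real_, p_adj = NA_real_,
                  significant = oo$marker)
         } else {
           map_dfr(seq_len(length(stages) - 1), function(i) {
             ct <- c(stages[i], stages[i + 1])
             mt <- moderated_t(sub, groups, contrast = ct)
             adj <- bh_adjust(mt$p, alpha = alpha)
             tibble(dataset = ds, lineage = ln, gene = mt$gene,
                    method = "moderated_t",
                    contrast = paste(ct, collapse = "|"),
                    statistic = mt$t, p = mt$p, p_adj = adj$p_adj,
                    significant = adj$reject)
           })
         }
       }) |> bind_rows()
}

#' Cross-dataset consensus markers
#'
#' A gene is confirmed for a lineage iff it is significant (BH-adjusted
#' p <= alpha, or an on/off marker) for that lineage in at least two
#' datasets. `exclusive` flags consensus genes significant in exactly one
#' lineage, the lineage-specific markers used downstream.
#'
#' @param calls Output of [call_markers()] (dataset ordering irrelevant).
#' @return Tibble (lineage, gene, n_datasets, datasets_supporting,
#'   consensus, exclusive).
#' @export
consensus_markers <- function(calls) {
  if (nrow(calls) == 0)
    return(tibble(lineage = character(), gene = character(),
                  n_datasets = integer(), datasets_supporting = character(),
                  consensus = logical(), exclusive = logical()))
  per <- calls |>
    filter(.data$significant) |>
    distinct(.data$dataset, .data$lineage, .data$gene) |>
    group_by(.data$lineage, .data$gene) |>
    summarise(n_datasets = dplyr::n_distinct(.data$dataset),
              datasets_supporting = paste(sort(unique(.data$dataset)),
                                          collapse = ","),
              .groups = "drop") |>
    mutate(consensus = .data$n_datasets >= 2)
  lineage_count <- per |>
    filter(.data$consensus) |>
    count(.data$gene, name = "n_lineages")
  per |>
    left_join(lineage_count, by = "gene") |>
    mutate(exclusive = .data$consensus &
             !is.na(.data$n_lineages) & .data$n_lineages == 1) |>
    select(-"n_lineages") |>
    arrange(.data$lineage, .data$gene)
}
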