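make_two_group <- function(n_genes = 50, n1 = 4, n2 = 4, delta = 0,
                           seed = 1, sd = 1) {
  set.seed(seed)
  m <- cbind(matrix(rnorm(n_genes * n1, 0, sd), n_genes, n1),
             matrix(rnorm(n_genes * n2, delta, sd), n_genes, n2))
  dimnames(m) <- list(sprintf("G%03d", seq_len(n_genes)),
                      sprintf("S%02d", seq_len(n1 + n2)))
  list(expression = tibble::as_tibble(m, rownames = "gene"),
       groups = tibble::tibble(sample = colnames(m),
                               stage = rep(c("early", "terminal"),
                                           c(n1, n2))))
}

test_that("moderated t with d0 = 0 reduces to the classical pooled t", {
  fx <- make_two_group(n_genes = 30, delta = 0.8, seed = 5)
  mt <- moderated_t(fx$expression, fx$groups, c("early", "terminal"), d0 = 0)
  m <- as.matrix(fx$expression[, -1])
  for (i in c(1, 7, 30)) {
    ct <- t.test(m[i, 5:8], m[i, 1:4], var.equal = TRUE)
    expect_equal(mt$t[i], unname(ct$statistic), tolerance = 1e-10)
    expect_equal(mt$p[i], ct$p.value, tolerance = 1e-10)
  }
})

test_that("shrinkage has the expected fixed point and limits", {
  fx <- make_two_group(n_genes = 20, seed = 6)
  mt <- moderated_t(fx$expression, fx$groups, c("early", "terminal"))
  # posterior variances lie between the prior and the observed variance
  s0 <- attr(mt, "s0_sq")
  expect_true(all(mt$s2_post >= pmin(mt$s2, s0) - 1e-12 &
                    mt$s2_post <= pmax(mt$s2, s0) + 1e-12))
  # d0 = Inf collapses every posterior variance onto the prior
  mt_inf <- moderated_t(fx$expression, fx$groups, c("early", "terminal"),
                        d0 = Inf)
  expect_true(all(mt_inf$s2_post == mt_inf$s2_post[1]))
  # if the prior equals the common variance, shrinkage is a no-op
  m <- as.matrix(fx$expression[, -1])
  mt0 <- moderated_t(fx$expression, fx$groups, c("early", "terminal"),
                     d0 = 4)
  s2 <- mt0$s2
  manual <- (4 * attr(mt0, "s0_sq") + mt0$df_residual * s2) /
    (4 + mt0$df_residual)
  expect_equal(mt0$s2_post, manual, tolerance = 1e-12)
  expect_error(
    moderated_t(fx$expression,
                tibble::tibble(sample = fx$groups$sample,
                               stage = c("early", rep("terminal", 7))),
                c("early", "terminal")),
    "fewer than 2")
})

test_that("moderated t agrees with the limma empirical-Bayes machinery", {
  skip_if_not_installed("limma")
  fx <- make_two_group(n_genes = 200, delta = 0.5, seed = 7)
  mt <- moderated_t(fx$expression, fx$groups, c("early", "terminal"))
  m <- as.matrix(fx$expression[, -1])
  design <- cbind(1, fx$groups$stage == "terminal")
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(attr(mt, "d0"), fit$df.prior, tolerance = 1e-4)
  expect_equal(attr(mt, "s0_sq"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(mt$s2_post, unname(fit$s2.post), tolerance = 1e-8)
  expect_equal(mt$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(mt$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("null p-values are uniform", {
  fx <- make_two_group(n_genes = 200, n1 = 3, n2 = 3, delta = 0, seed = 8)
  mt <- moderated_t(fx$expression, fx$groups, c("early", "terminal"))
  ks <- suppressWarnings(ks.test(mt$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment matches the hand-computed and brute-force step-up", {
  res <- bh_adjust(c(0.01, 0.02, 0.03), alpha = 0.05)
  expect_equal(res$p_adj, c(0.03, 0.03, 0.03))
  expect_true(all(res$reject))
  expect_equal(bh_adjust(0.2)$p_adj, 0.2)
  set.seed(9)
  for (n in c(5, 50, 400)) {
    p <- runif(n)
    got <- bh_adjust(p)
    expect_equal(got$p_adj, oracle_bh(p), tolerance = 1e-14)
    expect_true(all(got$p_adj >= got$p))
    # monotone in the order statistics
    o <- order(p)
    expect_true(all(diff(got$p_adj[o]) >= -1e-14))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("on/off calling identifies uniquely expressed genes", {
  m <- rbind(on_early = c(8, 8, 2, 2),
             on_both = c(8, 8, 8, 8),
             off_both = c(2, 2, 2, 2),
             on_term = c(2, 2, 8, 8))
  colnames(m) <- sprintf("S%d", 1:4)
  expr <- tibble::as_tibble(m, rownames = "gene")
  groups <- tibble::tibble(sample = colnames(m),
                           stage = rep(c("early", "terminal"), each = 2))
  oo <- onoff_markers(expr, groups, threshold = 5)
  expect_equal(oo$marker, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(oo$marker_stage, c("early", NA, NA, "terminal"))
  # one sample below threshold switches the call off (all-replicates rule)
  m2 <- m; m2["on_early", 2] <- 4
  oo2 <- onoff_markers(tibble::as_tibble(m2, rownames = "gene"), groups,
                       threshold = 5)
  expect_false(oo2$marker[1])
  groups3 <- groups; groups3$stage[1] <- "mid"
  expect_error(onoff_markers(expr, groups3, threshold = 5), "exactly two")
})

test_that("consensus requires two datasets and flags lineage exclusivity", {
  calls <- tibble::tibble(
    dataset = c("DS1", "DS2", "DS2", "DS3", "DS1"),
    lineage = c("B", "B", "T", "B", "T"),
    gene = c("g1", "g1", "g2", "g2", "g2"),
    method = "moderated_t", contrast = "early|terminal",
    statistic = NA_real_, p = NA_real_, p_adj = NA_real_,
    significant = c(TRUE, TRUE, TRUE, TRUE, TRUE))
  cons <- consensus_markers(calls)
  g1 <- cons[cons$gene == "g1" & cons$lineage == "B", ]
  expect_true(g1$consensus)
  expect_true(g1$exclusive)
  # g2: significant once in lineage B, twice in T-lineage datasets? no:
  # T has DS1+DS2 -> consensus; B has only DS3 -> no consensus
  g2t <- cons[cons$gene == "g2" & cons$lineage == "T", ]
  g2b <- cons[cons$gene == "g2" & cons$lineage == "B", ]
  expect_true(g2t$consensus)
  expect_false(g2b$consensus)
  expect_true(g2t$exclusive)
  # invariant to dataset row order
  cons2 <- consensus_markers(calls[sample(nrow(calls)), ])
  expect_equal(cons, cons2)
})

test_that("planted lineage markers are recovered through the consensus rule", {
  cfg <- simulation_config(n_genes = 300, n_planted_markers_per_lineage = 8,
                           rng_seed = 31)
  sim <- simulate_expression(cfg)
  calls <- call_markers(sim$expression, sim$annotations, alpha = 0.05)
  cons <- consensus_markers(calls)
  truth <- sim$ground_truth$planted_markers
  excl <- cons[cons$exclusive, ]
  tp <- nrow(merge(excl, truth, by = c("lineage", "gene")))
  expect_gte(tp / nrow(truth), 0.85)
  expect_lte((nrow(excl) - tp) / max(nrow(excl), 1), 0.15)
})
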