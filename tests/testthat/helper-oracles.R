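# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own code paths.

# SimScore by an explicit double loop over genes and samples.
oracle_simscore <- function(m, mu, sdev) {
  out <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    acc <- 0
    for (j in seq_len(ncol(m))) {
      x <- m[i, j]
      phi <- exp(-(x - mu[j])^2 / (2 * sdev[j]^2)) / (sdev[j] * sqrt(2 * pi))
      acc <- acc + phi * x
    }
    out[i] <- acc
  }
  setNames(out, rownames(m))
}

# Benjamini-Hochberg step-up from its definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exhaustive upper-tail hypergeometric by enumerating every size-n draw
# from an N-element universe containing K marked items.
oracle_hyper_tail <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  overlaps <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(overlaps >= k)
}

# Exact one-sided Mann-Whitney p (x greater) by enumerating all group
# assignments of the pooled sample.
oracle_u_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  assignments <- utils::combn(length(pooled), n1)
  u_all <- apply(assignments, 2, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(u_all >= u_obs)
}

# All FFL instances by scanning every ordered (tf, mirna, target) triple.
oracle_motifs <- function(edges) {
  has <- function(s, t, ty)
    any(edges$source == s & edges$target == t & edges$type == ty)
  tfs <- unique(c(edges$source[edges$type %in% c("TF->miRNA", "TF->gene")],
                  edges$target[edges$type == "miRNA->TF"]))
  mirnas <- unique(c(edges$target[edges$type == "TF->miRNA"],
                     edges$source[edges$type %in% c("miRNA->gene",
                                                    "miRNA->TF")]))
  targets <- unique(c(edges$target[edges$type %in% c("TF->gene",
                                                     "miRNA->gene")]))
  out <- list()
  for (tf in tfs) for (mi in mirnas) for (tg in targets) {
    if (tg == tf || tg == mi) next
    co_t <- has(tf, tg, "TF->gene") && has(mi, tg, "miRNA->gene")
    if (!co_t) next
    if (has(tf, mi, "TF->miRNA"))
      out[[length(out) + 1]] <- data.frame(tf = tf, mirna = mi, target = tg,
                                           motif_type = "TF-FFL")
    if (has(mi, tf, "miRNA->TF"))
      out[[length(out) + 1]] <- data.frame(tf = tf, mirna = mi, target = tg,
                                           motif_type = "miRNA-FFL")
    if (has(tf, mi, "TF->miRNA") && has(mi, tf, "miRNA->TF"))
      out[[length(out) + 1]] <- data.frame(tf = tf, mirna = mi, target = tg,
                                           motif_type = "composite-FFL")
  }
  if (length(out) == 0)
    return(data.frame(tf = character(), mirna = character(),
                      target = character(), motif_type = character()))
  res <- do.call(rbind, out)
  res[order(res$motif_type, res$tf, res$mirna, res$target), , drop = FALSE]
}

# Wang term similarity evaluated directly from its recursive definition:
# S_A(t) = 1 if t == A else max over children c on a path to A of w * S_A(c).
oracle_wang_svalues <- function(term, parent_list, w = 0.8) {
  svals <- new.env()
  assign(term, 1, envir = svals)
  frontier <- term
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (cur in frontier) {
      for (p in parent_list[[cur]]) {
        cand <- w * get(cur, envir = svals)
        old <- if (exists(p, envir = svals)) get(p, envir = svals) else -Inf
        if (cand > old) {
          assign(p, cand, envir = svals)
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  vals <- sapply(ls(svals), get, envir = svals)
  vals
}

oracle_wang_sim <- function(t1, t2, parent_list, w = 0.8) {
  s1 <- oracle_wang_svalues(t1, parent_list, w)
  s2 <- oracle_wang_svalues(t2, parent_list, w)
  common <- intersect(names(s1), names(s2))
  (sum(s1[common]) + sum(s2[common])) / (sum(s1) + sum(s2))
}

# Random typed graph fixture.
random_typed_graph <- function(seed, n_tf = 10, n_mi = 10, n_g = 40,
                               e_tm = 20, e_tg = 40, e_mg = 40, e_mt = 10) {
  set.seed(seed)
  tfs <- sprintf("T%02d", seq_len(n_tf))
  mis <- sprintf("m%02d", seq_len(n_mi))
  gs <- sprintf("g%02d", seq_len(n_g))
  draw <- function(src, tgt, n, ty) {
    e <- unique(data.frame(source = sample(src, 3 * n, replace = TRUE),
                           target = sample(tgt, 3 * n, replace = TRUE)))
    e <- e[e$source != e$target, , drop = FALSE]
    e <- utils::head(e, n)
    if (nrow(e) == 0) return(NULL)
    e$type <- ty
    e$evidence <- sample(c("experimental", "predicted"), nrow(e),
                         replace = TRUE)
    e
  }
  out <- rbind(draw(tfs, mis, e_tm, "TF->miRNA"),
               draw(tfs, gs, e_tg, "TF->gene"),
               draw(mis, gs, e_mg, "miRNA->gene"),
               draw(mis, tfs, e_mt, "miRNA->TF"))
  tibble::as_tibble(out)
}

# Small deterministic expression fixture: genes x samples with annotations.
small_expression <- function(n_genes = 10, n_samples = 4, seed = 99) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean = 7, sd = 1.5),
              n_genes, n_samples,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  list(expression = tibble::as_tibble(m, rownames = "gene"),
       annotations = tibble::tibble(sample = colnames(m),
                                    cell_type = rep(c("A", "B"),
                                                    length.out = n_samples),
                                    dataset = "DS1"))
}

# Per-node per-type in/out degree table of an edge tibble.
degree_table <- function(edges) {
  outd <- stats::aggregate(list(n = rep(1, nrow(edges))),
                           by = list(node = edges$source, type = edges$type),
                           FUN = sum)
  ind <- stats::aggregate(list(n = rep(1, nrow(edges))),
                          by = list(node = edges$target, type = edges$type),
                          FUN = sum)
  list(out = outd[order(outd$node, outd$type), ],
       `in` = ind[order(ind$node, ind$type), ])
}
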