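#' Construct an ontology graph
#'
#' Validated container for a term DAG with gene annotations. The edge
#' relation graph must be acyclic; annotations must reference known terms.
#'
#' @param terms Tibble (id, name, namespace).
#' @param edges Tibble (child, parent, relation) with relation in
#'   `is_a` / `part_of`.
#' @param annotations Optional tibble (gene, term).
#' @return An `ontology_graph` list (terms, edges, annotations).
#' @export
ontology <- function(terms, edges, annotations = NULL) {
  terms <- as_tibble(terms); edges <- as_tibble(edges)
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)),
            all(c("child", "parent", "relation") %in% names(edges)))
  unknown <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(unknown) > 0)
    abort(sprintf("Edges reference unknown terms: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  # Kahn's algorithm on child -> parent edges: every term must become
  # removable once all its children are processed, else there is a cycle
  parents_of <- split(edges$parent, edges$child)
  children_of <- split(edges$child, edges$parent)
  pending <- setNames(rep(0L, nrow(terms)), terms$id)
  for (p in names(children_of)) pending[p] <- length(children_of[[p]])
  queue <- names(pending)[pending == 0]
  seen <- 0L
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (par in parents_of[[cur]] %||% character(0)) {
      pending[par] <- pending[par] - 1L
      if (pending[par] == 0L) queue <- c(queue, par)
    }
  }
  if (seen < nrow(terms)) abort("Ontology relation graph contains a cycle.")
  if (!is.null(annotations)) {
    annotations <- as_tibble(annotations)
    stopifnot(all(c("gene", "term") %in% names(annotations)))
    bad <- setdiff(unique(annotations$term), terms$id)
    if (length(bad) > 0)
      abort(sprintf("Annotations reference unknown terms: %s",
                    paste(head(bad, 5), collapse = ", ")))
  }
  structure(list(terms = terms, edges = edges,
                 annotations = annotations %||%
                   tibble(gene = character(), term = character())),
            class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("Ontology graph: %d terms, %d relations, %d annotations (%d genes)\n",
              nrow(x$terms), nrow(x$edges), nrow(x$annotations),
              length(unique(x$annotations$gene))))
  invisible(x)
}

#' Read an ontology from an OBO file
#'
#' Minimal OBO 1.2 reader covering `[Term]` stanzas with `id`, `name`,
#' `namespace`, `is_a` and (optionally) `relationship: part_of` lines;
#' obsolete terms are skipped.
#' @param path OBO path.
#' @param include_part_of Keep `part_of` relations (default FALSE: is_a
#'   only).
#' @return An `ontology_graph` without annotations.
#' @export
read_obo <- function(path, include_part_of = FALSE) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  bounds <- c(starts, length(lines) + 1L)
  terms <- list(); edges <- list()
  for (i in seq_along(starts)) {
    block <- lines[(bounds[i] + 1):(bounds[i + 1] - 1)]
    block <- block[nzchar(block) & !startsWith(block, "[")]
    get1 <- function(key) {
      v <- block[startsWith(block, paste0(key, ": "))]
      if (length(v) == 0) return(NA_character_)
      sub(paste0("^", key, ": "), "", v[1])
    }
    if (identical(get1("is_obsolete"), "true")) next
    id <- get1("id")
    if (is.na(id)) next
    terms[[length(terms) + 1]] <-
      tibble(id = id, name = get1("name") %||% NA_character_,
             namespace = get1("namespace") %||% NA_character_)
    isa <- block[startsWith(block, "is_a: ")]
    for (l in isa) {
      parent <- sub("\\s*!.*$", "", sub("^is_a: ", "", l))
      edges[[length(edges) + 1]] <-
        tibble(child = id, parent = trimws(parent), relation = "is_a")
    }
    if (include_part_of) {
      po <- block[startsWith(block, "relationship: part_of ")]
      for (l in po) {
        parent <- sub("\\s*!.*$", "", sub("^relationship: part_of ", "", l))
        edges[[length(edges) + 1]] <-
          tibble(child = id, parent = trimws(parent), relation = "part_of")
      }
    }
  }
  ontology(bind_rows(terms), bind_rows(edges))
}

#' Read gene annotations from a GAF 2.x file
#'
#' @param path GAF path (comment lines starting with `!` are skipped).
#' @param gene_column Column holding the gene identifier (default 3, the
#'   object symbol; use 2 for the database object id).
#' @param aspects GO aspects to keep; default `P` (biological process).
#' @return Tibble (gene, term, aspect), deduplicated.
#' @export
read_gaf <- function(path, gene_column = 3, aspects = "P") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0) return(tibble(gene = character(),
                                        term = character(),
                                        aspect = character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  out <- tibble(gene = vapply(f, `[`, "", gene_column),
                term = vapply(f, `[`, "", 5L),
                aspect = vapply(f, `[`, "", 9L))
  out |> filter(.data$aspect %in% aspects) |> distinct()
}

#' Attach annotations to an ontology graph
#' @param onto An `ontology_graph`.
#' @param annotations Tibble (gene, term).
#' @return The updated `ontology_graph`.
#' @export
attach_annotations <- function(onto, annotations) {
  ontology(onto$terms, onto$edges, annotations)
}

# Wang S-values of a term: contribution of every ancestor, found by
# upward propagation with multiplicative per-edge weights (is_a 0.8,
# part_of 0.6), taking the max over paths.
wang_svalues <- function(term, parents_of, relation_of,
                         w = c(is_a = 0.8, part_of = 0.6)) {
  s <- setNames(1, term)
  queue <- term
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    pars <- parents_of[[cur]]
    if (is.null(pars)) next
    rels <- relation_of[[cur]]
    for (k in seq_along(pars)) {
      cand <- unname(w[rels[k]]) * s[[cur]]
      if (is.na(cand)) cand <- 0.8 * s[[cur]]
      old <- s[pars[k]]
      if (is.na(old) || cand > old) {
        s[pars[k]] <- cand
        queue <- c(queue, pars[k])
      }
    }
  }
  s
}

# All ancestors (inclusive) of a term.
term_ancestors <- function(term, parents_of) {
  seen <- character(0)
  queue <- term
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    queue <- c(queue, parents_of[[cur]] %||% character(0))
  }
  seen
}

# Pairwise term similarity matrix for the given terms.
term_sim_matrix <- function(terms, onto, measure = c("Wang", "Resnik")) {
  measure <- match.arg(measure)
  parents_of <- split(onto$edges$parent, onto$edges$child)
  relation_of <- split(onto$edges$relation, onto$edges$child)
  n <- length(terms)
  sim <- matrix(0, n, n, dimnames = list(terms, terms))
  if (measure == "Wang") {
    sv <- lapply(setNames(terms, terms), wang_svalues,
                 parents_of = parents_of, relation_of = relation_of)
    tot <- vapply(sv, sum, numeric(1))
    for (i in seq_len(n)) for (j in i:n) {
      common <- intersect(names(sv[[i]]), names(sv[[j]]))
      val <- if (length(common) == 0) 0 else
        (sum(sv[[i]][common]) + sum(sv[[j]][common])) / (tot[i] + tot[j])
      sim[i, j] <- sim[j, i] <- val
    }
  } else {
    anc <- lapply(setNames(terms, terms), term_ancestors,
                  parents_of = parents_of)
    # information content from annotation frequencies, propagated upward
    ann <- onto$annotations
    all_terms <- unique(ann$term)
    anc_all <- lapply(setNames(all_terms, all_terms), term_ancestors,
                      parents_of = parents_of)
    gene_terms <- split(ann$term, ann$gene)
    counts <- table(unlist(lapply(gene_terms, function(ts)
      unique(unlist(anc_all[ts])))))
    n_genes <- length(gene_terms)
    ic <- -log(as.numeric(counts) / n_genes)
    names(ic) <- names(counts)
    max_ic <- max(ic[is.finite(ic) & ic > 0], 0)
    for (i in seq_len(n)) for (j in i:n) {
      common <- intersect(anc[[i]], anc[[j]])
      common_ic <- ic[intersect(common, names(ic))]
      val <- if (length(common_ic) == 0 || max_ic == 0) 0 else
        max(common_ic) / max_ic
      sim[i, j] <- sim[j, i] <- min(val, 1)
    }
  }
  sim
}

# Best-match average of two term sets given a term similarity matrix.
bma_similarity <- function(t1, t2, tsim) {
  sub <- tsim[t1, t2, drop = FALSE]
  (mean(apply(sub, 1, max)) + mean(apply(sub, 2, max))) / 2
}

#' Pairwise GO semantic similarity of a gene set
#'
#' Gene-level similarity combines per-term similarities by best-match
#' averaging across the two genes' annotation sets. The Wang measure
#' (default) scores term pairs by weighted shared-ancestor contributions
#' (0.8 per is_a step, 0.6 per part_of); Resnik scores them by the
#' max-normalized information content of the most informative common
#' ancestor. Genes without annotations are dropped (logged), not scored 0.
#'
#' @param genes Character vector (>= 2 annotated genes).
#' @param onto An `ontology_graph` with annotations.
#' @param measure "Wang" (default) or "Resnik".
#' @param namespace Optional namespace restriction (e.g.
#'   "biological_process"); default uses all annotated terms.
#' @return Tibble (gene1, gene2, similarity), one row per unordered pair.
#' @export
pairwise_semantic_similarity <- function(genes, onto,
                                         measure = c("Wang", "Resnik"),
                                         namespace = NULL) {
  measure <- match.arg(measure)
  ann <- onto$annotations
  if (!is.null(namespace)) {
    keep_terms <- onto$terms$id[onto$terms$namespace == namespace]
    ann <- ann |> filter(.data$term %in% keep_terms)
  }
  gene_terms <- split(ann$term, ann$gene)
  genes <- unique(genes)
  missing <- setdiff(genes, names(gene_terms))
  if (length(missing) > 0)
    inform(sprintf("Dropping %d unannotated gene(s).", length(missing)))
  genes <- intersect(genes, names(gene_terms))
  if (length(genes) < 2)
    abort("Need at least 2 annotated genes to form pairs.")
  terms <- unique(unlist(gene_terms[genes]))
  tsim <- term_sim_matrix(terms, onto, measure = measure)
  pairs <- combn(sort(genes), 2)
  tibble(gene1 = pairs[1, ], gene2 = pairs[2, ],
         similarity = vapply(seq_len(ncol(pairs)), function(i) {
           bma_similarity(unique(gene_terms[[pairs[1, i]]]),
                          unique(gene_terms[[pairs[2, i]]]), tsim)
         }, numeric(1)))
}

#' Functional-homogeneity test of motif co-regulated genes
#'
#' Compares the pairwise semantic-similarity distribution of a gene set
#' (e.g. the union of targets of a motif's TF and miRNA) against a null
#' built from `n_perm` equally sized random draws from all annotated genes
#' (pair scores pooled across draws), using a one-sided two-sample
#' Kolmogorov-Smirnov test of whether the observed scores are
#' stochastically larger.
#'
#' @param motif_genes Character vector of co-regulated genes.
#' @param onto An `ontology_graph` with annotations.
#' @param n_perm Number of random draws (default 100).
#' @param seed Integer seed.
#' @param measure,namespace Passed to [pairwise_semantic_similarity()].
#' @return A `similarity_report`: list with `pair_scores`, `null_scores`
#'   (pooled) and `null_draws` (per draw), the one-sided `ks_statistic` and
#'   analytic `ks_p`, and `empirical_p` — the add-one-smoothed rank of the
#'   observed KS statistic among the null draws' statistics, which stays
#'   calibrated when pair scores are dependent.
#' @export
functional_homogeneity_test <- function(motif_genes, onto, n_perm = 100,
                                        seed = 1L,
                                        measure = c("Wang", "Resnik"),
                                        namespace = NULL) {
  measure <- match.arg(measure)
  assert_count(n_perm, "n_perm")
  annotated <- unique(onto$annotations$gene)
  motif_genes <- intersect(unique(motif_genes), annotated)
  if (length(motif_genes) < 2)
    abort("Fewer than 2 annotated motif genes.")
  if (length(annotated) < 2 * length(motif_genes))
    abort("Annotated universe too small for a size-matched null.")
  observed <- pairwise_semantic_similarity(motif_genes, onto,
                                           measure = measure,
                                           namespace = namespace)
  null_draws <- with_seed(seed, {
    lapply(seq_len(n_perm), function(i) {
      draw <- sample(annotated, length(motif_genes))
      pairwise_semantic_similarity(draw, onto, measure = measure,
                                   namespace = namespace)$similarity
    })
  })
  null_scores <- unlist(null_draws)
  # alternative = "less": the observed CDF lies below the null CDF,
  # i.e. observed scores are stochastically larger
  ks_stat <- function(x) suppressWarnings(
    ks.test(x, null_scores, alternative = "less"))
  ks <- ks_stat(observed$similarity)
  # The analytic KS p treats pair scores as independent, but pairs within
  # a draw share genes, which makes it anti-conservative. The empirical p
  # compares the observed KS statistic with the same statistic of each
  # null draw (exchangeable under the null), with add-one smoothing.
  null_D <- vapply(null_draws, function(s) unname(ks_stat(s)$statistic),
                   numeric(1))
  empirical_p <- (sum(null_D >= unname(ks$statistic)) + 1) / (n_perm + 1)
  structure(list(pair_scores = observed, null_scores = null_scores,
                 null_draws = null_draws,
                 ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
                 empirical_p = empirical_p,
                 n_perm = n_perm, measure = measure, seed = seed),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf(
    "Functional homogeneity (%s, %d pairs vs %d null scores): D = %.3f, p = %.3g\n",
    x$measure, nrow(x$pair_scores), length(x$null_scores),
    x$ks_statistic, x$ks_p))
  invisible(x)
}

#' @export
tidy.similarity_report <- function(x, ...) x$pair_scores

#' @export
glance.similarity_report <- function(x, ...) {
  tibble(n_pairs = nrow(x$pair_scores),
         mean_similarity = mean(x$pair_scores$similarity),
         null_mean = mean(x$null_scores),
         ks_statistic = x$ks_statistic, ks_p = x$ks_p,
         empirical_p = x$empirical_p, n_perm = x$n_perm)
}

#' @export
autoplot.similarity_report <- function(object, ...) {
  df <- bind_rows(
    tibble(similarity = object$pair_scores$similarity, set = "co-regulated"),
    tibble(similarity = object$null_scores, set = "random"))
  ggplot(df, aes(x = .data$similarity, colour = .data$set)) +
    stat_ecdf() +
    labs(x = "semantic similarity", y = "cumulative fraction",
         title = "Functional similarity: co-regulated vs random gene pairs") +
    theme_minimal()
}

#' Cross-set functional similarity with a resampled background
#'
#' Mean best-match-average similarity across all pairs (a, b) with a in
#' `setA` and b in `setB`, compared to `n_background` size-matched random
#' set pairs drawn from all annotated genes.
#'
#' @param setA,setB Character vectors of genes.
#' @param onto An `ontology_graph` with annotations.
#' @param n_background Number of background draws (default 100).
#' @param seed Integer seed.
#' @param measure,namespace Passed to the similarity machinery.
#' @return List with `observed_mean`, `background_means` and the add-one
#'   smoothed empirical `p`.
#' @export
geneset_class_similarity <- function(setA, setB, onto, n_background = 100,
                                     seed = 1L,
                                     measure = c("Wang", "Resnik"),
                                     namespace = NULL) {
  measure <- match.arg(measure)
  ann <- onto$annotations
  gene_terms <- split(ann$term, ann$gene)
  annotated <- names(gene_terms)
  setA <- intersect(unique(setA), annotated)
  setB <- intersect(unique(setB), annotated)
  if (length(setA) == 0 || length(setB) == 0)
    abort("Both sets need at least one annotated gene.")
  cross_mean <- function(a, b) {
    terms <- unique(unlist(gene_terms[union(a, b)]))
    tsim <- term_sim_matrix(terms, onto, measure = measure)
    vals <- vapply(a, function(g1) {
      vapply(b, function(g2) {
        bma_similarity(unique(gene_terms[[g1]]),
                       unique(gene_terms[[g2]]), tsim)
      }, numeric(1))
    }, numeric(length(b)))
    mean(vals)
  }
  observed <- cross_mean(setA, setB)
  background <- with_seed(seed, {
    vapply(seq_len(n_background), function(i) {
      cross_mean(sample(annotated, length(setA)),
                 sample(annotated, length(setB)))
    }, numeric(1))
  })
  list(observed_mean = observed, background_means = background,
       p = (sum(background >= observed) + 1) / (n_background + 1))
}
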