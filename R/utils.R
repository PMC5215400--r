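# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed derivation; keeps results within 32-bit range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 69069 + 12345 * as.double(k)) %% 2147483647L)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0 || x > 1)
    abort(sprintf("`%s` must be a single fraction in (0, 1].", name))
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x))
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  invisible(as.integer(x))
}

# Convert a wide expression tibble (gene + one column per sample) into a
# numeric matrix with gene rownames. Validates identifier uniqueness.
expr_matrix <- function(expression) {
  stopifnot(is.data.frame(expression), "gene" %in% names(expression))
  genes <- expression$gene
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    abort(sprintf("Duplicate gene identifiers: %s", paste(dup, collapse = ", ")))
  }
  m <- as.matrix(expression[, setdiff(names(expression), "gene"), drop = FALSE])
  if (anyDuplicated(colnames(m))) {
    dup <- unique(colnames(m)[duplicated(colnames(m))])
    abort(sprintf("Duplicate sample identifiers: %s", paste(dup, collapse = ", ")))
  }
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

# Inverse of expr_matrix.
matrix_to_tibble <- function(m) {
  out <- as_tibble(m, rownames = "gene")
  out
}
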