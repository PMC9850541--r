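# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

`%||%` <- function(a, b) if (is.null(a)) b else a

# ExpressionMatrix with a norm layer built from a plain matrix; existing
# dimnames win over the generated defaults.
norm_mat <- function(x, genes = NULL, cells = NULL) {
  genes <- genes %||% rownames(x) %||% sprintf("G%03d", seq_len(nrow(x)))
  cells <- cells %||% colnames(x) %||% sprintf("C%03d", seq_len(ncol(x)))
  dimnames(x) <- list(genes, cells)
  expression_matrix(norm = x)
}

count_mat <- function(x, genes = NULL, cells = NULL) {
  genes <- genes %||% rownames(x) %||% sprintf("G%03d", seq_len(nrow(x)))
  cells <- cells %||% colnames(x) %||% sprintf("C%03d", seq_len(ncol(x)))
  dimnames(x) <- list(genes, cells)
  expression_matrix(counts = x)
}

# Small default-world simulation shared by the heavier tests (memoised so
# several test files can reuse one draw).
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- sim_spec(n_genes = 800, n_cells = 800,
                       marker_genes_per_class = 20, risk_set_size = 40,
                       seed = 11)
      sim <- simulate_dataset(spec)
      sim$matrix <- normalize_counts(sim$matrix)
      cache <<- list(spec = spec, sim = sim)
    }
    cache
  }
})

# Two well-separated gaussian populations in gene space (for embedding /
# graph tests): returns list(matrix, labels).
two_pop_matrix <- function(n_genes = 40, n_per = 30, shift = 5, seed = 1) {
  set.seed(seed)
  x1 <- matrix(rnorm(n_genes * n_per), n_genes, n_per)
  x2 <- matrix(rnorm(n_genes * n_per, mean = shift), n_genes, n_per)
  m <- norm_mat(abs(cbind(x1, x2)))
  list(matrix = m, labels = rep(c("a", "b"), each = n_per))
}

# Independent oracle: exact two-sided Wilcoxon p by direct enumeration of
# all C(n1+n2, n1) assignments (kept deliberately separate from the
# package's internal implementation).
oracle_wilcox_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_all <- apply(utils::combn(n1 + n2, n1), 2, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Independent oracle: AUROC as the concordant-pair fraction (ties half).
oracle_auroc <- function(scores, is_pos) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
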