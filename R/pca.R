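# PCA on standardized HVG expression and jackstraw significance testing of
# principal components.

#' Principal component analysis on standardized genes
#'
#' Genes are centered and scaled to unit variance across cells before the
#' decomposition (zero-variance genes are dropped with a warning). The
#' eigendecomposition is done on the smaller of the two Gram matrices, so
#' cost scales with min(genes, cells)^2.
#'
#' @param m an `ExpressionMatrix` with a norm layer
#' @param genes gene ids to use (typically selected HVGs); default all
#' @param n_components number of PCs (default 20, capped at min(dim) - 1)
#' @return `PCAModel` list: `loadings` (gene x PC, orthonormal), `scores`
#'   (cell x PC), `sdev`, `var_explained`, `genes` used, and the
#'   centering/scaling record
#' @export
run_pca <- function(m, genes = NULL, n_components = 20) {
  x <- get_layer(m, "norm")
  if (!is.null(genes)) {
    missing_g <- setdiff(genes, rownames(x))
    if (length(missing_g)) stop("genes not in matrix: ",
                                paste(utils::head(missing_g, 5), collapse = ", "))
    x <- x[genes, , drop = FALSE]
  }
  z <- standardize_rows(x)
  if (length(attr(z, "dropped")))
    warning(length(attr(z, "dropped")), " zero-variance genes dropped before PCA")
  g <- nrow(z); n <- ncol(z)
  max_k <- min(g, n)
  if (n_components > max_k)
    stop(sprintf("n_components (%d) exceeds min(genes, cells) = %d",
                 n_components, max_k))
  k <- n_components
  dec <- pca_decompose(z, k)
  rownames(dec$loadings) <- rownames(z)
  rownames(dec$scores) <- colnames(z)
  colnames(dec$loadings) <- colnames(dec$scores) <- paste0("PC", seq_len(k))
  structure(list(loadings = dec$loadings, scores = dec$scores,
                 sdev = dec$sdev, var_explained = dec$var_explained,
                 genes = rownames(z),
                 standardized = TRUE),
            class = "PCAModel")
}

# Core decomposition of an already-standardized gene x cell matrix.
# Returns loadings (gene x k, unit columns), scores (cell x k), sdev and
# fraction of variance explained. Sign convention: the loading of largest
# magnitude on each PC is positive.
pca_decompose <- function(z, k) {
  g <- nrow(z); n <- ncol(z)
  if (g <= n) {
    eig <- eigen(tcrossprod(z), symmetric = TRUE)
    load <- eig$vectors[, seq_len(k), drop = FALSE]
    ev <- pmax(eig$values, 0)
  } else {
    eig <- eigen(crossprod(z), symmetric = TRUE)
    ev <- pmax(eig$values, 0)
    d <- sqrt(ev[seq_len(k)])
    d[d < 1e-12] <- 1e-12
    load <- z %*% eig$vectors[, seq_len(k), drop = FALSE] %*% diag(1 / d, k)
  }
  flip <- apply(load, 2, function(u) sign(u[which.max(abs(u))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2, flip, "*")
  scores <- crossprod(z, load)
  sdev <- sqrt(ev[seq_len(k)] / (n - 1))
  list(loadings = load, scores = scores, sdev = sdev,
       var_explained = ev[seq_len(k)] / sum(ev))
}

#' Jackstraw significance test for principal components
#'
#' Per iteration, a small fraction of genes is row-permuted (breaking their
#' association with every cell-level structure), the PCA is refit, and the
#' permuted genes' association statistics — squared loading scaled by the
#' PC's variance — are pooled into a per-PC null. The observed statistic is
#' the mean association over all genes; the empirical p-value is the
#' add-one-smoothed fraction of null draws at or above it, so p is strictly
#' inside (0, 1).
#'
#' @param m an `ExpressionMatrix` with norm layer
#' @param pca a `PCAModel` fitted on the same matrix/genes
#' @param n_iter permutation iterations (default 100; < 10 warns)
#' @param perm_fraction fraction of genes permuted per iteration (default
#'   0.01; must yield at least one gene)
#' @param alpha significance level (default 0.01)
#' @param seed RNG seed
#' @return `JackstrawReport` data.frame: PC, p, significant; parameters in
#'   `attr(, "params")`
#' @export
jackstraw <- function(m, pca, n_iter = 100, perm_fraction = 0.01,
                      alpha = 0.01, seed = 0) {
  stopifnot(inherits(pca, "PCAModel"))
  x <- get_layer(m, "norm")[pca$genes, , drop = FALSE]
  z <- standardize_rows(x)
  g <- nrow(z)
  n_perm <- floor(perm_fraction * g)
  if (n_perm < 1)
    stop("perm_fraction * genes < 1; increase perm_fraction")
  if (n_iter < 10) warning("jackstraw with fewer than 10 iterations is unreliable")
  k <- ncol(pca$loadings)
  obs_stat <- colMeans((pca$loadings^2) * rep(pca$sdev^2, each = g))
  set.seed(seed)
  null_stats <- matrix(NA_real_, n_iter * n_perm, k)
  for (it in seq_len(n_iter)) {
    zi <- z
    idx <- sample.int(g, n_perm)
    for (j in idx) zi[j, ] <- zi[j, sample.int(ncol(zi))]
    dec <- pca_decompose(zi, k)
    null_stats[(it - 1) * n_perm + seq_len(n_perm), ] <-
      (dec$loadings[idx, , drop = FALSE]^2) * rep(dec$sdev^2, each = n_perm)
  }
  n_null <- nrow(null_stats)
  p <- vapply(seq_len(k), function(j)
    (sum(null_stats[, j] >= obs_stat[j]) + 1) / (n_null + 2), numeric(1))
  out <- data.frame(PC = colnames(pca$loadings), p = p,
                    significant = p < alpha, row.names = NULL)
  attr(out, "params") <- list(n_iter = n_iter, perm_fraction = perm_fraction,
                              alpha = alpha, seed = seed, n_null = n_null)
  log_stage("jackstraw", n_iter = n_iter, significant = sum(out$significant))
  out
}
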