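# Gene-set-restricted neighbour-voting AUROC between cluster pairs:
# quantifies whether a gene set can distinguish clusters better than
# chance (0.5). The affinity network is the rank-standardized Spearman
# correlation between cells over the gene set; votes for a cell are its
# mean affinity to a training set of labelled cells; the AUROC is the
# probability that a target-cluster cell outranks a non-target cell by
# votes (ties count one half).
#
# The published method is designed for cross-dataset voting; applied
# within a single dataset we use a seeded two-fold scheme (vote from one
# fold, score the other, swap and average). This is the largest
# reinterpretation in the package and is documented as such.

#' Build a neighbour-voting affinity network
#'
#' Spearman correlation between all cell pairs over the gene set, then
#' rank-standardized: each unique pair's correlation is replaced by its
#' average rank among all pairs, scaled to (0, 1]. The diagonal is excluded
#' from voting (NA). Cells with constant expression over the set get the
#' minimum rank, with a warning.
#'
#' @param m an `ExpressionMatrix` with norm layer
#' @param gene_set a `GeneSet` or character vector of gene ids (at least 2
#'   must be present in the matrix)
#' @return `VoteNetwork`: symmetric cell x cell matrix with NA diagonal
#' @export
build_vote_network <- function(m, gene_set) {
  genes <- if (inherits(gene_set, "GeneSet")) gene_set$genes else gene_set
  present <- intersect(genes, m$gene_ids)
  if (length(present) < 2)
    stop("fewer than 2 gene-set genes present in the matrix; missing: ",
         paste(utils::head(setdiff(genes, m$gene_ids), 10), collapse = ", "))
  x <- get_layer(m, "norm")[present, , drop = FALSE]
  const <- apply(x, 2, function(v) max(v) == min(v))
  s <- suppressWarnings(stats::cor(x, method = "spearman"))
  if (any(const)) {
    warning(sum(const), " cell(s) with constant expression over the set; ",
            "their affinities set to the minimum rank")
    s[const, ] <- -Inf
    s[, const] <- -Inf
  }
  n <- ncol(s)
  ut <- upper.tri(s)
  vals <- s[ut]
  r <- rank(vals, ties.method = "average") / length(vals)
  net <- matrix(NA_real_, n, n, dimnames = dimnames(s))
  net[ut] <- r
  net <- pmax(net, t(net), na.rm = TRUE)   # mirror to the lower triangle
  dimnames(net) <- dimnames(s)
  diag(net) <- NA_real_
  structure(net, class = c("VoteNetwork", "matrix"),
            genes = present)
}

#' AUROC of a score vector for a positive/negative labelling
#'
#' Mann-Whitney AUROC — the probability that a random positive outranks a
#' random negative, with half credit for ties — computed via the rank-sum
#' identity.
#'
#' @param scores numeric vector
#' @param is_pos logical vector marking positives
#' @return AUROC in \[0, 1\]; NA when either class is empty
#' @export
#' @examples
#' auroc_from_scores(c(0.9, 0.7, 0.8, 0.1), c(TRUE, TRUE, FALSE, FALSE))
auroc_from_scores <- function(scores, is_pos) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pairwise neighbour-voting AUROC between clusters
#'
#' For an ordered cluster pair (A, B): all cells are split into two seeded
#' random folds; each fold-2 cell's vote is its mean affinity to the fold-1
#' cells labelled A; the entry is the AUROC of fold-2 B-cells against all
#' other fold-2 cells, averaged over the fold swap. The reported matrix is
#' symmetrized by averaging entries (A, B) and (B, A); the diagonal is the
#' cluster's cross-fold self-replicability. A fold missing some cluster is
#' redrawn (up to 10 attempts).
#'
#' @param network a `VoteNetwork`
#' @param clusters cluster labels, one per network cell (named by cell id
#'   or in network order)
#' @param seed fold-split seed
#' @return `AUROCMatrix`: symmetric cluster x cluster matrix in \[0, 1\]
#' @export
pairwise_auroc <- function(network, clusters, seed = 0) {
  n <- nrow(network)
  clusters <- align_groups(clusters, rownames(network) %||%
                             as.character(seq_len(n)))
  labs <- sort(unique(clusters))
  if (any(table(clusters) < 2)) stop("every cluster needs at least 2 cells")
  set.seed(seed)
  fold <- NULL
  for (attempt in seq_len(10)) {
    cand <- sample(rep(1:2, length.out = n))
    if (all(table(clusters, cand) > 0)) { fold <- cand; break }
  }
  if (is.null(fold))
    stop("could not split cells into two folds containing every cluster")
  net0 <- network
  net0[is.na(net0)] <- 0
  votes_for <- function(train_idx, test_idx) {
    # mean affinity of each test cell to the training cells (diagonal NA
    # never enters: train and test folds are disjoint)
    net0[test_idx, train_idx, drop = FALSE] %*%
      rep(1 / length(train_idx), length(train_idx))
  }
  out <- matrix(NA_real_, length(labs), length(labs),
                dimnames = list(labs, labs))
  for (a in labs) {
    for (b in labs) {
      acc <- numeric(0)
      for (f in 1:2) {
        train <- which(fold == f & clusters == a)
        test <- which(fold != f)
        v <- votes_for(train, test)
        acc <- c(acc, auroc_from_scores(as.numeric(v),
                                        clusters[test] == b))
      }
      out[a, b] <- mean(acc)
    }
  }
  sym <- (out + t(out)) / 2
  attr(sym, "unsymmetrized") <- out
  attr(sym, "seed") <- seed
  class(sym) <- c("AUROCMatrix", "matrix")
  sym
}

#' Gene-set discrimination AUROC between two clusters
#'
#' Restricts the matrix to the two clusters' cells, builds the vote network
#' on the gene set, and returns the target cluster's self-replicability
#' AUROC — the probability that a held-out target cell outranks a held-out
#' other-cluster cell when votes come from target-cluster cells. 0.5 means
#' the set cannot distinguish the two clusters better than chance.
#'
#' @param m an `ExpressionMatrix` with norm layer
#' @param clusters cluster labels (named by cell id or in matrix order)
#' @param target,other the two cluster labels to compare
#' @param gene_set a `GeneSet` or character vector
#' @param seed fold-split seed
#' @return numeric AUROC in \[0, 1\]
#' @export
geneset_discrimination_auroc <- function(m, clusters, target, other,
                                         gene_set, seed = 0) {
  if (!is.null(names(clusters))) {
    # labels may cover only a subset of cells (e.g. one cardinal class)
    m <- m[, intersect(m$cell_ids, names(clusters))]
  }
  clusters <- align_groups(clusters, m$cell_ids)
  keep <- clusters %in% c(target, other)
  if (sum(clusters == target) < 2 || sum(clusters == other) < 2)
    stop("both clusters need at least 2 cells")
  m2 <- m[, keep]
  net <- build_vote_network(m2, gene_set)
  am <- pairwise_auroc(net, clusters[keep], seed = seed)
  unname(am[target, target])
}
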