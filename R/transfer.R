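# Cross-dataset label transfer: shared-feature selection, diagonal CCA,
# per-dimension quantile alignment, joint 2-D embedding, and KNN
# majority-vote identity assignment with the published voting rule
# (majority AND at least `min_votes` of the k nearest reference
# neighbours; ties leave the cell unassigned).

#' Kruskal-Wallis discriminability score per gene
#'
#' The Kruskal-Wallis rank statistic of each gene against reference type
#' labels: a deterministic stand-in for the under-specified random-forest
#' feature selection of the published analysis. Larger means the gene
#' separates the types better.
#'
#' @param m an `ExpressionMatrix` with norm layer
#' @param labels type labels (named by cell id or in matrix order)
#' @param genes genes to score (default all)
#' @return named numeric vector of statistics
#' @export
feature_discriminability <- function(m, labels, genes = NULL) {
  x <- get_layer(m, "norm")
  labels <- align_groups(labels, m$cell_ids)
  if (!is.null(genes)) x <- x[intersect(genes, rownames(x)), , drop = FALSE]
  grp <- factor(labels)
  apply(x, 1, function(v) {
    if (max(v) == min(v)) return(0)
    unname(stats::kruskal.test(v, grp)$statistic)
  })
}

#' Select shared variable features across two datasets
#'
#' Intersection of the genes selected in both HVG tables, optionally ranked
#' by a per-gene type-discriminability score (see
#' [feature_discriminability()]) and capped at `top_n`.
#'
#' @param hvg_a,hvg_b `HVGTable` data.frames from [select_hvg()]
#' @param ranking optional named numeric score (larger first)
#' @param top_n optional cap after ranking
#' @return `SharedFeatureSet`: character vector of gene ids; ranking scores
#'   (when given) in `attr(, "scores")`
#' @export
select_shared_features <- function(hvg_a, hvg_b, ranking = NULL,
                                   top_n = NULL) {
  shared <- intersect(hvg_a$gene[hvg_a$selected], hvg_b$gene[hvg_b$selected])
  if (!length(shared))
    stop("no shared variable genes; consider relaxing the HVG thresholds")
  if (!is.null(ranking)) {
    sc <- ranking[shared]
    sc[is.na(sc)] <- -Inf
    shared <- shared[order(sc, decreasing = TRUE)]
    attr(shared, "scores") <- sort(sc, decreasing = TRUE)
  }
  if (!is.null(top_n)) shared <- shared[seq_len(min(top_n, length(shared)))]
  shared
}

#' Diagonal canonical correlation analysis across two datasets
#'
#' Both matrices are standardized per gene over cells on the shared
#' features; the canonical vectors are the left/right singular vectors of
#' the cross-product `t(Z_A) %*% Z_B`, giving one score per cell per
#' canonical component (CC). The canonical correlation of CC j is the jth
#' cross singular value over the geometric mean of each dataset's own jth
#' singular value, clamped to \[0, 1\] and reported in non-increasing
#' order: 1 when the datasets coincide, and concentrated near ~0.55 for
#' independent data (the "shared variance over within variance" analogue
#' of a correlation).
#'
#' @param m_a,m_b `ExpressionMatrix` objects with norm layers
#' @param features shared gene ids
#' @param n_cc number of canonical components (default 4, as published)
#' @return `CCAScores` list: `scores_a`, `scores_b` (cell x CC),
#'   `correlations`, `n_cc`, `features`
#' @export
diagonal_cca <- function(m_a, m_b, features, n_cc = 4) {
  xa <- get_layer(m_a, "norm")[features, , drop = FALSE]
  xb <- get_layer(m_b, "norm")[features, , drop = FALSE]
  za <- standardize_rows(xa); zb <- standardize_rows(xb)
  common <- intersect(rownames(za), rownames(zb))
  if (length(common) < 2) stop("fewer than 2 usable shared features")
  za <- za[common, , drop = FALSE]; zb <- zb[common, , drop = FALSE]
  if (n_cc > min(dim(za)[2], dim(zb)[2], length(common)))
    stop("n_cc exceeds the smallest available dimension")
  k <- crossprod(za, zb)                       # cells_a x cells_b
  sv <- svd(k, nu = n_cc, nv = n_cc)
  u <- sv$u; v <- sv$v
  flip <- vapply(seq_len(n_cc), function(j)
    sign(u[which.max(abs(u[, j])), j]), numeric(1))
  flip[flip == 0] <- 1
  u <- sweep(u, 2, flip, "*"); v <- sweep(v, 2, flip, "*")
  d_aa <- svd(crossprod(za), nu = 0, nv = 0)$d[seq_len(n_cc)]
  d_bb <- svd(crossprod(zb), nu = 0, nv = 0)$d[seq_len(n_cc)]
  denom <- sqrt(d_aa * d_bb)
  corr <- ifelse(denom > 0, pmin(1, sv$d[seq_len(n_cc)] / denom), 0)
  corr <- sort(corr, decreasing = TRUE)
  rownames(u) <- colnames(za); rownames(v) <- colnames(zb)
  colnames(u) <- colnames(v) <- paste0("CC", seq_len(n_cc))
  structure(list(scores_a = u, scores_b = v, correlations = corr,
                 n_cc = n_cc, features = common),
            class = "CCAScores")
}

#' Align CC score distributions across datasets
#'
#' Per CC dimension, each dataset's scores are mapped onto the pooled
#' empirical quantiles via their within-dataset plotting positions
#' `(rank - 0.5) / n`. The map is monotone, so within-dataset rank order is
#' preserved exactly; after alignment the two datasets' per-CC
#' distributions agree at the quantile grid. This replaces the published
#' (unstated-parameter) subspace warping with an explicitly testable
#' contract.
#'
#' @param cca a `CCAScores` object
#' @return the object with `scores_a`/`scores_b` replaced by aligned values
#' @export
align_cc_scores <- function(cca) {
  stopifnot(inherits(cca, "CCAScores"))
  for (j in seq_len(cca$n_cc)) {
    a <- cca$scores_a[, j]; b <- cca$scores_b[, j]
    pooled <- c(a, b)
    map <- function(x) {
      p <- (rank(x, ties.method = "average") - 0.5) / length(x)
      stats::quantile(pooled, probs = p, names = FALSE, type = 7)
    }
    cca$scores_a[, j] <- map(a)
    cca$scores_b[, j] <- map(b)
  }
  cca$aligned <- TRUE
  cca
}

#' KNN majority-vote identity assignment
#'
#' For each query cell, the k nearest reference cells (Euclidean distance
#' in the supplied coordinate space; ties broken by stable reference index)
#' vote with their type labels. The cell is assigned the label holding a
#' unique plurality of at least `min_votes` votes; an equal top count
#' leaves the cell UNASSIGNED (reason "tie"), a top count below `min_votes`
#' leaves it UNASSIGNED (reason "below_min_votes").
#'
#' @param query_coords query cell x d coordinates
#' @param ref_coords reference cell x d coordinates (at least k rows)
#' @param ref_labels reference type labels (one per reference cell)
#' @param k neighbours (default 30)
#' @param min_votes minimum top count (default 5)
#' @return `TransferTable` data.frame: cell, assigned (label or
#'   "UNASSIGNED"), reason ("ok", "tie", "below_min_votes"), top_count,
#'   and one vote-count column per label (columns prefixed "votes_")
#' @export
knn_assign <- function(query_coords, ref_coords, ref_labels, k = 30,
                       min_votes = 5) {
  query_coords <- as.matrix(query_coords)
  ref_coords <- as.matrix(ref_coords)
  if (nrow(ref_coords) < k)
    stop("fewer reference cells than k = ", k)
  if (length(ref_labels) != nrow(ref_coords))
    stop("ref_labels length must match reference cell count")
  ref_labels <- as.character(ref_labels)
  labs <- sort(unique(ref_labels))
  n_q <- nrow(query_coords)
  votes <- matrix(0L, n_q, length(labs), dimnames = list(NULL, labs))
  assigned <- character(n_q); reason <- character(n_q)
  top_count <- integer(n_q)
  for (i in seq_len(n_q)) {
    d2 <- colSums((t(ref_coords) - query_coords[i, ])^2)
    nn <- order(d2)[seq_len(k)]
    tab <- table(factor(ref_labels[nn], levels = labs))
    votes[i, ] <- as.integer(tab)
    top <- max(tab)
    top_count[i] <- top
    winners <- names(tab)[tab == top]
    if (length(winners) > 1) {
      assigned[i] <- "UNASSIGNED"; reason[i] <- "tie"
    } else if (top < min_votes) {
      assigned[i] <- "UNASSIGNED"; reason[i] <- "below_min_votes"
    } else {
      assigned[i] <- winners; reason[i] <- "ok"
    }
  }
  out <- data.frame(cell = rownames(query_coords) %||% as.character(seq_len(n_q)),
                    assigned = assigned, reason = reason,
                    top_count = top_count, stringsAsFactors = FALSE)
  vt <- as.data.frame(votes)
  colnames(vt) <- paste0("votes_", labs)
  out <- cbind(out, vt)
  attr(out, "params") <- list(k = k, min_votes = min_votes)
  class(out) <- c("TransferTable", class(out))
  out
}

#' Per-cluster composition of transferred identities
#'
#' @param transfer a `TransferTable`
#' @param query_clusters cluster labels for the query cells (named by cell
#'   or in transfer order)
#' @return `CompositionTable` data.frame: cluster, type, count, proportion
#'   (including UNASSIGNED); proportions sum to 1 within each cluster
#' @export
composition_summary <- function(transfer, query_clusters) {
  cl <- align_groups(query_clusters, transfer$cell)
  tab <- table(cluster = cl, type = transfer$assigned)
  prop <- prop.table(tab, 1)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  out$proportion <- as.data.frame(prop)$Freq
  colnames(out) <- c("cluster", "type", "count", "proportion")
  class(out) <- c("CompositionTable", class(out))
  out
}

#' End-to-end reference-based label transfer
#'
#' HVG selection in each dataset, shared-feature intersection (optionally
#' discriminability-ranked), diagonal CCA, per-CC quantile alignment, then
#' KNN voting — by default in the full aligned CC space
#' (`knn_space = "cca"`); `knn_space = "embedding"` votes in the joint 2-D
#' embedding as published.
#'
#' @param m_query,m_ref `ExpressionMatrix` objects with norm layers
#' @param ref_labels reference type labels (named by cell id or in
#'   reference order)
#' @param config pipeline configuration (default [default_config()])
#' @param hvg_params optional list(mean_min, mean_max, vmr_cut, vmr_side)
#'   overriding the config HVG window for both datasets
#' @param rank_features rank shared features by reference-type
#'   discriminability (default TRUE)
#' @param top_n cap on shared features after ranking (default NULL)
#' @return list: features, cca (aligned), embedding (`Embedding2D` over the
#'   joint cells), transfer (`TransferTable`)
#' @export
transfer_labels <- function(m_query, m_ref, ref_labels,
                            config = default_config(), hvg_params = NULL,
                            rank_features = TRUE, top_n = NULL) {
  hp <- hvg_params %||% list(mean_min = config$hvg_mean_min,
                             mean_max = config$hvg_mean_max,
                             vmr_cut = config$hvg_vmr_cut,
                             vmr_side = config$hvg_vmr_side)
  hvg_q <- select_hvg(m_query, hp$mean_min, hp$mean_max, hp$vmr_cut,
                      hp$vmr_side)
  hvg_r <- select_hvg(m_ref, hp$mean_min, hp$mean_max, hp$vmr_cut,
                      hp$vmr_side)
  ranking <- NULL
  if (rank_features) {
    shared0 <- intersect(hvg_q$gene[hvg_q$selected], hvg_r$gene[hvg_r$selected])
    if (length(shared0))
      ranking <- feature_discriminability(m_ref, ref_labels, genes = shared0)
  }
  features <- select_shared_features(hvg_q, hvg_r, ranking = ranking,
                                     top_n = top_n)
  cca <- diagonal_cca(m_query, m_ref, features, n_cc = config$n_cc)
  cca <- align_cc_scores(cca)
  joint <- rbind(cca$scores_a, cca$scores_b)
  perpl <- min(config$transfer_perplexity, floor((nrow(joint) - 2) / 3))
  emb <- embed_2d(joint, perplexity = perpl,
                  seed = derive_seed(config$seed, 21))
  nq <- nrow(cca$scores_a)
  if (config$knn_space == "cca") {
    qc <- cca$scores_a; rc <- cca$scores_b
  } else {
    qc <- emb$coords[seq_len(nq), , drop = FALSE]
    rc <- emb$coords[-seq_len(nq), , drop = FALSE]
  }
  ref_labels <- align_groups(ref_labels, m_ref$cell_ids)
  transfer <- knn_assign(qc, rc, ref_labels,
                         k = min(config$transfer_k, nrow(rc)),
                         min_votes = config$min_votes)
  list(features = features, cca = cca, embedding = emb, transfer = transfer)
}
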