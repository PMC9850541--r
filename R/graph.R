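# KNN-Jaccard graph construction, Louvain community detection, and
# cluster-comparison utilities (mean-profile Pearson similarity and
# contingency tables).

#' Build a Jaccard-weighted k-nearest-neighbour graph
#'
#' Each cell's neighbourhood set is itself plus its k nearest neighbours
#' (Euclidean distance on the supplied coordinates; distance ties broken by
#' stable index order). An edge joins cells i and j when either is in the
#' other's kNN set, weighted by the Jaccard similarity of the two
#' neighbourhood sets — 1.0 for cells with identical neighbourhoods;
#' zero-weight edges are dropped, so all weights lie in (0, 1]. Including
#' the cell in its own set follows the shared-nearest-neighbour convention
#' of the upstream tooling.
#'
#' @param coords cell x d coordinate matrix (2-D embedding or PC scores)
#' @param k neighbourhood size (default 30; must be < number of cells)
#' @return an undirected weighted `igraph` graph with vertex names from
#'   `rownames(coords)`
#' @export
build_knn_jaccard <- function(coords, k = 30) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k >= n) stop("k must be smaller than the number of cells")
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  nn_sets <- lapply(seq_len(n), function(i) sort(c(i, nn[i, ])))
  # candidate edges: all (i, j) with j in kNN(i), deduplicated
  from <- rep(seq_len(n), each = k)
  to <- as.integer(t(nn))
  a <- pmin(from, to); b <- pmax(from, to)
  pair_key <- (a - 1) * n + b
  keep <- !duplicated(pair_key)
  a <- a[keep]; b <- b[keep]
  w <- vapply(seq_along(a), function(e) {
    si <- nn_sets[[a[e]]]; sj <- nn_sets[[b[e]]]
    inter <- length(intersect(si, sj))
    inter / (2 * (k + 1) - inter)
  }, numeric(1))
  nz <- w > 0
  g <- igraph::graph_from_edgelist(cbind(a[nz], b[nz]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w[nz]
  igraph::V(g)$name <- rownames(coords) %||% as.character(seq_len(n))
  g
}

#' Louvain community detection
#'
#' Resolution-scaled modularity maximisation on the weighted graph;
#' deterministic for a fixed seed. Cluster labels are relabelled to
#' consecutive integers ordered by decreasing size, optionally prefixed
#' with a parent-class name when sub-clustering within a cardinal class.
#'
#' @param graph weighted `igraph` graph from [build_knn_jaccard()]
#' @param resolution modularity resolution (default 1; the published
#'   per-class values are NPC 1, ExN 0.1, IN 0.5)
#' @param seed RNG seed
#' @param parent optional parent-class prefix for labels (e.g. "IN" gives
#'   labels "IN_1", "IN_2", ...)
#' @return `ClusterAssignment` data.frame: cell, cluster; parameters in
#'   `attr(, "params")`
#' @export
louvain_cluster <- function(graph, resolution = 1, seed = 0, parent = NULL) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  # canonicalize vertex order by name so the result is invariant to the
  # order cells arrived in
  if (!is.null(igraph::V(graph)$name))
    graph <- igraph::permute(graph, rank(igraph::V(graph)$name,
                                         ties.method = "first"))
  set.seed(seed)
  comm <- igraph::cluster_louvain(graph, resolution = resolution)
  member <- igraph::membership(comm)
  sizes <- sort(table(member), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  lab <- relabel[as.character(member)]
  lab <- if (is.null(parent)) as.character(lab) else paste(parent, lab, sep = "_")
  out <- data.frame(cell = igraph::V(graph)$name, cluster = lab,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "params") <- list(resolution = resolution, seed = seed,
                              parent = parent,
                              modularity = igraph::modularity(comm))
  log_stage("louvain", resolution = resolution,
            clusters = length(unique(lab)))
  out
}

#' Pearson similarity between two clusterings' mean profiles
#'
#' For the top-n highly variable genes, computes each cluster's mean
#' log-normalized expression and returns the Pearson correlation between
#' every cluster of assignment A and every cluster of assignment B.
#' Clusters with fewer than 2 cells are computed but flagged.
#'
#' @param m an `ExpressionMatrix` with norm layer
#' @param clusters_a,clusters_b `ClusterAssignment` data.frames covering the
#'   same cells
#' @param top_n_hvg number of HVGs to use (default 3000, as published)
#' @return `ClusterSimilarityMatrix`: cluster_a x cluster_b correlation
#'   matrix; `attr(, "flagged")` lists clusters with < 2 cells,
#'   `attr(, "n_hvg")` the gene count used
#' @export
cluster_similarity <- function(m, clusters_a, clusters_b, top_n_hvg = 3000) {
  if (!setequal(clusters_a$cell, clusters_b$cell))
    stop("cluster assignments must cover the same cells")
  genes <- select_top_hvg(m, n = top_n_hvg)
  x <- get_layer(m, "norm")[genes, , drop = FALSE]
  mean_profile <- function(cl) {
    labs <- sort(unique(cl$cluster))
    sapply(labs, function(l) rowMeans(x[, cl$cell[cl$cluster == l],
                                        drop = FALSE]))
  }
  pa <- mean_profile(clusters_a)
  pb <- mean_profile(clusters_b)
  sim <- stats::cor(pa, pb)
  small <- c(names(which(table(clusters_a$cluster) < 2)),
             names(which(table(clusters_b$cluster) < 2)))
  attr(sim, "flagged") <- unique(small)
  attr(sim, "n_hvg") <- length(genes)
  class(sim) <- c("ClusterSimilarityMatrix", class(sim))
  sim
}

#' Contingency table between two clusterings
#'
#' @param clusters_a,clusters_b `ClusterAssignment` data.frames over the
#'   same cells
#' @return contingency table (rows = A clusters, columns = B clusters);
#'   total equals the number of cells
#' @export
cross_tabulate <- function(clusters_a, clusters_b) {
  if (!setequal(clusters_a$cell, clusters_b$cell))
    stop("cluster assignments must cover the same cells")
  b <- clusters_b$cluster[match(clusters_a$cell, clusters_b$cell)]
  table(A = clusters_a$cluster, B = b)
}

#' Cluster cells end-to-end
#'
#' Convenience wrapper running the published route: PCA on HVGs, jackstraw,
#' 2-D embedding, KNN-Jaccard graph, Louvain. By default the graph is built
#' on all jackstraw-significant PC scores (`cluster_on = "pca"`, the robust
#' choice given the linear 2-D embedding); `cluster_on = "embedding"`
#' reproduces the published cluster-on-2-D-coordinates route.
#'
#' @param m an `ExpressionMatrix` with norm layer
#' @param hvg_genes gene ids to use for PCA
#' @param config pipeline configuration (default [default_config()])
#' @param parent optional parent-class label prefix
#' @param resolution override for the config resolution
#' @return list: pca, jackstraw, embedding, graph, clusters
#' @export
cluster_cells <- function(m, hvg_genes, config = default_config(),
                          parent = NULL, resolution = NULL) {
  resolution <- resolution %||% config$resolution
  n_pcs <- min(config$n_pcs, length(hvg_genes) - 1, length(m$cell_ids) - 1)
  pca <- run_pca(m, genes = hvg_genes, n_components = n_pcs)
  # the pooled null must be able to resolve alpha: need
  # n_iter * n_perm_genes >~ 3 / alpha draws
  g <- length(pca$genes)
  n_perm_min <- ceiling(3 / (config$jackstraw_alpha * config$jackstraw_iter))
  frac <- max(config$jackstraw_frac, min(n_perm_min, g) / g)
  js <- jackstraw(m, pca, n_iter = config$jackstraw_iter,
                  perm_fraction = frac,
                  alpha = config$jackstraw_alpha,
                  seed = derive_seed(config$seed, 11))
  sig <- which(js$significant)
  if (!length(sig)) sig <- 1L   # degenerate: keep at least PC1
  perpl <- min(config$perplexity, floor((length(m$cell_ids) - 2) / 3))
  emb <- embed_2d(pca$scores, significant = sig, perplexity = perpl,
                  seed = derive_seed(config$seed, 12))
  coords <- if (config$cluster_on == "pca")
    pca$scores[, sig, drop = FALSE] else emb$coords
  graph <- build_knn_jaccard(coords, k = min(config$knn_k,
                                             length(m$cell_ids) - 1))
  clusters <- louvain_cluster(graph, resolution = resolution,
                              seed = derive_seed(config$seed, 13),
                              parent = parent)
  list(pca = pca, jackstraw = js, embedding = emb, graph = graph,
       clusters = clusters)
}
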