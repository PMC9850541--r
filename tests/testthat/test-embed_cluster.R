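# 2-D embedding, KNN-Jaccard graph, Louvain clustering, cluster comparison.

test_that("embedding is deterministic and separates distant populations", {
  pops <- two_pop_matrix(shift = 10, seed = 3)
  pca <- run_pca(pops$matrix, n_components = 5)
  e1 <- embed_2d(pca$scores, perplexity = 10, seed = 1)
  e2 <- embed_2d(pca$scores, perplexity = 10, seed = 1)
  expect_identical(e1$coords, e2$coords)

  # silhouette of the true labels on the embedding (hand-computed)
  d <- as.matrix(dist(e1$coords))
  sil <- vapply(seq_len(nrow(d)), function(i) {
    own <- pops$labels == pops$labels[i]
    a <- mean(d[i, own & seq_along(own) != i])
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)

  expect_error(embed_2d(pca$scores, perplexity = 50), "perplexity")
  expect_error(embed_2d(pca$scores[, 0, drop = FALSE]), "no principal")
})

test_that("KNN-Jaccard weights match brute-force enumeration on a line", {
  coords <- cbind(1:10, 0)
  rownames(coords) <- paste0("p", 1:10)
  g <- build_knn_jaccard(coords, k = 2)
  # independent oracle: recompute kNN sets (self included) and Jaccard
  d <- as.matrix(dist(coords)); diag(d) <- Inf
  knn <- lapply(1:10, function(i) c(i, order(d[i, ])[1:2]))
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  for (e in seq_len(nrow(el))) {
    i <- el[e, 1]; j <- el[e, 2]
    expect_true(j %in% knn[[i]][-1] || i %in% knn[[j]][-1])
    jac <- length(intersect(knn[[i]], knn[[j]])) /
      length(union(knn[[i]], knn[[j]]))
    expect_equal(w[e], jac, tolerance = 1e-12)
  }
  # no zero-weight edges survive
  expect_true(all(w > 0))
})

test_that("identical and disjoint neighbourhoods give weight 1 and no edge", {
  # two tight triplets far apart: within a triplet, neighbourhood sets
  # (self + 2 nearest) coincide exactly -> Jaccard weight 1
  coords <- rbind(c(0, 0), c(0, 0.1), c(0, 0.05),
                  c(100, 0), c(100, 0.1), c(100, 0.05))
  rownames(coords) <- paste0("c", 1:6)
  g <- build_knn_jaccard(coords, k = 2)
  w <- igraph::E(g)$weight
  ends <- igraph::as_edgelist(g)
  left <- c("c1", "c2", "c3")
  within <- (ends[, 1] %in% left) == (ends[, 2] %in% left)
  expect_true(all(within))        # disjoint neighbourhoods never connect
  expect_equal(w, rep(1, length(w)))  # identical sets -> weight exactly 1
  expect_error(build_knn_jaccard(coords, k = 6), "smaller")
})

test_that("Louvain separates components and respects the resolution limit", {
  # two disconnected 5-cliques
  g <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
  igraph::E(g)$weight <- 1
  igraph::V(g)$name <- paste0("v", 1:10)
  for (res in c(0.1, 0.5, 1, 2)) {
    cl <- louvain_cluster(g, resolution = res, seed = 1)
    expect_equal(length(unique(cl$cluster)), 2)
  }
  # resolution -> 0: one cluster per connected component
  cl0 <- louvain_cluster(g, resolution = 1e-4, seed = 1)
  expect_equal(length(unique(cl0$cluster)), 2)
  expect_error(louvain_cluster(igraph::make_empty_graph(0)), "empty")

  # parent prefix produces contiguous labelled clusters
  clp <- louvain_cluster(g, resolution = 0.5, seed = 1, parent = "IN")
  expect_setequal(unique(clp$cluster), c("IN_1", "IN_2"))
})

test_that("Louvain output is invariant to cell order up to relabelling", {
  pops <- two_pop_matrix(n_per = 40, shift = 8, seed = 9)
  pca <- run_pca(pops$matrix, n_components = 4)
  g <- build_knn_jaccard(pca$scores[, 1:2], k = 10)
  cl <- louvain_cluster(g, resolution = 0.5, seed = 2)
  set.seed(33)
  perm <- sample(nrow(pca$scores))
  g2 <- build_knn_jaccard(pca$scores[perm, 1:2], k = 10)
  cl2 <- louvain_cluster(g2, resolution = 0.5, seed = 2)
  merged <- merge(cl, cl2, by = "cell")
  expect_equal(adjusted_rand_index(merged$cluster.x, merged$cluster.y), 1)
})

test_that("cluster similarity is reflexive and permutation invariant", {
  w <- small_world()
  m <- w$sim$matrix
  truth <- w$sim$truth
  cl <- data.frame(cell = truth$cell_id, cluster = truth$true_class)
  sim_ab <- cluster_similarity(m, cl, cl, top_n_hvg = 200)
  expect_equal(unname(diag(sim_ab)), rep(1, nrow(sim_ab)), tolerance = 1e-9)
  expect_true(all(sim_ab >= -1 & sim_ab <= 1))

  # permuting genes identically leaves the matrix unchanged
  set.seed(2)
  perm <- sample(length(m$gene_ids))
  sim_p <- cluster_similarity(m[perm, ], cl, cl, top_n_hvg = 200)
  expect_equal(sim_p, sim_ab, tolerance = 1e-12)

  # clusters with < 2 cells are computed but flagged
  cl2 <- cl
  cl2$cluster[1] <- "singleton"
  cl2$cluster[cl2$cell != cl2$cell[1] & cl2$cluster == "Microglia"] <- "IN"
  sim_f <- cluster_similarity(m, cl2, cl, top_n_hvg = 200)
  expect_true("singleton" %in% attr(sim_f, "flagged"))
})

test_that("similarity orders shared-structure pairs between self and random", {
  # planted: clusters A and B share half their marker structure; C disjoint
  set.seed(21)
  base <- abs(rnorm(120, 1, 0.2))
  mk <- function(idx, n = 25) {
    prof <- base
    prof[idx] <- prof[idx] * 6
    sapply(seq_len(n), function(i) log1p(abs(prof * exp(rnorm(120, 0, 0.1)))))
  }
  xa <- mk(1:20); xb <- mk(11:30); xc <- mk(61:80)
  m <- norm_mat(cbind(xa, xb, xc))
  cl <- data.frame(cell = m$cell_ids,
                   cluster = rep(c("A", "B", "C"), each = 25))
  s <- cluster_similarity(m, cl, cl, top_n_hvg = 120)
  expect_gt(s["A", "B"], s["A", "C"])   # shared structure beats disjoint
  expect_gt(s["A", "A"], s["A", "B"])   # self beats partial overlap
})

test_that("cross tabulation conserves counts", {
  cl_a <- data.frame(cell = paste0("c", 1:30),
                     cluster = rep(c("x", "y", "z"), each = 10))
  tab <- cross_tabulate(cl_a, cl_a)
  expect_equal(sum(tab), 30)
  expect_equal(unname(diag(tab)), c(10L, 10L, 10L), ignore_attr = TRUE)
  expect_equal(sum(tab) - sum(diag(tab)), 0)

  cl_b <- cl_a
  cl_b$cluster <- rev(cl_b$cluster)
  tab2 <- cross_tabulate(cl_a, cl_b)
  expect_equal(rowSums(tab2), c(x = 10, y = 10, z = 10))
  expect_error(cross_tabulate(cl_a, cl_b[1:5, ]), "same cells")
})
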