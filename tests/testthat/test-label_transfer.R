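# Shared features, diagonal CCA, score alignment, KNN voting, composition.

hvg_table_of <- function(genes, selected) {
  data.frame(gene = genes, mean_log_expr = 1, vmr = 1, selected = selected)
}

test_that("shared feature selection intersects and ranks", {
  ha <- hvg_table_of(sprintf("G%02d", 1:20), rep(c(TRUE, FALSE), 10))
  expect_setequal(select_shared_features(ha, ha),
                  sprintf("G%02d", seq(1, 19, 2)))
  hb <- hvg_table_of(sprintf("G%02d", 1:20), rep(c(FALSE, TRUE), 10))
  expect_error(select_shared_features(ha, hb), "no shared")

  ranking <- setNames(seq(10, 1), sprintf("G%02d", seq(1, 19, 2)))
  ranked <- select_shared_features(ha, ha, ranking = ranking, top_n = 3)
  expect_equal(as.character(ranked[1:3]), c("G01", "G03", "G05"))
})

test_that("discriminability ranks planted markers above background", {
  set.seed(14)
  n_per <- 30
  markers <- sprintf("M%02d", 1:5)
  noise <- sprintf("N%02d", 1:20)
  prof <- function(type) {
    mu <- c(setNames(rep(1, 5), markers), setNames(rep(1, 20), noise))
    if (type == "a") mu[markers] <- 6
    mu
  }
  x <- cbind(sapply(seq_len(n_per), function(i) log1p(rpois(25, prof("a")))),
             sapply(seq_len(n_per), function(i) log1p(rpois(25, prof("b")))))
  m <- norm_mat(x, genes = c(markers, noise))
  disc <- feature_discriminability(m, rep(c("a", "b"), each = n_per))
  expect_true(min(disc[markers]) > max(disc[noise]))
})

test_that("diagonal CCA: self-correspondence, null bound, SVD oracle", {
  set.seed(3)
  mk <- function(n_cells, prefix) {
    x <- matrix(abs(rnorm(200 * n_cells)), 200, n_cells)
    norm_mat(x, genes = sprintf("G%03d", 1:200),
             cells = sprintf("%s%03d", prefix, seq_len(n_cells)))
  }
  a <- mk(100, "a"); b <- mk(100, "b")
  # identical datasets: first canonical correlation is exactly 1
  cc_self <- diagonal_cca(a, a, a$gene_ids, n_cc = 4)
  expect_equal(cc_self$correlations[1], 1, tolerance = 1e-6)
  # independent data: all canonical correlations below 0.6
  cc_null <- diagonal_cca(a, b, a$gene_ids, n_cc = 4)
  expect_true(all(cc_null$correlations < 0.6))
  expect_true(all(diff(cc_null$correlations) <= 1e-12))
  expect_error(diagonal_cca(a, b, a$gene_ids, n_cc = 400), "n_cc")

  # 10 genes x 8 cells toy: scores equal the direct SVD of the cross-product
  set.seed(9)
  xa <- abs(matrix(rnorm(10 * 8), 10, 8))
  xb <- abs(matrix(rnorm(10 * 6), 10, 6))
  ta <- norm_mat(xa, genes = paste0("g", 1:10))
  tb <- norm_mat(xb, genes = paste0("g", 1:10), cells = paste0("r", 1:6))
  cc <- diagonal_cca(ta, tb, paste0("g", 1:10), n_cc = 3)
  za <- t(scale(t(xa))); zb <- t(scale(t(xb)))
  sv <- svd(t(za) %*% zb)
  expect_equal(abs(unname(cc$scores_a)), abs(sv$u[, 1:3]), tolerance = 1e-8)
  expect_equal(abs(unname(cc$scores_b)), abs(sv$v[, 1:3]), tolerance = 1e-8)
})

test_that("quantile alignment equalises distributions and keeps ranks", {
  set.seed(4)
  mk <- function(x, prefix) {
    dimnames(x) <- list(NULL, paste0("CC", 1:2))
    rownames(x) <- sprintf("%s%03d", prefix, seq_len(nrow(x)))
    x
  }
  cca <- structure(list(
    scores_a = mk(cbind(rnorm(150), rnorm(150)), "a"),
    scores_b = mk(cbind(rnorm(150) + 5, rnorm(150)), "b"),
    correlations = c(1, 1), n_cc = 2, features = "x"),
    class = "CCAScores")
  al <- align_cc_scores(cca)
  # the +5 shift on CC1 vanishes: means differ by < 0.05 pooled SD
  pooled_sd <- stats::sd(c(al$scores_a[, 1], al$scores_b[, 1]))
  expect_lt(abs(mean(al$scores_a[, 1]) - mean(al$scores_b[, 1])),
            0.05 * pooled_sd)
  # within-dataset rank order preserved exactly
  expect_equal(order(al$scores_a[, 1]), order(cca$scores_a[, 1]))
  expect_equal(order(al$scores_b[, 2]), order(cca$scores_b[, 2]))
  # identical distributions: alignment is near-identity
  cca2 <- cca; cca2$scores_b <- cca2$scores_a
  al2 <- align_cc_scores(cca2)
  expect_equal(al2$scores_a, cca2$scores_a, tolerance = 0.05)
})

test_that("KNN voting implements the published rule exactly", {
  # geometry realising vote multisets: rings of reference cells at
  # increasing distance from the query at the origin
  ring <- function(n, radius) {
    th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
    cbind(radius * cos(th), radius * sin(th))
  }
  ref <- rbind(ring(20, 1), ring(6, 2), ring(3, 3), ring(1, 4), ring(10, 50))
  labels <- c(rep("SST", 20), rep("PV", 6), rep("VIP", 3), rep("NG", 1),
              rep("FAR", 10))
  q <- matrix(0, 1, 2, dimnames = list("q1", NULL))

  tt <- knn_assign(q, ref, labels, k = 30, min_votes = 5)
  expect_equal(tt$assigned, "SST")     # {SST:20, PV:6, VIP:3, NG:1}
  expect_equal(tt$reason, "ok")
  expect_equal(sum(as.matrix(tt[, grep("^votes_", names(tt))])), 30)

  # top count below min_votes -> UNASSIGNED (unique maximum of 4)
  ref2 <- rbind(ring(4, 1), ring(3, 2), ring(3, 2.5), ring(3, 3),
                ring(3, 3.5), ring(14, 9))
  lab2 <- c(rep("a", 4), rep("b", 3), rep("c", 3), rep("d", 3), rep("e", 3),
            rep("far", 14))
  t2 <- knn_assign(q, ref2, lab2, k = 16, min_votes = 5)
  expect_equal(t2$assigned, "UNASSIGNED")
  expect_equal(t2$reason, "below_min_votes")

  # equal top counts -> UNASSIGNED(tie)
  ref3 <- rbind(ring(12, 1), ring(12, 2), ring(6, 3))
  lab3 <- c(rep("SST", 12), rep("PV", 12), rep("VIP", 6))
  t3 <- knn_assign(q, ref3, lab3, k = 30, min_votes = 5)
  expect_equal(t3$reason, "tie")

  expect_error(knn_assign(q, ref3[1:10, ], lab3[1:10], k = 30), "fewer")
})

test_that("knn_assign agrees with a brute-force rule on vote multisets", {
  # independent reimplementation of the voting rule
  oracle_rule <- function(votes, min_votes) {
    top <- max(votes)
    winners <- names(votes)[votes == top]
    if (length(winners) > 1) "tie"
    else if (top < min_votes) "below_min_votes"
    else winners
  }
  set.seed(15)
  ring <- function(n, radius) {
    th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
    cbind(radius * cos(th), radius * sin(th))
  }
  q <- matrix(0, 1, 2, dimnames = list("q", NULL))
  for (i in 1:30) {
    # random composition of k = 30 votes over 4 labels
    cuts <- sort(sample(0:30, 3, replace = TRUE))
    comp <- diff(c(0, cuts, 30))
    names(comp) <- c("w", "x", "y", "z")
    comp <- comp[comp > 0]
    ref <- do.call(rbind, lapply(seq_along(comp), function(j)
      ring(comp[j], j)))
    labels <- rep(names(comp), comp)
    pad <- ring(10, 99)
    tt <- knn_assign(q, rbind(ref, pad), c(labels, rep("pad", 10)),
                     k = 30, min_votes = 5)
    expected <- oracle_rule(comp, 5)
    got <- if (tt$assigned == "UNASSIGNED") tt$reason else tt$assigned
    expect_equal(got, expected, label = paste(comp, collapse = "/"))
  }
})

test_that("composition summary conserves proportions", {
  tt <- data.frame(cell = paste0("c", 1:12),
                   assigned = c(rep("SST", 8), rep("UNASSIGNED", 4)),
                   reason = c(rep("ok", 8), rep("tie", 4)))
  class(tt) <- c("TransferTable", class(tt))
  comp <- composition_summary(tt, rep(c("k1", "k2"), each = 6))
  agg <- tapply(comp$proportion, comp$cluster, sum)
  expect_equal(as.numeric(agg), c(1, 1), tolerance = 1e-9)
  all_sst <- tt; all_sst$assigned <- "SST"
  comp2 <- composition_summary(all_sst, rep("k1", 12))
  expect_equal(comp2$proportion[comp2$type == "SST"], 1)
})
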