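# One-vs-rest Wilcoxon rank-sum differential expression with
# detection-fraction gating, log fold-change filtering, multiple-testing
# adjustment, and risk-gene-set summaries.

#' One-vs-rest Wilcoxon differential expression
#'
#' For each group, each gene is compared between the group's cells and all
#' remaining cells with the Wilcoxon rank-sum (Mann-Whitney) test. A gene
#' is tested only when it is detected (norm > 0) in at least `min_frac` of
#' cells in either population; untested genes carry `p = NA`. P-values come
#' from the tie- and continuity-corrected normal approximation, or from
#' exact enumeration
#' of rank splits when both group sizes are at most `exact_max`. Log
#' fold-changes use [log_fold_change()]; `p_adj` is adjusted per group over
#' tested genes. A gene is `significant` when it was tested,
#' `p_adj < alpha` and `log_fc > lfc_threshold`.
#'
#' @param m an `ExpressionMatrix` with norm layer
#' @param groups vector of group labels, one per cell (names or order must
#'   match `m$cell_ids`)
#' @param min_frac detection-fraction gate (default 0.33)
#' @param alpha significance level on adjusted p (default 0.05)
#' @param lfc_threshold natural-log fold-change threshold (default 0.33;
#'   the figure-legend value 0.3 is one argument away)
#' @param p_adjust "bonferroni" (default) or "bh"
#' @param exact_max maximum group size for the exact enumeration route
#'   (default 8)
#' @return `DETable` data.frame with columns gene, cluster, p, p_adj,
#'   log_fc, pct_in, pct_out, tested, significant
#' @export
wilcoxon_one_vs_rest <- function(m, groups, min_frac = 0.33, alpha = 0.05,
                                 lfc_threshold = 0.33,
                                 p_adjust = c("bonferroni", "bh"),
                                 exact_max = 8) {
  p_adjust <- match.arg(p_adjust)
  x <- get_layer(m, "norm")
  groups <- align_groups(groups, m$cell_ids)
  labs <- sort(unique(groups))
  if (length(labs) < 2) stop("need at least 2 groups")
  n_all <- ncol(x)
  sizes <- table(groups)
  usable <- names(sizes)[sizes >= 2]
  skipped <- setdiff(labs, usable)
  if (length(skipped))
    warning("groups with fewer than 2 cells skipped: ",
            paste(skipped, collapse = ", "))

  ranks <- t(apply(x, 1, rank))          # combined ranks once per gene
  tie_term <- apply(x, 1, function(v) {
    t <- rle(sort(v))$lengths
    sum(t^3 - t)
  })
  detected <- x > 0

  res <- lapply(usable, function(g) {
    in_idx <- which(groups == g)
    n1 <- length(in_idx); n2 <- n_all - n1
    pct_in <- rowMeans(detected[, in_idx, drop = FALSE])
    pct_out <- rowMeans(detected[, -in_idx, drop = FALSE])
    tested <- pct_in >= min_frac | pct_out >= min_frac
    w <- rowSums(ranks[, in_idx, drop = FALSE])
    u <- w - n1 * (n1 + 1) / 2
    p <- rep(NA_real_, nrow(x))
    if (n1 <= exact_max && n2 <= exact_max) {
      for (i in which(tested))
        p[i] <- wilcox_exact_p(x[i, in_idx], x[i, -in_idx])
    } else {
      mu <- n1 * n2 / 2
      sigma <- sqrt(n1 * n2 / 12 *
                      ((n_all + 1) - tie_term / (n_all * (n_all - 1))))
      # continuity-corrected two-sided normal approximation
      z <- pmax(abs(u - mu) - 0.5, 0) / sigma
      p_norm <- pmin(1, 2 * stats::pnorm(-z))
      p_norm[sigma == 0] <- 1   # all values tied
      p[tested] <- p_norm[tested]
    }
    lfc <- log_fold_change_vec(x, in_idx)
    data.frame(gene = m$gene_ids, cluster = g, p = p,
               pct_in = pct_in, pct_out = pct_out, log_fc = lfc,
               tested = tested, stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  for (g in usable) {
    sel <- out$cluster == g
    out$p_adj[sel] <- adjust_pvalues(out$p[sel], method = p_adjust)
  }
  out$significant <- !is.na(out$p_adj) & out$tested &
    out$p_adj < alpha & out$log_fc > lfc_threshold
  attr(out, "params") <- list(min_frac = min_frac, alpha = alpha,
                              lfc_threshold = lfc_threshold,
                              p_adjust = p_adjust)
  class(out) <- c("DETable", class(out))
  out
}

# Match a labelled or ordered group vector to cell ids.
align_groups <- function(groups, cell_ids) {
  if (!is.null(names(groups))) {
    if (!all(cell_ids %in% names(groups)))
      stop("groups are named but do not cover all cells")
    return(as.character(groups[cell_ids]))
  }
  if (length(groups) != length(cell_ids))
    stop("groups length does not match cell count")
  as.character(groups)
}

# Exact two-sided Wilcoxon p by enumeration of all rank splits; handles
# ties because enumeration acts on the observed (possibly tied) ranks.
wilcox_exact_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[splits], nrow = n1)) - n1 * (n1 + 1) / 2
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# logFC for one group against the rest, vectorized over genes.
log_fold_change_vec <- function(x, in_idx) {
  mean_in <- rowMeans(expm1(x[, in_idx, drop = FALSE]))
  mean_out <- rowMeans(expm1(x[, -in_idx, drop = FALSE]))
  log(mean_in + 1) - log(mean_out + 1)
}

#' Log fold-change of each group against the rest
#'
#' `logFC = ln(mean(expm1(norm_in)) + 1) - ln(mean(expm1(norm_out)) + 1)`:
#' means are taken on the linear scale, a pseudocount of 1 stabilises genes
#' absent from one side, and the difference is on the natural-log scale.
#'
#' @param m an `ExpressionMatrix` with norm layer
#' @param groups group labels (as in [wilcoxon_one_vs_rest()])
#' @return gene x group matrix of log fold-changes
#' @export
log_fold_change <- function(m, groups) {
  x <- get_layer(m, "norm")
  groups <- align_groups(groups, m$cell_ids)
  labs <- sort(unique(groups))
  out <- sapply(labs, function(g) log_fold_change_vec(x, which(groups == g)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(x),
                                     dimnames = list(NULL, labs))
  rownames(out) <- m$gene_ids
  out
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni (`min(1, p * m)`) or Benjamini-Hochberg step-up with monotone
#' enforcement, where `m` counts the non-NA p-values; NA entries propagate
#' NA.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed)
#' @param method "bonferroni" or "bh"
#' @return adjusted p-values, same length and order as `p`
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok],
                             method = if (method == "bh") "BH" else "bonferroni")
  out
}

#' Summarise differential expression of risk gene sets
#'
#' For each gene set: how many of its genes are present/tested in the
#' matrix, how many are significant in at least one group, a per-group
#' breakdown, and a row-scaled (zero mean, unit variance) per-group mean
#' expression matrix for heatmap export. Counts are reported against the
#' full set size (genes absent from the matrix are listed, not silently
#' dropped from the denominator).
#'
#' @param de a `DETable` from [wilcoxon_one_vs_rest()]
#' @param sets a `GeneSetCollection` (or single `GeneSet`)
#' @param m the `ExpressionMatrix` the DE was computed on
#' @param groups the grouping used for the DE
#' @return `RiskSummary`: named list per set with n_in_set, n_present,
#'   n_tested, n_significant, missing_genes, significant_genes, per_group
#'   counts and `heatmap` matrix
#' @export
summarise_risk_sets <- function(de, sets, m, groups) {
  if (inherits(sets, "GeneSet")) {
    sets <- structure(setNames(list(sets), sets$name),
                      class = "GeneSetCollection")
  }
  x <- get_layer(m, "norm")
  groups <- align_groups(groups, m$cell_ids)
  labs <- sort(unique(groups))
  group_means <- sapply(labs, function(g)
    rowMeans(x[, groups == g, drop = FALSE]))
  out <- lapply(sets, function(s) {
    genes <- s$genes
    present <- intersect(genes, m$gene_ids)
    d <- de[de$gene %in% present, , drop = FALSE]
    tested_genes <- unique(d$gene[d$tested])
    sig <- d[d$significant, , drop = FALSE]
    per_group <- table(factor(sig$cluster, levels = labs))
    hm <- NULL
    if (length(present)) {
      hm <- group_means[present, , drop = FALSE]
      sdv <- apply(hm, 1, stats::sd)
      hm <- (hm - rowMeans(hm)) / ifelse(sdv > 0, sdv, 1)
    }
    flagged <- length(present) == 0
    list(name = s$name, n_in_set = length(genes),
         n_present = length(present), n_tested = length(tested_genes),
         n_significant = length(unique(sig$gene)),
         significant_genes = sort(unique(sig$gene)),
         missing_genes = setdiff(genes, present),
         per_group = as.list(per_group), heatmap = hm, flagged = flagged)
  })
  structure(out, class = "RiskSummary")
}
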