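# QC filters, blacklist exclusion, library-size normalization and
# highly-variable-gene selection.
#
# Boundary conventions follow the published filters exactly: "less than"
# removals are strict, "between" windows are inclusive.

qc_report <- function(step, before, after, extra = list()) {
  c(list(step = step,
         genes_in = before[1], cells_in = before[2],
         genes_out = after[1], cells_out = after[2]),
    extra)
}

#' Remove cells expressing too few genes
#'
#' A gene is "expressed" in a cell when its value is > 0 (counts layer when
#' present, otherwise norm). Cells expressing fewer than `min_genes` genes
#' are removed (strict less-than; a cell at exactly `min_genes` is kept).
#'
#' @param m an `ExpressionMatrix`
#' @param min_genes threshold (default 1000)
#' @return list(matrix, report)
#' @export
filter_cells <- function(m, min_genes = 1000) {
  x <- m$counts %||% m$norm
  n_expressed <- colSums(x > 0)
  keep <- n_expressed >= min_genes
  if (!any(keep)) stop("filter_cells removed every cell (min_genes = ",
                       min_genes, ")")
  out <- m[, keep]
  out <- add_provenance(out, sprintf("filter_cells(min_genes=%d): %d -> %d cells",
                                     min_genes, ncol(x), sum(keep)))
  log_stage("filter_cells", min_genes = min_genes,
            cells_in = ncol(x), cells_out = sum(keep))
  list(matrix = out,
       report = qc_report("filter_cells", dim(m), dim(out),
                          list(min_genes = min_genes)))
}

#' Remove genes detected in too few cells
#'
#' A gene is retained iff it reaches at least `min_value` normalized
#' expression in at least `min_cells` cells (the published rule: genes
#' "expressed by less than 3 cells at less than 1 normalized expression
#' value" are removed).
#'
#' @param m an `ExpressionMatrix` with a norm layer
#' @param min_cells minimum qualifying cells (default 3)
#' @param min_value minimum normalized value to qualify (default 1.0)
#' @return list(matrix, report)
#' @export
filter_genes <- function(m, min_cells = 3, min_value = 1.0) {
  x <- get_layer(m, "norm")
  keep <- rowSums(x >= min_value) >= min_cells
  out <- m[keep, ]
  out <- add_provenance(out,
    sprintf("filter_genes(min_cells=%d, min_value=%g): %d -> %d genes",
            min_cells, min_value, nrow(x), sum(keep)))
  log_stage("filter_genes", min_cells = min_cells, min_value = min_value,
            genes_in = nrow(x), genes_out = sum(keep))
  list(matrix = out,
       report = qc_report("filter_genes", dim(m), dim(out),
                          list(min_cells = min_cells, min_value = min_value)))
}

#' Default blacklist regex patterns per category
#'
#' Pseudogenes, miRNA, rRNA, mitochondrial and ribosomal genes are excluded
#' from analysis; the default anchored patterns avoid false hits such as
#' MTOR (`^MT-` requires the hyphen).
#' @return named list of regex vectors
#' @export
default_blacklist <- function() {
  list(mito = "^MT-", miRNA = "^MIR", ribo = c("^RPL", "^RPS"),
       rRNA = "^RNA5", pseudogene = character())
}

#' Exclude blacklisted genes
#'
#' @param m an `ExpressionMatrix`
#' @param patterns named list of regex vectors per category
#'   (default [default_blacklist()])
#' @param explicit_ids extra gene ids to drop (category "explicit")
#' @return list(matrix, report); report carries per-category hit counts
#' @export
exclude_blacklist <- function(m, patterns = default_blacklist(),
                              explicit_ids = character()) {
  hits <- setNames(vector("list", length(patterns)), names(patterns))
  for (cat in names(patterns)) {
    matched <- character()
    for (p in patterns[[cat]]) {
      ok <- tryCatch(suppressWarnings(grepl(p, m$gene_ids)),
                     error = function(e)
        stop("blacklist regex failed to compile for category '", cat, "': ",
             conditionMessage(e)))
      matched <- union(matched, m$gene_ids[ok])
    }
    hits[[cat]] <- matched
  }
  hits$explicit <- intersect(explicit_ids, m$gene_ids)
  drop <- unique(unlist(hits))
  keep <- !(m$gene_ids %in% drop)
  out <- m[keep, ]
  out <- add_provenance(out, sprintf("exclude_blacklist: dropped %d genes",
                                     length(drop)))
  log_stage("exclude_blacklist", dropped = length(drop))
  list(matrix = out,
       report = qc_report("exclude_blacklist", dim(m), dim(out),
                          list(hits_per_category = lapply(hits, length))))
}

#' Library-size normalize counts
#'
#' `norm[g,c] = log(1 + counts[g,c] / libsize_c * scale_factor)` with the
#' natural log and `libsize_c` the cell's total counts. The published
#' analysis does not restate its normalization formula; this log1p of
#' library-size-scaled counts is the field's standard, and the downstream
#' rank statistics are invariant to the monotone choice.
#'
#' @param m an `ExpressionMatrix` with counts
#' @param scale_factor scale (default 10000)
#' @return the matrix with a `norm` layer added
#' @export
normalize_counts <- function(m, scale_factor = 10000) {
  x <- get_layer(m, "counts")
  libsize <- colSums(x)
  if (any(libsize == 0))
    stop("zero library size for cell(s): ",
         paste(utils::head(m$cell_ids[libsize == 0], 5), collapse = ", "))
  m$norm <- log1p(sweep(x, 2, libsize, "/") * scale_factor)
  add_provenance(m, sprintf("normalize_counts(scale_factor=%g)", scale_factor))
}

#' Select highly variable genes by mean / VMR window
#'
#' For each gene: `mean_log_expr` is the mean of the log-scale normalized
#' values; VMR is the variance-to-mean ratio of the linear-scale normalized
#' values (`expm1(norm)`). A gene is selected when its mean lies inside
#' `[mean_min, mean_max]` (inclusive) and its VMR falls on the configured
#' side of `vmr_cut` (strict). The published thresholds select VMR *below*
#' the cutoff; `vmr_side = "above"` gives the conventional high-dispersion
#' direction. Zero-variance genes (and genes with undefined VMR) are never
#' selected.
#'
#' @param m an `ExpressionMatrix` with norm layer
#' @param mean_min,mean_max inclusive window on mean log expression
#'   (defaults 1 and 8; the published per-class windows are NPC 0.5–8,
#'   ExN/IN 1–10 with cut 0.5)
#' @param vmr_cut VMR threshold (default 1.2)
#' @param vmr_side "below" (as published) or "above"
#' @return `HVGTable` data.frame: gene, mean_log_expr, vmr, selected; the
#'   parameters used are stored in `attr(, "params")`
#' @export
select_hvg <- function(m, mean_min = 1, mean_max = 8, vmr_cut = 1.2,
                       vmr_side = c("below", "above")) {
  vmr_side <- match.arg(vmr_side)
  x <- get_layer(m, "norm")
  mean_log <- rowMeans(x)
  lin <- expm1(x)
  mu <- rowMeans(lin)
  v <- row_vars(lin)
  vmr <- ifelse(mu > 0, v / mu, NA_real_)
  in_window <- mean_log >= mean_min & mean_log <= mean_max
  vmr_ok <- !is.na(vmr) & v > 0 &
    (if (vmr_side == "below") vmr < vmr_cut else vmr > vmr_cut)
  selected <- in_window & vmr_ok
  if (!any(selected))
    stop("select_hvg selected no genes; review mean window [", mean_min, ", ",
         mean_max, "] and vmr_cut ", vmr_cut, " (side = ", vmr_side, ")")
  out <- data.frame(gene = m$gene_ids, mean_log_expr = mean_log, vmr = vmr,
                    selected = selected, row.names = NULL)
  attr(out, "params") <- list(mean_min = mean_min, mean_max = mean_max,
                              vmr_cut = vmr_cut, vmr_side = vmr_side)
  log_stage("select_hvg", selected = sum(selected), of = nrow(out))
  out
}

#' Top-n genes by variability
#'
#' Conventional "top N HVG" ranking (highest VMR within a mean window),
#' used by the cluster-similarity comparison which the published analysis
#' runs on the top 3000 HVGs.
#'
#' @param m an `ExpressionMatrix` with norm layer
#' @param n number of genes
#' @param mean_min lower bound on mean log expression (default 0, i.e. any
#'   detected gene)
#' @return character vector of gene ids, highest VMR first
#' @export
select_top_hvg <- function(m, n = 3000, mean_min = 0) {
  x <- get_layer(m, "norm")
  mean_log <- rowMeans(x)
  lin <- expm1(x)
  mu <- rowMeans(lin)
  v <- row_vars(lin)
  vmr <- ifelse(mu > 0, v / mu, -Inf)
  vmr[mean_log < mean_min] <- -Inf
  ord <- order(vmr, decreasing = TRUE)
  m$gene_ids[ord[seq_len(min(n, sum(is.finite(vmr) & vmr > -Inf)))]]
}
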