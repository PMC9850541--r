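# Pipeline configuration: every stage parameter with its default, validated
# against legal ranges at load time. Config files are JSON; values given in
# the file override defaults, everything else stays at its default.

#' Default pipeline configuration
#'
#' Returns the full parameter list with defaults taken from the published
#' analysis where stated (cell/gene filters, HVG windows, jackstraw settings,
#' per-class clustering resolutions, DE thresholds, KNN voting rule, number
#' of canonical components) and from the documented design choices otherwise.
#'
#' @return named list of parameters
#' @export
default_config <- function() {
  list(
    # preprocessing
    min_genes_per_cell = 1000,
    min_cells_per_gene = 3,
    min_norm_value = 1.0,
    scale_factor = 10000,
    hvg_mean_min = 1, hvg_mean_max = 8,
    hvg_vmr_cut = 1.2, hvg_vmr_side = "below",
    hvg_top_n = NULL,              # when set, cluster on the top-n HVGs
                                   # instead of the window rule

    # dimensionality reduction / clustering
    n_pcs = 20,
    jackstraw_iter = 100, jackstraw_frac = 0.01, jackstraw_alpha = 0.01,
    perplexity = 20,
    knn_k = 30,
    resolution = 0.5,              # whole-dataset default: favours cardinal-
                                   # class granularity; per-class blocks below
                                   # use the published values
    cluster_on = "pca",            # "pca" (robust default) or "embedding"
    # per-cardinal-class sub-clustering blocks (class, hvg params, resolution)
    subcluster = list(
      list(class = "NPC", hvg_mean_min = 0.5, hvg_mean_max = 8,
           hvg_vmr_cut = 1.2, resolution = 1.0),
      list(class = "ExN", hvg_mean_min = 1, hvg_mean_max = 10,
           hvg_vmr_cut = 0.5, resolution = 0.1),
      list(class = "IN", hvg_mean_min = 1, hvg_mean_max = 10,
           hvg_vmr_cut = 0.5, resolution = 0.5)
    ),
    # differential expression
    de_min_frac = 0.33,
    de_lfc = 0.33,
    de_alpha = 0.05,
    p_adjust = "bonferroni",
    # label transfer
    transfer_k = 30, min_votes = 5, n_cc = 4,
    transfer_perplexity = 40,
    knn_space = "cca",             # "cca" (robust default) or "embedding"
    seed = 0
  )
}

#' Validate a pipeline configuration
#'
#' Checks every numeric parameter against its legal range and the
#' enumerated parameters against their vocabularies; stops with the name of
#' the first offending parameter.
#'
#' @param cfg named list as returned by [default_config()]
#' @return `cfg`, invisibly
#' @export
validate_config <- function(cfg) {
  chk <- function(name, ok) {
    if (!isTRUE(ok)) stop("invalid config parameter '", name, "'")
  }
  num <- function(name, lo = -Inf, hi = Inf, strict_lo = FALSE) {
    v <- cfg[[name]]
    chk(name, is.numeric(v) && length(v) == 1 && is.finite(v) &&
          (if (strict_lo) v > lo else v >= lo) && v <= hi)
  }
  num("min_genes_per_cell", 0)
  num("min_cells_per_gene", 0)
  num("min_norm_value", 0)
  num("scale_factor", 0, strict_lo = TRUE)
  num("hvg_mean_min"); num("hvg_mean_max")
  chk("hvg_mean_max", cfg$hvg_mean_max >= cfg$hvg_mean_min)
  num("hvg_vmr_cut", 0)
  chk("hvg_vmr_side", cfg$hvg_vmr_side %in% c("below", "above"))
  if (!is.null(cfg$hvg_top_n)) num("hvg_top_n", 1)
  num("n_pcs", 1)
  num("jackstraw_iter", 1)
  num("jackstraw_frac", 0, 1, strict_lo = TRUE)
  num("jackstraw_alpha", 0, 1, strict_lo = TRUE)
  num("perplexity", 1)
  num("knn_k", 1)
  num("resolution", 0, strict_lo = TRUE)
  num("de_min_frac", 0, 1)
  num("de_lfc", 0)
  num("de_alpha", 0, 1, strict_lo = TRUE)
  chk("p_adjust", cfg$p_adjust %in% c("bonferroni", "bh"))
  num("transfer_k", 1)
  num("min_votes", 1)
  num("n_cc", 1)
  num("transfer_perplexity", 1)
  chk("knn_space", cfg$knn_space %in% c("cca", "embedding"))
  chk("cluster_on", cfg$cluster_on %in% c("pca", "embedding"))
  num("seed", 0, .Machine$integer.max)
  for (blk in cfg$subcluster) {
    chk("subcluster.class", is.character(blk$class) && nzchar(blk$class))
    chk("subcluster.resolution",
        is.numeric(blk$resolution) && blk$resolution > 0)
  }
  invisible(cfg)
}

#' Read a JSON configuration file
#'
#' Values present in the file override [default_config()]; the merged
#' configuration is validated before it is returned.
#'
#' @param path JSON file path, or NULL for pure defaults
#' @return validated configuration list
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (k in names(user)) {
      if (k == "subcluster") {
        # keep list-of-blocks shape whether JSON gave a data.frame or list
        blk <- user[[k]]
        if (is.data.frame(blk)) blk <- split(blk, seq_len(nrow(blk)))
        cfg[[k]] <- lapply(blk, as.list)
      } else cfg[[k]] <- user[[k]]
    }
  }
  validate_config(cfg)
  cfg
}
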