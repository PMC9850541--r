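# Synthetic single-cell data generator: negative-binomial counts over
# planted cardinal classes, nested subclusters within one class, and one
# "vulnerable" subcluster with elevated expression of a designated risk
# gene set. A paired "adult reference" dataset reuses the type signatures
# under a per-gene batch shift. Ground truth is always produced.

#' Simulation specification
#'
#' Defines the stated world the generator emulates: six cardinal classes of
#' developing cortex at realistic proportions, subclusters nested in the IN
#' class, and a vulnerable IN subcluster whose only distinguishing signature
#' is elevated expression of the planted risk gene set (mirroring a
#' population defined by risk-set enrichment rather than by its own marker
#' program). Counts are negative-binomial with a shared dispersion and
#' lognormal library sizes; all means are on the natural-log scale where
#' logged.
#'
#' @param n_genes,n_cells matrix dimensions
#' @param class_proportions named numeric vector summing to 1; names define
#'   the classes
#' @param n_subclusters named integer vector: subclusters per class
#'   (classes omitted get 1)
#' @param marker_genes_per_class markers planted per class
#' @param marker_log_fc marker elevation, natural-log scale (default ln 4)
#' @param subcluster_marker_genes markers planted per non-vulnerable
#'   subcluster (the vulnerable one is defined by the risk set instead)
#' @param risk_set_size number of planted risk genes
#' @param risk_log_fc mean risk-gene elevation in the vulnerable
#'   subcluster, natural-log scale
#' @param risk_log_fc_sd lognormal spread of the per-gene risk effect
#'   around `risk_log_fc` (mean-preserving; 0 gives a uniform shift).
#'   Real risk transcripts are elevated to varying degrees, and a strictly
#'   uniform shift would leave the within-set expression ranking — and
#'   hence correlation-based neighbour voting — unchanged
#' @param vulnerable_subcluster list(class=, index=) naming the vulnerable
#'   population
#' @param baseline_log_mean,baseline_log_sd lognormal baseline mean
#'   parameters for background genes
#' @param marker_baseline_log_mean,marker_baseline_log_sd lognormal baseline
#'   parameters for structured genes (class/subcluster markers and risk
#'   genes); the defaults place markers in the detectably-expressed range,
#'   as real marker genes are
#' @param nb_dispersion negative-binomial size parameter (shared across
#'   genes); larger is closer to Poisson
#' @param dispersion_per_gene optional numeric vector overriding
#'   `nb_dispersion` gene by gene
#' @param libsize_log_mean,libsize_log_sd lognormal library-size factor
#'   parameters
#' @param batch_shift_sd SD of the per-gene log-mean shift applied to the
#'   reference dataset
#' @param seed integer seed for all randomized steps
#' @return validated `SimSpec` list
#' @export
sim_spec <- function(n_genes = 2000, n_cells = 2000,
                     class_proportions = c(NPC = 0.20, ExN = 0.35, IN = 0.25,
                                           OPC = 0.08, Astrocyte = 0.08,
                                           Microglia = 0.04),
                     n_subclusters = c(IN = 2),
                     marker_genes_per_class = 25,
                     marker_log_fc = log(4),
                     subcluster_marker_genes = 10,
                     risk_set_size = 50,
                     risk_log_fc = 1.0,
                     risk_log_fc_sd = 0.4,
                     vulnerable_subcluster = list(class = "IN", index = 1),
                     baseline_log_mean = 0, baseline_log_sd = 1,
                     marker_baseline_log_mean = 1,
                     marker_baseline_log_sd = 0.5,
                     nb_dispersion = 2,
                     dispersion_per_gene = NULL,
                     libsize_log_mean = 0, libsize_log_sd = 0.3,
                     batch_shift_sd = 0.3,
                     seed = 0) {
  spec <- as.list(environment())
  validate_sim_spec(spec)
  class(spec) <- "SimSpec"
  spec
}

validate_sim_spec <- function(spec) {
  with(spec, {
    if (abs(sum(class_proportions) - 1) > 1e-9)
      stop("class_proportions must sum to 1")
    if (is.null(names(class_proportions)) || anyDuplicated(names(class_proportions)))
      stop("class_proportions must have unique names")
    if (any(class_proportions <= 0)) stop("class proportions must be positive")
    if (n_genes < 1 || n_cells < 1) stop("n_genes and n_cells must be >= 1")
    if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
    if (!is.null(dispersion_per_gene) &&
        (length(dispersion_per_gene) != n_genes || any(dispersion_per_gene <= 0)))
      stop("dispersion_per_gene must be length n_genes and positive")
    if (length(n_subclusters) &&
        !all(names(n_subclusters) %in% names(class_proportions)))
      stop("n_subclusters names must be classes")
    if (!vulnerable_subcluster$class %in% names(class_proportions))
      stop("vulnerable_subcluster class unknown")
    if (risk_set_size < 0 || marker_genes_per_class < 0 ||
        subcluster_marker_genes < 0)
      stop("gene-count parameters must be >= 0")
    if (libsize_log_sd < 0 || batch_shift_sd < 0) stop("SDs must be >= 0")
  })
  invisible(spec)
}

# Population bookkeeping: population = class_subindex ("IN_1", "IN_2") for
# classes with nested subclusters, the bare class name otherwise.
sim_populations <- function(spec) {
  classes <- names(spec$class_proportions)
  nsub <- setNames(rep(1L, length(classes)), classes)
  nsub[names(spec$n_subclusters)] <- as.integer(spec$n_subclusters)
  pops <- unlist(lapply(classes, function(cl) {
    if (nsub[[cl]] == 1) cl else paste(cl, seq_len(nsub[[cl]]), sep = "_")
  }))
  pop_class <- unlist(lapply(classes, function(cl) rep(cl, nsub[[cl]])))
  list(classes = classes, n_subclusters = nsub, populations = pops,
       pop_class = pop_class)
}

#' Build per-population mean expression profiles
#'
#' Draws a lognormal baseline mean per gene, multiplies class markers by
#' `exp(marker_log_fc)` in all populations of their class, subcluster
#' markers by the same factor in their own (non-vulnerable) population, and
#' risk genes by `exp(risk_log_fc)` in the vulnerable population. Marker and
#' risk gene blocks are disjoint.
#'
#' @param spec a `SimSpec`
#' @return list with `profiles` (gene x population, linear scale),
#'   `baseline`, `marker_of` (per-gene label, "none" for background),
#'   `risk_genes`, `log_fc` (gene x population, natural log vs baseline),
#'   and `populations`
#' @export
make_profiles <- function(spec) {
  stopifnot(inherits(spec, "SimSpec"))
  pop <- sim_populations(spec)
  set.seed(derive_seed(spec$seed, 1))
  gene_ids <- sprintf("GENE%05d", seq_len(spec$n_genes))

  vul_class <- spec$vulnerable_subcluster$class
  vul_pop <- if (pop$n_subclusters[[vul_class]] == 1) vul_class else
    paste(vul_class, spec$vulnerable_subcluster$index, sep = "_")
  if (!vul_pop %in% pop$populations)
    stop("vulnerable subcluster ", vul_pop, " does not exist")
  sub_marker_pops <- pop$populations[
    pop$pop_class %in% names(spec$n_subclusters) & pop$populations != vul_pop]
  n_marked <- spec$marker_genes_per_class * length(pop$classes) +
    spec$subcluster_marker_genes * length(sub_marker_pops) +
    spec$risk_set_size
  if (n_marked > spec$n_genes)
    stop(sprintf("spec error: %d marker/risk genes demanded but only %d genes",
                 n_marked, spec$n_genes))

  baseline <- stats::rlnorm(spec$n_genes, meanlog = spec$baseline_log_mean,
                            sdlog = spec$baseline_log_sd)
  names(baseline) <- gene_ids
  log_fc <- matrix(0, spec$n_genes, length(pop$populations),
                   dimnames = list(gene_ids, pop$populations))
  marker_of <- rep("none", spec$n_genes)
  names(marker_of) <- gene_ids

  cursor <- 0L
  take <- function(n) {
    idx <- cursor + seq_len(n)
    cursor <<- cursor + n
    idx
  }
  for (cl in pop$classes) {
    idx <- take(spec$marker_genes_per_class)
    marker_of[idx] <- cl
    log_fc[idx, pop$pop_class == cl] <- spec$marker_log_fc
  }
  for (p in sub_marker_pops) {
    idx <- take(spec$subcluster_marker_genes)
    marker_of[idx] <- p
    log_fc[idx, p] <- spec$marker_log_fc
  }
  risk_idx <- take(spec$risk_set_size)
  marker_of[risk_idx] <- "risk"
  risk_fc <- if (spec$risk_log_fc_sd > 0 && spec$risk_log_fc != 0) {
    spec$risk_log_fc * stats::rlnorm(length(risk_idx),
                                     meanlog = -spec$risk_log_fc_sd^2 / 2,
                                     sdlog = spec$risk_log_fc_sd)
  } else rep(spec$risk_log_fc, length(risk_idx))
  log_fc[risk_idx, vul_pop] <- risk_fc

  # structured genes draw their baseline from the detectable range
  struct <- which(marker_of != "none")
  baseline[struct] <- stats::rlnorm(length(struct),
                                    meanlog = spec$marker_baseline_log_mean,
                                    sdlog = spec$marker_baseline_log_sd)

  profiles <- baseline * exp(log_fc)
  list(profiles = profiles, baseline = baseline, marker_of = marker_of,
       risk_genes = gene_ids[risk_idx], log_fc = log_fc,
       populations = pop, vulnerable = vul_pop)
}

# Deterministic cell allocation: largest-remainder split over populations
# (class proportions split equally across its subclusters).
allocate_cells <- function(spec, pop) {
  frac <- spec$class_proportions[pop$pop_class] / pop$n_subclusters[pop$pop_class]
  target <- frac * spec$n_cells
  n <- floor(target)
  rem <- spec$n_cells - sum(n)
  if (rem > 0) {
    extra <- order(target - n, decreasing = TRUE)[seq_len(rem)]
    n[extra] <- n[extra] + 1
  }
  setNames(as.integer(n), pop$populations)
}

#' Simulate counts from mean profiles
#'
#' Cell `c` of population `p` has counts `~ NB(mean = mu[g,p] * s_c,
#' size = dispersion)` with `s_c` lognormal. Cells are allocated to
#' populations deterministically (largest remainder), so population sizes
#' are reproducible exactly.
#'
#' @param prof output of [make_profiles()]
#' @param spec the `SimSpec`
#' @param seed seed (default derived from `spec$seed`)
#' @param cell_prefix prefix for cell identifiers
#' @return list with `matrix` (an `ExpressionMatrix` with counts),
#'   `meta` (cell_id, cardinal_class, subcluster, stage), and
#'   `truth` (a `GroundTruth` list)
#' @export
simulate_counts <- function(prof, spec, seed = derive_seed(spec$seed, 2),
                            cell_prefix = "CELL") {
  stopifnot(inherits(spec, "SimSpec"))
  pop <- prof$populations
  n_per_pop <- allocate_cells(spec, pop)
  set.seed(seed)
  pop_of_cell <- rep(names(n_per_pop), n_per_pop)
  n_cells <- length(pop_of_cell)
  cell_ids <- sprintf("%s%05d", cell_prefix, seq_len(n_cells))
  s <- stats::rlnorm(n_cells, spec$libsize_log_mean, spec$libsize_log_sd)
  size <- spec$dispersion_per_gene %||% rep(spec$nb_dispersion, spec$n_genes)

  mu <- prof$profiles[, pop_of_cell, drop = FALSE] *
    rep(s, each = spec$n_genes)
  counts <- matrix(stats::rnbinom(length(mu), size = size, mu = mu),
                   nrow = spec$n_genes,
                   dimnames = list(rownames(prof$profiles), cell_ids))
  m <- expression_matrix(counts = counts,
                         provenance = sprintf("simulate_counts(seed=%d)", seed))
  meta <- data.frame(
    cell_id = cell_ids,
    cardinal_class = pop$pop_class[match(pop_of_cell, pop$populations)],
    subcluster = pop_of_cell,
    stage = "GW23",
    stringsAsFactors = FALSE)
  truth <- structure(list(
    cell_id = cell_ids,
    true_class = meta$cardinal_class,
    true_subcluster = pop_of_cell,
    marker_of = prof$marker_of,
    risk_set = prof$risk_genes,
    vulnerable = prof$vulnerable,
    log_fc = prof$log_fc,
    libsize_factor = s), class = "GroundTruth")
  list(matrix = m, meta = meta, truth = truth)
}

#' Simulate a complete query dataset
#'
#' Convenience wrapper: [make_profiles()] then [simulate_counts()].
#' @param spec a `SimSpec`
#' @return as [simulate_counts()], plus `profiles`
#' @export
simulate_dataset <- function(spec) {
  prof <- make_profiles(spec)
  out <- simulate_counts(prof, spec)
  out$profiles <- prof
  out
}

#' Simulate a paired reference dataset
#'
#' The reference reuses the query's type signatures for the populations it
#' shares, then perturbs every gene's log-mean by `N(0, batch_shift_sd)`
#' (one draw per gene, shared across populations) to emulate a dataset /
#' batch effect. Library sizes and counts are drawn fresh.
#'
#' @param prof output of [make_profiles()] for the query
#' @param spec the query `SimSpec`
#' @param populations which query populations the reference contains
#'   (default: all); the reference labels cells with these names as types
#' @param n_cells reference size (split evenly across populations)
#' @param batch_shift_sd per-gene log-mean shift SD (default from spec)
#' @param seed seed
#' @return list with `matrix`, `meta` (cell_id, cardinal_class = type),
#'   and `profiles` (shifted, linear scale)
#' @export
make_reference <- function(prof, spec, populations = NULL, n_cells = 500,
                           batch_shift_sd = spec$batch_shift_sd,
                           seed = derive_seed(spec$seed, 1000)) {
  pops <- populations %||% prof$populations$populations
  missing_p <- setdiff(pops, prof$populations$populations)
  if (length(missing_p)) stop("unknown populations: ",
                              paste(missing_p, collapse = ", "))
  set.seed(seed)
  shift <- stats::rnorm(spec$n_genes, 0, batch_shift_sd)
  ref_profiles <- prof$profiles[, pops, drop = FALSE] * exp(shift)
  n_per <- rep(n_cells %/% length(pops), length(pops))
  n_per[seq_len(n_cells %% length(pops))] <- n_per[seq_len(n_cells %% length(pops))] + 1
  pop_of_cell <- rep(pops, n_per)
  cell_ids <- sprintf("REF%05d", seq_along(pop_of_cell))
  s <- stats::rlnorm(length(cell_ids), spec$libsize_log_mean, spec$libsize_log_sd)
  size <- spec$dispersion_per_gene %||% rep(spec$nb_dispersion, spec$n_genes)
  mu <- ref_profiles[, pop_of_cell, drop = FALSE] * rep(s, each = spec$n_genes)
  counts <- matrix(stats::rnbinom(length(mu), size = size, mu = mu),
                   nrow = spec$n_genes,
                   dimnames = list(rownames(ref_profiles), cell_ids))
  list(matrix = expression_matrix(
         counts = counts,
         provenance = sprintf("make_reference(seed=%d, shift_sd=%g)",
                              seed, batch_shift_sd)),
       meta = data.frame(cell_id = cell_ids, cardinal_class = pop_of_cell,
                         stage = "adult", stringsAsFactors = FALSE),
       profiles = ref_profiles)
}

#' Write ground truth to JSON
#' @param truth a `GroundTruth`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth
  out$log_fc <- list(genes = rownames(truth$log_fc),
                     populations = colnames(truth$log_fc),
                     values = unname(apply(truth$log_fc, 1, as.numeric,
                                           simplify = FALSE)))
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ground truth from JSON
#' @param path JSON path written by [write_ground_truth()]
#' @return a `GroundTruth`
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lf <- x$log_fc
  v <- lf$values
  x$log_fc <- if (is.list(v)) do.call(rbind, lapply(v, as.numeric)) else
    matrix(as.numeric(v), nrow = length(lf$genes), byrow = FALSE)
  dimnames(x$log_fc) <- list(lf$genes, lf$populations)
  x$marker_of <- setNames(as.character(x$marker_of), lf$genes)
  structure(x, class = "GroundTruth")
}
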