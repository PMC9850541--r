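# The ExpressionMatrix container: gene x cell values with optional raw-count
# and log-normalized layers, plus a provenance trail of applied operations.

#' Construct an ExpressionMatrix
#'
#' Gene x cell container holding up to two layers: `counts` (raw,
#' non-negative) and `norm` (library-size normalized, natural-log scale).
#' At least one layer must be present; layers share dimensions and
#' gene/cell orderings. Gene and cell identifiers must be unique.
#'
#' @param counts numeric gene x cell matrix of raw counts, or NULL
#' @param norm numeric gene x cell matrix of log-normalized values, or NULL
#' @param gene_ids,cell_ids character vectors; taken from the dimnames of the
#'   first available layer when omitted
#' @param provenance character vector recording applied operations
#' @return an object of class `ExpressionMatrix`
#' @export
#' @examples
#' m <- expression_matrix(counts = matrix(0:5, 3, 2,
#'   dimnames = list(paste0("G", 1:3), paste0("C", 1:2))))
#' dim(m)
expression_matrix <- function(counts = NULL, norm = NULL,
                              gene_ids = NULL, cell_ids = NULL,
                              provenance = character()) {
  layer <- counts %||% norm
  if (is.null(layer)) stop("at least one of 'counts' or 'norm' must be given")
  gene_ids <- gene_ids %||% rownames(layer)
  cell_ids <- cell_ids %||% colnames(layer)
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene_ids and cell_ids are required (as arguments or dimnames)")
  set_names <- function(x, what) {
    if (is.null(x)) return(NULL)
    x <- as.matrix(x)
    if (nrow(x) != length(gene_ids) || ncol(x) != length(cell_ids))
      stop(sprintf("layer '%s' is %dx%d but ids imply %dx%d",
                   what, nrow(x), ncol(x), length(gene_ids), length(cell_ids)))
    dimnames(x) <- list(gene_ids, cell_ids)
    x
  }
  obj <- structure(
    list(counts = set_names(counts, "counts"), norm = set_names(norm, "norm"),
         gene_ids = as.character(gene_ids), cell_ids = as.character(cell_ids),
         provenance = provenance),
    class = "ExpressionMatrix")
  validate_expression_matrix(obj)
  obj
}

#' Validate ExpressionMatrix invariants
#'
#' Checks layer presence, dimension agreement, identifier uniqueness and
#' finiteness/non-negativity of the counts layer; stops on violation.
#'
#' @param m an `ExpressionMatrix`
#' @return `m`, invisibly
#' @export
validate_expression_matrix <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.null(m$counts) && is.null(m$norm))
    stop("ExpressionMatrix must carry at least one layer")
  ng <- length(m$gene_ids); nc <- length(m$cell_ids)
  for (ly in c("counts", "norm")) {
    x <- m[[ly]]
    if (is.null(x)) next
    if (nrow(x) != ng || ncol(x) != nc)
      stop(sprintf("layer '%s' is %dx%d but ids imply %dx%d",
                   ly, nrow(x), ncol(x), ng, nc))
  }
  if (anyDuplicated(m$gene_ids))
    stop("duplicate gene_ids: ",
         paste(unique(m$gene_ids[duplicated(m$gene_ids)])[1:3], collapse = ", "))
  if (anyDuplicated(m$cell_ids))
    stop("duplicate cell_ids: ",
         paste(unique(m$cell_ids[duplicated(m$cell_ids)])[1:3], collapse = ", "))
  if (!is.null(m$counts)) {
    if (any(!is.finite(m$counts))) stop("counts layer contains non-finite values")
    if (any(m$counts < 0)) stop("counts layer contains negative values")
  }
  if (!is.null(m$norm) && any(!is.finite(m$norm)))
    stop("norm layer contains non-finite values")
  invisible(m)
}

#' @export
dim.ExpressionMatrix <- function(x) {
  c(length(x$gene_ids), length(x$cell_ids))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  layers <- c(if (!is.null(x$counts)) "counts", if (!is.null(x$norm)) "norm")
  cat(sprintf("ExpressionMatrix: %d genes x %d cells [layers: %s]\n",
              length(x$gene_ids), length(x$cell_ids),
              paste(layers, collapse = ", ")))
  if (length(x$provenance))
    cat("provenance:", paste(utils::tail(x$provenance, 3), collapse = " | "), "\n")
  invisible(x)
}

#' Subset an ExpressionMatrix by genes and/or cells
#'
#' @param x an `ExpressionMatrix`
#' @param i gene selector (ids, indices, or logical)
#' @param j cell selector
#' @param ... ignored
#' @return a new `ExpressionMatrix`
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$gene_ids)
  if (missing(j)) j <- seq_along(x$cell_ids)
  take <- function(layer) if (is.null(layer)) NULL else layer[i, j, drop = FALSE]
  cts <- take(x$counts); nrm <- take(x$norm)
  ref <- cts %||% nrm
  expression_matrix(counts = cts, norm = nrm,
                    gene_ids = rownames(ref), cell_ids = colnames(ref),
                    provenance = x$provenance)
}

# Append one provenance record.
add_provenance <- function(m, record) {
  m$provenance <- c(m$provenance, record)
  m
}

# Pick a layer, with a clear error when absent.
get_layer <- function(m, layer = c("norm", "counts")) {
  layer <- match.arg(layer)
  x <- m[[layer]]
  if (is.null(x)) stop(sprintf("ExpressionMatrix has no '%s' layer", layer))
  x
}
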