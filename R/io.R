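# Readers and writers for the plain-text formats the pipeline consumes:
# MatrixMarket MTX (+ genes.tsv/barcodes.tsv sidecars), dense TSV, GMT gene
# sets, one-gene-per-line lists, and CSV cell metadata.

#' Read a gene x cell expression matrix
#'
#' Supports MatrixMarket (`.mtx` with `genes.tsv`/`barcodes.tsv` sidecars in
#' the same directory, or explicit sidecar paths) and dense TSV (genes in
#' rows, header row of cell ids, first column gene ids). Orientation is
#' normalized to gene x cell; set `transpose = TRUE` when the file stores
#' cells in rows — the reader never guesses.
#'
#' @param path file path
#' @param format "auto" (from extension), "mtx" or "tsv"
#' @param layer which layer the values populate: "counts" or "norm"
#' @param transpose logical; transpose after reading
#' @param genes_file,cells_file sidecar paths for MTX (default
#'   `genes.tsv`/`barcodes.tsv` next to `path`)
#' @return an `ExpressionMatrix`
#' @export
read_matrix <- function(path, format = c("auto", "mtx", "tsv"),
                        layer = c("counts", "norm"), transpose = FALSE,
                        genes_file = NULL, cells_file = NULL) {
  format <- match.arg(format)
  layer <- match.arg(layer)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  if (format == "mtx") {
    genes_file <- genes_file %||% file.path(dirname(path), "genes.tsv")
    cells_file <- cells_file %||% file.path(dirname(path), "barcodes.tsv")
    for (f in c(genes_file, cells_file))
      if (!file.exists(f)) stop("MTX sidecar not found: ", f)
    x <- as.matrix(Matrix::readMM(path))
    genes <- utils::read.delim(genes_file, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.delim(cells_file, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    if (transpose) x <- t(x)
    if (nrow(x) != length(genes) || ncol(x) != length(cells))
      stop(sprintf(
        "MTX is %dx%d but sidecars list %d genes and %d cells",
        nrow(x), ncol(x), length(genes), length(cells)))
    dimnames(x) <- list(genes, cells)
  } else {
    df <- utils::read.delim(path, header = TRUE, row.names = 1,
                            check.names = FALSE, stringsAsFactors = FALSE)
    x <- as.matrix(df)
    if (transpose) x <- t(x)
    genes <- rownames(x); cells <- colnames(x)
  }
  args <- list(gene_ids = rownames(x), cell_ids = colnames(x),
               provenance = sprintf("read_matrix(%s, format=%s, layer=%s)",
                                    basename(path), format, layer))
  args[[layer]] <- x
  do.call(expression_matrix, args)
}

#' Write an ExpressionMatrix layer to disk
#'
#' MTX output writes `genes.tsv` and `barcodes.tsv` sidecars next to the
#' matrix file; TSV output is dense with gene rows and a cell-id header.
#'
#' @param m an `ExpressionMatrix`
#' @param path output path
#' @param format "mtx" or "tsv"
#' @param layer layer to write
#' @return `path`, invisibly
#' @export
write_matrix <- function(m, path, format = c("mtx", "tsv"),
                         layer = c("counts", "norm")) {
  format <- match.arg(format)
  layer <- match.arg(layer)
  x <- get_layer(m, layer)
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(x, sparse = TRUE), "generalMatrix"),
                    path)
    writeLines(m$gene_ids, file.path(dirname(path), "genes.tsv"))
    writeLines(m$cell_ids, file.path(dirname(path), "barcodes.tsv"))
  } else {
    df <- data.frame(gene = m$gene_ids, x, check.names = FALSE)
    colnames(df) <- c("gene", m$cell_ids)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' MSigDB dialect: one set per line, TAB-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Gene symbols are uppercased
#' on load (set `uppercase = FALSE` to keep case); duplicates within a line
#' are dropped with a warning; empty sets are rejected. Collection order
#' follows file order.
#'
#' @param path GMT file path
#' @param uppercase uppercase gene symbols on load (default TRUE)
#' @return a `GeneSetCollection`: named list of `GeneSet` objects, each a
#'   list with `name`, `description`, `genes`
#' @export
read_gene_sets <- function(path, uppercase = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT parse error at line %d: fewer than 3 fields", i))
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (uppercase) genes <- toupper(genes)
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT line %d ('%s'): duplicate genes deduplicated",
                      i, fields[1]))
      genes <- unique(genes)
    }
    if (!length(genes))
      stop(sprintf("GMT parse error at line %d: empty gene set", i))
    sets[[i]] <- structure(
      list(name = fields[1], description = fields[2], genes = genes),
      class = "GeneSet")
  }
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  structure(sets, class = "GeneSetCollection")
}

#' Write a GeneSetCollection to GMT
#' @param sets a `GeneSetCollection` (or plain named list of gene vectors)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (!is.list(s)) s <- list(name = names(sets)[i], description = "", genes = s)
    paste(c(s$name, if (nzchar(s$description %||% "")) s$description else ".",
            s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain one-gene-per-line list as a single GeneSet
#' @param path file path; blank lines ignored
#' @param name set name (default: file basename)
#' @param uppercase uppercase symbols (default TRUE)
#' @return a `GeneSet`
#' @export
read_gene_list <- function(path, name = NULL, uppercase = TRUE) {
  genes <- trimws(readLines(path))
  genes <- genes[nzchar(genes)]
  if (uppercase) genes <- toupper(genes)
  genes <- unique(genes)
  if (!length(genes)) stop("empty gene list: ", path)
  structure(list(name = name %||% basename(path), description = "",
                 genes = genes), class = "GeneSet")
}

#' Read cell metadata CSV
#'
#' Requires a `cell_id` column; optional `stage`, `cardinal_class` and
#' `cluster` columns. When vocabularies are supplied, off-vocabulary values
#' are a validation error listing the offending labels.
#'
#' @param path CSV path
#' @param class_vocab allowed `cardinal_class` labels, or NULL to accept any
#' @param stage_vocab allowed `stage` labels, or NULL
#' @return a data.frame of cell metadata
#' @export
read_cell_meta <- function(path, class_vocab = NULL, stage_vocab = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"cell_id" %in% colnames(df))
    stop("cell metadata schema error: no 'cell_id' column in ", path)
  if (anyDuplicated(df$cell_id))
    stop("duplicate cell_id in metadata: ",
         paste(unique(df$cell_id[duplicated(df$cell_id)])[1:3], collapse = ", "))
  check_vocab <- function(col, vocab) {
    if (is.null(vocab) || !col %in% colnames(df)) return()
    bad <- setdiff(unique(df[[col]]), vocab)
    if (length(bad))
      stop(sprintf("metadata column '%s' has off-vocabulary values: %s",
                   col, paste(bad, collapse = ", ")))
  }
  check_vocab("cardinal_class", class_vocab)
  check_vocab("stage", stage_vocab)
  df
}

#' Align metadata with an ExpressionMatrix
#'
#' Returns the metadata rows for cells present in the matrix, ordered to
#' match the matrix; cells present in only one of the two are reported.
#' An empty intersection is a hard error.
#'
#' @param m an `ExpressionMatrix`
#' @param meta data.frame with a `cell_id` column
#' @return data.frame with attribute `unmatched` listing ids found in only
#'   one input
#' @export
align_cell_meta <- function(m, meta) {
  common <- intersect(m$cell_ids, meta$cell_id)
  if (!length(common))
    stop("no overlap between matrix cells and metadata cell_id values")
  unmatched <- list(matrix_only = setdiff(m$cell_ids, meta$cell_id),
                    meta_only = setdiff(meta$cell_id, m$cell_ids))
  out <- meta[match(m$cell_ids[m$cell_ids %in% common], meta$cell_id), ,
              drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmatched") <- unmatched
  out
}
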