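# core_io: ExpressionMatrix invariants, matrix / gene-set / metadata IO.

test_that("ExpressionMatrix enforces its invariants", {
  x <- matrix(0:5, 3, 2)
  m <- count_mat(x)
  expect_s3_class(m, "ExpressionMatrix")
  expect_equal(dim(m), c(3L, 2L))

  expect_error(expression_matrix(), "at least one")
  expect_error(count_mat(x, genes = c("A", "A", "B")), "duplicate gene_ids")
  expect_error(count_mat(x, cells = c("c", "c")), "duplicate cell_ids")
  bad <- x; bad[1] <- -1
  expect_error(count_mat(bad), "negative")
  bad <- x; bad[1] <- NA
  expect_error(count_mat(bad), "non-finite")
  # layers must agree in shape
  expect_error(
    expression_matrix(counts = x, norm = matrix(0, 2, 2),
                      gene_ids = c("a", "b", "c"), cell_ids = c("x", "y")),
    "layer")
})

test_that("dense TSV round-trips and respects orientation", {
  x <- matrix(c(0, 1.5, 2, 3, 0, 4), 3, 2)
  m <- count_mat(x)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, f, format = "tsv", layer = "counts")
  back <- read_matrix(f, format = "tsv", layer = "counts")
  expect_identical(back$counts, m$counts)
  expect_equal(back$gene_ids, m$gene_ids)
  # transpose flag flips orientation rather than guessing
  tback <- read_matrix(f, format = "tsv", layer = "counts", transpose = TRUE)
  expect_equal(dim(tback), rev(dim(m)))
})

test_that("MTX round-trips, preserves sparsity, and checks sidecars", {
  d <- withr::local_tempdir()
  x <- matrix(0, 4, 3)
  x[cbind(c(1, 2, 3, 4, 1), c(1, 2, 3, 1, 3))] <- c(5, 1, 2.5, 7, 3)
  m <- count_mat(x)
  f <- file.path(d, "m.mtx")
  write_matrix(m, f, format = "mtx")
  back <- read_matrix(f, format = "mtx")
  expect_identical(unname(back$counts), unname(m$counts))
  expect_equal(sum(back$counts != 0), 5)
  # sidecar / dimension mismatch is a format error
  writeLines(c("G1", "G2"), file.path(d, "genes.tsv"))
  expect_error(read_matrix(f, format = "mtx"), "sidecars list")
  file.remove(file.path(d, "genes.tsv"))
  file.remove(file.path(d, "barcodes.tsv"))
  expect_error(read_matrix(f, format = "mtx"), "sidecar not found")
})

test_that("round-trip is value-preserving across random shapes (property)", {
  set.seed(42)
  for (i in 1:100) {
    ng <- sample(1:12, 1); nc <- sample(2:10, 1)
    x <- matrix(rpois(ng * nc, 2), ng, nc)
    m <- count_mat(x)
    if (i %% 2 == 0) {
      f <- withr::local_tempfile(fileext = ".tsv")
      write_matrix(m, f, format = "tsv", layer = "counts")
      back <- read_matrix(f, format = "tsv")
    } else {
      d <- withr::local_tempdir()
      f <- file.path(d, "m.mtx")
      write_matrix(m, f, format = "mtx", layer = "counts")
      back <- read_matrix(f, format = "mtx")
    }
    got <- unname(back$counts)
    storage.mode(got) <- "double"
    expect_identical(got, unname(m$counts) * 1.0)
  }
})

test_that("GMT parsing: order, case, duplicates, malformed lines", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S16p\tdesc\tMAPK3\tKCTD13",
               "dup\td\tfoxp1\tFOXP1\tSCN2A",
               "zz_first_is_not_sorted\t.\tA1\tB2"), f)
  expect_warning(sets <- read_gene_sets(f), "duplicate")
  expect_equal(names(sets), c("S16p", "dup", "zz_first_is_not_sorted"))
  expect_equal(sets[["S16p"]]$genes, c("MAPK3", "KCTD13"))
  expect_equal(sets[["dup"]]$genes, c("FOXP1", "SCN2A"))   # uppercased, deduped
  # re-read gives identical ordering (deterministic loading)
  expect_warning(again <- read_gene_sets(f))
  expect_identical(names(again), names(sets))

  writeLines(c("ok\td\tA", "short\tonly2fields"), f)
  expect_error(read_gene_sets(f), "line 2")
})

test_that("risk gene-set sizes round-trip at the published sizes", {
  # 83 monogenic (SFARI 1+2) and 27 16p11.2 protein-coding genes
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gene_sets(list(
    list(name = "SFARI_1_2", description = "monogenic",
         genes = sprintf("RISK%02d", 1:83)),
    list(name = "LOCUS_16P11", description = "cnv",
         genes = sprintf("CNV%02d", 1:27))), f)
  sets <- read_gene_sets(f)
  expect_equal(lengths(lapply(sets, `[[`, "genes")),
               c(SFARI_1_2 = 83L, LOCUS_16P11 = 27L))
})

test_that("plain gene-list reader handles the secondary format", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Mapk3", "", "KCTD13 "), f)
  s <- read_gene_list(f, name = "locus")
  expect_equal(s$genes, c("MAPK3", "KCTD13"))
  writeLines(character(), f)
  expect_error(read_gene_list(f), "empty")
})

test_that("cell metadata validation catches schema and vocabulary errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  classes <- c("NPC", "ExN", "IN", "OPC", "Astrocyte", "Microglia")
  df <- data.frame(cell_id = sprintf("c%02d", 1:10),
                   cardinal_class = rep(classes, length.out = 10),
                   stage = "GW23")
  utils::write.csv(df, f, row.names = FALSE)
  meta <- read_cell_meta(f, class_vocab = classes)
  expect_equal(nrow(meta), 10)

  df2 <- df; df2$cardinal_class[3] <- "Sputnik"
  utils::write.csv(df2, f, row.names = FALSE)
  expect_error(read_cell_meta(f, class_vocab = classes), "Sputnik")

  utils::write.csv(data.frame(id = 1:3), f, row.names = FALSE)
  expect_error(read_cell_meta(f), "cell_id")
})

test_that("matrix-metadata alignment flags unmatched cells, errors when empty", {
  m <- count_mat(matrix(1, 2, 3), cells = c("a", "b", "c"))
  meta <- data.frame(cell_id = c("b", "c", "zz"), cardinal_class = "IN")
  out <- align_cell_meta(m, meta)
  expect_equal(out$cell_id, c("b", "c"))
  expect_equal(attr(out, "unmatched")$matrix_only, "a")
  expect_equal(attr(out, "unmatched")$meta_only, "zz")
  expect_error(align_cell_meta(m, data.frame(cell_id = "nope")), "no overlap")
})

test_that("configuration defaults validate and bad values are rejected", {
  cfg <- default_config()
  expect_silent(validate_config(cfg))
  bad <- cfg; bad$resolution <- -1
  expect_error(validate_config(bad), "resolution")
  bad <- cfg; bad$hvg_vmr_side <- "sideways"
  expect_error(validate_config(bad), "hvg_vmr_side")
  bad <- cfg; bad$de_min_frac <- 1.5
  expect_error(validate_config(bad), "de_min_frac")

  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(knn_k = 10, resolution = 0.25), f,
                       auto_unbox = TRUE)
  merged <- read_config(f)
  expect_equal(merged$knn_k, 10)
  expect_equal(merged$resolution, 0.25)
  expect_equal(merged$min_genes_per_cell, 1000)   # untouched default
})
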