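test_that("lognormalize matches the closed form and inverts to proportions", {
  m <- matrix(c(1, 1,
                0, 0,
                3, 7), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("c", 1:3), c("g1", "g2")))
  out <- lognormalize(m)
  expect_equal(out[1, ], c(g1 = log(1 + 5000), g2 = log(1 + 5000)))
  expect_equal(out[2, ], c(g1 = 0, g2 = 0))
  one <- lognormalize(matrix(10000, 1, 1,
                             dimnames = list("c", "g")))
  expect_equal(drop(one), log(10001))
  # exp-inverse recovers count proportions for positive cells
  back <- expm1(out[c(1, 3), ]) / 1e4
  expect_equal(back, m[c(1, 3), ] / rowSums(m[c(1, 3), ]), tolerance = 1e-10)
  expect_error(lognormalize(matrix(-1, 1, 1)), class = "clonespace_validation_error")
})

test_that("clone size filtering applies the threshold and is idempotent", {
  clone <- c(rep("a", 5), rep("b", 2), "c")
  lab <- clonal_labeling(setNames(clone, paste0("c", 1:8)))
  f3 <- filter_clones_by_size(lab, 3)
  expect_equal(f3$clone_ids, "a")
  expect_equal(sum(is.na(f3$clone)), 3)
  expect_equal(filter_clones_by_size(lab, 1)$clone, lab$clone)
  lab2 <- clonal_labeling(setNames(c("a", "a", "b", "b"), paste0("c", 1:4)))
  expect_equal(filter_clones_by_size(lab2, 2)$clone_ids, c("a", "b"))
  # idempotence
  expect_equal(filter_clones_by_size(f3, 3)$clone, f3$clone)
})

test_that("clonal labeling validates ids and indexes sizes", {
  lab <- clonal_labeling(setNames(c("a", "a", NA, "b"), paste0("c", 1:4)))
  expect_equal(unname(lab$sizes), c(2L, 1L))
  expect_equal(sum(lab$sizes), sum(!is.na(lab$clone)))
  expect_error(clonal_labeling(c(a = "x", a = "y")),
               class = "clonespace_validation_error")
  expect_warning(clonal_labeling(setNames(rep(NA_character_, 3),
                                          paste0("c", 1:3))),
                 "null")
})

test_that("TCR clonotype derivation follows both chain-matching rules", {
  airr <- tibble::tibble(
    cell_id = c("c1", "c1", "c2", "c2", "c3", "c3",
                "c4", "c4", "c4",
                "c5", "c5", "c5", "c6", "c6", "c6",
                "c7", "c7"),
    locus = c("TRB", "TRA", "TRB", "TRA", "TRB", "TRA",
              "TRB", "TRB", "TRA",
              "TRB", "TRA", "TRA", "TRB", "TRA", "TRA",
              "TRB", "TRA"),
    junction = c("b1", "a1", "b1", "a1", "b1", "a1",
                 "b2", "b3", "a2",
                 "b4", "ax", "ay", "b4", "ax", "ay",
                 "b4", "ax"))
  lab <- derive_tcr_clonotypes(airr)
  # c1-c3 share TRB b1 + TRA a1 -> one clone of 3
  expect_equal(length(unique(lab$clone[c("c1", "c2", "c3")])), 1L)
  expect_equal(unname(lab$sizes[lab$clone[["c1"]]]), 3L)
  # c4 carries two distinct TRB sequences -> excluded
  expect_true(is.na(lab$clone[["c4"]]))
  # c5/c6 share TRB b4 and full TRA set {ax, ay}; c7 has TRA {ax} only
  expect_equal(lab$clone[["c5"]], lab$clone[["c6"]])
  expect_false(identical(lab$clone[["c7"]], lab$clone[["c5"]]))
  expect_error(derive_tcr_clonotypes(tibble::tibble(cell_id = "c")),
               class = "clonespace_schema_error")
})

test_that("TCR clonotypes are invariant to input row order", {
  set.seed(7)
  airr <- tibble::tibble(
    cell_id = rep(sprintf("c%02d", 1:12), each = 2),
    locus = rep(c("TRB", "TRA"), 12),
    junction = rep(c("b1.a1", "b2.a2", "b1.a3", "b3.a1"),
                   each = 6)[seq_len(24)])
  lab1 <- derive_tcr_clonotypes(airr)
  lab2 <- derive_tcr_clonotypes(airr[sample(nrow(airr)), ])
  expect_equal(lab1$clone, lab2$clone)
})

test_that("cell tables round-trip through the writer and loader", {
  cells <- toy_cells(n_clones = 2, size = 3)
  space <- cell_state_space(as.matrix(cells[, c("x", "y")]), cells$cell_id)
  lab <- clonal_labeling(setNames(cells$clone, cells$cell_id))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cell_table(space, lab, path)
  got <- load_inputs(path, embedding_key = "PC", clone_key = "clone")
  expect_equal(dim(got$space$coords), c(6, 2))
  expect_equal(unname(got$space$coords), unname(space$coords))
  expect_equal(length(got$labeling$clone_ids), 2L)
  expect_equal(got$labeling$clone, lab$clone)
  expect_error(load_inputs(path, embedding_key = "UMAP", clone_key = "clone"),
               class = "clonespace_key_error")
  expect_error(load_inputs(path, embedding_key = "PC", clone_key = "nope"),
               class = "clonespace_key_error")
  # all-null clone column -> C = 0 with a warning
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  tab$clone <- NA_character_
  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tab, path2)
  expect_warning(got2 <- load_inputs(path2, "PC", "clone"), "null")
  expect_equal(length(got2$labeling$clone_ids), 0L)
})

test_that("counts matrices load from MTX with aligned cells", {
  cells <- toy_cells(n_clones = 2, size = 3)
  space <- cell_state_space(as.matrix(cells[, c("x", "y")]), cells$cell_id)
  lab <- clonal_labeling(setNames(cells$clone, cells$cell_id))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cells.tsv")
  write_cell_table(space, lab, path)
  m <- matrix(rpois(6 * 4, 5), 4, 6)  # genes x cells (CellRanger layout)
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(x = cells$cell_id),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  readr::write_tsv(tibble::tibble(x = paste0("g", 1:4)),
                   file.path(dir, "features.tsv"), col_names = FALSE)
  got <- load_inputs(path, "PC", "clone", counts_dir = dir)
  expect_equal(dim(got$counts), c(6, 4))
  expect_equal(unname(got$counts), unname(t(m)))
})
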