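#' Cell state space
#'
#' A lightweight container for the latent expression coordinates of cells
#' (for example a batch-corrected PCA), the input manifold on which clonal
#' neighbourhoods are measured. Coordinates are dimensionless latent units;
#' typical inputs carry 15--30 dimensions.
#'
#' @param coords Numeric matrix, cells in rows and latent dimensions in
#'   columns. Row names, if present, are used as cell ids.
#' @param cell_ids Character vector of unique cell identifiers; defaults to
#'   row names of `coords`.
#' @param batch Optional per-cell batch labels (character/factor).
#' @return An object of class `cell_state_space` with elements `coords`
#'   (matrix with cell ids as row names) and `batch`.
#' @export
cell_state_space <- function(coords, cell_ids = rownames(coords), batch = NULL) {
  assert_finite_matrix(coords, "coords")
  if (ncol(coords) < 1) {
    abort("`coords` needs at least one dimension.", class = "clonespace_validation_error")
  }
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(coords)))
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != nrow(coords)) {
    abort("`cell_ids` length must match rows of `coords`.",
          class = "clonespace_alignment_error")
  }
  if (anyDuplicated(cell_ids)) {
    abort("Duplicated cell ids are an error, not silently merged.",
          class = "clonespace_validation_error")
  }
  rownames(coords) <- cell_ids
  if (!is.null(batch)) {
    batch <- as.character(batch)
    if (length(batch) != nrow(coords)) {
      abort("`batch` length must match the number of cells.",
            class = "clonespace_alignment_error")
    }
  }
  structure(list(coords = coords, batch = batch), class = "cell_state_space")
}

#' @exportS3Method
print.cell_state_space <- function(x, ...) {
  cat(sprintf("<cell_state_space> %d cells x %d dims%s\n",
              nrow(x$coords), ncol(x$coords),
              if (is.null(x$batch)) "" else sprintf(", %d batches",
                                                    length(unique(x$batch)))))
  invisible(x)
}

#' Clonal labelling of cells
#'
#' Per-cell clone identity. Cells without a lineage label carry `NA`; the
#' null label is never counted among the clones.
#'
#' @param clone Character vector of clone labels per cell (`NA` = unlabelled);
#'   names, if present, are cell ids.
#' @param cell_ids Optional cell ids (defaults to names of `clone`).
#' @return Object of class `clonal_labeling`: `clone` (named character),
#'   `clone_ids` (sorted unique labels), `sizes` (named integer clone sizes).
#' @export
clonal_labeling <- function(clone, cell_ids = names(clone)) {
  force(cell_ids)
  clone <- as.character(clone)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_along(clone))
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != length(clone)) {
    abort("`cell_ids` must match `clone` in length.",
          class = "clonespace_alignment_error")
  }
  if (anyDuplicated(cell_ids)) {
    abort("Duplicated cell ids are an error, not silently merged.",
          class = "clonespace_validation_error")
  }
  names(clone) <- cell_ids
  tab <- table(clone, useNA = "no")
  clone_ids <- sort(names(tab))
  sizes <- as.integer(tab[clone_ids])
  names(sizes) <- clone_ids
  if (length(clone_ids) == 0) {
    warn("All clone labels are null; C = 0.")
  }
  structure(list(clone = clone, clone_ids = clone_ids, sizes = sizes),
            class = "clonal_labeling")
}

#' @exportS3Method
print.clonal_labeling <- function(x, ...) {
  cat(sprintf("<clonal_labeling> %d cells, %d clones (%d labelled cells)\n",
              length(x$clone), length(x$clone_ids), sum(!is.na(x$clone))))
  invisible(x)
}

#' @rdname clonal_labeling
#' @param x A `clonal_labeling`.
#' @param ... Unused.
#' @export
tidy.clonal_labeling <- function(x, ...) {
  tibble(cell_id = names(x$clone), clone = unname(x$clone))
}

#' Library-size log-normalisation
#'
#' Scales each cell to a common total count and applies `log1p`, the
#' standard `log(1 + target_sum * count / rowsum)` transform. Cells with a
#' zero total pass through as zeros.
#'
#' @param counts Matrix (or `Matrix`) of raw counts, cells x genes.
#' @param target_sum Per-cell total after scaling (default 10000 UMIs).
#' @return Matrix of the same shape with log-normalised values.
#' @export
lognormalize <- function(counts, target_sum = 1e4) {
  if (min(counts) < 0) {
    abort("Raw counts must be nonnegative.", class = "clonespace_validation_error")
  }
  rs <- Matrix::rowSums(counts)
  scale <- ifelse(rs > 0, target_sum / rs, 0)
  out <- as.matrix(counts) * scale
  log1p(out)
}

#' Drop clones below a minimum size
#'
#' Labels of clones with fewer than `min_size` cells are set to null and the
#' size index is rebuilt. Idempotent for a fixed `min_size`.
#'
#' @param labeling A [clonal_labeling()].
#' @param min_size Minimum number of cells per retained clone (default 3).
#' @return A new `clonal_labeling`.
#' @export
filter_clones_by_size <- function(labeling, min_size = 3) {
  min_size <- assert_scalar_int(min_size, "min_size", min = 1)
  keep <- names(labeling$sizes)[labeling$sizes >= min_size]
  clone <- labeling$clone
  clone[!(clone %in% keep)] <- NA_character_
  clonal_labeling(clone, names(labeling$clone))
}

#' Derive TCR clonotypes from an AIRR rearrangement table
#'
#' Groups cells into clones by full nucleotide identity of the CDR3
#' junctions of both chains: cells belong to the same clone when their TRB
#' junction set and their complete TRA junction set match exactly. Clones
#' whose cells carry more than one distinct TRB sequence are excluded
#' (labels set to null). Rows from other loci are ignored. The productive
#' flag is not filtered on by default.
#'
#' @param airr Data frame with columns `cell_id`, `locus`, `junction`
#'   (nucleotide CDR3), the standard AIRR rearrangement columns.
#' @param productive_only If `TRUE` and a `productive` column is present,
#'   restrict to productive rearrangements first. Default `FALSE`.
#' @return A [clonal_labeling()] over the cells present in `airr`.
#' @export
derive_tcr_clonotypes <- function(airr, productive_only = FALSE) {
  needed <- c("cell_id", "locus", "junction")
  miss <- setdiff(needed, names(airr))
  if (length(miss) > 0) {
    abort(paste0("AIRR table lacks required columns: ",
                 paste(miss, collapse = ", ")),
          class = "clonespace_schema_error")
  }
  df <- as_tibble(airr)
  if (productive_only && "productive" %in% names(df)) {
    df <- dplyr::filter(df, .data$productive %in% c(TRUE, "T", "TRUE", "true"))
  }
  df <- dplyr::filter(df, .data$locus %in% c("TRA", "TRB"),
                      !is.na(.data$junction), .data$junction != "")
  cells <- sort(unique(as.character(airr$cell_id)))

  key_tbl <- df |>
    dplyr::distinct(.data$cell_id, .data$locus, .data$junction) |>
    dplyr::group_by(.data$cell_id, .data$locus) |>
    dplyr::summarise(chain_key = paste(sort(.data$junction), collapse = ";"),
                     n_seq = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "locus",
                       values_from = c("chain_key", "n_seq"),
                       values_fill = list(chain_key = "", n_seq = 0L))
  for (col in c("chain_key_TRA", "chain_key_TRB", "n_seq_TRA", "n_seq_TRB")) {
    if (!col %in% names(key_tbl)) {
      key_tbl[[col]] <- if (grepl("^n_", col)) 0L else ""
    }
  }
  key_tbl <- key_tbl |>
    dplyr::mutate(clone_key = ifelse(.data$chain_key_TRB == "", NA_character_,
                                     paste(.data$chain_key_TRB,
                                           .data$chain_key_TRA, sep = "|")),
                  multi_trb = .data$n_seq_TRB > 1L)

  # clones whose cells carry >1 distinct TRB are excluded outright
  key_tbl$clone_key[key_tbl$multi_trb] <- NA_character_

  clone <- setNames(rep(NA_character_, length(cells)), cells)
  ok <- !is.na(key_tbl$clone_key)
  clone[as.character(key_tbl$cell_id[ok])] <- key_tbl$clone_key[ok]
  # relabel deterministically in order of first sorted key
  keys <- sort(unique(clone[!is.na(clone)]))
  if (length(keys) > 0) {
    new <- setNames(sprintf("clonotype%03d", seq_along(keys)), keys)
    clone[!is.na(clone)] <- new[clone[!is.na(clone)]]
  }
  clonal_labeling(clone, cells)
}

#' Load embedding, clone labels and (optionally) counts
#'
#' Reads a delimited cell table (TSV/CSV, cells as rows, header required)
#' holding latent coordinates and a clone column, and optionally a
#' MatrixMarket counts triplet (`matrix.mtx`, `barcodes.tsv`,
#' `features.tsv`). Cells are aligned across outputs by cell id.
#'
#' @param path Path to the cell table.
#' @param embedding_key Prefix naming the coordinate columns (e.g. `"PC"`
#'   matches `PC1`, `PC2`, ...), or a character vector of column names.
#' @param clone_key Name of the clone column; missing labels become null.
#' @param cell_id_key Name of the cell-id column (default `cell_id`).
#' @param batch_key Optional batch column name.
#' @param counts_dir Optional directory with `matrix.mtx` (cells x genes or
#'   genes x cells with `features_as_rows = TRUE`), `barcodes.tsv`,
#'   `features.tsv`.
#' @param features_as_rows Are features rows in the MTX (CellRanger
#'   convention)? Default `TRUE`.
#' @return List with `space` ([cell_state_space()]), `labeling`
#'   ([clonal_labeling()]) and `counts` (matrix or `NULL`).
#' @export
load_inputs <- function(path, embedding_key, clone_key,
                        cell_id_key = "cell_id", batch_key = NULL,
                        counts_dir = NULL, features_as_rows = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("Input file not found: ", path), class = "clonespace_io_error")
  }
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!cell_id_key %in% names(tab)) {
    abort(paste0("Cell-id column not found: ", cell_id_key),
          class = "clonespace_key_error")
  }
  if (length(embedding_key) == 1 && !embedding_key %in% names(tab)) {
    coord_cols <- grep(paste0("^", embedding_key, "[0-9]+$"), names(tab),
                       value = TRUE)
  } else {
    coord_cols <- embedding_key
  }
  if (length(coord_cols) == 0 || !all(coord_cols %in% names(tab))) {
    abort(paste0("Embedding key does not resolve to any columns: ",
                 paste(embedding_key, collapse = ", ")),
          class = "clonespace_key_error")
  }
  if (!clone_key %in% names(tab)) {
    abort(paste0("Clone column not found: ", clone_key),
          class = "clonespace_key_error")
  }
  ids <- as.character(tab[[cell_id_key]])
  coords <- as.matrix(tab[, coord_cols, drop = FALSE])
  rownames(coords) <- ids
  batch <- if (!is.null(batch_key)) as.character(tab[[batch_key]]) else NULL
  space <- cell_state_space(coords, ids, batch)
  cl <- as.character(tab[[clone_key]])
  cl[cl %in% c("", "NA")] <- NA_character_
  labeling <- clonal_labeling(setNames(cl, ids))

  counts <- NULL
  if (!is.null(counts_dir)) {
    m <- Matrix::readMM(file.path(counts_dir, "matrix.mtx"))
    bc <- readr::read_tsv(file.path(counts_dir, "barcodes.tsv"),
                          col_names = FALSE, show_col_types = FALSE,
                          progress = FALSE)[[1]]
    ft <- readr::read_tsv(file.path(counts_dir, "features.tsv"),
                          col_names = FALSE, show_col_types = FALSE,
                          progress = FALSE)[[1]]
    if (features_as_rows) m <- Matrix::t(m)
    m <- as.matrix(m)
    rownames(m) <- as.character(bc)
    colnames(m) <- as.character(ft)
    missing_cells <- setdiff(ids, rownames(m))
    if (length(missing_cells) > 0) {
      abort("Counts matrix does not cover all cells in the table.",
            class = "clonespace_alignment_error")
    }
    counts <- m[ids, , drop = FALSE]
  }
  # cells labelled but absent from the embedding cannot happen here (single
  # table), but counts cells absent from the table are dropped with a note
  list(space = space, labeling = labeling, counts = counts)
}

#' Write a cell table consumable by [load_inputs()]
#'
#' Deterministic column order: cell id, coordinates, clone, then batch.
#'
#' @param space A [cell_state_space()].
#' @param labeling A [clonal_labeling()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(space, labeling, path) {
  ids <- rownames(space$coords)
  coords <- space$coords
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  out <- tibble(cell_id = ids)
  out <- dplyr::bind_cols(out, as_tibble(coords))
  out$clone <- unname(labeling$clone[ids])
  if (!is.null(space$batch)) out$batch <- space$batch
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
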