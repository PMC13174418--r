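#' k-nearest-neighbour graph on clonally labelled cells
#'
#' Builds an exact Euclidean kNN graph restricted to cells that carry a
#' clone label. Ties at the k-th distance are broken by the lower cell
#' index so results are reproducible. Labelled cells absent from the
#' embedding are dropped with a warning.
#'
#' @param space A [cell_state_space()].
#' @param labeling A [clonal_labeling()].
#' @param k Neighbours per cell (default 15).
#' @return Object of class `neighbor_graph`: `neighbor_index` (cells x k
#'   integer matrix of 1-based indices into the labelled cells), `cell_ids`
#'   (labelled cells, in embedding order), `k`, `metric`.
#' @export
build_cell_knn <- function(space, labeling, k = 15) {
  k <- assert_scalar_int(k, "k", min = 1)
  emb_ids <- rownames(space$coords)
  lab <- labeling$clone
  missing_cells <- setdiff(names(lab)[!is.na(lab)], emb_ids)
  if (length(missing_cells) > 0) {
    warn(sprintf("%d labelled cells missing from the embedding were dropped.",
                 length(missing_cells)))
  }
  keep <- emb_ids[emb_ids %in% names(lab)[!is.na(lab)]]
  if (length(keep) <= k) {
    abort(sprintf("Need more than k = %d labelled cells (have %d).",
                  k, length(keep)),
          class = "clonespace_parameter_error")
  }
  coords <- space$coords[keep, , drop = FALSE]
  idx <- .knn_exact(coords, k)
  structure(list(neighbor_index = idx, cell_ids = keep, k = k,
                 metric = "euclidean"),
            class = "neighbor_graph")
}

#' @exportS3Method
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d cells, k = %d (%s)\n",
              length(x$cell_ids), x$k, x$metric))
  invisible(x)
}

#' Clone-by-clone neighbour co-occurrence matrix
#'
#' Aggregates the cell kNN graph to the clone level: entry (i, j) counts
#' neighbours from clone j across the expression neighbourhoods of all
#' cells of clone i. Without collapsing, row i sums to `k * size(i)`
#' exactly. With `collapse_groups`, neighbour labels of cells inside a
#' named group are replaced by the group's pseudo-label before counting:
#' pseudo-entities appear as extra context columns only, and clones fully
#' inside a collapsed group are dropped from the rows with a warning.
#'
#' @param graph A `neighbor_graph` from [build_cell_knn()].
#' @param labeling The [clonal_labeling()] used to build the graph.
#' @param collapse_groups Optional named character vector mapping cell ids
#'   to pseudo-entity labels (e.g. all monocytes to `"monocyte"`).
#' @return Object of class `clone_cooc`: sparse `counts` (rows = embedded
#'   clones, columns = clones plus pseudo-entities), `clone_ids`,
#'   `context_ids`, `k`.
#' @export
aggregate_cooccurrence <- function(graph, labeling, collapse_groups = NULL) {
  ids <- graph$cell_ids
  clone <- labeling$clone[ids]
  if (any(is.na(clone))) {
    abort("Graph contains cells without a clone label.",
          class = "clonespace_consistency_error")
  }
  row_label <- clone
  ctx_label <- clone
  if (!is.null(collapse_groups)) {
    hit <- ids %in% names(collapse_groups)
    ctx_label[hit] <- collapse_groups[ids[hit]]
    # a clone entirely inside a collapsed group has no embeddable cells
    masked_cells <- ids[hit]
    full_in <- vapply(split(ids, clone), function(cc) all(cc %in% masked_cells),
                      logical(1))
    drop_clones <- names(full_in)[full_in]
    if (length(drop_clones) > 0) {
      warn(sprintf("%d clones fully inside a collapsed group dropped from rows.",
                   length(drop_clones)))
    }
    # cells of partially masked clones remain sources; only neighbour
    # labels are replaced, so retained rows keep the k * size identity
    row_keep <- !(clone %in% drop_clones)
  } else {
    row_keep <- rep(TRUE, length(ids))
  }
  clone_ids <- sort(unique(row_label[row_keep]))
  context_ids <- c(clone_ids,
                   sort(setdiff(unique(ctx_label), clone_ids)))
  ri <- match(row_label, clone_ids)
  ci <- match(ctx_label, context_ids)
  k <- graph$k
  nb <- graph$neighbor_index
  src <- rep(seq_along(ids), times = k)
  keep_pair <- row_keep[src]
  counts <- Matrix::sparseMatrix(
    i = ri[src][keep_pair],
    j = ci[as.vector(nb)][keep_pair],
    x = 1,
    dims = c(length(clone_ids), length(context_ids)),
    dimnames = list(clone_ids, context_ids)
  )
  structure(list(counts = counts, clone_ids = clone_ids,
                 context_ids = context_ids, k = k),
            class = "clone_cooc")
}

#' @exportS3Method
print.clone_cooc <- function(x, ...) {
  cat(sprintf("<clone_cooc> %d clones x %d contexts, k = %d, total count %g\n",
              length(x$clone_ids), length(x$context_ids), x$k,
              sum(x$counts)))
  invisible(x)
}

#' One-call clone co-occurrence from a cell table
#'
#' Convenience wrapper chaining size filtering, kNN construction and
#' neighbourhood aggregation, the first half of the clonal-embedding
#' pipeline.
#'
#' @param cells Data frame with one row per cell.
#' @param coords Names of the coordinate columns (default `c("x", "y")`).
#' @param clone Name of the clone column (default `"clone"`).
#' @param cell_id Name of the cell-id column, or `NULL` to use row order.
#' @param k Neighbours per cell.
#' @param min_clone_size Minimum clone size retained (default 3).
#' @inheritParams aggregate_cooccurrence
#' @return A `clone_cooc`.
#' @export
clone_cooccurrence <- function(cells, coords = c("x", "y"), clone = "clone",
                               cell_id = NULL, k = 15, min_clone_size = 3,
                               collapse_groups = NULL) {
  ids <- if (!is.null(cell_id)) as.character(cells[[cell_id]]) else
    paste0("cell", seq_len(nrow(cells)))
  space <- cell_state_space(as_coord_matrix(cells, coords), ids)
  labeling <- clonal_labeling(setNames(as.character(cells[[clone]]), ids))
  labeling <- filter_clones_by_size(labeling, min_clone_size)
  graph <- build_cell_knn(space, labeling, k = k)
  aggregate_cooccurrence(graph, labeling, collapse_groups = collapse_groups)
}

#' Write / read a co-occurrence matrix as MatrixMarket + id sidecars
#'
#' @param cooc A `clone_cooc`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cooccurrence <- function(cooc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(cooc$counts, "generalMatrix"),
                  file.path(dir, "cooccurrence.mtx"))
  readr::write_tsv(tibble(clone_id = cooc$clone_ids),
                   file.path(dir, "clone_ids.tsv"), progress = FALSE)
  readr::write_tsv(tibble(context_id = cooc$context_ids),
                   file.path(dir, "context_ids.tsv"), progress = FALSE)
  readr::write_tsv(tibble(k = cooc$k), file.path(dir, "params.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' @rdname write_cooccurrence
#' @export
read_cooccurrence <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "cooccurrence.mtx"))
  clone_ids <- readr::read_tsv(file.path(dir, "clone_ids.tsv"),
                               show_col_types = FALSE, progress = FALSE)$clone_id
  context_ids <- readr::read_tsv(file.path(dir, "context_ids.tsv"),
                                 show_col_types = FALSE, progress = FALSE)$context_id
  k <- readr::read_tsv(file.path(dir, "params.tsv"),
                       show_col_types = FALSE, progress = FALSE)$k
  counts <- methods::as(counts, "CsparseMatrix")
  dimnames(counts) <- list(clone_ids, context_ids)
  structure(list(counts = counts, clone_ids = as.character(clone_ids),
                 context_ids = as.character(context_ids), k = as.integer(k)),
            class = "clone_cooc")
}
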