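#' Maximum mean discrepancy between two cell samples
#'
#' Biased (V-statistic) squared MMD with an RBF kernel. The bandwidth
#' defaults to the median pairwise distance over the pooled sample.
#'
#' @param cellsA,cellsB Numeric matrices of cell coordinates (rows are
#'   cells).
#' @param bandwidth Kernel bandwidth sigma; `NULL` for the median
#'   heuristic.
#' @return Nonnegative scalar MMD^2.
#' @export
mmd_distance <- function(cellsA, cellsB, bandwidth = NULL) {
  cellsA <- as_sample_matrix(cellsA)
  cellsB <- as_sample_matrix(cellsB)
  .mmd_pair(cellsA, cellsB, bandwidth %||% -1)
}

#' Debiased Sinkhorn divergence between two cell samples
#'
#' Entropic optimal transport with squared-Euclidean cost and uniform
#' marginals, debiased by the self-transport terms:
#' `S = W_eps(a, b) - (W_eps(a, a) + W_eps(b, b)) / 2`, which is
#' nonnegative and zero for identical samples. The regularisation defaults
#' to `0.05 *` the mean pairwise squared distance of the pooled sample.
#'
#' @inheritParams mmd_distance
#' @param epsilon Entropic regularisation; `NULL` for the default rule.
#' @param tol Relative stabilisation tolerance on the entropic cost.
#' @param max_iter Maximum scaling iterations (error if exceeded).
#' @return Nonnegative scalar.
#' @export
sinkhorn_divergence <- function(cellsA, cellsB, epsilon = NULL,
                                tol = 1e-8, max_iter = 20000) {
  cellsA <- as_sample_matrix(cellsA)
  cellsB <- as_sample_matrix(cellsB)
  .sinkhorn_pair(cellsA, cellsB, epsilon %||% -1, tol, max_iter)
}

#' Energy distance between two cell samples
#'
#' `2 E|a - b| - E|a - a'| - E|b - b'|` over the empirical samples
#' (V-statistic convention: all ordered pairs, diagonal included), zero
#' for identical samples.
#'
#' @inheritParams mmd_distance
#' @return Nonnegative scalar.
#' @export
energy_distance <- function(cellsA, cellsB) {
  .energy_pair(as_sample_matrix(cellsA), as_sample_matrix(cellsB))
}

as_sample_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  if (nrow(x) == 0) {
    abort("Samples must be nonempty.", class = "clonespace_parameter_error")
  }
  x
}

#' Clone-to-clone distance matrix from cell coordinates
#'
#' Computes a full C x C matrix of distribution distances between the cell
#' sets of every clone pair, used as embedding-free baselines: each clone
#' is its empirical distribution of cells in the original expression
#' space.
#'
#' @param cells Data frame with coordinate columns and a clone column.
#' @param method One of `"energy"`, `"mmd"`, `"sinkhorn"`,
#'   `"composition"`.
#' @param coords Names of coordinate columns.
#' @param clone Name of the clone column.
#' @param ... Passed to the per-pair distance (e.g. `bandwidth`,
#'   `epsilon`); for `"composition"`, `resolution` and `seed` of the
#'   cell-space clustering.
#' @return Symmetric matrix with clone ids as dimnames.
#' @export
clone_distance_matrix <- function(cells, method = c("energy", "mmd",
                                                    "sinkhorn", "composition"),
                                  coords = c("x", "y"), clone = "clone",
                                  ...) {
  method <- match.arg(method)
  X <- as_coord_matrix(cells, coords)
  cl <- as.character(cells[[clone]])
  clone_ids <- sort(unique(cl))
  if (method == "composition") {
    return(composition_distance_matrix(X, cl, clone_ids, ...))
  }
  idx0 <- split(seq_len(nrow(X)) - 1L, factor(cl, levels = clone_ids))
  ptr <- c(0L, cumsum(lengths(idx0)))
  opts <- list(...)
  D <- .pairwise_clone_distance(
    X, as.integer(ptr), as.integer(unlist(idx0)),
    method = switch(method, energy = 1L, mmd = 2L, 3L),
    bandwidth = opts$bandwidth %||% -1,
    eps = opts$epsilon %||% -1,
    tol = opts$tol %||% 1e-8,
    max_iter = opts$max_iter %||% 20000L)
  dimnames(D) <- list(clone_ids, clone_ids)
  D
}

# Cluster-composition baseline: Leiden clustering of the cell space once,
# then Euclidean distance between clone-level cluster-proportion vectors.
composition_distance_matrix <- function(X, cl, clone_ids, resolution = 1,
                                        k = 15, seed = 1) {
  nn <- .knn_exact(X, min(k, nrow(X) - 1))
  edges <- cbind(rep(seq_len(nrow(X)), times = ncol(nn)), as.vector(nn))
  g <- igraph::simplify(igraph::as_undirected(
    igraph::graph_from_edgelist(edges, directed = TRUE), mode = "collapse"))
  memb <- with_seed(seed, {
    as.integer(igraph::membership(
      igraph::cluster_leiden(g, objective_function = "modularity",
                             resolution = resolution)))
  })
  P <- as.matrix(prop.table(table(factor(cl, levels = clone_ids), memb),
                            margin = 1))
  D <- as.matrix(dist(P))
  dimnames(D) <- list(clone_ids, clone_ids)
  D
}

#' Per-pair cluster-composition distance
#'
#' Euclidean distance between the cell-cluster proportion vectors of two
#' clones, given a precomputed cell-space clustering.
#'
#' @param membership Integer cluster per cell.
#' @param cloneA,cloneB Logical or integer indices of each clone's cells.
#' @return Nonnegative scalar.
#' @export
cluster_composition_distance <- function(membership, cloneA, cloneB) {
  lv <- sort(unique(membership))
  pa <- prop.table(table(factor(membership[cloneA], levels = lv)))
  pb <- prop.table(table(factor(membership[cloneB], levels = lv)))
  sqrt(sum((pa - pb)^2))
}
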