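#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions under the permutation
#' model (standard closed form from the contingency table).
#'
#' @param a,b Label vectors of equal length.
#' @return Scalar in `[-1, 1]`; 1 iff the partitions coincide.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    abort("Label vectors must have equal length.",
          class = "clonespace_parameter_error")
  }
  tab <- table(a, b)
  n <- length(a)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' Best-ARI resolution sweep
#'
#' Builds a clone kNN graph (k = 15) from an embedding or a precomputed
#' distance matrix, runs Leiden community detection at every resolution of
#' the sweep (0.1 to 2 in steps of 0.1 by default, 20 resolutions) and
#' scores each partition against the ground truth with the adjusted Rand
#' index.
#'
#' @param source A [clone_embedding()], coordinate matrix, or symmetric
#'   distance matrix (`is_distance = TRUE`).
#' @param truth Named vector (by clone id) or vector in graph order of
#'   ground-truth labels.
#' @param resolutions Resolution grid.
#' @param k Graph neighbours (default 15).
#' @param seed Integer seed for Leiden.
#' @param is_distance Treat a matrix `source` as distances.
#' @return Object of class `benchmark_result`: `sweep` tibble
#'   (`resolution`, `n_clusters`, `ari`), `best_ari`, `best_resolution`.
#' @export
best_ari <- function(source, truth, resolutions = seq(0.1, 2, by = 0.1),
                     k = 15, seed = 1, is_distance = FALSE) {
  graph <- build_clone_graph(source, k = k, is_distance = is_distance)
  if (!is.null(names(truth))) {
    truth <- truth[graph$clone_ids]
  }
  if (anyNA(truth)) {
    abort("Truth labels must cover every clone.",
          class = "clonespace_parameter_error")
  }
  sweep_tbl <- purrr::map_dfr(resolutions, function(res) {
    cl <- cluster_clones(graph, resolution = res, seed = seed)
    tibble(resolution = res,
           n_clusters = length(unique(cl$cluster)),
           ari = adjusted_rand_index(cl$cluster, truth))
  })
  best <- which.max(sweep_tbl$ari)
  structure(list(sweep = sweep_tbl,
                 best_ari = sweep_tbl$ari[best],
                 best_resolution = sweep_tbl$resolution[best],
                 k = k, seed = seed),
            class = "benchmark_result")
}

#' @exportS3Method
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> best ARI %.3f at resolution %.1f (%d resolutions)\n",
              x$best_ari, x$best_resolution, nrow(x$sweep)))
  invisible(x)
}

#' Correlation between embedding PC1 and planted clone proportion
#'
#' On the two-cluster benchmark, the leading principal component of the
#' clonal embedding should order clones by their cluster-A proportion; this
#' reports the absolute Pearson correlation between PC1 scores and truth.
#'
#' @param embedding A [clone_embedding()] (2-D by construction of the
#'   benchmark) or coordinate matrix.
#' @param truth Named (by clone) or aligned numeric vector of proportions.
#' @return `|r|` in `[0, 1]`.
#' @export
proportion_correlation <- function(embedding, truth) {
  X <- if (inherits(embedding, "clone_embedding")) embedding$coords else embedding
  if (!is.null(names(truth)) && !is.null(rownames(X))) {
    truth <- truth[rownames(X)]
  }
  pc1 <- prcomp(X, rank. = 1)$x[, 1]
  if (sd(pc1) == 0) {
    abort("PC1 is constant; correlation undefined.",
          class = "clonespace_degenerate_error")
  }
  abs(cor(pc1, truth))
}

#' End-to-end clonal embedding of a synthetic dataset
#'
#' Convenience wrapper: co-occurrence (min clone size 2, the subsampling
#' convention), factorisation with the chosen backend, and the embedding.
#'
#' @param ds A `synthetic_clones` object.
#' @param z Latent dimension.
#' @param k Cell-graph neighbours.
#' @param backend `"skipgram"` or `"poisson"`.
#' @param min_clone_size Minimum clone size (default 2).
#' @param seed Integer seed.
#' @param ... Passed to the fitting backend.
#' @return A [clone_embedding()].
#' @export
embed_synthetic <- function(ds, z = 10, k = 15,
                            backend = c("skipgram", "poisson"),
                            min_clone_size = 2, seed = 1, ...) {
  backend <- match.arg(backend)
  cooc <- clone_cooccurrence(ds$cells, coords = c("x", "y"), clone = "clone",
                             cell_id = "cell_id", k = k,
                             min_clone_size = min_clone_size)
  fit <- if (backend == "skipgram") {
    fit_skipgram(cooc, z = z, seed = seed, ...)
  } else {
    fit_poisson_glmpca(cooc, z = z, seed = seed, ...)
  }
  clone_embedding(fit)
}

#' Benchmark sweep of embedding versus distance baselines
#'
#' Runs the clonal embedding and the distribution-distance baselines on one
#' (possibly subsampled) synthetic dataset and reports each method's best
#' ARI over the resolution sweep.
#'
#' @param ds A `synthetic_clones` object.
#' @param methods Baselines to include.
#' @param z,k,backend,seed Passed to [embed_synthetic()] / [best_ari()].
#' @param epochs Skip-gram epochs (default 60).
#' @return Tibble with `method`, `best_ari`, `best_resolution`,
#'   `n_clones`.
#' @export
benchmark_methods <- function(ds, methods = c("clone_embedding", "energy",
                                              "mmd", "sinkhorn",
                                              "composition"),
                              z = 10, k = 15, backend = "skipgram",
                              seed = 1, epochs = 60) {
  truth <- setNames(ds$clone_truth$truth, ds$clone_truth$clone)
  # clones of size >= 2 survive into every method for comparability
  sizes <- table(ds$cells$clone)
  keep <- names(sizes)[sizes >= 2]
  cells <- ds$cells[ds$cells$clone %in% keep, ]
  rows <- list()
  for (m in methods) {
    if (m == "clone_embedding") {
      extra <- if (backend == "skipgram") list(epochs = epochs) else list()
      emb <- do.call(embed_synthetic, c(
        list(new_synthetic_dataset(cells, ds$clone_truth, ds$params),
             z = z, k = k, backend = backend, min_clone_size = 2,
             seed = seed), extra))
      res <- best_ari(emb, truth, k = k, seed = seed)
      n <- nrow(emb$coords)
    } else {
      D <- clone_distance_matrix(cells, method = m)
      res <- best_ari(D, truth, k = k, seed = seed, is_distance = TRUE)
      n <- nrow(D)
    }
    rows[[m]] <- tibble(method = m, best_ari = res$best_ari,
                        best_resolution = res$best_resolution, n_clones = n)
  }
  dplyr::bind_rows(rows)
}
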