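# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @rdname fit_skipgram
#' @param x A `skipgram_fit`.
#' @param ... Unused.
#' @export
tidy.skipgram_fit <- function(x, ...) {
  tidy(clone_embedding(x))
}

#' @rdname fit_skipgram
#' @export
glance.skipgram_fit <- function(x, ...) {
  tibble(n_clones = nrow(x$U), z = x$z, epochs = x$epochs_run,
         nll_initial = x$loss_history[1],
         nll_final = utils::tail(x$loss_history, 1),
         lr_final = x$lr_final, seed = x$seed)
}

#' @rdname fit_poisson_glmpca
#' @param x A `glmpca_fit`.
#' @param ... Unused.
#' @export
tidy.glmpca_fit <- function(x, ...) {
  tidy(clone_embedding(x))
}

#' @rdname fit_poisson_glmpca
#' @export
glance.glmpca_fit <- function(x, ...) {
  tibble(n_clones = nrow(x$U), z = x$z, iterations = x$iterations,
         deviance_initial = x$deviance_history[1],
         deviance_final = utils::tail(x$deviance_history, 1),
         converged = x$converged, seed = x$seed)
}

#' @rdname fit_archetypes
#' @param x An `archetype_fit`.
#' @param ... Unused.
#' @export
tidy.archetype_fit <- function(x, ...) {
  W <- x$W
  colnames(W) <- paste0("archetype", seq_len(ncol(W)))
  dplyr::bind_cols(
    tibble(clone = x$clone_ids %||% paste0("clone", seq_len(nrow(W)))),
    as_tibble(W))
}

#' @rdname fit_archetypes
#' @export
glance.archetype_fit <- function(x, ...) {
  tibble(A = x$A, n_clones = nrow(x$W),
         rss = utils::tail(x$rss_history, 1),
         iterations = length(x$rss_history) - 1, converged = x$converged)
}

#' @rdname supervised_pca
#' @param x An `spca_fit`.
#' @param ... Unused.
#' @export
tidy.spca_fit <- function(x, ...) {
  L <- x$loadings
  tibble(gene = rep(rownames(L), ncol(L)),
         component = rep(colnames(L), each = nrow(L)),
         loading = as.vector(L))
}

#' @rdname supervised_pca
#' @export
glance.spca_fit <- function(x, ...) {
  tibble(n_components = ncol(x$loadings), n_genes = nrow(x$loadings),
         eigenvalue_1 = x$eigenvalues[1])
}

#' @rdname best_ari
#' @param x A `benchmark_result`.
#' @param ... Unused.
#' @export
tidy.benchmark_result <- function(x, ...) x$sweep

#' @rdname best_ari
#' @export
glance.benchmark_result <- function(x, ...) {
  tibble(best_ari = x$best_ari, best_resolution = x$best_resolution,
         k = x$k, seed = x$seed)
}

#' Plot a 2-D clone embedding
#'
#' @param object A `clone_embedding`.
#' @param colour Optional named vector (by clone) used to colour points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clone_embedding <- function(object, colour = NULL, ...) {
  df <- tidy(object)
  if (!is.null(colour)) df$colour <- colour[df$clone]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$Z1, y = .data$Z2)) +
    ggplot2::labs(x = "dim 1", y = "dim 2") +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point(alpha = 0.6, size = 0.8)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour),
                            alpha = 0.8, size = 0.8) +
      ggplot2::labs(colour = "value")
  }
}

#' Plot the resolution sweep of a benchmark result
#'
#' @param object A `benchmark_result`.
#' @param ... Unused.
#' @return A ggplot of ARI versus resolution.
#' @export
autoplot.benchmark_result <- function(object, ...) {
  ggplot2::ggplot(object$sweep,
                  ggplot2::aes(x = .data$resolution, y = .data$ari)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Leiden resolution", y = "adjusted Rand index") +
    ggplot2::theme_minimal()
}

#' Plot a synthetic benchmark dataset
#'
#' @param object A `synthetic_clones` object.
#' @param ... Unused.
#' @return A ggplot of the 2-D cells coloured by planted structure.
#' @export
autoplot.synthetic_clones <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$cluster)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(colour = "structure")
}

#' @importFrom rlang .data
NULL
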