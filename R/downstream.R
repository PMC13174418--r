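#' Clone-to-clone similarity kNN graph
#'
#' Builds a kNN graph over clones, either from embedding coordinates
#' (Euclidean) or from a user-supplied symmetric nonnegative distance
#' matrix (as produced by the distribution-distance baselines). The graph
#' is symmetrised by union and carries no self loops; ties are broken by
#' the lower clone index.
#'
#' @param source A [clone_embedding()], a coordinate matrix, or a square
#'   distance matrix (pass `is_distance = TRUE` or a `dist` object).
#' @param k Neighbours per clone (default 15).
#' @param is_distance Treat a square matrix input as distances.
#' @return Object of class `clone_graph`: igraph `graph`, `clone_ids`, `k`,
#'   `source` tag.
#' @export
build_clone_graph <- function(source, k = 15, is_distance = FALSE) {
  k <- assert_scalar_int(k, "k", min = 1)
  if (inherits(source, "clone_embedding")) {
    coords <- source$coords
    mode <- "embedding"
  } else if (inherits(source, "dist")) {
    source <- as.matrix(source)
    mode <- "distance_matrix"
  } else if (is.matrix(source) && is_distance) {
    mode <- "distance_matrix"
  } else if (is.matrix(source)) {
    coords <- source
    mode <- "embedding"
  } else {
    abort("Unsupported `source` for clone graph.",
          class = "clonespace_validation_error")
  }
  if (mode == "distance_matrix") {
    D <- as.matrix(source)
    if (nrow(D) != ncol(D)) {
      abort("Distance matrix must be square.", class = "clonespace_validation_error")
    }
    if (any(D < 0) || max(abs(D - t(D))) > 1e-8) {
      abort("Distance matrix must be symmetric and nonnegative.",
            class = "clonespace_validation_error")
    }
    n <- nrow(D)
    if (k >= n) {
      abort("`k` must be smaller than the number of clones.",
            class = "clonespace_parameter_error")
    }
    clone_ids <- rownames(D) %||% paste0("clone", seq_len(n))
    nn <- t(vapply(seq_len(n), function(i) {
      d <- D[i, ]
      d[i] <- Inf
      order(d, seq_len(n))[seq_len(k)]
    }, integer(k)))
    if (k == 1) nn <- matrix(nn, ncol = 1)
  } else {
    n <- nrow(coords)
    if (k >= n) {
      abort("`k` must be smaller than the number of clones.",
            class = "clonespace_parameter_error")
    }
    clone_ids <- rownames(coords) %||% paste0("clone", seq_len(n))
    nn <- .knn_exact(coords, k)
  }
  edges <- cbind(rep(seq_len(n), times = k), as.vector(nn))
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  g <- igraph::as_undirected(g, mode = "collapse")
  g <- igraph::simplify(g)
  igraph::V(g)$name <- clone_ids
  structure(list(graph = g, clone_ids = clone_ids, k = k, source = mode),
            class = "clone_graph")
}

#' @exportS3Method
print.clone_graph <- function(x, ...) {
  cat(sprintf("<clone_graph> %d clones, k = %d, %d edges (%s)\n",
              length(x$clone_ids), x$k, igraph::ecount(x$graph), x$source))
  invisible(x)
}

# Symmetrised binary adjacency (union) of a clone graph, sparse.
clone_graph_adjacency <- function(graph) {
  A <- igraph::as_adjacency_matrix(graph$graph, sparse = TRUE)
  methods::as(A, "CsparseMatrix")
}

#' Leiden community detection on the clone graph
#'
#' Modularity-objective Leiden communities; deterministic given `seed`.
#'
#' @param graph A `clone_graph`.
#' @param resolution Resolution parameter (default 1).
#' @param seed Integer seed.
#' @param n_iterations Leiden refinement iterations (default 5).
#' @return Tibble with `clone`, `cluster` (integer, 1-based, attribute
#'   `resolution` and `seed` stored on the result).
#' @export
cluster_clones <- function(graph, resolution = 1, seed = 1, n_iterations = 5) {
  res <- with_seed(seed, {
    igraph::cluster_leiden(graph$graph, objective_function = "modularity",
                           resolution = resolution,
                           n_iterations = n_iterations)
  })
  out <- tibble(clone = graph$clone_ids,
                cluster = as.integer(igraph::membership(res)))
  attr(out, "resolution") <- resolution
  attr(out, "seed") <- seed
  out
}

# Euclidean projection of each row of W onto the probability simplex
# (sort-based algorithm; deterministic).
project_rows_simplex <- function(W) {
  out <- W
  for (i in seq_len(nrow(W))) {
    v <- W[i, ]
    u <- sort(v, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u + (1 - css) / seq_along(u) > 0))
    theta <- (css[rho] - 1) / rho
    out[i, ] <- pmax(v - theta, 0)
  }
  out
}

#' Archetypal analysis of the clone embedding
#'
#' Fits a convex polytope with `A` vertices to the clone coordinates:
#' minimises `||X - W B X||^2` where the weight rows of `W` (clone over
#' archetypes) and of `B` (archetype over clones) live on the probability
#' simplex, so each clone is a convex mixture of archetypes and each
#' archetype a convex mixture of clones. Optimisation alternates projected
#' gradient updates of `W` and `B` with Lipschitz step sizes; each
#' half-step is monotone, so the recorded RSS never increases.
#' Initialisation places archetypes on a furthest-point subset of the
#' clones (seeded).
#'
#' @param embedding A [clone_embedding()] or coordinate matrix.
#' @param A Number of archetypes.
#' @param max_iter Outer iterations (default 200).
#' @param tol Relative RSS-change convergence threshold (default 1e-8).
#' @param seed Integer seed for the furthest-point initialisation.
#' @param inner_iter Projected-gradient steps per half update (default 30).
#' @return Object of class `archetype_fit`: `W` (C x A), `B` (A x C),
#'   `archetype_coords` (`B %*% X`), `rss_history`, `converged`.
#' @export
fit_archetypes <- function(embedding, A, max_iter = 200, tol = 1e-8,
                           seed = 1, inner_iter = 30) {
  X <- if (inherits(embedding, "clone_embedding")) embedding$coords else embedding
  assert_finite_matrix(X, "embedding")
  C <- nrow(X)
  A <- assert_scalar_int(A, "A", min = 1)
  if (A > C) abort("`A` cannot exceed the number of clones.",
                   class = "clonespace_parameter_error")

  # furthest-point initialisation: seeded random start, then maximin
  init_idx <- with_seed(seed, {
    idx <- integer(A)
    idx[1] <- sample.int(C, 1)
    if (A > 1) {
      d2 <- rowSums((X - matrix(X[idx[1], ], C, ncol(X), byrow = TRUE))^2)
      for (t in seq(2, A)) {
        idx[t] <- which.max(d2)
        d2 <- pmin(d2, rowSums((X - matrix(X[idx[t], ], C, ncol(X),
                                           byrow = TRUE))^2))
      }
    }
    idx
  })
  B <- matrix(0, A, C)
  B[cbind(seq_len(A), init_idx)] <- 1
  W <- matrix(1 / A, C, A)

  rss <- function(W, B) sum((X - W %*% B %*% X)^2)
  hist <- rss(W, B)
  XXt_norm <- norm(X %*% t(X), "2")

  it <- max_iter
  for (it in seq_len(max_iter)) {
    # W step: f(W) = ||X - W Z||^2, Z = B X; Lipschitz const 2||Z Z'||
    Z <- B %*% X
    G <- Z %*% t(Z)
    L <- 2 * max(norm(G, "2"), 1e-12)
    for (s in seq_len(inner_iter)) {
      grad <- 2 * (W %*% G - X %*% t(Z))
      W <- project_rows_simplex(W - grad / L)
    }
    # B step: f(B) = ||X - W B X||^2; grad = 2 W'(W B X - X) X'
    WtW <- t(W) %*% W
    L2 <- 2 * max(norm(WtW, "2") * XXt_norm, 1e-12)
    for (s in seq_len(inner_iter)) {
      R <- W %*% B %*% X - X
      grad <- 2 * t(W) %*% R %*% t(X)
      B <- project_rows_simplex(B - grad / L2)
    }
    cur <- rss(W, B)
    hist <- c(hist, min(cur, utils::tail(hist, 1)))
    if (utils::tail(hist, 2)[1] - cur < tol * (hist[1] + 1e-300)) break
  }
  converged <- it < max_iter
  if (!converged) {
    warn("Archetypal analysis hit max_iter; best iterate returned.")
  }
  rownames(W) <- rownames(X)
  structure(list(W = W, B = B, archetype_coords = B %*% X, A = A,
                 rss_history = hist, converged = converged,
                 clone_ids = rownames(X)),
            class = "archetype_fit")
}

#' @exportS3Method
print.archetype_fit <- function(x, ...) {
  cat(sprintf("<archetype_fit> %d archetypes over %d clones, RSS %.4g\n",
              x$A, nrow(x$W), utils::tail(x$rss_history, 1)))
  invisible(x)
}

#' Hard archetype assignment
#'
#' Labels each clone with the archetype carrying the largest weight; ties
#' go to the lowest archetype index.
#'
#' @param model An `archetype_fit`.
#' @return Tibble with `clone`, `archetype` (integer) and `weight` (the
#'   winning weight).
#' @export
hard_assign_archetypes <- function(model) {
  lab <- apply(model$W, 1, which.max)  # which.max takes the first tie
  tibble(clone = model$clone_ids %||% paste0("clone", seq_len(nrow(model$W))),
         archetype = as.integer(lab),
         weight = model$W[cbind(seq_len(nrow(model$W)), lab)])
}

#' RSS-versus-A elbow diagnostics for archetype selection
#'
#' Fits archetypal analysis over a range of polytope sizes and reports the
#' residual sum of squares and fraction of variance explained, supporting a
#' manual elbow choice of `A`.
#'
#' @inheritParams fit_archetypes
#' @param A_range Candidate numbers of archetypes.
#' @return Tibble with `A`, `rss`, `variance_explained`.
#' @export
archetype_elbow <- function(embedding, A_range = 2:8, max_iter = 100,
                            seed = 1) {
  X <- if (inherits(embedding, "clone_embedding")) embedding$coords else embedding
  total <- sum(scale(X, scale = FALSE)^2)
  purrr::map_dfr(A_range, function(A) {
    fit <- fit_archetypes(embedding, A, max_iter = max_iter, seed = seed)
    r <- utils::tail(fit$rss_history, 1)
    tibble(A = A, rss = r, variance_explained = 1 - r / total)
  })
}
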