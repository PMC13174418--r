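#' Fit the skip-gram clonal embedding
#'
#' Factorises the clone co-occurrence matrix with a single-hidden-layer
#' linear network: scores `u_i . V` over context clones are pushed through
#' a softmax and compared with the empirical neighbour distribution of
#' clone i under a multinomial likelihood. Training runs by mini-batch SGD
#' over the multiset of (target, context) pairs, each pair repeated
#' `N[i, j]` times and reshuffled every epoch. The input-to-hidden weights
#' `U` are the clone embedding.
#'
#' The mean per-event negative log-likelihood is evaluated on the full data
#' after every epoch. An epoch that increases it is rolled back and retried
#' at half the learning rate, so the recorded loss history is
#' non-increasing; training stops at `epochs` or when the improvement falls
#' below `min_rel_improve` of the initial loss.
#'
#' @param cooc A `clone_cooc` from [aggregate_cooccurrence()].
#' @param z Latent dimension (default 10).
#' @param epochs Maximum training epochs (default 100).
#' @param lr Initial SGD learning rate (default 0.05).
#' @param batch_size Events per mini-batch (default 1024).
#' @param seed Integer seed; initialisation and shuffles are reproducible
#'   (bit-identical reruns under a single thread).
#' @param min_rel_improve Plateau threshold relative to the initial NLL.
#' @return Object of class `skipgram_fit` with `U` (C x z embedding), `V`
#'   (z x M context weights), `loss_history` (mean NLL per epoch, entry 1 =
#'   before training), `z`, `seed`, `clone_ids`, `context_ids`.
#' @export
fit_skipgram <- function(cooc, z = 10, epochs = 100, lr = 0.05,
                         batch_size = 1024, seed = 1,
                         min_rel_improve = 1e-5) {
  N <- cooc$counts
  C <- nrow(N)
  M <- ncol(N)
  if (C < 2) abort("Need at least two clones.", class = "clonespace_parameter_error")
  if (sum(N) == 0) {
    abort("All-zero co-occurrence matrix.", class = "clonespace_degenerate_error")
  }
  z <- assert_scalar_int(z, "z", min = 1)
  if (z >= C) abort("`z` must be smaller than the number of clones.",
                    class = "clonespace_parameter_error")
  # general storage: symmetric/triangular classes keep only one triangle
  N <- methods::as(methods::as(N, "generalMatrix"), "CsparseMatrix")
  Nt <- methods::as(N, "TsparseMatrix")
  mult <- as.integer(round(Nt@x))
  ev_i <- rep.int(Nt@i, mult)          # 0-based
  ev_j <- rep.int(Nt@j, mult)
  # CSR pieces for the NLL evaluation
  Ncsr <- methods::as(Matrix::t(N), "CsparseMatrix")
  row_ptr <- Ncsr@p
  col_idx <- Ncsr@i
  vals <- Ncsr@x

  res <- with_seed(seed, {
    U0 <- matrix(rnorm(C * z, sd = 0.1 / sqrt(z)), C, z)
    V0 <- matrix(rnorm(z * M, sd = 0.1 / sqrt(z)), z, M)
    .skipgram_sgd(ev_i, ev_j, U0, V0, row_ptr, col_idx, vals,
                  lr = lr, epochs = epochs, batch_size = batch_size,
                  min_rel_improve = min_rel_improve, max_retry = 10L)
  })
  U <- res$U
  rownames(U) <- cooc$clone_ids
  V <- res$V
  colnames(V) <- cooc$context_ids
  structure(list(U = U, V = V, z = z, loss_history = res$loss,
                 seed = seed, lr_final = res$lr_final,
                 epochs_run = res$epochs_run,
                 clone_ids = cooc$clone_ids, context_ids = cooc$context_ids),
            class = "skipgram_fit")
}

#' @exportS3Method
print.skipgram_fit <- function(x, ...) {
  cat(sprintf(
    "<skipgram_fit> %d clones, z = %d, %d epochs, NLL %.4f -> %.4f\n",
    nrow(x$U), x$z, x$epochs_run, x$loss_history[1],
    utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Predicted neighbour distribution of a clone
#'
#' Softmax of the fitted output scores for one target clone: the model's
#' probability of drawing each context clone in its expression
#' neighbourhood.
#'
#' @param model A `skipgram_fit`.
#' @param clone Clone index (1-based) or clone id.
#' @return Named probability vector over context entities (sums to 1).
#' @export
predict_neighbor_distribution <- function(model, clone) {
  if (is.character(clone)) clone <- match(clone, model$clone_ids)
  if (is.na(clone) || clone < 1 || clone > nrow(model$U)) {
    abort("Clone index out of range.", class = "clonespace_parameter_error")
  }
  s <- drop(model$U[clone, , drop = FALSE] %*% model$V)
  s <- s - max(s)
  p <- exp(s) / sum(exp(s))
  names(p) <- model$context_ids
  p
}

#' Multinomial negative log-likelihood of a fitted skip-gram model
#'
#' `sum_ij N[i, j] * -log softmax_j(u_i . V)`, the full-data training
#' objective (not averaged per event).
#'
#' @param cooc The `clone_cooc` the model was (or could be) fitted to.
#' @param model A `skipgram_fit`.
#' @return Nonnegative scalar.
#' @export
multinomial_nll <- function(cooc, model) {
  N <- as.matrix(cooc$counts)
  if (!all(dim(N) == c(nrow(model$U), ncol(model$V)))) {
    abort("Model and co-occurrence shapes do not match.",
          class = "clonespace_parameter_error")
  }
  S <- model$U %*% model$V
  lse <- apply(S, 1, function(s) {
    m <- max(s)
    m + log(sum(exp(s - m)))
  })
  sum(N * (lse - S))
}

#' Poisson GLM-PCA factorisation of the co-occurrence matrix
#'
#' Scalable alternative to the multinomial skip-gram: models
#' `log E N[i, j] = alpha_i + beta_j + u_i . v_j`, where the row and column
#' intercepts absorb clone-size effects, and fits by alternating per-row /
#' per-column damped Newton Poisson regressions. The Poisson likelihood
#' decouples the context units, so each half-step is a set of independent
#' small regressions and the total deviance is non-increasing across outer
#' iterations.
#'
#' @inheritParams fit_skipgram
#' @param max_iter Maximum outer iterations (default 100).
#' @param tol Convergence threshold on the deviance change, relative to the
#'   initial deviance (default 1e-6).
#' @return Object of class `glmpca_fit` with `U` (C x z, the clone
#'   embedding), `V`, `alpha`, `beta`, `deviance_history`, `converged`.
#' @export
fit_poisson_glmpca <- function(cooc, z = 10, max_iter = 100, tol = 1e-6,
                               seed = 1) {
  N <- as.matrix(cooc$counts)
  C <- nrow(N)
  M <- ncol(N)
  if (C < 2) abort("Need at least two clones.", class = "clonespace_parameter_error")
  z <- assert_scalar_int(z, "z", min = 1)
  tot <- sum(N)
  rs <- pmax(rowSums(N), 0.5)
  cs <- pmax(colSums(N), 0.5)
  a0 <- log(rs) - 0.5 * log(tot)
  b0 <- log(cs) - 0.5 * log(tot)
  res <- with_seed(seed, {
    U0 <- matrix(rnorm(C * z, sd = 1e-2 / sqrt(z)), C, z)
    V0 <- matrix(rnorm(M * z, sd = 1e-2 / sqrt(z)), M, z)
    .glmpca_fit(N, U0, V0, a0, b0, max_iter = max_iter, tol = tol)
  })
  if (!res$converged) {
    warn(sprintf("Poisson GLM-PCA did not converge in %d iterations; best iterate returned.",
                 max_iter))
  }
  U <- res$U
  rownames(U) <- cooc$clone_ids
  V <- res$V
  rownames(V) <- cooc$context_ids
  structure(list(U = U, V = V, alpha = drop(res$alpha), beta = drop(res$beta),
                 z = z, deviance_history = res$deviance,
                 iterations = res$iterations, converged = res$converged,
                 seed = seed, clone_ids = cooc$clone_ids,
                 context_ids = cooc$context_ids),
            class = "glmpca_fit")
}

#' @exportS3Method
print.glmpca_fit <- function(x, ...) {
  cat(sprintf(
    "<glmpca_fit> %d clones, z = %d, %d iterations, deviance %.4g -> %.4g%s\n",
    nrow(x$U), x$z, x$iterations, x$deviance_history[1],
    utils::tail(x$deviance_history, 1),
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Extract the clone embedding from a fitted factorisation
#'
#' @param fit A `skipgram_fit` or `glmpca_fit`.
#' @return Object of class `clone_embedding`: `coords` (C x z matrix, clone
#'   ids as row names) and `provenance` (`"skipgram"` or `"poisson"`).
#' @export
clone_embedding <- function(fit) {
  UseMethod("clone_embedding")
}

#' @export
clone_embedding.skipgram_fit <- function(fit) {
  new_clone_embedding(fit$U, "skipgram")
}

#' @export
clone_embedding.glmpca_fit <- function(fit) {
  new_clone_embedding(fit$U, "poisson")
}

#' @export
clone_embedding.matrix <- function(fit) {
  new_clone_embedding(fit, "user")
}

new_clone_embedding <- function(coords, provenance) {
  assert_finite_matrix(coords, "coords")
  if (is.null(rownames(coords))) {
    rownames(coords) <- paste0("clone", seq_len(nrow(coords)))
  }
  colnames(coords) <- paste0("Z", seq_len(ncol(coords)))
  structure(list(coords = coords, provenance = provenance),
            class = "clone_embedding")
}

#' @exportS3Method
print.clone_embedding <- function(x, ...) {
  cat(sprintf("<clone_embedding> %d clones x %d dims (%s)\n",
              nrow(x$coords), ncol(x$coords), x$provenance))
  invisible(x)
}

#' @rdname clone_embedding
#' @param x A `clone_embedding`.
#' @param ... Unused.
#' @export
tidy.clone_embedding <- function(x, ...) {
  dplyr::bind_cols(tibble(clone = rownames(x$coords)), as_tibble(x$coords))
}

#' Write a clone embedding as TSV (clone id + z columns)
#'
#' @param embedding A `clone_embedding`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  readr::write_tsv(tidy(embedding), path, progress = FALSE)
  invisible(path)
}
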