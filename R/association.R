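#' Clone-level pseudobulk expression
#'
#' Averages log-normalised expression over the (optionally masked) cells of
#' each clone, making clones the units of replication for downstream
#' tests. Clones with no masked cell are dropped with a warning.
#'
#' @param expr Cells x genes matrix of log-normalised values, cell ids as
#'   row names.
#' @param labeling A [clonal_labeling()].
#' @param cell_mask Optional logical vector (named by cell id or aligned to
#'   `expr` rows) restricting to a cell type of interest.
#' @return Clones x genes matrix, clone ids as row names.
#' @export
clone_pseudobulk <- function(expr, labeling, cell_mask = NULL) {
  ids <- rownames(expr)
  if (is.null(ids)) abort("`expr` needs cell ids as row names.",
                          class = "clonespace_validation_error")
  if (is.null(cell_mask)) {
    cell_mask <- rep(TRUE, nrow(expr))
  } else if (!is.null(names(cell_mask))) {
    cell_mask <- unname(cell_mask[ids])
  }
  cell_mask[is.na(cell_mask)] <- FALSE
  if (!any(cell_mask)) {
    abort("Mask excludes every cell.", class = "clonespace_degenerate_error")
  }
  clone <- labeling$clone[ids]
  keep <- cell_mask & !is.na(clone)
  groups <- split(which(keep), clone[keep])
  dropped <- setdiff(labeling$clone_ids, names(groups))
  if (length(dropped) > 0) {
    warn(sprintf("%d clones have no cell passing the mask and were dropped.",
                 length(dropped)))
  }
  out <- t(vapply(groups, function(rows) {
    colMeans(expr[rows, , drop = FALSE])
  }, numeric(ncol(expr))))
  if (ncol(expr) == 1) out <- matrix(out, ncol = 1)
  rownames(out) <- names(groups)
  colnames(out) <- colnames(expr)
  out
}

#' Welch's t differential expression between clone groups
#'
#' Two-sided Welch's t-test per gene on clone-level pseudobulk rows, with
#' Benjamini-Hochberg correction across genes. Genes with zero variance in
#' both groups get statistic 0 and p = 1 by convention. `logFC` is the
#' difference of group means on the log scale.
#'
#' @param pb Pseudobulk matrix from [clone_pseudobulk()].
#' @param groupA,groupB Disjoint character vectors of clone ids (each of
#'   size >= 2).
#' @return Tibble with `gene`, `statistic`, `df`, `logFC`, `p`, `q`.
#' @export
clone_differential_expression <- function(pb, groupA, groupB) {
  if (length(intersect(groupA, groupB)) > 0) {
    abort("Groups must be disjoint.", class = "clonespace_parameter_error")
  }
  if (length(groupA) < 2 || length(groupB) < 2) {
    abort("Each group needs at least two clones.",
          class = "clonespace_parameter_error")
  }
  XA <- pb[groupA, , drop = FALSE]
  XB <- pb[groupB, , drop = FALSE]
  nA <- nrow(XA); nB <- nrow(XB)
  mA <- colMeans(XA); mB <- colMeans(XB)
  vA <- apply(XA, 2, var); vB <- apply(XB, 2, var)
  se2 <- vA / nA + vB / nB
  stat <- ifelse(se2 > 0, (mA - mB) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1)),
               NA_real_)
  p <- ifelse(se2 > 0, 2 * pt(-abs(stat), df), 1)
  tibble(gene = colnames(pb) %||% paste0("g", seq_along(stat)),
         statistic = unname(stat), df = unname(df),
         logFC = unname(mA - mB), p = unname(p),
         q = p.adjust(unname(p), method = "BH"))
}

#' Cell-type-expanded pseudobulk with marker signal removed
#'
#' Represents each clone by one row per cell type it spans (mean
#' log-normalised expression over that clone's cells of that type), then
#' subtracts the per-cell-type mean computed across all clones, removing
#' cell-type marker signal so that only clone-specific deviations remain.
#'
#' @inheritParams clone_pseudobulk
#' @param cell_type Character vector of cell types (named by cell id or
#'   aligned to `expr` rows).
#' @return Matrix with rows named `"<clone>|<cell_type>"`; attributes
#'   `clone` and `cell_type` give the row keys.
#' @export
expand_clones_by_celltype <- function(expr, labeling, cell_type) {
  ids <- rownames(expr)
  if (!is.null(names(cell_type))) cell_type <- unname(cell_type[ids])
  clone <- labeling$clone[ids]
  keep <- !is.na(clone) & !is.na(cell_type)
  key <- paste(clone[keep], cell_type[keep], sep = "|")
  groups <- split(which(keep), key)
  out <- t(vapply(groups, function(rows) colMeans(expr[rows, , drop = FALSE]),
                  numeric(ncol(expr))))
  rownames(out) <- names(groups)
  colnames(out) <- colnames(expr)
  parts <- strsplit(names(groups), "|", fixed = TRUE)
  row_clone <- vapply(parts, `[`, "", 1)
  row_type <- vapply(parts, `[`, "", 2)
  # centre within cell type across clones
  for (ct in unique(row_type)) {
    rows <- row_type == ct
    out[rows, ] <- sweep(out[rows, , drop = FALSE], 2,
                         colMeans(out[rows, , drop = FALSE]))
  }
  attr(out, "clone") <- row_clone
  attr(out, "cell_type") <- row_type
  out
}

#' Graph-aware supervised PCA
#'
#' Identifies the directions in gene expression space along which
#' neighbouring clones (in embedding space) are most similar: centres the
#' pseudobulk columns, forms the symmetrised binary affinity `K` of the
#' clone kNN graph, and solves the eigenproblem of `M = X' K X`. With
#' `K = I` this reduces to ordinary PCA. Eigenvalues rank the components by
#' how much neighbour-structured variation they capture.
#'
#' @param pb Pseudobulk matrix (clones x genes), clone ids as row names.
#' @param graph A `clone_graph` over (a superset of) the pseudobulk rows,
#'   or `NULL` for the identity affinity.
#' @param n_components Number of components to return.
#' @param normalize_degree Divide the affinity by node degree (off by
#'   default).
#' @return Object of class `spca_fit`: `loadings` (genes x components,
#'   orthonormal), `eigenvalues` (non-increasing), `scores` (clones x
#'   components), `graph_k`.
#' @export
supervised_pca <- function(pb, graph = NULL, n_components = 10,
                           normalize_degree = FALSE) {
  X <- scale(pb, center = TRUE, scale = FALSE)
  n <- nrow(X)
  if (is.null(graph)) {
    K <- Matrix::Diagonal(n)
  } else {
    if (!all(rownames(pb) %in% graph$clone_ids)) {
      abort("Graph must cover all pseudobulk rows.",
            class = "clonespace_validation_error")
    }
    A <- clone_graph_adjacency(graph)
    A <- A[rownames(pb), rownames(pb)]
    K <- (A + Matrix::t(A)) / 2
    K@x[K@x > 0] <- 1  # binary union adjacency
    if (normalize_degree) {
      d <- pmax(Matrix::rowSums(K), 1)
      K <- Matrix::Diagonal(x = 1 / sqrt(d)) %*% K %*%
        Matrix::Diagonal(x = 1 / sqrt(d))
    }
  }
  M <- crossprod(X, as.matrix(K %*% X))
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  r <- sum(eig$values > max(eig$values[1], 0) * 1e-12)
  if (n_components > r) {
    warn(sprintf("Requested %d components but rank is %d; truncating.",
                 n_components, r))
    n_components <- r
  }
  loadings <- eig$vectors[, seq_len(n_components), drop = FALSE]
  rownames(loadings) <- colnames(pb)
  colnames(loadings) <- paste0("SPC", seq_len(n_components))
  scores <- X %*% loadings
  structure(list(loadings = loadings,
                 eigenvalues = eig$values[seq_len(n_components)],
                 scores = scores,
                 graph_k = if (is.null(graph)) NA_integer_ else graph$k),
            class = "spca_fit")
}

#' @exportS3Method
print.spca_fit <- function(x, ...) {
  cat(sprintf("<spca_fit> %d components over %d genes\n",
              ncol(x$loadings), nrow(x$loadings)))
  invisible(x)
}

#' Moran's I on the clone graph
#'
#' Graph autocorrelation of a per-clone signal with row-standardised
#' weights:
#' `I = (n / sum(W)) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`.
#'
#' @param values Numeric vector, one value per clone (graph order).
#' @param graph A `clone_graph`.
#' @return Scalar Moran's I.
#' @export
morans_i <- function(values, graph) {
  n <- length(values)
  if (n < 3) abort("Need at least three clones.",
                   class = "clonespace_parameter_error")
  if (sd(values) == 0) {
    abort("Moran's I is undefined for a constant vector.",
          class = "clonespace_degenerate_error")
  }
  W <- morans_weights(graph)
  xc <- values - mean(values)
  s0 <- sum(W)
  as.numeric((n / s0) * sum(xc * as.vector(W %*% xc)) / sum(xc^2))
}

# Row-standardised sparse weight matrix of a clone graph.
morans_weights <- function(graph) {
  A <- clone_graph_adjacency(graph)
  A <- (A + Matrix::t(A))
  A@x[A@x > 0] <- 1
  d <- Matrix::rowSums(A)
  d[d == 0] <- 1
  Matrix::Diagonal(x = 1 / d) %*% A
}

#' Permutation test of graph structure for every gene
#'
#' Tests, per gene, whether expression is more structured over the clone
#' graph than expected by chance: one-sided permutation p-value
#' `(1 + #{I_perm >= I_obs}) / (1 + n_perm)`, BH-adjusted across genes.
#' Genes that are constant across clones return `NA`.
#'
#' @param pb Pseudobulk matrix (clones x genes) aligned to the graph order.
#' @param graph A `clone_graph`.
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Integer seed.
#' @return Tibble with `gene`, `statistic` (observed I), `p`, `q`.
#' @export
morans_i_test <- function(pb, graph, n_perm = 999, seed = 1) {
  n_perm <- assert_scalar_int(n_perm, "n_perm", min = 99)
  W <- morans_weights(graph)
  n <- nrow(pb)
  s0 <- sum(W)
  Xc <- scale(pb, center = TRUE, scale = FALSE)
  denom <- colSums(Xc^2)
  ok <- denom > 0
  i_of <- function(M) (n / s0) * colSums(M * as.matrix(W %*% M)) /
    pmax(colSums(M^2), 1e-300)
  obs <- i_of(Xc)
  exceed <- integer(ncol(pb))
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      P <- apply(Xc, 2, sample)
      exceed <- exceed + as.integer(i_of(P) >= obs)
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  p[!ok] <- NA_real_
  tibble(gene = colnames(pb) %||% paste0("g", seq_len(ncol(pb))),
         statistic = ifelse(ok, unname(obs), NA_real_),
         p = unname(p),
         q = p.adjust(unname(p), method = "BH"))
}

#' Permutation test of clonotype frequency per cluster and stratum
#'
#' For every (cluster, stratum) pair, the statistic is the difference
#' between the cluster's mean clonotype frequency and the unweighted mean
#' of all cluster means in that stratum. The null permutes cluster labels
#' within the stratum; the two-sided p-value is
#' `(1 + #{|stat_perm| >= |stat_obs|}) / (1 + n_perm)`, BH-adjusted across
#' all pairs. Clusters absent from a stratum return `NA` with a warning.
#'
#' @param data Data frame with columns `clone`, `freq`, `cluster` and
#'   (optionally) `stratum`; one row per clone per stratum.
#' @param n_perm Number of permutations (default 1e5).
#' @param seed Integer seed.
#' @return Tibble with `stratum`, `cluster`, `statistic`, `p`, `q`.
#' @export
frequency_permutation_test <- function(data, n_perm = 1e5, seed = 1) {
  n_perm <- assert_scalar_int(n_perm, "n_perm", min = 1)
  if (!"stratum" %in% names(data)) data$stratum <- "all"
  data <- dplyr::arrange(as_tibble(data), .data$stratum, .data$clone)
  all_clusters <- sort(unique(data$cluster))
  out <- list()
  with_seed(seed, {
    for (s in sort(unique(data$stratum))) {
      d <- data[data$stratum == s, ]
      if (length(unique(d$cluster)) < 2) {
        abort("Each stratum needs at least two clusters.",
              class = "clonespace_parameter_error")
      }
      cl <- as.character(d$cluster)
      freq <- d$freq
      sizes <- table(cl)
      present <- names(sizes)
      # permuting cluster labels within the stratum is equivalent to
      # permuting the frequency vector against fixed cluster membership
      mu_of <- function(F) sweep(rowsum(F, cl), 1, as.vector(sizes), "/")
      obs_mu <- mu_of(matrix(freq, ncol = 1))
      obs <- drop(obs_mu - mean(obs_mu))
      names(obs) <- present
      exceed <- setNames(numeric(length(present)), present)
      done <- 0
      chunk <- 2000L
      while (done < n_perm) {
        b <- min(chunk, n_perm - done)
        F <- vapply(seq_len(b), function(i) sample(freq), numeric(length(freq)))
        mu <- mu_of(F)
        st <- sweep(mu, 2, colMeans(mu))
        exceed <- exceed + rowSums(abs(st) >= abs(obs) - 1e-12)
        done <- done + b
      }
      p <- (1 + exceed) / (1 + n_perm)
      missing_cl <- setdiff(as.character(all_clusters), present)
      if (length(missing_cl) > 0) {
        warn(sprintf("Clusters absent from stratum '%s': %s", s,
                     paste(missing_cl, collapse = ", ")))
      }
      out[[s]] <- tibble(stratum = s,
                         cluster = c(present, missing_cl),
                         statistic = c(unname(obs[present]),
                                       rep(NA_real_, length(missing_cl))),
                         p = c(unname(p), rep(NA_real_, length(missing_cl))))
    }
  })
  res <- dplyr::bind_rows(out)
  res$q <- p.adjust(res$p, method = "BH")
  res
}
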