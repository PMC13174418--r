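#' Shared reduced space for anchor finding
#'
#' Clonal embeddings are identifiable only up to a linear map, so matching
#' clones across cohorts needs an external reference. This builds one from
#' per-clone average expression: clones from all cohorts are concatenated
#' as pseudo-cells, highly variable genes are chosen batch-aware (cohort as
#' batch), expression is scaled per cohort, PCA is computed, and the PCA
#' space is passed through a pluggable batch-correction stage (identity by
#' default).
#'
#' @param pseudobulks Named list of clone x gene matrices (log-normalised),
#'   one per cohort; gene namespaces are intersected.
#' @param n_hvg Number of highly variable genes (default 2000, capped at
#'   the number of shared genes).
#' @param n_pcs Number of principal components (default 30, capped).
#' @param correction Function `(coords, cohort) -> coords` applied to the
#'   PCA space; the default identity keeps the pipeline self-contained.
#' @param scale_by Scaling stage: `"cohort"` (default, genes standardised
#'   within each cohort) or `"pooled"` (standardised over the concatenated
#'   clones); every stage of the pipeline is swappable.
#' @return Tibble with `clone`, `cohort` and `PC1..PCn` columns.
#' @export
build_anchor_space <- function(pseudobulks, n_hvg = 2000, n_pcs = 30,
                               correction = NULL,
                               scale_by = c("cohort", "pooled")) {
  scale_by <- match.arg(scale_by)
  if (is.null(names(pseudobulks))) {
    names(pseudobulks) <- paste0("cohort", seq_along(pseudobulks))
  }
  shared <- Reduce(intersect, lapply(pseudobulks, colnames))
  if (length(shared) == 0) {
    abort("No shared genes across cohorts.", class = "clonespace_validation_error")
  }
  if (length(shared) < 50) {
    warn(sprintf("Only %d shared genes across cohorts.", length(shared)))
  }
  mats <- lapply(pseudobulks, function(m) m[, shared, drop = FALSE])

  # batch-aware HVG: rank genes by variance within each cohort, keep the
  # genes with the best (lowest) mean rank
  n_hvg <- min(n_hvg, length(shared))
  ranks <- vapply(mats, function(m) {
    v <- apply(m, 2, var)
    rank(-v, ties.method = "first")
  }, numeric(length(shared)))
  hvg <- shared[order(rowMeans(ranks))][seq_len(n_hvg)]

  if (scale_by == "cohort") {
    scaled <- lapply(mats, function(m) {
      s <- scale(m[, hvg, drop = FALSE])
      s[!is.finite(s)] <- 0  # zero-variance genes within a cohort
      s
    })
    X <- do.call(rbind, scaled)
  } else {
    X <- scale(do.call(rbind, lapply(mats, function(m) {
      m[, hvg, drop = FALSE]
    })))
    X[!is.finite(X)] <- 0
  }
  cohort <- rep(names(mats), vapply(mats, nrow, 1L))
  clone <- unlist(lapply(mats, rownames), use.names = FALSE)
  n_pcs <- min(n_pcs, ncol(X), nrow(X) - 1)
  pca <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n_pcs)
  coords <- pca$x
  if (!is.null(correction)) coords <- correction(coords, cohort)
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  dplyr::bind_cols(tibble(clone = clone, cohort = cohort), as_tibble(coords))
}

#' Mutual-nearest-neighbour anchors between cohorts
#'
#' A pair (a, b) from cohorts A and B is an anchor iff b is among the
#' `k_anchor` nearest neighbours of a within cohort B and vice versa
#' (Euclidean metric in the shared reduced space). Anchor weights default
#' to uniform; the weight definition is a declared package choice, with an
#' inverse-distance option `1 / (1 + d)`.
#'
#' @param coords Tibble from [build_anchor_space()] (columns `clone`,
#'   `cohort`, coordinates), or a matrix plus a `cohort` vector.
#' @param cohort Cohort per row when `coords` is a matrix.
#' @param k_anchor Neighbours considered per side (default 5); reduced with
#'   a warning for cohorts smaller than `k_anchor`.
#' @param weighting `"uniform"` (default) or `"inverse_distance"`.
#' @return Tibble with `clone_a`, `clone_b`, `cohort_a`, `cohort_b`,
#'   `distance`, `weight`.
#' @export
find_mutual_anchors <- function(coords, cohort = NULL, k_anchor = 5,
                                weighting = c("uniform", "inverse_distance")) {
  weighting <- match.arg(weighting)
  if (is.data.frame(coords)) {
    cohort <- coords$cohort
    clone <- coords$clone
    X <- as.matrix(coords[, grep("^PC", names(coords)), drop = FALSE])
  } else {
    X <- coords
    clone <- rownames(X) %||% paste0("clone", seq_len(nrow(X)))
  }
  cohorts <- sort(unique(cohort))
  if (length(cohorts) < 2) {
    abort("Need at least two cohorts.", class = "clonespace_parameter_error")
  }
  out <- list()
  for (ia in seq_along(cohorts)) {
    for (ib in seq_along(cohorts)) {
      if (ib <= ia) next
      a <- which(cohort == cohorts[ia])
      b <- which(cohort == cohorts[ib])
      k <- min(k_anchor, length(a), length(b))
      if (k < k_anchor) {
        warn(sprintf("k_anchor reduced to %d for pair (%s, %s).", k,
                     cohorts[ia], cohorts[ib]))
      }
      nb_ab <- .knn_cross(X[a, , drop = FALSE], X[b, , drop = FALSE], k)
      nb_ba <- .knn_cross(X[b, , drop = FALSE], X[a, , drop = FALSE], k)
      # mutual pairs
      hits_ab <- cbind(rep(seq_along(a), k), as.vector(nb_ab))
      mutual <- hits_ab[vapply(seq_len(nrow(hits_ab)), function(r) {
        i <- hits_ab[r, 1]; j <- hits_ab[r, 2]
        i %in% nb_ba[j, ]
      }, logical(1)), , drop = FALSE]
      if (nrow(mutual) == 0) next
      d <- sqrt(rowSums((X[a[mutual[, 1]], , drop = FALSE] -
                           X[b[mutual[, 2]], , drop = FALSE])^2))
      w <- if (weighting == "uniform") rep(1, length(d)) else 1 / (1 + d)
      out[[length(out) + 1]] <- tibble(
        clone_a = clone[a[mutual[, 1]]], clone_b = clone[b[mutual[, 2]]],
        cohort_a = cohorts[ia], cohort_b = cohorts[ib],
        distance = d, weight = w)
    }
  }
  if (length(out) == 0) {
    return(tibble(clone_a = character(), clone_b = character(),
                  cohort_a = character(), cohort_b = character(),
                  distance = numeric(), weight = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Weighted affine map between anchor coordinate sets
#'
#' Solves `min sum w || L s + t - tau ||^2` in closed form via the weighted
#' normal equations. The fit is invariant to rescaling all weights.
#'
#' @param source,target Matrices of matched anchor coordinates (rows are
#'   anchors).
#' @param weights Nonnegative anchor weights (default uniform).
#' @param ridge Ridge penalty added to the normal equations; `0` (default)
#'   raises a singularity error on rank-deficient designs.
#' @return Object of class `affine_map`: `linear` (z x z, acts on column
#'   vectors) and `translation` (length z).
#' @export
fit_weighted_affine <- function(source, target, weights = NULL, ridge = 0) {
  if (nrow(source) != nrow(target)) {
    abort("Source and target must have matching rows.",
          class = "clonespace_alignment_error")
  }
  z <- ncol(source)
  if (is.null(weights)) weights <- rep(1, nrow(source))
  A <- cbind(source, 1)
  AtWA <- crossprod(A, A * weights)
  if (ridge > 0) AtWA <- AtWA + diag(ridge, z + 1)
  if (rcond(AtWA) < 1e-12) {
    abort("Anchor design is rank deficient; supply `ridge` > 0.",
          class = "clonespace_singularity_error")
  }
  theta <- solve(AtWA, crossprod(A, target * weights))
  structure(list(linear = t(theta[seq_len(z), , drop = FALSE]),
                 translation = drop(theta[z + 1, ])),
            class = "affine_map")
}

#' Apply an affine map to coordinates
#'
#' @param map An `affine_map`.
#' @param coords Matrix of row vectors.
#' @return Transformed matrix.
#' @export
apply_affine <- function(map, coords) {
  out <- coords %*% t(map$linear)
  sweep(out, 2, map$translation, "+")
}

#' Hierarchical alignment of clonal embeddings across cohorts
#'
#' Greedily merges cohorts (or already-merged groups) in order of
#' decreasing anchor count -- group-to-group counts sum over their spanning
#' cohort pairs; ties break lexicographically on sorted cohort ids. At each
#' merge the side with fewer clones is mapped onto the larger by a weighted
#' affine fit on the anchor pairs. Cohorts disconnected from the anchor
#' graph are left unaligned and reported.
#'
#' @param embeddings Named list of [clone_embedding()]s (or coordinate
#'   matrices), one per cohort, all with the same dimension.
#' @param anchors Anchor tibble from [find_mutual_anchors()]; clone ids
#'   must match embedding row names.
#' @param ridge Ridge fallback used (with a warning) when an anchor design
#'   is rank deficient.
#' @return Object of class `integrated_embedding`: `coords` tibble (`clone`,
#'   `cohort`, dimensions), `merge_tree` (nested list), `newick` string,
#'   `unaligned` cohorts.
#' @export
hierarchical_align <- function(embeddings, anchors, ridge = 1e-8) {
  mats <- lapply(embeddings, function(e) {
    if (inherits(e, "clone_embedding")) e$coords else e
  })
  if (is.null(names(mats))) names(mats) <- paste0("cohort", seq_along(mats))
  cohorts <- names(mats)
  mats <- lapply(mats, function(m) {
    if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
    m
  })
  if (length(mats) == 1) {
    co <- mats[[1]]
    return(structure(list(
      coords = dplyr::bind_cols(tibble(clone = rownames(co),
                                       cohort = cohorts[1]), as_tibble(co)),
      merge_tree = cohorts[1], newick = paste0(cohorts[1], ";"),
      unaligned = character()), class = "integrated_embedding"))
  }

  groups <- as.list(cohorts)          # cohorts per group
  names(groups) <- cohorts
  trees <- as.list(cohorts)
  pair_count <- function(g1, g2) {
    sum((anchors$cohort_a %in% g1 & anchors$cohort_b %in% g2) |
          (anchors$cohort_a %in% g2 & anchors$cohort_b %in% g1))
  }
  group_sizes <- function(g) sum(vapply(mats[g], nrow, 1L))
  unaligned <- character()

  while (length(groups) > 1) {
    best <- NULL
    ng <- length(groups)
    for (i in seq_len(ng - 1)) {
      for (j in seq(i + 1, ng)) {
        cnt <- pair_count(groups[[i]], groups[[j]])
        key <- paste(sort(c(sort(groups[[i]])[1], sort(groups[[j]])[1])),
                     collapse = "\r")
        if (is.null(best) || cnt > best$cnt ||
            (cnt == best$cnt && key < best$key)) {
          best <- list(i = i, j = j, cnt = cnt, key = key)
        }
      }
    }
    if (best$cnt == 0) {
      # anchor graph disconnected: drop the smaller remaining group
      sizes <- vapply(groups, group_sizes, 1L)
      drop_i <- which.min(sizes)
      unaligned <- c(unaligned, unlist(groups[[drop_i]]))
      groups[[drop_i]] <- NULL
      trees[[drop_i]] <- NULL
      if (length(groups) == 1) break
      next
    }
    gi <- groups[[best$i]]; gj <- groups[[best$j]]
    # smaller side (fewer clones) is transformed onto the larger
    if (group_sizes(gi) <= group_sizes(gj)) {
      src_g <- gi; dst_g <- gj
    } else {
      src_g <- gj; dst_g <- gi
    }
    an <- anchors[(anchors$cohort_a %in% src_g & anchors$cohort_b %in% dst_g) |
                    (anchors$cohort_a %in% dst_g & anchors$cohort_b %in% src_g), ]
    flip <- an$cohort_a %in% dst_g
    src_clone <- ifelse(flip, an$clone_b, an$clone_a)
    src_cohort <- ifelse(flip, an$cohort_b, an$cohort_a)
    dst_clone <- ifelse(flip, an$clone_a, an$clone_b)
    dst_cohort <- ifelse(flip, an$cohort_a, an$cohort_b)
    S <- do.call(rbind, lapply(seq_along(src_clone), function(r) {
      mats[[src_cohort[r]]][src_clone[r], , drop = FALSE]
    }))
    Tm <- do.call(rbind, lapply(seq_along(dst_clone), function(r) {
      mats[[dst_cohort[r]]][dst_clone[r], , drop = FALSE]
    }))
    map <- tryCatch(
      fit_weighted_affine(S, Tm, weights = an$weight),
      clonespace_singularity_error = function(e) {
        warn("Rank-deficient anchor design; using ridge fallback.")
        fit_weighted_affine(S, Tm, weights = an$weight, ridge = ridge)
      })
    for (co in src_g) mats[[co]] <- apply_affine(map, mats[[co]])
    merged <- sort(c(gi, gj))
    ti <- trees[[best$i]]; tj <- trees[[best$j]]
    # order children by their smallest cohort id for a stable tree string
    if (min(gj) < min(gi)) {
      tmp <- ti; ti <- tj; tj <- tmp
    }
    keep <- setdiff(seq_along(groups), c(best$i, best$j))
    groups <- c(groups[keep], list(merged))
    trees <- c(trees[keep], list(list(ti, tj)))
  }

  aligned_cohorts <- setdiff(cohorts, unaligned)
  coords <- dplyr::bind_rows(lapply(aligned_cohorts, function(co) {
    m <- mats[[co]]
    dplyr::bind_cols(tibble(clone = rownames(m), cohort = co), as_tibble(m))
  }))
  tree <- trees[[1]]
  to_newick <- function(t) {
    if (is.character(t)) t else
      paste0("(", paste(vapply(t, to_newick, ""), collapse = ","), ")")
  }
  if (length(unaligned) > 0) {
    warn(paste0("Cohorts left unaligned (no anchors): ",
                paste(unaligned, collapse = ", ")))
  }
  structure(list(coords = coords, merge_tree = tree,
                 newick = paste0(to_newick(tree), ";"),
                 unaligned = unaligned),
            class = "integrated_embedding")
}

#' @exportS3Method
print.integrated_embedding <- function(x, ...) {
  cat(sprintf("<integrated_embedding> %d clones from %d cohorts; tree %s\n",
              nrow(x$coords), length(unique(x$coords$cohort)), x$newick))
  invisible(x)
}

#' Synthetic recovery check for the alignment pipeline
#'
#' Generates one clone cloud, forms three cohorts from it, applies a
#' distinct random invertible affine distortion to each non-reference
#' cohort's embedding, rebuilds anchors from a shared pseudobulk proxy and
#' re-integrates with [hierarchical_align()]. Reports the relative RMS
#' error between integrated and original pairwise clone distances.
#'
#' With `mode = "copies"` (default) every cohort carries the full cloud, so
#' mutual anchors are exact matches and the error measures pure pipeline
#' recovery. With `mode = "split"` the cloud is partitioned, anchors pair
#' merely similar clones, and the residual error reflects that
#' correspondence noise.
#'
#' @param seed Integer seed.
#' @param n_reference,n_other Clones in the reference and the two other
#'   cohorts; in `copies` mode the two non-reference cohorts carry exact
#'   copies of `n_other` reference clones each (kept below half the
#'   reference so the merged frame is the reference frame).
#' @param z Embedding dimension of the cloud.
#' @param k_anchor Anchor neighbours.
#' @param mode `"copies"` or `"split"` (see above).
#' @return List with `rel_rms_error`, the `integrated` embedding and the
#'   anchor tibble.
#' @export
alignment_recovery_error <- function(seed = 1, n_reference = 60,
                                     n_other = 25, z = 2, k_anchor = 1,
                                     mode = c("copies", "split")) {
  mode <- match.arg(mode)
  with_seed(seed, {
    if (mode == "copies") {
      # the reference keeps the whole cloud and stays strictly larger than
      # the two copy cohorts combined, so every merge lands in its frame
      n <- n_reference
      copied <- sort(sample.int(n, n_other))
      rows_by_cohort <- list(seq_len(n), copied, copied)
    } else {
      n <- n_reference + 2 * n_other
      rows_by_cohort <- split(seq_len(n),
                              rep(1:3, c(n_reference, n_other, n_other)))
    }
    cloud <- matrix(rnorm(n * z), n, z,
                    dimnames = list(sprintf("cl%03d", seq_len(n)), NULL))
    rand_affine <- function() {
      repeat {
        L <- matrix(rnorm(z * z), z, z)
        if (abs(det(L)) > 0.2) return(L)
      }
    }
    maps <- list(diag(z), rand_affine(), rand_affine())
    shifts <- list(rep(0, z), rnorm(z, sd = 5), rnorm(z, sd = 5))
    embeddings <- lapply(1:3, function(g) {
      rows <- rows_by_cohort[[g]]
      out <- cloud[rows, , drop = FALSE] %*% t(maps[[g]]) +
        matrix(shifts[[g]], length(rows), z, byrow = TRUE)
      colnames(out) <- paste0("V", seq_len(z))
      out
    })
    names(embeddings) <- paste0("coh", 1:3)
    # pseudobulk proxy: smooth gene programs over the latent cloud, shared
    # across cohorts so anchors are recoverable
    genes <- cbind(cloud, cloud^2, cloud[, 1] * cloud[, 2],
                   sin(cloud), exp(-cloud^2 / 2))
    colnames(genes) <- paste0("g", seq_len(ncol(genes)))
    pbs <- lapply(1:3, function(g) genes[rows_by_cohort[[g]], , drop = FALSE])
    names(pbs) <- names(embeddings)
    coords <- build_anchor_space(pbs, n_hvg = ncol(genes),
                                 n_pcs = min(6, ncol(genes)),
                                 scale_by = "pooled")
    anchors <- find_mutual_anchors(coords, k_anchor = k_anchor)
    integrated <- hierarchical_align(embeddings, anchors)
    # score pairwise distances over every integrated point (all cohorts,
    # including cross-cohort pairs) against the original cloud geometry
    X_all <- as.matrix(integrated$coords[, paste0("V", seq_len(z))])
    cohort_idx <- match(integrated$coords$cohort, names(embeddings))
    orig_rows <- vapply(seq_len(nrow(X_all)), function(r) {
      rows_by_cohort[[cohort_idx[r]]][
        match(integrated$coords$clone[r],
              rownames(cloud)[rows_by_cohort[[cohort_idx[r]]]])]
    }, integer(1))
    d_got <- as.vector(dist(X_all))
    d_true <- as.vector(dist(cloud[orig_rows, , drop = FALSE]))
    rel <- sqrt(mean((d_got - d_true)^2)) / sqrt(mean(pmax(d_true, 1e-12)^2))
    list(rel_rms_error = rel, integrated = integrated, anchors = anchors)
  })
}
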