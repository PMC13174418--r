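make_pseudobulk <- function(n_clones, n_genes, seed, prefix = "cl") {
  set.seed(seed)
  m <- matrix(rnorm(n_clones * n_genes), n_clones, n_genes,
              dimnames = list(paste0(prefix, seq_len(n_clones)),
                              paste0("g", seq_len(n_genes))))
  abs(m)
}

test_that("anchor space scales per cohort and collapses twin cohorts", {
  pb <- make_pseudobulk(30, 60, seed = 1)
  coords <- build_anchor_space(list(A = pb, B = pb), n_hvg = 40, n_pcs = 5)
  XA <- as.matrix(coords[coords$cohort == "A", grep("^PC", names(coords))])
  XB <- as.matrix(coords[coords$cohort == "B", grep("^PC", names(coords))])
  d_twin <- sqrt(rowSums((XA - XB)^2))
  med <- median(dist(XA))
  expect_true(all(d_twin < 0.05 * med))
  # single cohort reduces to a plain PCA of the scaled pseudobulk
  one <- build_anchor_space(list(A = pb), n_hvg = 60, n_pcs = 4)
  s <- scale(pb)
  pc <- prcomp(s, rank. = 4)
  for (j in 1:4) {
    expect_equal(abs(cor(one[[paste0("PC", j)]], pc$x[, j])), 1,
                 tolerance = 1e-8)
  }
  expect_error(build_anchor_space(list(
    A = make_pseudobulk(5, 10, 1),
    B = matrix(1, 5, 10, dimnames = list(paste0("x", 1:5),
                                         paste0("h", 1:10))))),
    class = "clonespace_validation_error")
})

test_that("mutual anchors require reciprocity and are order-symmetric", {
  set.seed(2)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("cl", 1:20), NULL))
  colnames(X) <- c("PC1", "PC2")
  coords <- dplyr::bind_cols(
    tibble::tibble(clone = rep(paste0("cl", 1:20), 2),
                   cohort = rep(c("A", "B"), each = 20)),
    tibble::as_tibble(rbind(X, X)))
  an <- find_mutual_anchors(coords, k_anchor = 1)
  # exact copies anchor to themselves
  expect_equal(nrow(an), 20L)
  expect_equal(an$clone_a, an$clone_b)
  expect_equal(an$distance, rep(0, 20))
  # cohort order does not change the anchor count
  coords2 <- coords[rev(seq_len(nrow(coords))), ]
  an2 <- find_mutual_anchors(coords2, k_anchor = 1)
  expect_equal(nrow(an2), 20L)
  # a point with no reciprocal neighbour is not an anchor
  A <- rbind(c(0, 0), c(10, 0))
  B <- rbind(c(0.1, 0), c(0.2, 0))
  rownames(A) <- c("a1", "a2"); rownames(B) <- c("b1", "b2")
  coords3 <- dplyr::bind_cols(
    tibble::tibble(clone = c("a1", "a2", "b1", "b2"),
                   cohort = c("A", "A", "B", "B")),
    tibble::as_tibble(rbind(A, B), .name_repair = ~c("PC1", "PC2")))
  an3 <- find_mutual_anchors(coords3, k_anchor = 1)
  expect_false("a2" %in% an3$clone_a)
})

test_that("weighted affine fits recover exact maps and respect WLS scaling", {
  set.seed(3)
  S <- matrix(rnorm(40), 20, 2)
  L0 <- matrix(c(0.8, -0.5, 0.4, 1.2), 2, 2)
  t0 <- c(3, -1)
  T0 <- S %*% t(L0) + matrix(t0, 20, 2, byrow = TRUE)
  map <- fit_weighted_affine(S, T0)
  expect_lt(max(abs(map$linear - L0)), 1e-8)
  expect_lt(max(abs(map$translation - t0)), 1e-8)
  expect_equal(apply_affine(map, S), T0, tolerance = 1e-8)
  # identity case
  mid <- fit_weighted_affine(S, S)
  expect_equal(mid$linear, diag(2), tolerance = 1e-8)
  expect_equal(mid$translation, c(0, 0), tolerance = 1e-8)
  # rescaling weights leaves the fit unchanged
  w <- runif(20, 0.5, 2)
  m1 <- fit_weighted_affine(S, T0, weights = w)
  m2 <- fit_weighted_affine(S, T0, weights = 2 * w)
  expect_equal(m1$linear, m2$linear, tolerance = 1e-10)
  # rank-deficient design errors without ridge
  Sdef <- cbind(rep(1, 5), rep(2, 5))
  expect_error(fit_weighted_affine(Sdef, Sdef),
               class = "clonespace_singularity_error")
  expect_s3_class(fit_weighted_affine(Sdef, Sdef, ridge = 1e-6), "affine_map")
})

test_that("affine maps preserve linear relations between clones", {
  set.seed(5)
  S <- matrix(rnorm(30), 15, 2)
  map <- fit_weighted_affine(S, S %*% matrix(c(1.1, 0.2, -0.3, 0.9), 2, 2) + 1)
  Y <- apply_affine(map, S)
  p <- S[1, ]; q <- S[2, ]; r <- S[3, ]
  lhs <- apply_affine(map, rbind(p - q + r))
  rhs <- rbind(Y[1, ] - Y[2, ] + Y[3, ])
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("hierarchical alignment reverses planted affine distortions", {
  set.seed(6)
  base <- matrix(rnorm(60), 30, 2, dimnames = list(paste0("cl", 1:30), NULL))
  L <- matrix(c(0.9, 0.4, -0.2, 1.1), 2, 2)
  distorted <- base %*% t(L) + matrix(c(5, -2), 30, 2, byrow = TRUE)
  rownames(distorted) <- rownames(base)
  anchors <- tibble::tibble(clone_a = rownames(base),
                            clone_b = rownames(base),
                            cohort_a = "A", cohort_b = "B", weight = 1)
  embeddings <- list(A = rbind(base, extraA = c(9, 9)),
                     B = distorted)
  out <- hierarchical_align(embeddings, anchors)
  got <- out$coords
  XA <- as.matrix(got[got$cohort == "A", c("V1", "V2")])
  XB <- as.matrix(got[got$cohort == "B", c("V1", "V2")])
  rownames(XA) <- got$clone[got$cohort == "A"]
  rownames(XB) <- got$clone[got$cohort == "B"]
  expect_lt(max(abs(XA[rownames(base), ] - XB[rownames(base), ])), 1e-6)
  expect_equal(out$newick, "(A,B);")
})

test_that("merge order follows anchor counts and singletons pass through", {
  set.seed(7)
  mk <- function(n, prefix) {
    m <- matrix(rnorm(2 * n), n, 2)
    rownames(m) <- paste0(prefix, seq_len(n))
    m
  }
  embeddings <- list(c1 = mk(10, "a"), c2 = mk(12, "b"), c3 = mk(8, "d"))
  anchors <- tibble::tibble(
    clone_a = c(paste0("a", 1:6), paste0("a", 1:2)),
    clone_b = c(paste0("b", 1:6), paste0("d", 1:2)),
    cohort_a = c(rep("c1", 6), rep("c1", 2)),
    cohort_b = c(rep("c2", 6), rep("c3", 2)),
    weight = 1)
  out <- hierarchical_align(embeddings, anchors)
  expect_equal(out$newick, "((c1,c2),c3);")
  single <- hierarchical_align(embeddings["c1"],
                               anchors[0, ])
  expect_equal(nrow(single$coords), 10L)
  expect_equal(single$newick, "c1;")
})

test_that("split-and-distort cohorts reintegrate with low distance error", {
  out <- alignment_recovery_error(seed = 8)
  expect_lt(out$rel_rms_error, 0.05)
  expect_equal(sort(unique(out$integrated$coords$cohort)),
               c("coh1", "coh2", "coh3"))
})
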