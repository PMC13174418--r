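make_expr <- function(clone, genes = 3, seed = 1, mean = 0) {
  set.seed(seed)
  m <- matrix(rnorm(length(clone) * genes, mean = mean), length(clone), genes,
              dimnames = list(names(clone), paste0("g", seq_len(genes))))
  m
}

test_that("clone pseudobulk averages masked cells per clone", {
  clone <- setNames(c("a", "a", "b", "b", "c"), paste0("c", 1:5))
  lab <- clonal_labeling(clone)
  expr <- matrix(c(1, 3, 2, 4, 7), 5, 1,
                 dimnames = list(names(clone), "g1"))
  pb <- clone_pseudobulk(expr, lab)
  expect_equal(pb["a", "g1"], 2)
  expect_equal(pb["c", "g1"], 7)  # one-cell clone passes through
  mask <- setNames(c(TRUE, TRUE, FALSE, FALSE, TRUE), names(clone))
  expect_warning(pb2 <- clone_pseudobulk(expr, lab, mask), "dropped")
  expect_false("b" %in% rownames(pb2))
  expect_error(clone_pseudobulk(expr, lab, setNames(rep(FALSE, 5),
                                                    names(clone))),
               class = "clonespace_degenerate_error")
})

test_that("Welch DE matches t.test and handles degenerate genes", {
  pb <- rbind(a1 = c(1, 5), a2 = c(2, 5), a3 = c(3, 5),
              b1 = c(4, 5), b2 = c(5, 5), b3 = c(6, 5))
  colnames(pb) <- c("g1", "g2")
  res <- clone_differential_expression(pb, c("a1", "a2", "a3"),
                                       c("b1", "b2", "b3"))
  oracle <- t.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic[1], unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$statistic[1], -3.674, tolerance = 1e-3)
  expect_equal(res$df[1], 4)
  expect_equal(res$p[1], oracle$p.value, tolerance = 1e-12)
  expect_equal(res$logFC[1], -3)
  # zero variance in both groups: statistic 0, p = 1 by convention
  expect_equal(res$statistic[2], 0)
  expect_equal(res$p[2], 1)
  # near-deterministic separation drives p below 1e-6
  set.seed(1)
  pb3 <- cbind(g = c(rnorm(3, 0, 1e-6), rnorm(3, 1, 1e-6)))
  rownames(pb3) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  res3 <- clone_differential_expression(pb3, c("a1", "a2", "a3"),
                                        c("b1", "b2", "b3"))
  expect_lt(res3$p[1], 1e-6)
  expect_error(clone_differential_expression(pb, "a1", c("b1", "b2")),
               class = "clonespace_parameter_error")
  expect_error(clone_differential_expression(pb, c("a1", "b1"), c("b1", "b2")),
               class = "clonespace_parameter_error")
})

test_that("cell-type expansion centres marker signal away", {
  clone <- setNames(c("a", "a", "a", "b", "b", "c"), paste0("c", 1:6))
  lab <- clonal_labeling(clone)
  type <- setNames(c("T", "B", "NK", "T", "B", "T"), names(clone))
  expr <- make_expr(clone, genes = 4, seed = 2, mean = 3)
  out <- expand_clones_by_celltype(expr, lab, type)
  # clone a spans three cell types -> three rows
  expect_equal(sum(attr(out, "clone") == "a"), 3L)
  expect_equal(sum(attr(out, "clone") == "c"), 1L)
  # per-cell-type column means are zero after centring
  for (ct in unique(attr(out, "cell_type"))) {
    rows <- attr(out, "cell_type") == ct
    expect_equal(unname(colMeans(out[rows, , drop = FALSE])),
                 rep(0, 4), tolerance = 1e-10)
  }
})

test_that("supervised PCA reduces to PCA under the identity affinity", {
  set.seed(4)
  pb <- matrix(rnorm(200), 20, 10,
               dimnames = list(paste0("cl", 1:20), paste0("g", 1:10)))
  sp <- supervised_pca(pb, graph = NULL, n_components = 5)
  pc <- prcomp(pb, center = TRUE, scale. = FALSE)
  for (j in 1:5) {
    expect_equal(abs(sum(sp$loadings[, j] * pc$rotation[, j])), 1,
                 tolerance = 1e-8)
  }
  expect_true(all(diff(sp$eigenvalues) <= 1e-8))
  expect_warning(supervised_pca(pb, NULL, n_components = 15), "rank|Truncat")
})

test_that("supervised PCA finds the gene aligned with graph structure", {
  set.seed(6)
  X <- rbind(matrix(rnorm(40, 0, 0.5), ncol = 2),
             matrix(rnorm(40, 10, 0.5), ncol = 2))
  rownames(X) <- paste0("cl", 1:40)
  graph <- build_clone_graph(X, k = 4)
  blob <- rep(c(0, 4), each = 20)
  pb <- cbind(g_signal = blob + rnorm(40, 0, 0.2),
              g_noise1 = rnorm(40), g_noise2 = rnorm(40))
  rownames(pb) <- rownames(X)
  sp <- supervised_pca(pb, graph, n_components = 2)
  expect_equal(which.max(abs(sp$loadings[, 1])), 1L, ignore_attr = TRUE)
  expect_gt(abs(sp$loadings["g_signal", 1]), 0.9)
})

test_that("Moran's I attains its closed-form values on toy graphs", {
  # two disconnected tight cliques, indicator signal -> I = 1 exactly
  X <- rbind(matrix(rnorm(20, 0, 0.1), ncol = 2),
             matrix(rnorm(20, 50, 0.1), ncol = 2))
  rownames(X) <- paste0("cl", 1:20)
  g <- build_clone_graph(X, k = 3)
  ind <- rep(c(0, 1), each = 10)
  expect_equal(morans_i(ind, g), 1, tolerance = 1e-12)
  expect_error(morans_i(rep(1, 20), g), class = "clonespace_degenerate_error")
  expect_error(morans_i(1:2, g), class = "clonespace_parameter_error")
  # exact permutation mean equals -1/(n-1) on a small graph
  set.seed(8)
  Xs <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("cl", 1:6), NULL))
  gs <- build_clone_graph(Xs, k = 2)
  vals <- c(3, 1, 4, 1.5, 5, 9)
  perms <- all_perms(vals)
  is <- vapply(perms, morans_i, numeric(1), graph = gs)
  expect_equal(mean(is), -1 / 5, tolerance = 1e-10)
})

test_that("Moran permutation test is calibrated and detects structure", {
  set.seed(3)
  X <- rbind(matrix(rnorm(60, 0, 0.5), ncol = 2),
             matrix(rnorm(60, 8, 0.5), ncol = 2))
  rownames(X) <- paste0("cl", 1:60)
  g <- build_clone_graph(X, k = 5)
  pb <- cbind(smooth = rep(c(0, 1), each = 30) + rnorm(60, 0, 0.1),
              matrix(rnorm(60 * 20), 60, 20))
  colnames(pb) <- c("smooth", paste0("n", 1:20))
  res <- morans_i_test(pb, g, n_perm = 4999, seed = 1)
  expect_lt(res$q[1], 0.01)
  expect_true(all(res$p >= 1 / 5000))
  expect_true(all(res$q >= res$p - 1e-12))
})

test_that("frequency permutation test handles null and saturated cases", {
  # constant frequencies: p = 1 everywhere
  d <- tibble::tibble(clone = paste0("cl", 1:20), freq = 1,
                      cluster = rep(c("x", "y"), 10), stratum = "t1")
  res <- frequency_permutation_test(d, n_perm = 199, seed = 1)
  expect_equal(res$p, c(1, 1))
  # one cluster 10x the rest saturates at the minimum attainable p
  d2 <- tibble::tibble(clone = paste0("cl", 1:30),
                       freq = c(rep(10, 15), rep(1, 15)),
                       cluster = rep(c("hot", "cold"), each = 15),
                       stratum = "t1")
  res2 <- frequency_permutation_test(d2, n_perm = 9999, seed = 1)
  expect_equal(unname(res2$p), c(1e-4, 1e-4))
  # clone order does not change the result for a fixed seed
  res3 <- frequency_permutation_test(d2[sample(30), ], n_perm = 999, seed = 5)
  res4 <- frequency_permutation_test(d2, n_perm = 999, seed = 5)
  expect_equal(res3, res4)
  # a cluster absent from a stratum comes back as NA with a warning
  d5 <- dplyr::bind_rows(d2, tibble::tibble(clone = "cl31", freq = 1,
                                            cluster = "hot", stratum = "t2"))
  d5 <- dplyr::bind_rows(d5, tibble::tibble(clone = "cl32", freq = 2,
                                            cluster = "warm", stratum = "t2"))
  expect_warning(res5 <- frequency_permutation_test(d5, n_perm = 99, seed = 1),
                 "absent")
  expect_true(is.na(res5$p[res5$stratum == "t2" & res5$cluster == "cold"]))
})

test_that("BH adjustment agrees with an independent step-up implementation", {
  set.seed(11)
  for (r in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(p.adjust(p, method = "BH"), brute_bh(p), tolerance = 1e-12)
  }
})
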