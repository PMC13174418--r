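test_that("skip-gram honours symmetry and exchangeability of the counts", {
  expect_equal(formals(fit_skipgram)$z, 10)
  # two clones with symmetric counts end up equidistant from the origin
  N <- matrix(c(0, 40, 40, 0), 2, 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  fit <- fit_skipgram(cooc_from_counts(N), z = 1, epochs = 50,
                      batch_size = 8, seed = 3)
  r <- sqrt(rowSums(fit$U^2))
  expect_lt(abs(r[1] - r[2]) / mean(r), 0.05)

  # clones with identical co-occurrence rows/columns embed close together
  cells <- toy_cells(n_clones = 4, size = 6, seed = 5, spread = 1)
  cooc <- clone_cooccurrence(cells, cell_id = "cell_id", k = 3,
                             min_clone_size = 1)
  N2 <- as.matrix(cooc$counts)
  N2 <- rbind(N2, dup = N2["cl01", ])
  N2 <- cbind(N2, dup = N2[, "cl01"])
  rownames(N2)[5] <- colnames(N2)[5] <- "dup"
  N2["cl01", "dup"] <- N2["dup", "cl01"] <- N2["cl01", "cl01"]
  fit2 <- fit_skipgram(cooc_from_counts(N2), z = 2, epochs = 150,
                       batch_size = 32, seed = 1)
  D <- as.matrix(dist(fit2$U))
  expect_lt(D["cl01", "dup"], 0.15 * median(D[upper.tri(D)]))
})

test_that("predicted neighbour distributions are proper and consistent", {
  cells <- toy_cells(n_clones = 4, size = 8, seed = 8, spread = 3)
  cooc <- clone_cooccurrence(cells, cell_id = "cell_id", k = 4,
                             min_clone_size = 1)
  fit <- fit_skipgram(cooc, z = 2, epochs = 120, seed = 2)
  p <- predict_neighbor_distribution(fit, 1)
  expect_true(all(p > 0))
  expect_equal(sum(p), 1, tolerance = 1e-8)
  # zero hidden weights + zero output weights give the exact uniform law
  fit0 <- fit
  fit0$U[] <- 0
  fit0$V[] <- 0
  expect_equal(unname(predict_neighbor_distribution(fit0, 2)),
               rep(1 / 4, 4))
  # on a well-fit model the modal context matches the empirical mode
  N <- as.matrix(cooc$counts)
  for (i in seq_len(nrow(N))) {
    expect_equal(which.max(predict_neighbor_distribution(fit, i)),
                 which.max(N[i, ]), ignore_attr = TRUE)
  }
  expect_error(predict_neighbor_distribution(fit, 99),
               class = "clonespace_parameter_error")
})

test_that("multinomial NLL matches the entropy bound and closed forms", {
  cells <- toy_cells(n_clones = 3, size = 6, seed = 4, spread = 2)
  cooc <- clone_cooccurrence(cells, cell_id = "cell_id", k = 2,
                             min_clone_size = 1)
  N <- as.matrix(cooc$counts)
  # entropy lower bound, attained iff the model reproduces the empirical
  # row distributions
  rowp <- N / rowSums(N)
  bound <- -sum(N * log(pmax(rowp, 1e-300)) * (N > 0))
  fit <- fit_skipgram(cooc, z = 2, epochs = 300, seed = 1,
                      min_rel_improve = 1e-9)
  expect_gte(multinomial_nll(cooc, fit) + 1e-9, bound)
  # zero embedding on uniform counts: NLL = total * log(C)
  Nu <- matrix(5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  fit0 <- fit
  fit0$U <- matrix(0, 3, 2)
  fit0$V <- matrix(0, 2, 3)
  expect_equal(multinomial_nll(cooc_from_counts(Nu), fit0),
               sum(Nu) * log(3))
  expect_gte(multinomial_nll(cooc, fit), 0)
})

test_that("skip-gram epoch NLL is non-increasing and seeded runs are identical", {
  cells <- toy_cells(n_clones = 6, size = 10, seed = 6, spread = 2)
  cooc <- clone_cooccurrence(cells, cell_id = "cell_id", k = 5,
                             min_clone_size = 1)
  fit1 <- fit_skipgram(cooc, z = 3, epochs = 40, seed = 11)
  expect_true(all(diff(fit1$loss_history) <= 1e-6 * abs(fit1$loss_history[1])))
  fit2 <- fit_skipgram(cooc, z = 3, epochs = 40, seed = 11)
  expect_identical(fit1$U, fit2$U)
  expect_identical(fit1$loss_history, fit2$loss_history)
  fit3 <- fit_skipgram(cooc, z = 3, epochs = 40, seed = 12)
  expect_false(identical(fit1$U, fit3$U))
  expect_error(fit_skipgram(cooc_from_counts(matrix(0, 2, 2))),
               class = "clonespace_degenerate_error")
})

test_that("Poisson GLM-PCA recovers planted structure and stays monotone", {
  # rank-1 ground truth with large means
  set.seed(9)
  u <- rnorm(30); v <- rnorm(30)
  eta <- outer(u, v) * 0.8 + 4
  N <- matrix(rpois(900, exp(eta)), 30, 30,
              dimnames = list(paste0("r", 1:30), paste0("c", 1:30)))
  fit <- fit_poisson_glmpca(cooc_from_counts(N), z = 1, max_iter = 200,
                            seed = 2)
  expect_gt(abs(cor(drop(fit$U), u)), 0.99)
  expect_true(all(diff(fit$deviance_history) <= 0))

  # constant matrix: intercepts absorb everything, U collapses to zero
  Nc <- matrix(7, 12, 12, dimnames = list(paste0("r", 1:12),
                                          paste0("c", 1:12)))
  fitc <- fit_poisson_glmpca(cooc_from_counts(Nc), z = 2, max_iter = 50,
                             seed = 1)
  expect_lt(norm(fitc$U, "F"), 1e-3 * sqrt(12 * 2))

  # first iteration strictly decreases deviance on non-degenerate input
  cells <- toy_cells(n_clones = 5, size = 8, seed = 10, spread = 2)
  cooc <- clone_cooccurrence(cells, cell_id = "cell_id", k = 4,
                             min_clone_size = 1)
  f1 <- fit_poisson_glmpca(cooc, z = 2, max_iter = 1, seed = 1)
  expect_lt(f1$deviance_history[2], f1$deviance_history[1])
})

test_that("Poisson and skip-gram embeddings agree on clone geometry", {
  sim <- simulate_two_cluster_clones(seed = 5, reps_per_level = 15)
  cooc <- clone_cooccurrence(sim$cells, cell_id = "cell_id", k = 15,
                             min_clone_size = 3)
  sg <- fit_skipgram(cooc, z = 2, epochs = 60, seed = 1)
  po <- fit_poisson_glmpca(cooc, z = 2, max_iter = 60, seed = 1)
  d1 <- as.vector(dist(sg$U))
  d2 <- as.vector(dist(po$U))
  expect_gt(cor(d1, d2, method = "spearman"), 0.8)
})

test_that("embeddings carry ids and write to TSV", {
  cells <- toy_cells(n_clones = 3, size = 5, seed = 2)
  cooc <- clone_cooccurrence(cells, cell_id = "cell_id", k = 2,
                             min_clone_size = 1)
  fit <- fit_skipgram(cooc, z = 2, epochs = 10, seed = 1)
  emb <- clone_embedding(fit)
  expect_equal(rownames(emb$coords), cooc$clone_ids)
  expect_equal(emb$provenance, "skipgram")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_embedding(emb, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$clone, cooc$clone_ids)
  expect_equal(as.matrix(back[, -1]), unname(emb$coords), ignore_attr = TRUE)
})
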