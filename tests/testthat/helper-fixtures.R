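# Shared fixtures, built in code at test time.

# A tiny labelled 2-D cell table: `n_clones` clones of `size` cells each,
# placed around well-separated centres.
toy_cells <- function(n_clones = 4, size = 5, seed = 42, spread = 0.3) {
  set.seed(seed)
  centers <- cbind(cos(2 * pi * seq_len(n_clones) / n_clones),
                   sin(2 * pi * seq_len(n_clones) / n_clones)) * 10
  n <- n_clones * size
  mu <- centers[rep(seq_len(n_clones), each = size), ]
  tibble::tibble(
    cell_id = sprintf("c%03d", seq_len(n)),
    x = mu[, 1] + rnorm(n, sd = spread),
    y = mu[, 2] + rnorm(n, sd = spread),
    clone = rep(sprintf("cl%02d", seq_len(n_clones)), each = size))
}

# Co-occurrence object assembled directly from a counts matrix.
cooc_from_counts <- function(N, k = 1) {
  ids <- rownames(N) %||% paste0("cl", seq_len(nrow(N)))
  ctx <- colnames(N) %||% ids
  structure(list(counts = Matrix::Matrix(N, sparse = TRUE),
                 clone_ids = ids, context_ids = ctx, k = k),
            class = "clone_cooc")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force clone co-occurrence: double loop over (cell, neighbour)
# pairs, independent of the package's aggregation path.
brute_cooccurrence <- function(coords, clone, k) {
  n <- nrow(coords)
  ids <- sort(unique(clone))
  N <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    d <- sqrt(rowSums((coords - matrix(coords[i, ], n, ncol(coords),
                                       byrow = TRUE))^2))
    ord <- order(d, seq_len(n))
    ord <- setdiff(ord, i)[seq_len(k)]
    for (j in ord) N[clone[i], clone[j]] <- N[clone[i], clone[j]] + 1
  }
  N
}

# Independent step-up Benjamini-Hochberg: literal definition.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  q[o] <- pmin(adj, 1)
  q
}

# Brute-force ARI from first principles over all element pairs.
brute_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a && same_b) s11 <- s11 + 1
      else if (!same_a && !same_b) s00 <- s00 + 1
      else if (same_a) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  total <- s11 + s00 + s10 + s01
  expected <- (s11 + s10) * (s11 + s01) / total
  maxi <- ((s11 + s10) + (s11 + s01)) / 2
  if (maxi == expected) return(0)
  (s11 - expected) / (maxi - expected)
}

# All permutations of a small vector (for exact permutation-null checks).
all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}
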