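# Synthetic 2-D "expression" spaces with planted clonal structure. The
# geometry constants (cluster centres and spreads, ring radii, cross bar
# shapes) are declared package defaults, exposed as arguments.

new_synthetic_dataset <- function(cells, clone_truth, params) {
  structure(list(cells = cells, clone_truth = clone_truth, params = params),
            class = "synthetic_clones")
}

#' @exportS3Method
print.synthetic_clones <- function(x, ...) {
  cat(sprintf("<synthetic_clones> %d cells, %d clones (%s)\n",
              nrow(x$cells), nrow(x$clone_truth), x$params$generator))
  invisible(x)
}

#' Two-cluster proportion benchmark
#'
#' Two well-separated 2-D Gaussian clusters A and B (centres `(-5, 0)` and
#' `(5, 0)`, sd 1 by default). Each clone holds `clone_size` cells with
#' exactly `n` from cluster A and `clone_size - n` from B, for every
#' `n = 0 .. clone_size`, repeated `reps_per_level` times. The ground truth
#' per clone is the A-proportion `n / clone_size`. Defaults yield
#' `11 * 500 = 5500` clones.
#'
#' @param seed Integer seed.
#' @param reps_per_level Clones per proportion level (default 500).
#' @param clone_size Cells per clone (default 10).
#' @param centers 2 x 2 matrix of cluster centres.
#' @param sd Within-cluster standard deviation.
#' @return A `synthetic_clones` object: `cells` tibble (`cell_id`, `x`,
#'   `y`, `clone`, `cluster`), `clone_truth` tibble (`clone`, `truth` =
#'   A-proportion), `params`.
#' @export
simulate_two_cluster_clones <- function(seed = 1, reps_per_level = 500,
                                        clone_size = 10,
                                        centers = rbind(c(-5, 0), c(5, 0)),
                                        sd = 1) {
  reps_per_level <- assert_scalar_int(reps_per_level, "reps_per_level", 1)
  clone_size <- assert_scalar_int(clone_size, "clone_size", 1)
  with_seed(seed, {
    levels <- 0:clone_size
    n_clones <- length(levels) * reps_per_level
    clone_n <- rep(levels, each = reps_per_level)
    clone_id <- sprintf("clone%05d", seq_len(n_clones))
    from_a <- rep(clone_n, times = 1)
    n_cells <- n_clones * clone_size
    cl_of_cell <- rep(clone_id, each = clone_size)
    is_a <- unlist(lapply(clone_n, function(n) {
      c(rep(TRUE, n), rep(FALSE, clone_size - n))
    }), use.names = FALSE)
    mu <- centers[ifelse(is_a, 1, 2), , drop = FALSE]
    coords <- mu + matrix(rnorm(2 * n_cells, sd = sd), n_cells, 2)
    cells <- tibble(cell_id = sprintf("cell%07d", seq_len(n_cells)),
                    x = coords[, 1], y = coords[, 2],
                    clone = cl_of_cell,
                    cluster = ifelse(is_a, "A", "B"))
    truth <- tibble(clone = clone_id, truth = clone_n / clone_size)
    new_synthetic_dataset(cells, truth,
                          list(generator = "two_cluster", seed = seed,
                               reps_per_level = reps_per_level,
                               clone_size = clone_size, sd = sd))
  })
}

#' Three-cluster portion benchmark
#'
#' Three 2-D Gaussian clusters on an equilateral triangle (side 10, sd 1 by
#' default). Each clone has 15 cells in three portions of 5; every portion
#' comes from cluster A, B or C, giving the 10 multiset types AAA, AAB,
#' ..., CCC; `per_type` clones per type (default 500, totalling 5000).
#' Ground truth is the multiset label.
#'
#' @param seed Integer seed.
#' @param per_type Clones per composition type (default 500).
#' @param side Triangle side length.
#' @param sd Within-cluster standard deviation.
#' @param portion_size Cells per portion (default 5).
#' @return A `synthetic_clones` object; `clone_truth$truth` holds the
#'   composition label (e.g. `"ABB"`).
#' @export
simulate_three_cluster_clones <- function(seed = 1, per_type = 500,
                                          side = 10, sd = 1,
                                          portion_size = 5) {
  per_type <- assert_scalar_int(per_type, "per_type", 1)
  centers <- rbind(A = c(0, 0), B = c(side, 0),
                   C = c(side / 2, side * sqrt(3) / 2))
  types <- c("AAA", "AAB", "AAC", "ABB", "ABC", "ACC",
             "BBB", "BBC", "BCC", "CCC")
  with_seed(seed, {
    clone_size <- 3 * portion_size
    n_clones <- length(types) * per_type
    clone_type <- rep(types, each = per_type)
    clone_id <- sprintf("clone%05d", seq_len(n_clones))
    comp <- strsplit(clone_type, "")
    src <- unlist(lapply(comp, function(p) rep(p, each = portion_size)),
                  use.names = FALSE)
    n_cells <- n_clones * clone_size
    mu <- centers[src, , drop = FALSE]
    coords <- mu + matrix(rnorm(2 * n_cells, sd = sd), n_cells, 2)
    cells <- tibble(cell_id = sprintf("cell%07d", seq_len(n_cells)),
                    x = coords[, 1], y = coords[, 2],
                    clone = rep(clone_id, each = clone_size),
                    cluster = src)
    truth <- tibble(clone = clone_id, truth = clone_type)
    new_synthetic_dataset(cells, truth,
                          list(generator = "three_cluster", seed = seed,
                               per_type = per_type, side = side, sd = sd))
  })
}

#' Rings-and-crosses benchmark
#'
#' A 2-D space with four concentric rings (radii 2, 4, 6, 8, radial noise
#' sd 0.2, centred at the origin) and six crosses (two orthogonal 8 x 0.4
#' bars) rotated by 0, 15, 30, 45, 60 and 75 degrees, centred away from
#' the rings. Every clone samples all its cells from one structure;
#' `per_structure` clones of `clone_size` cells per structure (defaults
#' 300 x 10 structures = 3000 clones). Ground truth is the structure id.
#'
#' @param seed Integer seed.
#' @param per_structure Clones per structure (default 300).
#' @param clone_size Cells per clone (default 30).
#' @param ring_radii Radii of the concentric rings.
#' @param ring_sd Radial noise sd.
#' @param cross_center Centre of the rotated crosses.
#' @param bar_length,bar_width Cross bar dimensions.
#' @return A `synthetic_clones` object; `clone_truth$truth` names the
#'   structure (`ring1..ring4`, `cross00..cross75`).
#' @export
simulate_rings_crosses <- function(seed = 1, per_structure = 300,
                                   clone_size = 30,
                                   ring_radii = c(2, 4, 6, 8), ring_sd = 0.2,
                                   cross_center = c(20, 0),
                                   bar_length = 8, bar_width = 0.4) {
  per_structure <- assert_scalar_int(per_structure, "per_structure", 1)
  clone_size <- assert_scalar_int(clone_size, "clone_size", 1)
  angles <- c(0, 15, 30, 45, 60, 75)
  structures <- c(paste0("ring", seq_along(ring_radii)),
                  sprintf("cross%02d", angles))
  sample_structure <- function(s, n) {
    if (startsWith(s, "ring")) {
      r0 <- ring_radii[as.integer(sub("ring", "", s))]
      th <- runif(n, 0, 2 * pi)
      r <- r0 + rnorm(n, sd = ring_sd)
      cbind(r * cos(th), r * sin(th))
    } else {
      ang <- as.numeric(sub("cross", "", s)) * pi / 180
      horiz <- runif(n) < 0.5
      u <- runif(n, -bar_length / 2, bar_length / 2)
      v <- runif(n, -bar_width / 2, bar_width / 2)
      px <- ifelse(horiz, u, v)
      py <- ifelse(horiz, v, u)
      cbind(cross_center[1] + px * cos(ang) - py * sin(ang),
            cross_center[2] + px * sin(ang) + py * cos(ang))
    }
  }
  with_seed(seed, {
    n_clones <- length(structures) * per_structure
    clone_struct <- rep(structures, each = per_structure)
    clone_id <- sprintf("clone%05d", seq_len(n_clones))
    coords <- do.call(rbind, lapply(clone_struct, sample_structure,
                                    n = clone_size))
    n_cells <- n_clones * clone_size
    cells <- tibble(cell_id = sprintf("cell%07d", seq_len(n_cells)),
                    x = coords[, 1], y = coords[, 2],
                    clone = rep(clone_id, each = clone_size),
                    cluster = rep(clone_struct, each = clone_size))
    truth <- tibble(clone = clone_id, truth = clone_struct)
    new_synthetic_dataset(cells, truth,
                          list(generator = "rings_crosses", seed = seed,
                               per_structure = per_structure,
                               clone_size = clone_size))
  })
}

#' Uniform cell subsampling of a synthetic dataset
#'
#' Samples `round(fraction * N)` cells without replacement; clones are
#' reduced to their surviving cells and clones left with no cell disappear.
#' Downstream embedding of subsampled data conventionally uses minimum
#' clone size 2.
#'
#' @param ds A `synthetic_clones` object.
#' @param fraction Fraction of cells kept, in (0, 1].
#' @param seed Integer seed.
#' @return A `synthetic_clones` object on the surviving cells.
#' @export
subsample_dataset <- function(ds, fraction, seed = 1) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("`fraction` must lie in (0, 1].", class = "clonespace_parameter_error")
  }
  if (fraction == 1) return(ds)
  with_seed(seed, {
    n <- nrow(ds$cells)
    keep <- sort(sample.int(n, size = round(fraction * n)))
    cells <- ds$cells[keep, ]
    truth <- ds$clone_truth[ds$clone_truth$clone %in% unique(cells$clone), ]
    params <- ds$params
    params$subsample_fraction <- fraction
    params$subsample_seed <- seed
    new_synthetic_dataset(cells, truth, params)
  })
}
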