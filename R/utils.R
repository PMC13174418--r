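# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so package functions never clobber user seeds.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

assert_scalar_int <- function(x, name, min = -Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %s.", name, min),
          class = "clonespace_parameter_error")
  }
  as.integer(x)
}

assert_finite_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix.", name),
          class = "clonespace_validation_error")
  }
  if (any(!is.finite(x))) {
    abort(sprintf("`%s` contains non-finite entries.", name),
          class = "clonespace_validation_error")
  }
  invisible(x)
}

# Sentinel used for the null clone label; never a legal clone name.
NULL_CLONE <- NA_character_

as_coord_matrix <- function(data, coords) {
  if (is.matrix(data)) {
    storage.mode(data) <- "double"
    return(data)
  }
  miss <- setdiff(coords, names(data))
  if (length(miss) > 0) {
    abort(paste0("Coordinate columns not found: ", paste(miss, collapse = ", ")),
          class = "clonespace_key_error")
  }
  as.matrix(as.data.frame(data)[, coords, drop = FALSE])
}
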