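# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded package functions do not
#' perturb the caller's random-number stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Row-wise medians of a numeric matrix without per-row apply().  Sorting by
# (row, value) in one pass keeps this O(nk log nk) and vectorised, which
# matters for the 50,000-repetition bootstrap.
row_medians <- function(m) {
  if (!is.matrix(m)) m <- matrix(m, nrow = 1L)
  n <- nrow(m)
  k <- ncol(m)
  if (k == 1L) return(m[, 1L])
  ord <- order(row(m), m)
  sorted <- matrix(m[ord], nrow = n, ncol = k, byrow = TRUE)
  if (k %% 2L == 1L) {
    sorted[, (k + 1L) %/% 2L]
  } else {
    (sorted[, k %/% 2L] + sorted[, k %/% 2L + 1L]) / 2
  }
}

# Vectorised median of three equal-length vectors.
median3 <- function(a, b, c) {
  a + b + c - pmax(a, b, c) - pmin(a, b, c)
}

# Maximal runs of TRUE in a logical vector; returns data.frame(start, end, length).
true_runs <- function(mask) {
  mask[is.na(mask)] <- FALSE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
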