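# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. All package randomness flows through this.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a parent seed and an index, staying within the
# 32-bit signed integer range.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + 97 * as.numeric(i)) %% 2147483587) + 1L
}

stop_if_not_3d <- function(x, name = deparse(substitute(x))) {
  if (length(dim(x)) != 3L) stop(sprintf("%s must be a 3D array", name))
  invisible(x)
}

check_same_dim <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s have mismatched dimensions: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
  invisible(TRUE)
}

# Cumulative integral of y(t) from 0 by trapezoid on (t, y) pairs, with a
# leading triangle from (0, 0) to the first point. Vectorised over columns
# when y is a matrix (rows = voxels, cols = time points).
cumtrapz_from_zero <- function(t, y) {
  if (is.matrix(y)) {
    n <- length(t)
    stopifnot(ncol(y) == n)
    out <- matrix(0, nrow(y), n)
    out[, 1] <- 0.5 * t[1] * y[, 1]
    if (n > 1) {
      for (i in 2:n) {
        out[, i] <- out[, i - 1] +
          0.5 * (y[, i] + y[, i - 1]) * (t[i] - t[i - 1])
      }
    }
    out
  } else {
    n <- length(t)
    stopifnot(length(y) == n)
    inc <- c(0.5 * t[1] * y[1],
             if (n > 1) 0.5 * (y[-1] + y[-n]) * diff(t) else NULL)
    cumsum(inc)
  }
}
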