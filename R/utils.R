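# Internal helpers shared across modules. Grid distributions are plain
# numeric vectors in row-major order (cell (r, c) of an R x C grid sits at
# flat index r*C + c, 0-based); ties in argmax break to the lowest flat
# index, which is what which.max() does on such a vector.

# preserves dim attributes (pmin/pmax would drop them)
clamp01 <- function(v) {
  v[v < 0] <- 0
  v[v > 1] <- 1
  v
}

# Normalize a non-negative vector to a mass function; uniform fallback for
# a (numerically) all-zero input.
normalize_mass <- function(v) {
  s <- sum(v)
  if (!is.finite(s) || s <= 0) return(rep(1 / length(v), length(v)))
  v / s
}

is_mass_function <- function(v, tol = 1e-9) {
  all(v >= -tol) && abs(sum(v) - 1) <= tol
}

# Row-major coordinates (0-based rows/cols) for flat indices 1..rows*cols.
grid_coords <- function(rows, cols) {
  idx <- seq_len(rows * cols) - 1L
  cbind(r = idx %/% cols, c = idx %% cols)
}

# M x M matrix of Euclidean distances between grid cells.
grid_dist_matrix <- function(rows, cols) {
  xy <- grid_coords(rows, cols)
  dr <- outer(xy[, 1], xy[, 1], "-")
  dc <- outer(xy[, 2], xy[, 2], "-")
  sqrt(dr^2 + dc^2)
}

#' Exponential decay schedule
#'
#' Geometric interpolation from `start` to `end` over `horizon` update steps,
#' constant at `end` afterwards; an optional `lag` holds the schedule at
#' `start` for its first `lag` steps (used by higher hierarchy levels whose
#' inputs are not well defined until lower units have learned).
#'
#' @param start,end positive schedule endpoints, `end <= start`.
#' @param horizon number of steps over which to decay.
#' @param lag steps to hold at `start` before decaying.
#' @return an object of class `ampf_schedule`.
#' @export
schedule <- function(start, end = start, horizon = 1, lag = 0) {
  stopifnot(start > 0, end > 0, end <= start, horizon >= 1, lag >= 0)
  structure(list(start = start, end = end, horizon = horizon, lag = lag),
            class = "ampf_schedule")
}

#' @rdname schedule
#' @param s an `ampf_schedule`.
#' @param t 0-based step counter.
#' @export
schedule_value <- function(s, t) {
  if (is.numeric(s)) return(s)  # plain constants are accepted anywhere
  tt <- max(0, t - s$lag)
  frac <- min(1, tt / s$horizon)
  s$start * (s$end / s$start)^frac
}
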