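#' Self-organizing map model grid
#'
#' A 2-d lattice of model vectors used for spatial pooling. Each of the
#' `rows * cols` cells holds a model of the input vector; classification of
#' an input against the grid produces a smooth normalized likelihood over
#' cells, and online Kohonen updates move models toward observed inputs
#' under a Gaussian grid neighbourhood.
#'
#' Weights are initialized uniformly at random in `[0, 1]` (the system
#' develops from a random initial configuration) and remain clamped to
#' `[0, 1]`, matching the unit-range contract of interface vectors.
#'
#' @param rows,cols grid dimensions.
#' @param input_dim length of the input vectors the grid models.
#' @param rng an [rng_handle()] used for weight initialization.
#' @param learning_rate an [schedule()] (or constant) for the Kohonen step.
#' @param radius an [schedule()] (or constant) for the Gaussian
#'   neighbourhood radius, in grid-cell units.
#' @param smoothing damping constant `beta` of the likelihood: every squared
#'   error is inflated by `beta` times the mean squared error before
#'   inversion, flattening the response within a cluster of near-duplicate
#'   models while leaving between-cluster contrasts decisive. `0` is the
#'   undamped inverse.
#' @return an environment of class `som_grid`.
#' @export
som_grid <- function(rows, cols, input_dim, rng,
                     learning_rate = schedule(0.25, 0.02, 5000),
                     radius = schedule(max(rows, cols) / 2, 0.5, 5000),
                     smoothing = 0) {
  stopifnot(rows >= 1, cols >= 1, input_dim >= 1, smoothing >= 0)
  g <- new.env(parent = emptyenv())
  g$rows <- as.integer(rows)
  g$cols <- as.integer(cols)
  g$m <- g$rows * g$cols
  g$input_dim <- as.integer(input_dim)
  g$W <- matrix(rng_runif(rng, g$m * g$input_dim), nrow = g$m)
  g$dist <- grid_dist_matrix(g$rows, g$cols)
  g$learning_rate <- learning_rate
  g$radius <- radius
  g$smoothing <- smoothing
  g$iter <- 0L
  class(g) <- "som_grid"
  g
}

#' SOM likelihood over grid models
#'
#' The likelihood of each model given the input is the inverse of the
#' normalized sum of squared errors: with `e_i = sum((w_i - x)^2)` and
#' `z_i = e_i / sum(e)`, the activation is `a_i = 1 / z_i` renormalized to
#' total mass 1 (a small epsilon guards exact-match models, so the result
#' stays strictly positive everywhere). The result is smooth, with
#' significant response from many models, which is what allows a
#' prediction bias to shift the winner. If every model is at zero distance
#' from the input the normalization degenerates and a uniform distribution
#' is returned.
#'
#' @param grid a [som_grid()].
#' @param x input vector of length `grid$input_dim`, components in `[0, 1]`.
#' @return a mass function over grid cells (row-major vector, sums to 1).
#' @export
activate_som <- function(grid, x) {
  if (length(x) != grid$input_dim)
    stop("activate_som: input length ", length(x),
         " does not match grid input_dim ", grid$input_dim)
  activate_som_vec(grid, x)
}

#' Online Kohonen weight update
#'
#' Moves every model toward the input by `lr * exp(-d^2 / (2 * radius^2))`
#' where `d` is the grid Euclidean distance to the winning cell; a radius at
#' or below numerical tolerance updates the winner alone. Weights are
#' clamped to `[0, 1]` afterwards. The grid's update counter (which drives
#' its schedules) advances by one.
#'
#' @param grid a [som_grid()], modified in place.
#' @param x training input vector.
#' @param winner flat (row-major) 1-based index of the winning cell.
#' @param lr,radius overrides for this step; `NULL` reads the grid's
#'   schedules at the current counter.
#' @return the grid, invisibly.
#' @export
update_som <- function(grid, x, winner, lr = NULL, radius = NULL) {
  if (length(x) != grid$input_dim) stop("update_som: input length mismatch")
  stopifnot(winner >= 1, winner <= grid$m)
  if (is.null(lr)) lr <- schedule_value(grid$learning_rate, grid$iter)
  if (is.null(radius)) radius <- schedule_value(grid$radius, grid$iter)
  if (lr < 0 || lr > 1) stop("update_som: learning rate must be in [0,1]")
  grid$iter <- grid$iter + 1L
  if (lr == 0) return(invisible(grid))
  d <- grid$dist[, winner]
  h <- if (radius < 1e-12) as.numeric(d == 0) else exp(-d^2 / (2 * radius^2))
  step <- lr * h
  grid$W <- clamp01(grid$W + step * (rep(x, each = grid$m) - grid$W))
  invisible(grid)
}

#' One-hot orthogonalization of a grid distribution
#'
#' Sets the maximum value to 1 and all others to 0, producing the highly
#' orthogonal input the temporal pooler requires. Ties break to the lowest
#' row-major flat index.
#'
#' @param d non-negative vector with at least one positive value.
#' @return a one-hot mass function of the same length.
#' @export
orthogonalize <- function(d) {
  if (all(d <= 0)) stop("orthogonalize: input has no positive value")
  out <- numeric(length(d))
  out[which.max(d)] <- 1
  out
}

#' Recurrent SOM state for temporal pooling
#'
#' A SOM whose effective input is a leaky integration of its one-hot input
#' stream: `y <- (1 - leak) * y + leak * x`. Classification against the
#' integrated vector makes the winner change slowly, so cells come to
#' represent temporally adjacent classifications (sequences). `leak = 1`
#' makes the RSOM behave exactly like a SOM on the same stream.
#'
#' @param grid a [som_grid()] whose `input_dim` equals the number of models
#'   in the pooler below.
#' @param leak leak coefficient in `(0, 1]`.
#' @param update_every decimation of the learning updates (the integrated
#'   trace still advances every step); 1 updates every step.
#' @return an environment of class `rsom_state`.
#' @export
rsom_state <- function(grid, leak = 0.3, update_every = 1L) {
  stopifnot(leak > 0, leak <= 1, update_every >= 1)
  s <- new.env(parent = emptyenv())
  s$grid <- grid
  s$leak <- leak
  s$update_every <- as.integer(update_every)
  s$integrated <- numeric(grid$input_dim)
  s$tick <- 0L
  class(s) <- "rsom_state"
  s
}

#' RSOM activation from a one-hot input
#'
#' Blends the new one-hot input into the integrated trace, then computes the
#' same inverse-normalized-squared-error likelihood as the SOM against the
#' integrated vector.
#'
#' @param state an [rsom_state()], integrated trace modified in place.
#' @param one_hot one-hot vector of length `state$grid$input_dim`.
#' @return a mass function over RSOM cells.
#' @export
activate_rsom <- function(state, one_hot) {
  if (length(one_hot) != state$grid$input_dim)
    stop("activate_rsom: input length mismatch")
  if (sum(one_hot == 1) != 1 || any(one_hot != 0 & one_hot != 1))
    stop("activate_rsom: input must be one-hot")
  state$integrated <- (1 - state$leak) * state$integrated + state$leak * one_hot
  activate_som_vec(state$grid, state$integrated)
}

# Same likelihood form, callable on an arbitrary (non unit-range) vector.
activate_som_vec <- function(grid, v) {
  e <- rowSums((grid$W - rep(v, each = grid$m))^2)
  s <- sum(e)
  if (s <= 0) return(rep(1 / grid$m, grid$m))
  damp <- max(grid$smoothing * s / grid$m, 1e-12 * s)
  normalize_mass(s / (e + damp))
}

#' RSOM weight update
#'
#' The Kohonen update of [update_som()] with the integrated trace as the
#' training vector, decimated by `state$update_every`.
#'
#' @param state an [rsom_state()].
#' @param winner flat index of the winning RSOM cell.
#' @inheritParams update_som
#' @return the state, invisibly.
#' @export
update_rsom <- function(state, winner, lr = NULL, radius = NULL) {
  state$tick <- state$tick + 1L
  if (state$tick %% state$update_every != 0L) return(invisible(state))
  update_som(state$grid, state$integrated, winner, lr = lr, radius = radius)
  invisible(state)
}

# --- serialization ---------------------------------------------------------

grid_snapshot <- function(g) {
  list(rows = g$rows, cols = g$cols, input_dim = g$input_dim,
       weights = as.numeric(g$W), iter = g$iter, smoothing = g$smoothing,
       learning_rate = unclass(g$learning_rate), radius = unclass(g$radius))
}

grid_restore <- function(snap) {
  g <- new.env(parent = emptyenv())
  g$rows <- as.integer(snap$rows); g$cols <- as.integer(snap$cols)
  g$m <- g$rows * g$cols
  g$input_dim <- as.integer(snap$input_dim)
  g$W <- matrix(as.numeric(snap$weights), nrow = g$m)
  g$dist <- grid_dist_matrix(g$rows, g$cols)
  restore_sched <- function(s)
    if (length(s) == 1) as.numeric(s) else do.call(schedule, as.list(s))
  g$learning_rate <- restore_sched(snap$learning_rate)
  g$radius <- restore_sched(snap$radius)
  g$smoothing <- if (is.null(snap$smoothing)) 0 else as.numeric(snap$smoothing)
  g$iter <- as.integer(snap$iter)
  class(g) <- "som_grid"
  g
}
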