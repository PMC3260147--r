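#' SOM-MPF unit
#'
#' One node of the memory-prediction hierarchy. The feed-forward pass
#' classifies the input against the spatial-pooling SOM, biases the
#' classification by the prediction cached from the previous feed-back
#' pass, orthogonalizes it, and (when present) passes the one-hot result
#' through the temporal-pooling RSOM. The feed-back pass inverts the pooler
#' transforms by roulette selection, combines the higher-level prediction
#' with the unit's own Markov prediction into the bias cache for the next
#' iteration, and emits a noisy copy of a selected SOM model as predicted
#' input. Either pooler may be omitted: units doing heavy spatial
#' compression can drop the RSOM, and units high in the hierarchy can drop
#' the SOM (the input then passes through as its own "classification").
#'
#' @param input_dim length of the FF input vector.
#' @param som_rows,som_cols SOM shape; `NULL` omits the spatial pooler.
#' @param rsom_rows,rsom_cols RSOM shape; `NULL` omits the temporal pooler.
#'   At least one pooler must be present.
#' @param mode predictor mode, `"first_order"` or `"variable_order"`.
#' @param seed seed for the unit's private RNG stream.
#' @param leak RSOM leak coefficient.
#' @param rsom_update_every RSOM learning decimation.
#' @param learning_rate,radius SOM schedules (see [som_grid()]).
#' @param rsom_learning_rate,rsom_radius RSOM schedules; default to the SOM
#'   schedules.
#' @param smoothing likelihood damping for the spatial SOM (see
#'   [som_grid()]).
#' @param lambda_f transition-learning schedule (see [transition_model()]).
#' @param noise feed-back exploration noise schedule (eta); initially 1,
#'   decayed to a low value; its `lag` should grow with hierarchy level.
#' @param vmm a [vmm_params()] for `variable_order` mode; `NULL` ties the
#'   DoG widths to the SOM's current neighbourhood radius.
#' @param bias_floor total weight `eps` of the uniform mass added when the
#'   bias cache is formed, `B = normalize(P * Z + eps / M)`; keeps every
#'   model selectable (plasticity, numerical rescue) while contributing
#'   only a small fraction of the selection mass against a peaked product.
#'   A constant or an [schedule()]; scheduling it high-to-low trades early
#'   exploration against late exploitation, like the feed-back noise.
#' @return an environment of class `mpf_unit`.
#' @export
mpf_unit <- function(input_dim, som_rows = NULL, som_cols = NULL,
                     rsom_rows = NULL, rsom_cols = NULL,
                     mode = c("first_order", "variable_order"),
                     seed = 1L, leak = 0.3, rsom_update_every = 1L,
                     learning_rate = schedule(0.25, 0.02, 5000),
                     radius = NULL,
                     rsom_learning_rate = learning_rate,
                     rsom_radius = NULL, smoothing = 0,
                     lambda_f = schedule(0.99, 0.01, 5000),
                     noise = schedule(1, 0.01, 5000),
                     vmm = NULL, bias_floor = 0.05) {
  mode <- match.arg(mode)
  has_som <- !is.null(som_rows)
  has_rsom <- !is.null(rsom_rows)
  if (!has_som && !has_rsom) stop("mpf_unit: at least one pooler is required")
  u <- new.env(parent = emptyenv())
  u$input_dim <- as.integer(input_dim)
  u$rng <- rng_handle(seed)
  if (has_som) {
    if (is.null(radius)) radius <- schedule(max(som_rows, som_cols) / 2, 0.5, 5000)
    u$som <- som_grid(som_rows, som_cols, input_dim, u$rng,
                      learning_rate = learning_rate, radius = radius,
                      smoothing = smoothing)
    u$m <- u$som$m
    u$som_rows <- as.integer(som_rows); u$som_cols <- as.integer(som_cols)
  } else {
    u$som <- NULL
    u$m <- u$input_dim          # input dimensions stand in for SOM states
    u$som_rows <- 1L; u$som_cols <- u$input_dim
  }
  if (has_rsom) {
    if (is.null(rsom_radius))
      rsom_radius <- schedule(max(rsom_rows, rsom_cols) / 2, 0.5, 5000)
    rg <- som_grid(rsom_rows, rsom_cols, u$m, u$rng,
                   learning_rate = rsom_learning_rate, radius = rsom_radius)
    u$rsom <- rsom_state(rg, leak = leak, update_every = rsom_update_every)
  } else u$rsom <- NULL
  u$mode <- mode
  u$tm <- transition_model(u$m, learning_rate = lambda_f)
  u$vmm <- vmm
  u$noise <- noise
  u$bias_floor <- bias_floor
  u$B <- rep(1 / u$m, u$m)      # bias cache, initialized uniform
  u$iter <- 0L
  u$learn <- TRUE
  u$flat_context <- FALSE       # set for topmost units (uninformative prior)
  u$ps <- NULL                  # current biased classification P^s
  u$ps_pred <- NULL             # predictor-input view of P^s (preprocessed in VMM mode)
  u$last_A <- NULL
  u$last_onehot <- NULL
  u$last_Y <- NULL
  class(u) <- "mpf_unit"
  u
}

#' Number of elements in a unit's FF output
#' @param u an [mpf_unit()].
#' @export
unit_output_dim <- function(u) if (!is.null(u$rsom)) u$rsom$grid$m else u$m

# Current VMM parameters; DoG widths track the SOM neighbourhood radius
# unless fixed parameters were supplied.
.unit_vmm <- function(u) {
  if (!is.null(u$vmm)) return(u$vmm)
  sig <- if (!is.null(u$som))
    max(schedule_value(u$som$radius, u$som$iter), 0.5) else 1
  vmm_params(excite_sigma = sig)
}

# Predictor-input view of a biased classification.
.unit_pred_input <- function(u, ps) {
  if (u$mode == "variable_order")
    vmm_preprocess(ps, u$som_rows, u$som_cols, .unit_vmm(u))
  else ps
}

#' Feed-forward pass of a unit
#'
#' Computes the smooth SOM likelihood `A` of the input, biases it by the
#' cached prediction `B` (element-wise product, renormalized) to give the
#' biased classification `P^s`, orthogonalizes `P^s`, and feeds the one-hot
#' through the RSOM when present; the unit FF output `Y` is the RSOM
#' activation, or `P^s` itself without a temporal pooler. While learning is
#' enabled, the SOM trains on the input with the `P^s` winner, the RSOM on
#' its integrated trace with the `Y` winner, and the transition model on
#' consecutive (predictor-view) biased classifications.
#'
#' @param u an [mpf_unit()], modified in place.
#' @param x FF input vector of length `u$input_dim`, components in `[0, 1]`.
#' @return the FF output mass function `Y`.
#' @export
unit_ff <- function(u, x) {
  if (length(x) != u$input_dim)
    stop("unit_ff: input length ", length(x), " != ", u$input_dim)
  A <- if (!is.null(u$som)) activate_som(u$som, x) else normalize_mass(x)
  ps <- normalize_mass(A * u$B)
  if (!is.null(u$som) && u$learn)
    update_som(u$som, x, which.max(ps))
  oh <- orthogonalize(ps)
  if (!is.null(u$rsom)) {
    Y <- activate_rsom(u$rsom, oh)
    if (u$learn) update_rsom(u$rsom, which.max(Y))
  } else Y <- ps
  ps_pred <- .unit_pred_input(u, ps)
  if (u$learn && !is.null(u$ps_pred))
    update_transitions(u$tm, u$ps_pred, ps_pred)
  u$last_A <- A; u$ps <- ps; u$ps_pred <- ps_pred
  u$last_onehot <- oh; u$last_Y <- Y
  u$iter <- u$iter + 1L
  Y
}

#' Feed-back pass of a unit
#'
#' Starting from the higher-level prediction over the unit's output space:
#' with an RSOM, roulette-selects an RSOM model and takes its (noise-
#' perturbed, clamped) weight vector as a distribution over SOM states;
#' without one the incoming message is used directly. That distribution is
#' combined with the unit's own Markov prediction of the next
#' classification by element-wise product plus a small uniform mass
#' `1 / M`, giving the bias cache `B` for the next FF pass — the uniform
#' term keeps every model selectable and prevents the bias locking out
#' observation. Finally a SOM model is roulette-selected from `B` and its
#' weight vector, plus noise, clamped to unit range, is emitted as the
#' predicted FF input.
#'
#' @param u an [mpf_unit()], modified in place.
#' @param yhat mass function over the unit's output space (from the parent,
#'   or a uniform prior at the top of the hierarchy).
#' @return the FB output vector (predicted input, length `u$input_dim`).
#' @export
unit_fb <- function(u, yhat) {
  if (length(yhat) != unit_output_dim(u))
    stop("unit_fb: prediction length mismatch")
  if (!is_mass_function(yhat, tol = 1e-6))
    stop("unit_fb: prediction must be a mass function")
  if (is.null(u$ps)) stop("unit_fb: feed-forward pass must run first")
  eta <- schedule_value(u$noise, u$iter)
  z <- if (!is.null(u$rsom)) {
    if (isTRUE(u$flat_context)) {
      # topmost unit: the prior carries no information, so inverting it
      # through roulette would hallucinate a sequence context; combine the
      # predictor output with a flat (uniform) context instead
      rep(1, u$m)
    } else {
      r <- roulette_select(yhat, u$rng)
      add_noise(clamp01(u$rsom$grid$W[r, ]), eta, u$rng)
    }
  } else yhat
  P <- predict_next(u$tm, u$mode, u$ps_pred,
                    rows = u$som_rows, cols = u$som_cols,
                    params = if (u$mode == "variable_order") .unit_vmm(u))
  u$B <- normalize_mass(P * z + schedule_value(u$bias_floor, u$iter) / u$m)
  sel <- roulette_select(u$B, u$rng)
  u$last_P <- P
  u$last_sel <- sel
  if (!is.null(u$som)) add_noise(u$som$W[sel, ], eta, u$rng) else u$B
}

#' Roulette selection from a non-negative vector
#'
#' Draws an index with probability proportional to value.
#'
#' @param d non-negative vector with positive total mass.
#' @param rng an [rng_handle()].
#' @return a 1-based index.
#' @export
roulette_select <- function(d, rng) {
  if (any(d < 0)) stop("roulette_select: negative mass")
  s <- sum(d)
  if (s <= 0) stop("roulette_select: zero total mass")
  r <- rng_runif(rng, 1) * s
  cs <- cumsum(d)
  min(which(cs >= r), length(d))
}

#' Zero-mean uniform exploration noise
#'
#' Perturbs each component by a uniform draw from `[-eta/2, +eta/2]` and
#' clamps the result to `[0, 1]`. Zero-mean noise does not drag values
#' toward either end of the unit range.
#'
#' @param v vector with components in `[0, 1]`.
#' @param eta noise magnitude, >= 0.
#' @param rng an [rng_handle()].
#' @return the perturbed, clamped vector.
#' @export
add_noise <- function(v, eta, rng) {
  stopifnot(eta >= 0)
  if (eta == 0) return(v)
  clamp01(v + eta * (rng_runif(rng, length(v)) - 0.5))
}

unit_snapshot <- function(u) {
  list(input_dim = u$input_dim, mode = u$mode,
       som = if (!is.null(u$som)) grid_snapshot(u$som),
       som_rows = u$som_rows, som_cols = u$som_cols,
       rsom = if (!is.null(u$rsom))
         list(grid = grid_snapshot(u$rsom$grid), leak = u$rsom$leak,
              update_every = u$rsom$update_every,
              integrated = u$rsom$integrated, tick = u$rsom$tick),
       tm = tm_snapshot(u$tm),
       noise = unclass(u$noise), bias_floor = unclass(u$bias_floor),
       B = u$B, iter = u$iter, learn = u$learn,
       flat_context = u$flat_context,
       ps = u$ps, ps_pred = u$ps_pred,
       rng = rng_snapshot(u$rng),
       vmm = if (!is.null(u$vmm)) unclass(u$vmm))
}

unit_restore <- function(snap) {
  u <- new.env(parent = emptyenv())
  u$input_dim <- as.integer(snap$input_dim)
  u$mode <- snap$mode
  u$som <- if (!is.null(snap$som)) grid_restore(snap$som)
  u$som_rows <- as.integer(snap$som_rows)
  u$som_cols <- as.integer(snap$som_cols)
  u$m <- if (!is.null(u$som)) u$som$m else u$input_dim
  if (!is.null(snap$rsom)) {
    u$rsom <- rsom_state(grid_restore(snap$rsom$grid), leak = snap$rsom$leak,
                         update_every = as.integer(snap$rsom$update_every))
    u$rsom$integrated <- as.numeric(snap$rsom$integrated)
    u$rsom$tick <- as.integer(snap$rsom$tick)
  } else u$rsom <- NULL
  u$tm <- tm_restore(snap$tm)
  s <- snap$noise
  u$noise <- if (length(s) == 1) as.numeric(s) else do.call(schedule, as.list(s))
  bf <- snap$bias_floor
  u$bias_floor <- if (length(bf) == 1) as.numeric(bf) else
    do.call(schedule, as.list(bf))
  u$B <- as.numeric(snap$B)
  u$iter <- as.integer(snap$iter)
  u$learn <- isTRUE(snap$learn)
  u$flat_context <- isTRUE(snap$flat_context)
  u$ps <- if (!is.null(snap$ps)) as.numeric(snap$ps)
  u$ps_pred <- if (!is.null(snap$ps_pred)) as.numeric(snap$ps_pred)
  u$rng <- rng_restore(snap$rng)
  u$vmm <- if (!is.null(snap$vmm)) do.call(vmm_params, as.list(snap$vmm))
  class(u) <- "mpf_unit"
  u
}
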