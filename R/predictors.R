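#' First-order Markov transition model over grid models
#'
#' `F` is an M x M column-stochastic matrix; `F[j, i]` approximates the
#' probability of model `j` being active next given that model `i` is active
#' now. It is learned as a recency-biased relative frequency of transitions:
#' a decrease of mass at `i` is read as exiting state `i` and an increase at
#' `j` as entering state `j`.
#'
#' @param m number of models.
#' @param learning_rate an [schedule()] (or constant) for the frequency
#'   blending rate; typically 0.99 initially, reduced to around 0.01.
#' @return an environment of class `transition_model`.
#' @export
transition_model <- function(m, learning_rate = schedule(0.99, 0.01, 5000)) {
  stopifnot(m >= 1)
  tm <- new.env(parent = emptyenv())
  tm$m <- as.integer(m)
  tm$F <- matrix(1 / m, nrow = m, ncol = m)
  tm$learning_rate <- learning_rate
  tm$iter <- 0L
  class(tm) <- "transition_model"
  tm
}

#' Update transition estimates from consecutive distributions
#'
#' Exit mass `d_i = max(0, p_prev[i] - p_now[i])` and entry mass
#' `g_j = max(0, p_now[j] - p_prev[j])` combine as an outer product:
#' `F[j, i] <- F[j, i] + lambda * d_i * g_j`, after which every column is
#' renormalized to sum 1. Simultaneous multi-state shifts therefore spread
#' their evidence over all (exit, entry) pairs in proportion to the mass
#' moved. Columns receiving no evidence are unchanged.
#'
#' @param tm a [transition_model()], modified in place.
#' @param p_prev,p_now mass functions over the same `tm$m` models.
#' @param lambda override of the learning rate for this step; `NULL` reads
#'   the schedule at the model's update counter.
#' @return the model, invisibly.
#' @export
update_transitions <- function(tm, p_prev, p_now, lambda = NULL) {
  if (length(p_prev) != tm$m || length(p_now) != tm$m)
    stop("update_transitions: distribution size mismatch")
  if (is.null(lambda)) lambda <- schedule_value(tm$learning_rate, tm$iter)
  tm$iter <- tm$iter + 1L
  if (lambda == 0) return(invisible(tm))
  d <- pmax(p_prev - p_now, 0)   # exit mass per source state
  g <- pmax(p_now - p_prev, 0)   # entry mass per destination state
  if (sum(d) == 0 || sum(g) == 0) return(invisible(tm))
  Fm <- tm$F + lambda * outer(g, d)
  tm$F <- sweep(Fm, 2, colSums(Fm), "/")
  invisible(tm)
}

#' First-order prediction
#'
#' Matrix-vector product of the transition matrix with the current
#' distribution, renormalized to total mass 1.
#'
#' @param tm a [transition_model()].
#' @param p_now mass function over the models.
#' @return predicted mass function for the next step.
#' @export
predict_first_order <- function(tm, p_now) {
  if (length(p_now) != tm$m) stop("predict_first_order: size mismatch")
  normalize_mass(as.numeric(tm$F %*% p_now))
}

#' Parameters of the variable-order extension
#'
#' The variable-order behaviour arises from the SOM's 2-d topology: a
#' centre-excitatory/surround-inhibitory Difference-of-Gaussians (DoG)
#' sharpens the predictor input around its global maximum, elements whose
#' strong first-order priors were inactive are inhibited through a
#' log-sigmoid, and the mass lost to inhibition is promoted onto grid
#' neighbours of the inhibited cells (topological neighbours respond to
#' similar patterns and are viable alternatives).
#'
#' @param excite_sigma centre Gaussian width, in grid-cell units; defaults
#'   should track the SOM's current neighbourhood radius.
#' @param dog_gain `k > 1`; the surround width is `k * excite_sigma` and the
#'   surround amplitude `1 / k`, keeping the kernel centre-positive.
#' @param inhibit_sigma surround width; default `dog_gain * excite_sigma`.
#' @param sigmoid_gain gain of the log-sigmoid unpredicted-prior inhibition;
#'   0 disables that stage (neutral value).
#' @param strong_factor a first-order edge counts as "strong" when its
#'   weight exceeds `strong_factor / M` (multiples of the uniform baseline).
#' @return a list of class `vmm_params`.
#' @export
vmm_params <- function(excite_sigma = 1, dog_gain = 2,
                       inhibit_sigma = dog_gain * excite_sigma,
                       sigmoid_gain = 10, strong_factor = 1.5) {
  stopifnot(excite_sigma > 0, dog_gain > 1,
            inhibit_sigma > excite_sigma || is.infinite(excite_sigma),
            sigmoid_gain >= 0, strong_factor > 0)
  structure(list(excite_sigma = excite_sigma, inhibit_sigma = inhibit_sigma,
                 dog_gain = dog_gain, sigmoid_gain = sigmoid_gain,
                 strong_factor = strong_factor),
            class = "vmm_params")
}

# DoG kernel centred on grid cell `centre`, as a vector over all cells.
# Centre-positive, negative on the near surround, ~0 far away.
.dog_kernel <- function(rows, cols, centre, params) {
  xy <- grid_coords(rows, cols)
  d2 <- (xy[, 1] - xy[centre, 1])^2 + (xy[, 2] - xy[centre, 2])^2
  exp(-d2 / (2 * params$excite_sigma^2)) -
    (1 / params$dog_gain) * exp(-d2 / (2 * params$inhibit_sigma^2))
}

#' Local inhibition around the global maximum (preprocessing)
#'
#' A DoG kernel centred on the argmax of `p` is linearly scaled to `[0, 1]`
#' and multiplies `p` element-wise; the result is renormalized to mass 1.
#' This enforces a clear single winner within the winner's topological
#' cluster before the first-order core is applied. An infinite
#' `excite_sigma` is the neutral value (flat kernel, stage skipped); if the
#' product numerically destroys all mass, a one-hot at the argmax is
#' returned.
#'
#' @param p mass function over the grid.
#' @param rows,cols grid shape of `p`.
#' @param params a [vmm_params()].
#' @return a mass function.
#' @export
vmm_preprocess <- function(p, rows, cols, params) {
  stopifnot(length(p) == rows * cols)
  if (is.infinite(params$excite_sigma)) return(normalize_mass(p))
  k <- .dog_kernel(rows, cols, which.max(p), params)
  rng <- max(k) - min(k)
  if (rng < 1e-12) return(normalize_mass(p))
  k <- (k - min(k)) / rng
  out <- p * k
  if (sum(out) <= 1e-300) {
    out <- numeric(length(p)); out[which.max(p)] <- 1
    return(out)
  }
  normalize_mass(out)
}

#' Inhibition of predictions whose priors were not observed
#'
#' For each element `j` with strong first-order edges `i -> j`, the
#' inhibition drive is the weight-averaged inactivity of its strong priors:
#' `h_j = sum_i F[j, i] * (1 - act_i) / sum_i F[j, i]` over strong edges,
#' with `act_i = p_prev[i] / max(p_prev)`. An element whose dominant prior
#' was observed is left alone; one none of whose priors were observed is
#' fully inhibited ("if A implies B and A is not observed, inhibit B"). The
#' drive passes through a log-sigmoid of gain `sigmoid_gain` centred at
#' `h = 1/2`, linearly scaled so that `h = 0` maps to inhibition strength 0
#' and `h = 1` to strength 1, and the strength is removed multiplicatively
#' from `p`. Elements without strong incoming edges are never inhibited.
#'
#' @param p mass function being inhibited (the first-order prediction).
#' @param tm a [transition_model()].
#' @param p_prev prior activity (the preprocessed current classification).
#' @param params a [vmm_params()].
#' @return list with elements `p` (inhibited distribution, not
#'   renormalized) and `lost` (element-wise non-negative mass lost).
#' @export
vmm_inhibit_unpredicted <- function(p, tm, p_prev, params) {
  stopifnot(length(p) == tm$m, length(p_prev) == tm$m)
  zero <- list(p = p, lost = numeric(length(p)))
  if (params$sigmoid_gain == 0) return(zero)
  strong <- tm$F > params$strong_factor / tm$m
  if (!any(strong)) return(zero)
  mx <- max(p_prev)
  act <- if (mx > 0) p_prev / mx else numeric(tm$m)
  w <- tm$F * strong
  wtot <- rowSums(w)
  h <- ifelse(wtot > 0, as.numeric(w %*% (1 - act)) / pmax(wtot, 1e-300), 0)
  g <- params$sigmoid_gain
  sig <- 1 / (1 + exp(-g * (h - 0.5)))
  lo <- 1 / (1 + exp(g / 2))
  hi <- 1 / (1 + exp(-g / 2))
  strength <- (sig - lo) / (hi - lo)
  p_inh <- p * (1 - strength)
  list(p = p_inh, lost = p - p_inh)
}

#' Promotion of neighbours of inhibited elements
#'
#' Builds a promotion field by convolving the lost-mass matrix with an
#' inverted DoG of grid Euclidean distance (zero at the inhibited cell,
#' maximal on its near neighbours, vanishing far away), scales it so its
#' total equals the total lost mass (mass-conserving reallocation), adds it
#' to the inhibited distribution and renormalizes.
#'
#' @param p_inhibited inhibited distribution (from
#'   [vmm_inhibit_unpredicted()]).
#' @param lost element-wise non-negative lost mass.
#' @param rows,cols grid shape.
#' @param params a [vmm_params()].
#' @return a mass function.
#' @export
vmm_promote_neighbours <- function(p_inhibited, lost, rows, cols, params) {
  stopifnot(length(p_inhibited) == rows * cols, length(lost) == rows * cols,
            all(lost >= 0))
  total <- sum(lost)
  if (total <= 0) return(normalize_mass(p_inhibited))
  d <- grid_dist_matrix(rows, cols)
  kern <- exp(-d^2 / (2 * params$inhibit_sigma^2)) -
    exp(-d^2 / (2 * params$excite_sigma^2))   # 0 at d = 0, peak at small d > 0
  promo <- as.numeric(kern %*% lost)
  sp <- sum(promo)
  if (sp <= 0) return(normalize_mass(p_inhibited))
  normalize_mass(p_inhibited + promo * (total / sp))
}

#' Predictor dispatch: first-order or variable-order
#'
#' `first_order` applies [predict_first_order()] to the raw input.
#' `variable_order` composes preprocessing, the first-order core on the
#' preprocessed input, unpredicted-prior inhibition (using the preprocessed
#' input as prior activity) and neighbour promotion, returning a
#' renormalized mass function.
#'
#' @param tm a [transition_model()].
#' @param mode `"first_order"` or `"variable_order"`.
#' @param p_now current (biased) classification mass function.
#' @param rows,cols grid shape (required for `variable_order`).
#' @param params a [vmm_params()] (required for `variable_order`).
#' @return predicted mass function.
#' @export
predict_next <- function(tm, mode = c("first_order", "variable_order"),
                         p_now, rows = NULL, cols = NULL, params = NULL) {
  mode <- match.arg(mode)
  if (mode == "first_order") return(predict_first_order(tm, p_now))
  stopifnot(!is.null(rows), !is.null(cols), !is.null(params))
  p_pre <- vmm_preprocess(p_now, rows, cols, params)
  p1 <- predict_first_order(tm, p_pre)
  inh <- vmm_inhibit_unpredicted(p1, tm, p_pre, params)
  vmm_promote_neighbours(inh$p, inh$lost, rows, cols, params)
}

tm_snapshot <- function(tm) {
  list(m = tm$m, F = as.numeric(tm$F), iter = tm$iter,
       learning_rate = unclass(tm$learning_rate))
}

tm_restore <- function(snap) {
  tm <- transition_model(as.integer(snap$m))
  tm$F <- matrix(as.numeric(snap$F), nrow = tm$m)
  tm$iter <- as.integer(snap$iter)
  s <- snap$learning_rate
  tm$learning_rate <- if (length(s) == 1) as.numeric(s) else
    do.call(schedule, as.list(s))
  tm
}
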