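#' Smoothed reward-derivative tracker
#'
#' The adaptive system maximizes the first derivative of reward rather than
#' its level: a bad situation should motivate change regardless of how bad
#' it is. The per-iteration derivative, normalized by the maximum possible
#' absolute derivative `r_max` and clamped to `[-1, 1]`, is blended into a
#' running value by an exponentially-weighted moving average with
#' coefficient `alpha`. A constant reward stream drives the tracker to its
#' neutral value 0; the tracked value always stays within `[-1, 1]`.
#'
#' @param alpha smoothing coefficient in `(0, 1)`; the weight of the newest
#'   derivative sample.
#' @param r_max maximum absolute per-iteration reward derivative; must be
#'   positive.
#' @param r0 initial reward level (the reference for the first derivative).
#' @return an environment of class `reward_tracker`.
#' @export
reward_tracker <- function(alpha = 0.5, r_max = 1, r0 = 0.5) {
  stopifnot(alpha > 0, alpha < 1)
  if (r_max <= 0) stop("reward_tracker: r_max must be positive")
  t <- new.env(parent = emptyenv())
  t$alpha <- alpha
  t$r_max <- r_max
  t$r_prev <- r0
  t$rhat <- 0
  class(t) <- "reward_tracker"
  t
}

#' Update the smoothed reward derivative
#'
#' @param tracker a [reward_tracker()], modified in place.
#' @param r_now instantaneous reward in `[0, 1]`.
#' @return the updated smoothed derivative `rhat` in `[-1, 1]`.
#' @export
update_reward <- function(tracker, r_now) {
  stopifnot(r_now >= 0, r_now <= 1)
  dr <- (r_now - tracker$r_prev) / tracker$r_max
  dr <- max(-1, min(1, dr))
  tracker$rhat <- (1 - tracker$alpha) * tracker$rhat + tracker$alpha * dr
  tracker$r_prev <- r_now
  tracker$rhat
}

#' Reward correlator relay
#'
#' Sits on the edge between a lower and a higher unit. On the feed-forward
#' pass it relays the lower unit's output unaltered while correlating a
#' (possibly delayed) copy of it with the smoothed reward derivative; on
#' the feed-back pass it biases the higher unit's prediction toward
#' elements whose activity has correlated with increasing reward.
#'
#' Correlations are stored element-wise in `C`, updated only in proportion
#' to each element's (delayed) activation — inactive elements keep their
#' correlation. Because the update is an activation-gated moving average
#' toward `rhat`, every entry of `C` stays in `[-1, 1]`.
#'
#' In this implementation the sensor-motor convention already lags
#' perception by one iteration (the FF message at `t` classifies the
#' world's response to the action generated during the FB pass of `t - 1`),
#' so the required delay between acting and correlating is inherent;
#' `delay` counts additional buffered iterations beyond that.
#'
#' @param m number of elements in the relayed message.
#' @param theta maximum influence of the adaptive bias, in `[0, 1]`.
#' @param lambda correlation learning-rate [schedule()] (or constant),
#'   gradually decreased over time.
#' @param delay extra whole iterations by which the correlated FF message
#'   lags the reward signal (>= 0).
#' @return an environment of class `correlator`.
#' @export
make_correlator <- function(m, theta = 0.5,
                            lambda = schedule(0.2, 0.02, 20000),
                            delay = 1L) {
  stopifnot(m >= 1, theta >= 0, theta <= 1, delay >= 0)
  cr <- new.env(parent = emptyenv())
  cr$m <- as.integer(m)
  cr$C <- numeric(m)
  cr$theta <- theta
  cr$lambda <- lambda
  cr$delay <- as.integer(delay)
  cr$buffer <- vector("list", 0)
  cr$iter <- 0L
  class(cr) <- "correlator"
  cr
}

#' Feed-forward relay with reward correlation
#'
#' Pushes the incoming message onto the delay buffer; once the buffer is
#' warm, pops the message from `delay` iterations ago and updates
#' `C <- C + lambda * y_delayed * (rhat - C)` element-wise. The message
#' itself is relayed unaltered and without delay.
#'
#' @param cr a [make_correlator()], modified in place.
#' @param y FF message (mass function over `cr$m` elements).
#' @param rhat current smoothed reward derivative.
#' @return `y`, unchanged.
#' @export
relay_ff <- function(cr, y, rhat) {
  if (length(y) != cr$m) stop("relay_ff: message shape changed mid-stream")
  cr$buffer <- c(cr$buffer, list(y))
  if (length(cr$buffer) > cr$delay) {
    y_d <- cr$buffer[[1]]
    cr$buffer <- cr$buffer[-1]
    lam <- schedule_value(cr$lambda, cr$iter)
    cr$C <- cr$C + lam * y_d * (rhat - cr$C)
    cr$iter <- cr$iter + 1L
  }
  y
}

#' Feed-back relay with adaptive bias
#'
#' Elements whose correlation with reward is positive gain mass and
#' negative ones lose mass. The correlation passes through a signed square
#' root `b = sign(C) * sqrt(|C|)` — a nonlinearity that amplifies weak
#' correlations so they are rapidly tested and either strengthened or
#' depleted — and each element is scaled by the odd ratio factor
#' `(1 + theta * b) / (1 - theta * b)`, after which the message is
#' renormalized. For weak bias this is `1 + 2 * theta * b` (linear), while
#' as `theta * |b|` approaches 1 the factor tends to 0 (or grows without
#' bound), so a strongly anti-correlated element can be suppressed far
#' enough to overrule a peaked prediction — which is what lets adaptive
#' pressure reverse an entrenched losing habit. `theta` caps the influence;
#' total mass is conserved at 1, and with `C = 0` or `theta = 0` the
#' message passes through bit-identically.
#'
#' @param cr a [make_correlator()].
#' @param yhat FB message (mass function over `cr$m` elements).
#' @return the biased mass function.
#' @export
relay_fb <- function(cr, yhat) {
  if (length(yhat) != cr$m) stop("relay_fb: message shape changed mid-stream")
  if (cr$theta == 0 || !any(cr$C != 0)) return(yhat)
  b <- cr$theta * sign(cr$C) * sqrt(abs(cr$C))
  out <- yhat * pmax(1 + b, 0) / pmax(1 - b, 1e-3)
  if (sum(out) <= 0) return(yhat)
  normalize_mass(out)
}

correlator_snapshot <- function(cr) {
  list(m = cr$m, C = cr$C, theta = cr$theta, lambda = unclass(cr$lambda),
       delay = cr$delay, buffer = cr$buffer, iter = cr$iter)
}

correlator_restore <- function(snap) {
  s <- snap$lambda
  lam <- if (length(s) == 1) as.numeric(s) else do.call(schedule, as.list(s))
  cr <- make_correlator(as.integer(snap$m), theta = snap$theta,
                        lambda = lam, delay = as.integer(snap$delay))
  cr$C <- as.numeric(snap$C)
  cr$buffer <- lapply(snap$buffer, as.numeric)
  cr$iter <- as.integer(snap$iter)
  cr
}

tracker_snapshot <- function(t)
  list(alpha = t$alpha, r_max = t$r_max, r_prev = t$r_prev, rhat = t$rhat)

tracker_restore <- function(snap) {
  t <- reward_tracker(alpha = snap$alpha, r_max = snap$r_max, r0 = snap$r_prev)
  t$rhat <- as.numeric(snap$rhat)
  t
}
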