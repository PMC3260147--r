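#' Hierarchy specification
#'
#' Describes a tree of SOM-MPF units, the correlators on its edges, and the
#' level-0 sensor-motor interface. Edges run child -> parent; every
#' non-root unit must have exactly one parent and the edges must form a
#' tree. Units without children sit at level 0 and read (a slice of) the
#' interface vector, which is the concatenation of sensor values and, when
#' `n_actions > 0`, a one-hot encoding of the action actually chosen in the
#' previous iteration (state-action pairing).
#'
#' @param units list of per-unit configuration lists; recognised fields are
#'   `som = c(rows, cols)`, `rsom = c(rows, cols)` (either may be absent),
#'   `mode`, `leak`, `input_slice` (interface indices, level-0 units only)
#'   and any further arguments of [mpf_unit()] (schedules etc.).
#' @param edges list of `list(child =, parent =, correlator =)` entries;
#'   `correlator` is `NULL` (plain relay) or a list of arguments for
#'   [make_correlator()] (`theta`, `lambda`, `delay`).
#' @param sensor_dim length of the sensor part of the interface.
#' @param n_actions number of discrete actions (0 for a passive hierarchy).
#' @param seed master seed; every unit, actuator and correlator derives an
#'   independent stream from it.
#' @param alpha,r_max reward-tracker parameters (see [reward_tracker()]).
#' @return a list of class `hierarchy_spec`.
#' @export
hierarchy_spec <- function(units, edges = list(), sensor_dim, n_actions = 0,
                           seed = 1L, alpha = 0.5, r_max = 1) {
  structure(list(units = units, edges = edges, sensor_dim = sensor_dim,
                 n_actions = n_actions, seed = seed, alpha = alpha,
                 r_max = r_max),
            class = "hierarchy_spec")
}

#' Build a hierarchy from its specification
#'
#' Validates the tree (single root, one parent per unit, no cycles),
#' assigns levels bottom-up, instantiates units with independent seeded RNG
#' streams, places correlators on the configured edges, attaches a discrete
#' actuator when actions are requested, and sets the topmost FB prior to
#' uniform.
#'
#' @param spec a [hierarchy_spec()].
#' @return an environment of class `hierarchy`.
#' @export
build_hierarchy <- function(spec) {
  n <- length(spec$units)
  parent <- rep(NA_integer_, n)
  for (e in spec$edges) {
    if (!is.na(parent[e$child]))
      stop("build_hierarchy: unit ", e$child, " has more than one parent")
    parent[e$child] <- e$parent
  }
  roots <- which(is.na(parent))
  if (length(roots) != 1) stop("build_hierarchy: hierarchy must have one root")
  # level = longest child-chain below; also detects cycles
  level <- rep(NA_integer_, n)
  children <- lapply(seq_len(n), function(i) which(parent == i))
  assign_level <- function(i, seen) {
    if (i %in% seen) stop("build_hierarchy: cyclic edges")
    if (!is.na(level[i])) return(level[i])
    ch <- children[[i]]
    lv <- if (length(ch) == 0) 0L else
      1L + max(vapply(ch, assign_level, 0L, seen = c(seen, i)))
    level[i] <<- lv
    lv
  }
  for (i in seq_len(n)) assign_level(i, integer(0))

  h <- new.env(parent = emptyenv())
  h$spec <- spec
  h$parent <- parent
  h$children <- children
  h$level <- level
  h$ff_order <- order(level, seq_len(n))
  h$fb_order <- rev(h$ff_order)
  h$iter <- 0L
  h$tracker <- reward_tracker(alpha = spec$alpha, r_max = spec$r_max)

  iface_dim <- spec$sensor_dim + spec$n_actions
  h$sensor_slice <- seq_len(spec$sensor_dim)
  h$motor_slice <- if (spec$n_actions > 0)
    spec$sensor_dim + seq_len(spec$n_actions) else integer(0)

  # level-0 input slices must exactly tile the interface vector
  leaf <- which(level == 0L)
  slices <- vector("list", n)
  for (i in leaf) {
    sl <- spec$units[[i]]$input_slice
    slices[[i]] <- if (is.null(sl)) seq_len(iface_dim) else as.integer(sl)
  }
  tiled <- sort(unlist(slices[leaf]))
  if (!identical(tiled, seq_len(iface_dim)))
    stop("build_hierarchy: level-0 input slices must tile the interface")
  h$slices <- slices

  # build children-first so parent input dims are known
  h$units <- vector("list", n)
  for (i in h$ff_order) {
    cfg <- spec$units[[i]]
    dim_i <- if (level[i] == 0L) length(slices[[i]]) else
      sum(vapply(children[[i]], function(ch) unit_output_dim(h$units[[ch]]), 0L))
    args <- cfg
    args$input_slice <- NULL
    args$som <- NULL
    args$rsom <- NULL
    if (!is.null(cfg$som)) {
      args$som_rows <- cfg$som[1]; args$som_cols <- cfg$som[2]
    }
    if (!is.null(cfg$rsom)) {
      args$rsom_rows <- cfg$rsom[1]; args$rsom_cols <- cfg$rsom[2]
    }
    args$input_dim <- dim_i
    args$seed <- (as.integer(spec$seed) %% 2000000L) * 1000L + i
    h$units[[i]] <- do.call(mpf_unit, args)
  }

  # the root receives an uninformative uniform prior; its temporal pooler
  # is combined as a flat context rather than inverted by roulette
  h$units[[h$ff_order[n]]]$flat_context <- TRUE

  h$correlators <- vector("list", n)  # indexed by child unit
  for (e in spec$edges) {
    if (!is.null(e$correlator)) {
      args <- e$correlator
      args$m <- unit_output_dim(h$units[[e$child]])
      h$correlators[[e$child]] <- do.call(make_correlator, args)
    }
  }
  h$actuator <- if (spec$n_actions > 0)
    actuator_state(spec$n_actions, seed = (as.integer(spec$seed) %% 2000000L) * 1000L + n + 1L)
  class(h) <- "hierarchy"
  h
}

#' One full iteration of the hierarchy
#'
#' Samples the reward into the smoothed-derivative tracker, assembles the
#' level-0 interface vector by pairing the current sensor values with the
#' action chosen in the previous iteration, runs the feed-forward pass in
#' level order (relaying each child output through its edge correlator with
#' the shared reward signal), then the feed-back pass from the top with a
#' uniform prior (biasing each downward message through the edge
#' correlator), routes the motor slice of the level-0 FB output to the
#' actuator, and returns the chosen action together with the full FB
#' interface vector — whose sensor slice is the prediction of the next
#' sensor input.
#'
#' @param h a [build_hierarchy()] result, modified in place.
#' @param sensor sensor vector of length `spec$sensor_dim`, values in
#'   `[0, 1]`.
#' @param reward scalar reward in `[0, 1]` perceived this iteration (the
#'   result of the previous action).
#' @return list with `action` (index or `NA` for passive hierarchies),
#'   `fb` (FB interface vector), `rhat` (smoothed reward derivative).
#' @export
hierarchy_step <- function(h, sensor, reward) {
  if (length(sensor) != h$spec$sensor_dim)
    stop("hierarchy_step: sensor length mismatch")
  if (reward < 0 || reward > 1)
    stop("hierarchy_step: reward outside [0, 1]")
  rhat <- update_reward(h$tracker, reward)
  x <- c(sensor, if (!is.null(h$actuator)) da_ff(h$actuator))

  n <- length(h$units)
  Y <- vector("list", n)
  h$last_ff_order <- integer(0)
  for (i in h$ff_order) {
    xi <- if (h$level[i] == 0L) x[h$slices[[i]]] else
      unlist(lapply(h$children[[i]], function(ch) {
        y <- Y[[ch]]
        cr <- h$correlators[[ch]]
        if (!is.null(cr)) relay_ff(cr, y, rhat) else y
      }))
    Y[[i]] <- unit_ff(h$units[[i]], xi)
    h$last_ff_order <- c(h$last_ff_order, i)
  }

  xhat <- vector("list", n)
  yhat <- vector("list", n)
  root <- h$ff_order[n]
  yhat[[root]] <- topmost_prior(h$units[[root]])
  h$last_fb_order <- integer(0)
  for (i in h$fb_order) {
    xh <- unit_fb(h$units[[i]], yhat[[i]])
    xhat[[i]] <- xh
    h$last_fb_order <- c(h$last_fb_order, i)
    off <- 0L
    for (ch in h$children[[i]]) {
      dch <- unit_output_dim(h$units[[ch]])
      seg <- xh[off + seq_len(dch)]
      off <- off + dch
      msg <- normalize_mass(pmax(seg, 0))
      cr <- h$correlators[[ch]]
      yhat[[ch]] <- if (!is.null(cr)) relay_fb(cr, msg) else msg
    }
  }

  fb <- numeric(h$spec$sensor_dim + h$spec$n_actions)
  for (i in which(h$level == 0L)) fb[h$slices[[i]]] <- xhat[[i]]
  action <- if (!is.null(h$actuator))
    da_fb(h$actuator, pmax(fb[h$motor_slice], 1e-12)) else NA_integer_
  h$iter <- h$iter + 1L
  list(action = action, fb = fb, rhat = rhat)
}

#' Uniform topmost feed-back prior
#'
#' @param u the hierarchy's top [mpf_unit()].
#' @return uniform mass function over the unit's output space.
#' @export
topmost_prior <- function(u) {
  k <- unit_output_dim(u)
  rep(1 / k, k)
}

#' Discrete actuator
#'
#' Maps between discrete actions and probability mass functions at the
#' hierarchy's motor interface. Its FF output is a one-hot encoding of the
#' last action taken (exactly one 1); its FB input is a mass function over
#' actions from which the next action is roulette-selected.
#'
#' @param n_actions number of discrete actions.
#' @param seed seed for the actuator's RNG stream.
#' @return an environment of class `actuator_state`.
#' @export
actuator_state <- function(n_actions, seed = 1L) {
  stopifnot(n_actions >= 1)
  a <- new.env(parent = emptyenv())
  a$n_actions <- as.integer(n_actions)
  a$rng <- rng_handle(seed)
  a$last_action <- rng_int(a$rng, n_actions)
  class(a) <- "actuator_state"
  a
}

#' @rdname actuator_state
#' @param a an `actuator_state`.
#' @return `da_ff`: one-hot vector over actions.
#' @export
da_ff <- function(a) {
  out <- numeric(a$n_actions)
  out[a$last_action] <- 1
  out
}

#' @rdname actuator_state
#' @param pmf mass function over actions with positive total.
#' @return `da_fb`: the roulette-selected action index (also stored).
#' @export
da_fb <- function(a, pmf) {
  if (length(pmf) != a$n_actions) stop("da_fb: pmf length mismatch")
  a$last_action <- roulette_select(pmf, a$rng)
  a$last_action
}
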