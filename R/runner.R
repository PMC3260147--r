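#' Run one of the built-in demonstrations
#'
#' Builds the demo's hierarchy and environment, iterates full FF/FB passes,
#' and returns a per-iteration metrics log. With `out_dir` set, the log is
#' written as a headered CSV (`metrics.csv`) and the final hierarchy state
#' as a JSON checkpoint (`checkpoint.json`). A fixed seed yields an
#' identical log.
#'
#' @param demo demo id in 1..4 (see [demo_spec()]).
#' @param iterations number of hierarchy iterations (games, for demo 4).
#' @param seed master seed.
#' @param window moving-average window for the reward/error series.
#' @param out_dir optional output directory.
#' @param mode,adaptive configuration overrides passed to [demo_spec()].
#' @return invisible list with `log` (data.frame), `hierarchy`, `env`.
#' @export
run_demo <- function(demo, iterations = 10000, seed = 1L, window = 500,
                     out_dir = NULL, mode = NULL, adaptive = TRUE) {
  demo <- as.integer(demo)
  stopifnot(window >= 1)
  spec <- demo_spec(demo, seed = seed, mode = mode, adaptive = adaptive)
  h <- build_hierarchy(spec)
  env_seed <- (as.integer(seed) %% 2000000L) * 1000L + 999L
  env <- switch(demo,
                rgb_process(seed = env_seed),
                moving_lines(seed = env_seed),
                word_stream(seed = env_seed),
                rps_state(seed = env_seed))

  reward <- numeric(iterations)
  rhat <- numeric(iterations)
  err <- rep(NA_real_, iterations)
  action <- rep(NA_integer_, iterations)
  symbol <- rep(NA_character_, iterations)

  if (demo == 4L) {
    obs <- glyph("blank")
    r <- 0.5
    gestures <- env$gestures
    for (t in seq_len(iterations)) {
      st <- hierarchy_step(h, obs, r)
      res <- rps_step(env, st$action)
      reward[t] <- res$reward
      rhat[t] <- st$rhat
      action[t] <- st$action
      symbol[t] <- gestures[res$opponent]
      err[t] <- prediction_error(st$fb[h$sensor_slice], res$image)
      obs <- res$image
      r <- res$reward
    }
  } else {
    prev_fb <- NULL
    for (t in seq_len(iterations)) {
      o <- switch(demo,
                  list(x = rgb_step(env), sym = NA_character_),
                  { s <- moving_lines_step(env); list(x = s$frame, sym = s$class) },
                  { s <- words_step(env); list(x = s$image, sym = s$symbol) })
      if (!is.null(prev_fb)) err[t] <- prediction_error(prev_fb, o$x)
      st <- hierarchy_step(h, o$x, 0.5)
      reward[t] <- 0.5
      rhat[t] <- st$rhat
      symbol[t] <- o$sym
      prev_fb <- st$fb[h$sensor_slice]
    }
  }

  log <- data.frame(iteration = seq_len(iterations), reward = reward,
                    rhat = rhat, ma_reward = moving_average(reward, window),
                    pred_error = err, action = action, symbol = symbol,
                    stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(log, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    checkpoint_save(h, file.path(out_dir, "checkpoint.json"))
  }
  invisible(list(log = log, hierarchy = h, env = env))
}

#' Trailing moving average
#'
#' `ma[t]` is the arithmetic mean of the last `window` values ending at
#' `t`; `NA` while fewer than `window` values exist.
#'
#' @param x numeric vector.
#' @param window window length (>= 1).
#' @return vector of the same length as `x`.
#' @export
moving_average <- function(x, window) {
  stopifnot(window >= 1)
  n <- length(x)
  if (n < window) return(rep(NA_real_, n))
  cs <- cumsum(x)
  ma <- rep(NA_real_, n)
  ma[window:n] <- (cs[window:n] - c(0, cs)[(window:n) - window + 1L]) / window
  ma
}

#' Summarize a metrics log
#'
#' @param log a metrics data.frame from [run_demo()].
#' @param window moving-average window; the log must be at least this long.
#' @param threshold optional reward level; the summary reports the first
#'   iteration at which the windowed moving-average reward crosses it.
#' @return list with `final_ma_reward`, `final_ma_error`, `max_ma_reward`,
#'   and `first_crossing` (NA when never crossed or no threshold given).
#' @export
summarize_log <- function(log, window = 500, threshold = NULL) {
  if (nrow(log) < window) stop("summarize_log: log shorter than window")
  ma_r <- moving_average(log$reward, window)
  e <- log$pred_error
  e[is.na(e)] <- 0
  ma_e <- moving_average(e, window)
  first_crossing <- NA_integer_
  if (!is.null(threshold)) {
    hit <- which(ma_r >= threshold)
    if (length(hit) > 0) first_crossing <- hit[1]
  }
  list(final_ma_reward = ma_r[nrow(log)], final_ma_error = ma_e[nrow(log)],
       max_ma_reward = max(ma_r, na.rm = TRUE), first_crossing = first_crossing)
}

# --- checkpointing ---------------------------------------------------------

.CHECKPOINT_FORMAT <- 1L

#' Save / load a hierarchy checkpoint
#'
#' Checkpoints are JSON documents bundling the hierarchy specification and
#' named arrays for every component's state: SOM/RSOM weights and schedule
#' positions, transition matrices, bias caches, correlation matrices and
#' delay buffers, actuator state, the reward tracker, and all RNG streams.
#' `checkpoint_load(checkpoint_save(h))` continues a run with outputs
#' identical to the uninterrupted one.
#'
#' @param h a [build_hierarchy()] result.
#' @param path file path of the JSON checkpoint.
#' @return `checkpoint_save`: `path`, invisibly. `checkpoint_load`: the
#'   restored hierarchy.
#' @export
checkpoint_save <- function(h, path) {
  snap <- list(
    format = .CHECKPOINT_FORMAT,
    spec = .spec_to_plain(h$spec),
    iter = h$iter,
    units = lapply(h$units, unit_snapshot),
    correlators = lapply(h$correlators, function(cr)
      if (!is.null(cr)) correlator_snapshot(cr)),
    actuator = if (!is.null(h$actuator))
      list(n_actions = h$actuator$n_actions,
           last_action = h$actuator$last_action,
           rng = rng_snapshot(h$actuator$rng)),
    tracker = tracker_snapshot(h$tracker))
  jsonlite::write_json(snap, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname checkpoint_save
#' @export
checkpoint_load <- function(path) {
  snap <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                       simplifyDataFrame = FALSE,
                                       simplifyMatrix = FALSE),
                   error = function(e)
                     stop("checkpoint_load: cannot parse '", path, "': ",
                          conditionMessage(e)))
  if (is.null(snap$format) || snap$format != .CHECKPOINT_FORMAT)
    stop("checkpoint_load: unsupported checkpoint format")
  spec <- .spec_from_plain(snap$spec)
  h <- build_hierarchy(spec)
  h$iter <- as.integer(snap$iter)
  for (i in seq_along(h$units))
    h$units[[i]] <- unit_restore(.as_plain_list(snap$units)[[i]])
  crs <- .as_plain_list(snap$correlators)
  for (i in seq_along(h$correlators)) {
    ci <- if (i <= length(crs)) crs[[i]]
    if (is.list(ci) && !is.null(ci$m))
      h$correlators[[i]] <- correlator_restore(ci)
  }
  if (!is.null(snap$actuator) && length(snap$actuator) > 0) {
    h$actuator$n_actions <- as.integer(snap$actuator$n_actions)
    h$actuator$last_action <- as.integer(snap$actuator$last_action)
    h$actuator$rng <- rng_restore(snap$actuator$rng)
  }
  h$tracker <- tracker_restore(snap$tracker)
  h
}

# jsonlite may return data.frames for lists of records; force plain lists
.as_plain_list <- function(x) {
  if (is.data.frame(x)) lapply(seq_len(nrow(x)), function(i) as.list(x[i, ]))
  else x
}

.sched_fields_unit <- c("learning_rate", "radius", "rsom_learning_rate",
                        "rsom_radius", "lambda_f", "noise", "bias_floor")

.spec_to_plain <- function(spec) {
  out <- unclass(spec)
  out$units <- lapply(out$units, function(cfg) {
    for (f in .sched_fields_unit)
      if (!is.null(cfg[[f]])) cfg[[f]] <- unclass(cfg[[f]])
    if (!is.null(cfg$vmm)) cfg$vmm <- unclass(cfg$vmm)
    cfg
  })
  out$edges <- lapply(out$edges, function(e) {
    if (!is.null(e$correlator) && !is.null(e$correlator$lambda))
      e$correlator$lambda <- unclass(e$correlator$lambda)
    e
  })
  out
}

.restore_sched <- function(s) {
  if (is.null(s)) return(NULL)
  if (is.numeric(s) && length(s) == 1) return(as.numeric(s))
  do.call(schedule, as.list(s))
}

.spec_from_plain <- function(plain) {
  units <- lapply(.as_plain_list(plain$units), function(cfg) {
    cfg <- as.list(cfg)
    for (f in .sched_fields_unit)
      if (!is.null(cfg[[f]])) cfg[[f]] <- .restore_sched(cfg[[f]])
    if (!is.null(cfg$vmm)) cfg$vmm <- do.call(vmm_params, as.list(cfg$vmm))
    if (!is.null(cfg$som)) cfg$som <- as.numeric(cfg$som)
    if (!is.null(cfg$rsom)) cfg$rsom <- as.numeric(cfg$rsom)
    cfg
  })
  edges <- lapply(.as_plain_list(plain$edges), function(e) {
    e <- as.list(e)
    if (!is.null(e$correlator)) {
      e$correlator <- as.list(e$correlator)
      e$correlator$lambda <- .restore_sched(e$correlator$lambda)
    }
    e
  })
  hierarchy_spec(units = units, edges = edges,
                 sensor_dim = as.integer(plain$sensor_dim),
                 n_actions = as.integer(plain$n_actions),
                 seed = as.integer(plain$seed),
                 alpha = as.numeric(plain$alpha),
                 r_max = as.numeric(plain$r_max))
}

# --- configuration ---------------------------------------------------------

#' Parse a run configuration file
#'
#' YAML configuration with keys `demo` (1..4, required), `iterations`,
#' `seed` (integer or `"random"`, which draws a seed and records it in the
#' returned config), `window`, `out_dir`, `mode`, `adaptive`. Unset keys
#' take the defaults of [run_demo()].
#'
#' @param path YAML file path.
#' @return a named list of run parameters.
#' @export
parse_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(iterations = 10000, seed = 1L, window = 500,
                   out_dir = NULL, mode = NULL, adaptive = TRUE)
  cfg <- utils::modifyList(defaults, cfg)
  if (is.null(cfg$demo) || !cfg$demo %in% 1:4)
    stop("parse_config: 'demo' must be one of 1, 2, 3, 4")
  if (identical(cfg$seed, "random")) {
    cfg$seed <- as.integer(Sys.time()) %% 1000000L
    message("parse_config: drew random seed ", cfg$seed)
  }
  stopifnot(cfg$window >= 1, cfg$iterations >= cfg$window)
  cfg
}

#' Run a rocks-paper-scissors trial with optional early stopping
#'
#' Plays the demo-4 hierarchy against the cycling opponent, optionally
#' stopping once the trailing moving-average reward first reaches
#' `stop_at` (checked once per `check_every` games). Early stopping can
#' only under-report the maximum attained average.
#'
#' @param seed master seed for the hierarchy.
#' @param max_games upper bound on the number of games.
#' @param window moving-average window.
#' @param adaptive `FALSE` disables the reward correlator (baseline).
#' @param stop_at optional moving-average reward threshold for early
#'   stopping.
#' @param check_every how often (in games) to test the threshold.
#' @return list with `reward` and `win` (per-game vectors), `ma`
#'   (trailing moving average of reward), `ma_max`, `ma_final`, and
#'   `games` (number actually played).
#' @export
rps_trial <- function(seed, max_games = 60000, window = 500,
                      adaptive = TRUE, stop_at = NULL, check_every = 1000) {
  h <- build_hierarchy(demo_spec(4, seed = seed, adaptive = adaptive))
  env <- rps_state(seed = (as.integer(seed) %% 2000000L) * 1000L + 999L)
  reward <- numeric(max_games)
  win <- numeric(max_games)
  obs <- glyph("blank")
  r <- 0.5
  played <- max_games
  for (t in seq_len(max_games)) {
    st <- hierarchy_step(h, obs, r)
    res <- rps_step(env, st$action)
    reward[t] <- res$reward
    win[t] <- as.numeric(res$reward == 1)
    obs <- res$image
    r <- res$reward
    if (!is.null(stop_at) && t >= window && t %% check_every == 0 &&
        mean(reward[(t - window + 1):t]) >= stop_at) {
      played <- t
      break
    }
  }
  reward <- reward[seq_len(played)]
  win <- win[seq_len(played)]
  ma <- moving_average(reward, window)
  list(reward = reward, win = win, ma = ma,
       ma_max = max(ma, na.rm = TRUE), ma_final = ma[played], games = played)
}
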