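#' Built-in demonstration configurations
#'
#' Four self-contained demonstrations exercise the system end to end:
#'
#' 1. **Drifting colours** — a single SOM + first-order predictor unit
#'    models a stochastic RGB drift process and predicts the next colour.
#' 2. **Moving lines** — a SOM-RSOM pair performs spatial and temporal
#'    pooling of horizontal-line, vertical-line and blank image sequences.
#' 3. **Words** — a SOM + RSOM unit with a variable-order predictor learns
#'    the words `dad`, `bab`, `mad`, `dam` presented as letter images and
#'    predicts the next letter; a first-order variant exists for
#'    comparison.
#' 4. **Rocks, paper, scissors** — two units joined by a reward correlator
#'    and a discrete actuator play against an opponent that cycles its
#'    gestures; with the correlator enabled the hierarchy learns to win.
#'
#' @param demo demo id in 1..4.
#' @param seed master seed.
#' @param mode predictor mode override for demo 3 (`"variable_order"`
#'   default, `"first_order"` for the comparison run).
#' @param adaptive for demo 4: `FALSE` removes the reward correlator
#'   (plain relay), giving the non-adaptive baseline.
#' @return a [hierarchy_spec()].
#' @export
demo_spec <- function(demo, seed = 1L, mode = NULL, adaptive = TRUE) {
  demo <- as.integer(demo)
  if (demo == 1L) {
    hierarchy_spec(
      units = list(list(som = c(8, 8), mode = "first_order",
                        learning_rate = schedule(0.25, 0.02, 2000),
                        radius = schedule(4, 0.5, 2000),
                        lambda_f = schedule(0.99, 0.01, 2000),
                        noise = schedule(1, 0.02, 2000))),
      sensor_dim = 3, n_actions = 0, seed = seed)
  } else if (demo == 2L) {
    hierarchy_spec(
      units = list(list(som = c(5, 5), rsom = c(3, 3), leak = 0.45,
                        mode = "first_order",
                        learning_rate = schedule(0.25, 0.02, 4000),
                        radius = schedule(2.5, 0.5, 4000),
                        rsom_radius = schedule(1.5, 0.3, 4000),
                        lambda_f = schedule(0.99, 0.01, 4000),
                        noise = schedule(1, 0.02, 4000),
                        bias_floor = 5)),
      sensor_dim = 16, n_actions = 0, seed = seed)
  } else if (demo == 3L) {
    if (is.null(mode)) mode <- "variable_order"
    hierarchy_spec(
      units = list(list(som = c(5, 5), rsom = c(3, 3), leak = 0.45,
                        mode = mode, smoothing = 0.3,
                        learning_rate = schedule(0.25, 0.02, 4000),
                        radius = schedule(2.5, 0.5, 4000),
                        rsom_radius = schedule(1.5, 0.3, 4000),
                        lambda_f = schedule(0.99, 0.05, 4000),
                        noise = schedule(1, 0.02, 4000),
                        vmm = vmm_params(excite_sigma = 0.5,
                                         sigmoid_gain = 10,
                                         strong_factor = 3))),
      sensor_dim = 25, n_actions = 0, seed = seed)
  } else if (demo == 4L) {
    correlator <- if (adaptive)
      list(theta = 1, lambda = schedule(0.3, 0.05, 50000), delay = 0L)
    bf <- schedule(0.2, 0.01, 15000)
    units <- list(
      list(som = c(5, 5), mode = "first_order",
           learning_rate = schedule(0.25, 0.05, 10000),
           radius = schedule(2.5, 0.3, 10000),
           lambda_f = schedule(0.99, 0.01, 10000),
           noise = schedule(1, 0.01, 10000), bias_floor = bf),
      list(som = c(4, 4), mode = "first_order",
           learning_rate = schedule(0.25, 0.05, 10000),
           radius = schedule(2, 0.3, 10000),
           lambda_f = schedule(0.99, 0.01, 10000),
           noise = schedule(1, 0.01, 10000, lag = 2000), bias_floor = bf))
    hierarchy_spec(
      units = units,
      edges = list(list(child = 1, parent = 2, correlator = correlator)),
      sensor_dim = 25, n_actions = 3, seed = seed, alpha = 0.5)
  } else stop("demo_spec: unknown demo id ", demo)
}

#' Probe a trained moving-lines hierarchy for its class mapping
#'
#' Presents canonical stimulus sequences to a trained hierarchy with
#' learning frozen — each probe is a full horizontal sweep, a full vertical
#' sweep, or a blank run, always preceded by a blank run long enough to
#' flush the temporal pooler's trace — and records the winning RSOM model
#' at the end of each sequence. A hierarchy that has pooled the stream
#' temporally maps the three sequence classes onto distinct models with
#' high within-class winner purity.
#'
#' @param h a trained demo-2 hierarchy (see [run_demo()]).
#' @param n_probe number of probe repetitions per class.
#' @return list with `winners` (per-class integer vectors), `modal`
#'   (per-class modal model), `n_distinct`, and `purity` (per-class modal
#'   fraction).
#' @export
moving_lines_probe <- function(h, n_probe = 25) {
  u <- h$units[[1]]
  old_learn <- u$learn
  u$learn <- FALSE
  on.exit(u$learn <- old_learn)
  size <- sqrt(h$spec$sensor_dim)
  stopifnot(size == round(size))
  run_seq <- function(frames) {
    w <- NA_integer_
    for (f in frames) {
      hierarchy_step(h, f, 0.5)
      w <- which.max(u$last_Y)
    }
    w
  }
  flush <- replicate(4, numeric(size^2), simplify = FALSE)
  sweep_frames <- function(orient)
    lapply(seq_len(size), function(k) .line_frame(size, orient, k))
  winners <- list(horizontal = integer(0), vertical = integer(0),
                  blank = integer(0))
  for (i in seq_len(n_probe)) {
    run_seq(flush)
    winners$horizontal <- c(winners$horizontal, run_seq(sweep_frames("h")))
    run_seq(flush)
    winners$vertical <- c(winners$vertical, run_seq(sweep_frames("v")))
    winners$blank <- c(winners$blank, run_seq(flush))
  }
  modal <- vapply(winners, function(w)
    as.integer(names(sort(table(w), decreasing = TRUE))[1]), 0L)
  purity <- vapply(winners, function(w) max(table(w)) / length(w), 0)
  list(winners = winners, modal = modal,
       n_distinct = length(unique(modal)), purity = purity)
}
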