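# Seeded generator environments for the four demonstrations. Every
# environment is an environment object holding its own RNG stream; replay
# with the same seed reproduces the identical observation stream.

#' Drifting-colour stochastic process
#'
#' Each RGB channel advances by a fixed per-channel bias plus Gaussian
#' noise and wraps at the unit boundaries, producing a slowly cycling
#' colour for the spatial pooler to model.
#'
#' @param bias per-channel drift added each step.
#' @param noise per-channel Gaussian noise standard deviation.
#' @param start initial colour.
#' @param seed RNG seed.
#' @return an environment of class `rgb_process`.
#' @export
rgb_process <- function(bias = c(0.03, 0.01, 0.02), noise = 0.01,
                        start = c(0.5, 0.5, 0.5), seed = 1L) {
  p <- new.env(parent = emptyenv())
  p$value <- start
  p$bias <- bias
  p$noise <- noise
  p$rng <- rng_handle(seed)
  class(p) <- "rgb_process"
  p
}

#' @rdname rgb_process
#' @param p an `rgb_process`.
#' @return `rgb_step`: the next colour 3-vector in `[0, 1)`.
#' @export
rgb_step <- function(p) {
  eps <- if (p$noise > 0) rng_rnorm(p$rng, 3, sd = p$noise) else numeric(3)
  p$value <- (p$value + p$bias + eps) %% 1
  p$value
}

# --- glyph bitmaps ---------------------------------------------------------

.glyph_rows <- function(...) as.numeric(unlist(lapply(list(...), function(s)
  as.integer(strsplit(s, "")[[1]]))))

.GLYPHS <- list(
  blank    = rep(0, 25),
  d        = .glyph_rows("00011", "00001", "01111", "01001", "01111"),
  a        = .glyph_rows("00000", "01110", "00010", "01110", "01011"),
  b        = .glyph_rows("01000", "01000", "01110", "01010", "01110"),
  m        = .glyph_rows("00000", "11011", "10101", "10101", "10101"),
  rock     = .glyph_rows("00000", "01110", "01110", "01110", "00000"),
  paper    = .glyph_rows("11111", "10001", "10001", "10001", "11111"),
  scissors = .glyph_rows("10001", "01010", "00100", "01010", "10001"))

#' Fixed 5x5 binary glyph bitmaps
#'
#' Letter glyphs (`d`, `a`, `b`, `m`, `blank`) for the word stream and
#' gesture glyphs (`rock`, `paper`, `scissors`) for the game environment,
#' as row-major 25-vectors in `{0, 1}`. The bitmaps are synthetic fixtures:
#' pairwise distinct, with the gesture set separated by Hamming distance of
#' at least 4.
#'
#' @param symbol one of `names(glyph_set())`.
#' @return a 25-element binary vector.
#' @export
glyph <- function(symbol) {
  g <- .GLYPHS[[symbol]]
  if (is.null(g)) stop("glyph: unknown symbol '", symbol, "'")
  g
}

#' @rdname glyph
#' @export
glyph_set <- function() .GLYPHS

#' Glyph image shape
#' @return `c(rows, cols)` of every glyph bitmap.
#' @export
glyph_dim <- function() c(5L, 5L)

# --- moving lines ----------------------------------------------------------

#' Moving-line image stream
#'
#' Emits three kinds of sequence on a `size x size` binary image: a
#' horizontal line sweeping top to bottom, a vertical line sweeping left to
#' right, and blank frames. Line sequences are drawn uniformly and are
#' interspersed with uniformly drawn runs of 1-4 blank frames.
#'
#' @param size image side length.
#' @param blank_max largest blank-run length.
#' @param seed RNG seed.
#' @return an environment of class `moving_lines`.
#' @export
moving_lines <- function(size = 4, blank_max = 4, seed = 1L) {
  e <- new.env(parent = emptyenv())
  e$size <- as.integer(size)
  e$blank_max <- as.integer(blank_max)
  e$rng <- rng_handle(seed)
  e$queue <- list()          # frames waiting to be emitted
  e$queue_class <- character(0)
  class(e) <- "moving_lines"
  e
}

.line_frame <- function(size, orient, k) {
  img <- matrix(0, size, size)
  if (orient == "h") img[k, ] <- 1 else img[, k] <- 1
  as.numeric(t(img))         # row-major
}

#' @rdname moving_lines
#' @param e a `moving_lines` environment.
#' @return `moving_lines_step`: list with `frame` (row-major image vector)
#'   and `class` (`"horizontal"`, `"vertical"` or `"blank"`), plus
#'   `seq_end` flagging the last frame of the current sequence.
#' @export
moving_lines_step <- function(e) {
  if (length(e$queue) == 0) {
    n_blank <- rng_int(e$rng, e$blank_max)
    blanks <- replicate(n_blank, numeric(e$size^2), simplify = FALSE)
    orient <- if (rng_int(e$rng, 2) == 1) "h" else "v"
    frames <- lapply(seq_len(e$size), function(k) .line_frame(e$size, orient, k))
    e$queue <- c(blanks, frames)
    e$queue_class <- c(rep("blank", n_blank),
                       rep(if (orient == "h") "horizontal" else "vertical",
                           e$size))
  }
  frame <- e$queue[[1]]
  cls <- e$queue_class[1]
  e$queue <- e$queue[-1]
  e$queue_class <- e$queue_class[-1]
  seq_end <- length(e$queue) == 0 || e$queue_class[1] != cls
  list(frame = frame, class = cls, seq_end = seq_end)
}

# --- word stream -----------------------------------------------------------

#' Letter-image word stream
#'
#' Emits the letters of words drawn uniformly from `dad`, `bab`, `mad`,
#' `dam` as 5x5 glyph bitmaps, with 1-3 blank images between words. The
#' duplicated letters across words make next-letter prediction a
#' variable-order problem: what follows an `a` depends on the word it
#' occurs in.
#'
#' @param words character vector of words over letters with glyphs.
#' @param blank_max largest between-word blank run.
#' @param seed RNG seed.
#' @return an environment of class `word_stream`.
#' @export
word_stream <- function(words = c("dad", "bab", "mad", "dam"),
                        blank_max = 3, seed = 1L) {
  e <- new.env(parent = emptyenv())
  e$words <- words
  e$blank_max <- as.integer(blank_max)
  e$rng <- rng_handle(seed)
  e$queue <- character(0)    # symbols waiting to be emitted
  e$word <- NA_character_
  class(e) <- "word_stream"
  e
}

#' @rdname word_stream
#' @param e a `word_stream` environment.
#' @return `words_step`: list with `image` (25-vector), `symbol` (letter or
#'   `"blank"`) and `word` (the word being emitted, `NA` on blanks).
#' @export
words_step <- function(e) {
  if (length(e$queue) == 0) {
    n_blank <- rng_int(e$rng, e$blank_max)
    w <- e$words[rng_int(e$rng, length(e$words))]
    e$queue <- c(rep("blank", n_blank), strsplit(w, "")[[1]])
    e$word <- w
  }
  sym <- e$queue[1]
  e$queue <- e$queue[-1]
  list(image = glyph(sym), symbol = sym,
       word = if (sym == "blank") NA_character_ else e$word)
}

# --- rocks, paper, scissors ------------------------------------------------

#' Cycling rocks-paper-scissors opponent
#'
#' The opponent cycles rock -> paper -> scissors in order, one gesture per
#' game. Actions are indexed 1 = rock, 2 = paper, 3 = scissors; rock beats
#' scissors, paper beats rock, scissors beats paper. Reward is 1 for an
#' agent win, 0.5 for a draw, 0 for a loss.
#'
#' @param phase initial opponent phase in `{1, 2, 3}`.
#' @param seed RNG seed (kept for interface symmetry; the cycling opponent
#'   draws nothing).
#' @return an environment of class `rps_state`.
#' @export
rps_state <- function(phase = 1L, seed = 1L) {
  e <- new.env(parent = emptyenv())
  e$phase <- as.integer(phase)
  e$rng <- rng_handle(seed)
  e$gestures <- c("rock", "paper", "scissors")
  e$last_agent <- NA_integer_
  e$last_opponent <- NA_integer_
  e$last_reward <- NA_real_
  class(e) <- "rps_state"
  e
}

#' @rdname rps_state
#' @param e an `rps_state` environment.
#' @param agent_move action index in `{1, 2, 3}`.
#' @return `rps_step`: list with `image` (the opponent's gesture bitmap for
#'   this game), `reward` (1 / 0.5 / 0), `opponent` (gesture index).
#' @export
rps_step <- function(e, agent_move) {
  if (!agent_move %in% 1:3) stop("rps_step: invalid move index")
  opp <- e$phase
  e$phase <- e$phase %% 3L + 1L
  reward <- if (agent_move == opp) 0.5
  else if ((agent_move - opp) %% 3 == 1) 1 else 0
  e$last_agent <- as.integer(agent_move)
  e$last_opponent <- opp
  e$last_reward <- reward
  list(image = glyph(e$gestures[opp]), reward = reward, opponent = opp)
}

#' Normalized prediction error between two interface vectors
#'
#' Euclidean distance divided by the maximum attainable distance for the
#' vector length (`sqrt(n)` for unit-range components), giving an error in
#' `[0, 1]`.
#'
#' @param predicted,actual equal-length vectors with components in `[0, 1]`.
#' @return scalar error in `[0, 1]`.
#' @export
prediction_error <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("prediction_error: length mismatch")
  sqrt(sum((predicted - actual)^2)) / sqrt(length(actual))
}
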