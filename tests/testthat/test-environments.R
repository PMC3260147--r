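# Seeded synthetic worlds and the prediction-error metric.

test_that("colour channels drift, wrap, and match their stated moments", {
  p <- rgb_process(bias = c(0.3, 0, 0), noise = 0, start = c(0.9, 0.5, 0.5))
  expect_equal(rgb_step(p), c(0.2, 0.5, 0.5), tolerance = 1e-12)  # wrap at 1
  p0 <- rgb_process(bias = c(0, 0, 0), noise = 0, start = c(0.3, 0.6, 0.9))
  for (i in 1:5) expect_equal(rgb_step(p0), c(0.3, 0.6, 0.9))
  # moment estimation on circular increments
  p1 <- rgb_process(bias = c(0.03, 0.01, 0.02), noise = 0.01, seed = 70)
  n <- 10000
  prev <- p1$value
  inc <- matrix(0, n, 3)
  for (i in 1:n) {
    v <- rgb_step(p1)
    d <- v - prev
    inc[i, ] <- ((d + 0.5) %% 1) - 0.5  # shortest circular increment
    prev <- v
  }
  expect_lt(max(abs(colMeans(inc) - c(0.03, 0.01, 0.02))), 0.001)
  expect_lt(max(abs(apply(inc, 2, stats::sd) - 0.01)), 0.002)
})

test_that("line sequences sweep the image once, frame by frame", {
  e <- moving_lines(size = 4, seed = 71)
  frames <- list(); classes <- character(0)
  for (i in 1:400) {
    s <- moving_lines_step(e)
    frames[[i]] <- s$frame
    classes[i] <- s$class
  }
  for (i in seq_along(frames)) {
    img <- matrix(frames[[i]], 4, 4, byrow = TRUE)
    rows_on <- sum(rowSums(img) == 4)
    cols_on <- sum(colSums(img) == 4)
    if (classes[i] == "blank") expect_equal(sum(img), 0)
    if (classes[i] == "horizontal") expect_equal(c(rows_on, sum(img)), c(1, 4))
    if (classes[i] == "vertical") expect_equal(c(cols_on, sum(img)), c(1, 4))
  }
  # each line sequence is exactly 4 frames sweeping in order
  r <- rle(classes)
  full <- seq_len(length(r$lengths) - 1)  # last run may be truncated
  expect_true(all(r$lengths[full][r$values[full] != "blank"] == 4))
  h_runs <- which(r$values == "horizontal")
  start <- cumsum(c(1, r$lengths))[h_runs[1]]
  rows_hit <- vapply(0:3, function(k)
    which(rowSums(matrix(frames[[start + k]], 4, 4, byrow = TRUE)) == 4), 0L)
  expect_equal(rows_hit, 1:4)  # top to bottom
  expect_true(all(r$lengths[r$values == "blank"] <= 4))
})

test_that("the two line orientations occur equally often in the long run", {
  e <- moving_lines(size = 4, seed = 72)
  kinds <- character(0)
  for (i in 1:15000) {
    s <- moving_lines_step(e)
    if (s$class != "blank" && s$seq_end) kinds <- c(kinds, s$class)
  }
  n <- length(kinds)
  expect_lt(abs(mean(kinds == "horizontal") - 0.5), 3 * sqrt(0.25 / n))
})

test_that("words are spelled letter by letter with blank gaps between", {
  e <- word_stream(words = "dad", seed = 73)
  syms <- vapply(1:40, function(i) words_step(e)$symbol, "")
  runs <- rle(syms == "blank")
  # every non-blank run is a full 3-letter word preceded by >= 1 blank
  full <- seq_len(length(runs$lengths) - 1)  # last run may be truncated
  expect_true(all(runs$lengths[full][!runs$values[full]] == 3))
  first_word <- which(syms != "blank")[1:3]
  expect_equal(syms[first_word], c("d", "a", "d"))
  img <- words_step(e)
  expect_true(all(img$image %in% c(0, 1)))
})

test_that("the four words are drawn uniformly", {
  e <- word_stream(seed = 74)
  counts <- integer(4)
  names(counts) <- e$words
  n_words <- 0
  while (n_words < 4000) {
    s <- words_step(e)
    if (s$symbol != "blank" && length(e$queue) == 0) {  # word just finished
      counts[s$word] <- counts[s$word] + 1
      n_words <- n_words + 1
    }
  }
  freq <- counts / n_words
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / n_words)))
})

test_that("the payoff table follows rock-paper-scissors with 0.5 draws", {
  e <- rps_state(phase = 1)
  expect_equal(rps_step(e, 2)$reward, 1)    # paper beats rock
  expect_equal(rps_step(e, 2)$reward, 0.5)  # paper vs paper: draw
  expect_equal(rps_step(e, 2)$reward, 0)    # paper loses to scissors
  # opponent cycles in order
  e2 <- rps_state(phase = 1)
  opp <- vapply(1:6, function(i) rps_step(e2, 1)$opponent, 0L)
  expect_equal(opp, c(1L, 2L, 3L, 1L, 2L, 3L))
  # antisymmetry of the payoff around 0.5
  for (a in 1:3) for (o in 1:3) {
    ea <- rps_state(phase = o); eo <- rps_state(phase = a)
    expect_equal(rps_step(ea, a)$reward, 1 - rps_step(eo, o)$reward)
  }
  expect_error(rps_step(e, 4), "invalid move")
})

test_that("a uniformly random agent earns mean reward one half", {
  e <- rps_state(phase = 1)
  rng <- rng_handle(75)
  rewards <- vapply(1:10000, function(i)
    rps_step(e, rng_int(rng, 3))$reward, 0)
  expect_lt(abs(mean(rewards) - 0.5), 3 * sqrt(1 / 6 / 10000))
})

test_that("glyphs are distinct binary bitmaps with separable gestures", {
  expect_equal(glyph("blank"), rep(0, 25))
  expect_false(all(glyph("d") == glyph("b")))
  gs <- glyph_set()
  expect_true(all(vapply(gs, function(g) all(g %in% c(0, 1)), TRUE)))
  nm <- names(gs)
  for (i in seq_along(gs)) for (j in seq_along(gs)) {
    if (i < j) expect_gt(sum(gs[[i]] != gs[[j]]), 0)
  }
  gest <- c("rock", "paper", "scissors")
  for (i in 1:2) for (j in (i + 1):3) {
    expect_gte(sum(glyph(gest[i]) != glyph(gest[j])), 4)
  }
  expect_error(glyph("zebra"), "unknown symbol")
})

test_that("prediction error is the normalized Euclidean distance", {
  expect_equal(prediction_error(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(prediction_error(rep(0, 9), rep(1, 9)), 1)
  expect_equal(prediction_error(c(1, 0, 0, 0), c(0, 0, 0, 0)), 0.5)
  expect_error(prediction_error(1:3 / 3, 1:4 / 4), "length mismatch")
})
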