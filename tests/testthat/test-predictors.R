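# First-order transition learning and the variable-order extension.

onehot <- function(i, m) { v <- numeric(m); v[i] <- 1; v }

test_that("transition updates need both exit and entry evidence", {
  tm <- transition_model(4)
  F0 <- tm$F
  p <- c(0.25, 0.25, 0.25, 0.25)
  update_transitions(tm, p, p, lambda = 0.5)   # nothing moved
  expect_equal(tm$F, F0, tolerance = 1e-12)
  update_transitions(tm, onehot(1, 4), onehot(2, 4), lambda = 0)
  expect_equal(tm$F, F0, tolerance = 1e-12)    # zero learning rate
  expect_error(update_transitions(tm, p, c(0.5, 0.5)), "size mismatch")
})

test_that("alternating one-hot stream drives its transitions to 1", {
  tm <- transition_model(4, learning_rate = schedule(0.99, 0.01, 500))
  a <- onehot(1, 4); b <- onehot(3, 4)
  for (i in 1:1000) {
    if (i %% 2 == 1) update_transitions(tm, a, b)
    else update_transitions(tm, b, a)
  }
  expect_gt(tm$F[3, 1], 0.95)  # F[B|A]
  expect_gt(tm$F[1, 3], 0.95)  # F[A|B]
})

test_that("columns stay stochastic and non-negative under random updates", {
  tm <- transition_model(6)
  rng <- rng_handle(20)
  for (i in 1:1000) {
    p1 <- normalize_mass(rng_runif(rng, 6))
    p2 <- normalize_mass(rng_runif(rng, 6))
    update_transitions(tm, p1, p2, lambda = rng_runif(rng, 1))
    expect_true(all(tm$F >= 0))
    expect_equal(colSums(tm$F), rep(1, 6), tolerance = 1e-9)
  }
})

test_that("a deterministic cycle is recovered as a permutation matrix", {
  m <- 4
  tm <- transition_model(m, learning_rate = schedule(0.99, 0.01, 500))
  cyc <- c(2L, 3L, 4L, 1L)  # successor of each state
  state <- 1L
  for (i in 1:2000) {
    nxt <- cyc[state]
    update_transitions(tm, onehot(state, m), onehot(nxt, m))
    state <- nxt
  }
  P <- matrix(0, m, m)
  for (i in 1:m) P[cyc[i], i] <- 1
  expect_true(all(abs(tm$F - P) < 0.05))
})

test_that("first-order prediction equals the normalized matrix product", {
  tm <- transition_model(3)
  tm$F <- diag(3)
  expect_equal(predict_first_order(tm, onehot(2, 3)), onehot(2, 3))
  tm$F <- matrix(c(0, 1, 0,  0, 0, 1,  1, 0, 0), nrow = 3)  # 3-cycle
  expect_equal(predict_first_order(tm, onehot(1, 3)), onehot(2, 3))
  # exhaustive-summation oracle on an arbitrary stochastic matrix
  rng <- rng_handle(21)
  Fm <- apply(matrix(rng_runif(rng, 9), 3), 2, function(col) col / sum(col))
  tm$F <- Fm
  p <- normalize_mass(rng_runif(rng, 3))
  expected <- numeric(3)
  for (j in 1:3) for (i in 1:3) expected[j] <- expected[j] + Fm[j, i] * p[i]
  expected <- expected / sum(expected)
  expect_equal(predict_first_order(tm, p), expected, tolerance = 1e-12)
})

test_that("DoG preprocessing sharpens around the maximum", {
  params <- vmm_params(excite_sigma = 0.5, dog_gain = 2, sigmoid_gain = 10)
  p1 <- onehot(5, 9)
  expect_equal(which.max(vmm_preprocess(p1, 3, 3, params)), 5)
  expect_equal(sum(vmm_preprocess(p1, 3, 3, params)), 1, tolerance = 1e-9)
  # uniform input: winner at the tie-broken argmax (flat index 1, cell 0,0);
  # direct evaluation of the kernel product as oracle
  pu <- rep(1 / 9, 9)
  out <- vmm_preprocess(pu, 3, 3, params)
  coords <- expand.grid(c = 0:2, r = 0:2)[, c("r", "c")]
  d2 <- (coords$r - 0)^2 + (coords$c - 0)^2
  k <- exp(-d2 / (2 * 0.5^2)) - 0.5 * exp(-d2 / (2 * 1^2))
  k <- (k - min(k)) / (max(k) - min(k))
  expect_equal(out, (pu * k) / sum(pu * k), tolerance = 1e-12)
  expect_equal(which.max(out), 1)
  ring <- c(2, 4, 5)            # immediate neighbours of cell (0,0)
  far <- c(3, 7, 9)
  expect_true(max(out[ring]) < min(out[far]))  # surround suppressed
})

test_that("unpredicted-prior inhibition fires only on strong unseen priors", {
  m <- 9
  params <- vmm_params(excite_sigma = 0.6, sigmoid_gain = 10)
  tm <- transition_model(m)     # uniform F: no strong edges
  p <- normalize_mass(1:9)
  res <- vmm_inhibit_unpredicted(p, tm, onehot(1, m), params)
  expect_equal(res$p, p)
  expect_equal(res$lost, numeric(m))
  # strong edge 1 -> 5 with prior 1 active: element 5 not inhibited
  tm$F[, 1] <- c(0.05, 0.05, 0.05, 0.05, 0.6, 0.05, 0.05, 0.05, 0.05)
  act <- vmm_inhibit_unpredicted(p, tm, onehot(1, m), params)
  expect_equal(act$p[5], p[5], tolerance = 1e-9)
  # same edge with prior 1 inactive: element 5 strictly inhibited
  inact <- vmm_inhibit_unpredicted(p, tm, onehot(2, m), params)
  expect_lt(inact$p[5], p[5])
  expect_equal(inact$lost[5], p[5] - inact$p[5])
  expect_gt(inact$lost[5], 0)
  expect_true(all(inact$lost >= 0))
})

test_that("neighbour promotion reallocates lost mass topologically", {
  params <- vmm_params(excite_sigma = 0.6)
  p <- rep(1 / 9, 9)
  expect_equal(vmm_promote_neighbours(p, numeric(9), 3, 3, params), p)
  # all loss at centre cell (1,1) = flat index 5
  lost <- numeric(9); lost[5] <- 0.3
  p_inh <- normalize_mass(replace(p, 5, 0))
  out <- vmm_promote_neighbours(p_inh, lost, 3, 3, params)
  expect_equal(sum(out), 1, tolerance = 1e-9)
  # direct kernel evaluation: promotion peaks on the centre's neighbours
  kern <- function(d2) exp(-d2 / (2 * 1.2^2)) - exp(-d2 / (2 * 0.6^2))
  promo <- vapply(1:9, function(j) {
    rj <- (j - 1) %/% 3; cj <- (j - 1) %% 3
    kern((rj - 1)^2 + (cj - 1)^2) * 0.3
  }, 0)
  expect_equal(promo[5], 0)                     # not the cell itself
  ring <- c(2, 4, 6, 8)
  expect_true(min(promo[ring]) > max(promo[c(1, 3, 7, 9)]) - 1e-12 ||
                all(promo[ring] >= max(promo[-c(ring, 5)])))
  gain <- out - p_inh / sum(p_inh)
  expect_true(which.max(gain) %in% ring)
})

test_that("neutral parameters reduce the variable-order pipeline to first order", {
  m <- 9
  tm <- transition_model(m)
  rng <- rng_handle(22)
  tm$F <- apply(matrix(rng_runif(rng, m * m), m), 2, function(cl) cl / sum(cl))
  neutral <- vmm_params(excite_sigma = Inf, inhibit_sigma = Inf,
                        sigmoid_gain = 0)
  p <- normalize_mass(rng_runif(rng, m))
  expect_equal(predict_next(tm, "variable_order", p, 3, 3, neutral),
               predict_first_order(tm, p), tolerance = 1e-12)
  expect_equal(predict_next(tm, "first_order", p),
               predict_first_order(tm, p))
})

test_that("variable-order prediction always returns a mass function", {
  m <- 9
  tm <- transition_model(m, learning_rate = 0.3)
  params <- vmm_params(excite_sigma = 0.6, sigmoid_gain = 10)
  rng <- rng_handle(23)
  prev <- normalize_mass(rng_runif(rng, m))
  for (i in 1:200) {
    p <- normalize_mass(rng_runif(rng, m))
    update_transitions(tm, prev, p)
    out <- predict_next(tm, "variable_order", p, 3, 3, params)
    expect_equal(sum(out), 1, tolerance = 1e-9)
    expect_true(all(out >= 0))
    prev <- p
  }
})

test_that("vmm parameter constraints are enforced", {
  expect_error(vmm_params(excite_sigma = 1, dog_gain = 1), "dog_gain")
  expect_error(vmm_params(excite_sigma = 2, inhibit_sigma = 1), "inhibit_sigma")
  p <- vmm_params(excite_sigma = 1)
  expect_gt(p$inhibit_sigma, p$excite_sigma)
})
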