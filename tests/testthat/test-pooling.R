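# Spatial (SOM) and temporal (RSOM) pooling.

make_grid <- function(rows, cols, dim, seed = 1, ...) {
  som_grid(rows, cols, dim, rng_handle(seed), ...)
}

test_that("SOM activation is the inverse normalized squared error", {
  g <- make_grid(1, 2, 1)
  g$W <- matrix(c(0, 1), nrow = 2)
  a <- activate_som(g, 0.25)
  # direct evaluation: e = (0.0625, 0.5625); a_i ~ 1/(e_i/sum(e))
  expect_equal(a, c(0.9, 0.1), tolerance = 1e-9)
  expect_gt(a[1], a[2])  # closer model carries the larger value
})

test_that("SOM activation handles exact matches and degenerate grids", {
  g <- make_grid(2, 2, 3, seed = 2)
  x <- g$W[1, ]
  a <- activate_som(g, x)
  expect_equal(which.max(a), 1)       # zero-error cell dominates
  expect_true(all(a > 0))             # strictly positive everywhere
  g$W <- matrix(0.4, nrow = 4, ncol = 3)
  expect_equal(activate_som(g, c(0.1, 0.2, 0.3)), rep(0.25, 4))
  expect_error(activate_som(g, c(0.1, 0.2)), "input length")
})

test_that("SOM activation is a mass function and permutation-equivariant", {
  g <- make_grid(3, 3, 4, seed = 3)
  x <- c(0.2, 0.8, 0.5, 0.1)
  a <- activate_som(g, x)
  expect_equal(sum(a), 1, tolerance = 1e-9)
  perm <- sample(9)
  g2 <- make_grid(3, 3, 4, seed = 3)
  g2$W <- g$W[perm, ]
  expect_equal(activate_som(g2, x), a[perm], tolerance = 1e-12)
  # frozen weights: activation depends only on the current input
  expect_identical(activate_som(g, x), a)
})

test_that("Kohonen update matches a brute-force cell-by-cell oracle", {
  g <- make_grid(2, 2, 3, seed = 4)
  W0 <- g$W
  x <- c(0.9, 0.1, 0.6)
  winner <- 2L
  update_som(g, x, winner, lr = 0.5, radius = 1.0)
  # independent oracle: explicit loop over cells and components
  coords <- list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))  # row-major
  expected <- W0
  for (i in 1:4) {
    d2 <- sum((coords[[i]] - coords[[winner]])^2)
    hh <- exp(-d2 / (2 * 1.0^2))
    for (k in 1:3) {
      w <- W0[i, k] + 0.5 * hh * (x[k] - W0[i, k])
      expected[i, k] <- min(1, max(0, w))
    }
  }
  expect_equal(g$W, expected, tolerance = 1e-12)
})

test_that("Kohonen update limit cases: zero step, vanishing neighbourhood", {
  g <- make_grid(3, 3, 2, seed = 5)
  W0 <- g$W
  update_som(g, c(0.5, 0.5), 5L, lr = 0, radius = 1)
  expect_identical(g$W, W0)
  update_som(g, c(0.5, 0.5), 5L, lr = 0.5, radius = 1e-15)
  expect_equal(g$W[-5, ], W0[-5, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(g$W[5, ], W0[5, ])))
  d0 <- sum((W0[5, ] - c(0.5, 0.5))^2)
  expect_lt(sum((g$W[5, ] - c(0.5, 0.5))^2), d0)  # winner moves closer
  expect_error(update_som(g, c(0.5, 0.5), 5L, lr = 1.5, radius = 1),
               "learning rate")
})

test_that("weights stay in [0, 1] under sustained random updates", {
  g <- make_grid(3, 3, 4, seed = 6, learning_rate = 0.8, radius = 1.5)
  rng <- rng_handle(7)
  for (i in 1:2000) {
    x <- rng_runif(rng, 4)
    update_som(g, x, rng_int(rng, 9))
  }
  expect_true(all(g$W >= 0 & g$W <= 1))
})

test_that("orthogonalization is one-hot with lowest-flat-index tie-break", {
  expect_equal(orthogonalize(c(0, 0, 1, 0)), c(0, 0, 1, 0))  # idempotent
  d <- c(0.1, 0.2, 0.7, 0.2, 0.1, 0.3)  # unique max at flat index 3
  expect_equal(orthogonalize(d), c(0, 0, 1, 0, 0, 0))
  tied <- c(0.1, 0.5, 0.2, 0.5, 0.1)    # tie at flat indices 2 and 4
  expect_equal(orthogonalize(tied), c(0, 1, 0, 0, 0))
  expect_error(orthogonalize(c(0, 0, 0)), "positive")
})

test_that("RSOM with leak 1 is extensionally a SOM on the same stream", {
  g1 <- make_grid(2, 2, 5, seed = 8)
  g2 <- make_grid(2, 2, 5, seed = 8)
  s <- rsom_state(g2, leak = 1)
  rng <- rng_handle(9)
  for (i in 1:50) {
    oh <- numeric(5); oh[rng_int(rng, 5)] <- 1
    expect_equal(activate_rsom(s, oh), activate_som(g1, oh),
                 tolerance = 1e-12)
  }
})

test_that("leaky integration converges geometrically to a repeated input", {
  g <- make_grid(2, 2, 4, seed = 10)
  s <- rsom_state(g, leak = 0.3)
  oh <- c(0, 1, 0, 0)
  for (n in 1:40) {
    activate_rsom(s, oh)
    # closed form: after n blends of the same input, 1 - (1 - leak)^n
    expect_equal(s$integrated[2], 1 - 0.7^n, tolerance = 1e-12)
  }
  # fixed point: winner stable across further iterations after convergence
  w1 <- which.max(activate_rsom(s, oh))
  w2 <- which.max(activate_rsom(s, oh))
  expect_identical(w1, w2)
  expect_error(activate_rsom(s, c(0.5, 0.5, 0, 0)), "one-hot")
})

test_that("RSOM training separates disjoint repeating one-hot sequences", {
  g <- make_grid(2, 2, 6, seed = 11,
                 learning_rate = schedule(0.3, 0.05, 400),
                 radius = schedule(1, 0.2, 400))
  s <- rsom_state(g, leak = 0.5)
  seqs <- list(c(1L, 2L), c(3L, 4L), c(5L, 6L))
  rng <- rng_handle(12)
  present <- function(idx, learn = TRUE) {
    w <- NA_integer_
    for (rep in 1:4) for (k in seqs[[idx]]) {
      oh <- numeric(6); oh[k] <- 1
      y <- activate_rsom(s, oh)
      w <- which.max(y)
      if (learn) update_rsom(s, w)
    }
    w
  }
  for (i in 1:300) present(rng_int(rng, 3))
  winners <- vapply(1:3, present, 0L, learn = FALSE)
  expect_gte(length(unique(winners)), 3)
})

test_that("RSOM update decimation skips learning but not integration", {
  g <- make_grid(2, 2, 4, seed = 13)
  s <- rsom_state(g, leak = 0.4, update_every = 2L)
  W0 <- g$W
  activate_rsom(s, c(1, 0, 0, 0))
  update_rsom(s, 1L)              # tick 1: skipped
  expect_identical(g$W, W0)
  activate_rsom(s, c(1, 0, 0, 0)) # trace still advanced
  update_rsom(s, 1L)              # tick 2: applied
  expect_false(identical(g$W, W0))
})
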