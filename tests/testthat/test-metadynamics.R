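kBT300 <- 0.0083144621 * 300

test_that("bias evaluation: sum of Gaussians, hand value, gradient", {
  empty <- metad_bias(data.frame(center = numeric(0), height = numeric(0),
                                 width = numeric(0), step = integer(0)),
                      bias_factor = 10, pace = 1000)
  expect_equal(bias_value(empty, c(-1, 0, 2)), c(0, 0, 0))
  one <- metad_bias(data.frame(center = 0.5, height = 10, width = 0.3,
                               step = 0L), 10, 1000)
  expect_equal(bias_value(one, 0.5), 10)
  # hand evaluation: s - c = w -> h * exp(-1/2)
  expect_equal(bias_value(one, 0.8), 10 * exp(-0.5), tolerance = 1e-12)
  # gradient matches central finite differences to 1e-6 relative
  hills <- data.frame(center = c(-0.4, 0.2, 1.1), height = c(9, 5, 2),
                      width = 0.3, step = c(0L, 1000L, 2000L))
  b <- metad_bias(hills, 10, 1000)
  s <- seq(-1, 1.5, by = 0.25)
  h <- 1e-6
  fd <- (bias_value(b, s + h) - bias_value(b, s - h)) / (2 * h)
  expect_equal(bias_gradient(b, s), fd, tolerance = 1e-6)
  # periodic CV: minimum-image distance
  per <- metad_bias(data.frame(center = pi - 0.1, height = 10, width = 0.3,
                               step = 0L), 10, 1000, periodic = TRUE)
  expect_equal(bias_value(per, -pi + 0.1),
               10 * exp(-0.5 * (0.2 / 0.3)^2), tolerance = 1e-9)
  expect_error(metad_bias(hills, bias_factor = 1, pace = 1000), "bias_factor")
})

test_that("well-tempered deposition: first hill exact, heights temper", {
  run <- run_wt_metad(list(kind = "harmonic", k = 20), n_steps = 2e5,
                      height0 = 10, width = 0.3, pace = 1000,
                      bias_factor = 10, seed = 2)
  h <- run$bias$hills$height
  expect_equal(h[1], 10.0)  # V = 0 at the first deposit
  # tempering in a single well: late hills are much smaller than early ones
  expect_lt(mean(tail(h, 20)), 0.5 * mean(head(h, 5)))
  # the height rule is h0 * exp(-V/(kB dT)) at deposit time: recompute the
  # last hill from the preceding history
  hh <- run$bias$hills
  prev <- metad_bias(hh[-nrow(hh), ], 10, 1000)
  v_at <- bias_value(prev, hh$center[nrow(hh)])
  expect_equal(hh$height[nrow(hh)],
               10 * exp(-v_at / (0.0083144621 * 9 * 300)), tolerance = 1e-9)
  # gamma -> infinity: ordinary metadynamics, heights constant
  big <- run_wt_metad(list(kind = "harmonic", k = 20), n_steps = 5e4,
                      height0 = 10, width = 0.3, pace = 1000,
                      bias_factor = 1e12, seed = 2)
  expect_lt(abs(big$bias$hills$height[1] -
                  tail(big$bias$hills$height, 1)), 1e-3)
})

test_that("zero-height bias reproduces the unbiased stream exactly", {
  biased0 <- run_wt_metad(list(kind = "double_well", barrier_height = 8),
                          n_steps = 5e3, height0 = 0, width = 0.3,
                          pace = 1000, bias_factor = 10, friction = 1,
                          seed = 14, sample_every = 1L)
  unb <- gen_double_well(8, n_steps = 5e3, friction = 1, seed = 14)
  expect_equal(biased0$traj$data[, 1], unb$traj$data[, 1], tolerance = 1e-12)
  expect_equal(nrow(biased0$bias$hills), 0L)
})

test_that("bias drives barrier crossings the unbiased run cannot make", {
  h6 <- 6 * kBT300  # 6 kBT barrier
  # friction and run length put the spontaneous Kramers rate well below one
  # event per run; the matched-seed unbiased control is the oracle
  unb <- gen_double_well(h6, n_steps = 5e4, friction = 10, dt = 0.005,
                         seed = 7)
  xu <- unb$traj$data[, 1]
  crossings <- function(x) {
    s <- x[abs(x) > 0.5] > 0  # transitions between the two deep basins
    sum(diff(s) != 0)
  }
  biased <- run_wt_metad(list(kind = "double_well", barrier_height = h6),
                         n_steps = 5e4, height0 = 10, width = 0.3,
                         pace = 1000, bias_factor = 10, friction = 10,
                         dt = 0.005, seed = 7, sample_every = 1L)
  xb <- biased$traj$data[, 1]
  expect_equal(crossings(xu), 0)
  expect_gte(crossings(xb), 10)
})

test_that("free-energy estimator: single hill shape and harmonic curvature", {
  one <- metad_bias(data.frame(center = 0, height = 5, width = 0.3,
                               step = 0L), 10, 1000)
  grid <- seq(-1, 1, length.out = 101)
  fe <- estimate_free_energy(one, grid)
  expect_equal(min(fe$F), 0)
  # inverted scaled Gaussian: min at the hill center
  expect_equal(fe$s[which.min(fe$F)], 0)
  scaled <- (10 / 9) * (5 - 5 * exp(-0.5 * grid^2 / 0.09))
  expect_equal(fe$F, scaled, tolerance = 1e-9)

  # harmonic well: recovered curvature within 15%. The estimate is smoothed
  # over the hill width, so the width must be small against the thermal
  # width of the well (kw^2/kBT << 1) for the curvature to be unbiased.
  k_true <- 20
  run <- run_wt_metad(list(kind = "harmonic", k = k_true), n_steps = 4e5,
                      height0 = 2, width = 0.1, pace = 500,
                      bias_factor = 10, seed = 3)
  g <- seq(-0.6, 0.6, length.out = 61)
  fe_h <- estimate_free_energy(run$bias, g)
  fit <- lm(fe_h$F ~ I(g^2))
  expect_lt(abs(2 * coef(fit)[2] - k_true) / k_true, 0.15)
  expect_error(estimate_free_energy(metad_bias(
    data.frame(center = numeric(0), height = numeric(0),
               width = numeric(0), step = integer(0)), 10, 1000), grid),
    "no hills")
})

test_that("bias-exchange acceptance matches the Metropolis ratio", {
  mk <- function(center, height) {
    metad_bias(data.frame(center = center, height = height, width = 0.3,
                          step = 0L), 10, 1000)
  }
  # identical biases: delta = 0, always accepted
  reps <- list(list(state = -1, bias = mk(0, 5)),
               list(state = 1, bias = mk(0, 5)))
  set.seed(1)
  out <- bias_exchange_step(reps, temperature = 300)
  expect_equal(out$p_accept, 1)
  expect_true(out$accepted)
  expect_equal(out$replicas[[1]]$state, 1)  # swap applied
  # zero-bias replicas always accept
  empty <- metad_bias(data.frame(center = numeric(0), height = numeric(0),
                                 width = numeric(0), step = integer(0)),
                      10, 1000)
  out0 <- bias_exchange_step(list(list(state = 0, bias = empty),
                                  list(state = 2, bias = empty)))
  expect_equal(out0$p_accept, 1)
  # hand-computed ratio for asymmetric biases
  b1 <- mk(0, 6); b2 <- mk(1, 3)
  x1 <- 0.2; x2 <- 0.9
  delta <- (bias_value(b1, x2) + bias_value(b2, x1)) -
    (bias_value(b1, x1) + bias_value(b2, x2))
  p_hand <- min(1, exp(-delta / kBT300))
  set.seed(2)
  out2 <- bias_exchange_step(list(list(state = x1, bias = b1),
                                  list(state = x2, bias = b2)), 300)
  expect_equal(out2$p_accept, p_hand, tolerance = 1e-12)
  expect_error(bias_exchange_step(list(list(state = 0, bias = empty))),
               "2 replicas")
})

test_that("HILLS-style files round-trip", {
  run <- run_wt_metad(list(kind = "harmonic", k = 20), n_steps = 2e4,
                      height0 = 10, width = 0.3, pace = 1000,
                      bias_factor = 10, seed = 4)
  path <- withr::local_tempfile(fileext = ".txt")
  write_hills(run$bias, path, dt = 0.01)
  back <- read_hills(path, pace = 1000L, dt = 0.01)
  expect_equal(back$hills$center, run$bias$hills$center, tolerance = 1e-8)
  expect_equal(back$hills$height, run$bias$hills$height, tolerance = 1e-8)
  expect_equal(back$bias_factor, 10)
})
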