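test_that("Brownian paths are seeded with N(0, dt) increments", {
  a <- generate_brownian_path(64, 1, seed = 9)
  b <- generate_brownian_path(64, 1, seed = 9)
  expect_identical(a$increments, b$increments)
  expect_equal(length(a$times), 65L)
  expect_equal(a$dt, 1 / 64)

  big <- generate_brownian_path(1e5, 1, seed = 2)
  dt <- big$dt
  se_mean <- sqrt(dt / 1e5)
  expect_lt(abs(mean(big$increments)), 4 * se_mean)
  expect_lt(abs(var(big$increments) / dt - 1), 0.05)
})

test_that("Brownian refinement preserves the coarse path exactly", {
  bp <- generate_brownian_path(16, 2, seed = 31)
  fine <- refine_brownian_path(bp)
  finer <- refine_brownian_path(fine)
  expect_equal(fine$dt, bp$dt / 2)
  expect_equal(colSums(matrix(fine$increments, nrow = 2)), bp$increments)
  expect_equal(colSums(matrix(finer$increments, nrow = 4)), bp$increments)
  # refinement is itself deterministic
  expect_identical(refine_brownian_path(bp)$increments, fine$increments)
})

test_that("exact solution reduces to the drift exponential and stays positive", {
  bp <- generate_brownian_path(8, 1, seed = 1)
  # noise-free exponential growth: X_T = e
  p <- sde_params(force = 1, drag = 1, D = 0, x0 = 1, horizon = 1, n_steps = 8)
  expect_equal(exact_solution(p, bp)$positions[9], exp(1), tolerance = 1e-15)
  # no force, no noise: constant path
  p0 <- sde_params(force = 0, drag = 2, D = 0, x0 = 3, horizon = 1, n_steps = 8)
  expect_equal(exact_solution(p0, bp)$positions, rep(3, 9))
  # positivity under noise
  pn <- sde_params(force = 0.5, drag = 1, D = 2, x0 = 0.1, horizon = 1,
                   n_steps = 8)
  expect_true(all(exact_solution(pn, bp)$positions > 0))
})

test_that("terminal law matches the lognormal identities", {
  p <- sde_params(force = 0.5, drag = 1, D = 0.5, x0 = 1, horizon = 1)
  xt <- sample_terminal_positions(p, 1e4, seed = 3)
  se <- sd(xt) / sqrt(length(xt))
  expect_lt(abs(mean(xt) - exp(0.5)), 3 * se)

  lx <- log(xt)
  m <- (p$mu - p$D / 2) * p$horizon
  v <- p$D * p$horizon
  expect_lt(abs(mean(lx) - m), 3 * sqrt(v / length(lx)))
  expect_lt(abs(var(lx) - v), 3 * v * sqrt(2 / (length(lx) - 1)))
  expect_gt(ks.test(lx, "pnorm", mean = m, sd = sqrt(v))$p.value, 0.01)
})

test_that("Euler-Maruyama takes the explicit step and converges for D = 0", {
  # single deterministic step: 1 + 1*1 = 2
  p1 <- sde_params(force = 1, drag = 1, D = 0, x0 = 1, horizon = 1, n_steps = 1)
  expect_equal(euler_maruyama(p1, generate_brownian_path(1, 1, 4))$positions[2], 2)

  # deterministic Euler error shrinks like dt
  errs <- vapply(c(16L, 64L, 256L), function(n) {
    p <- sde_params(force = 1, drag = 1, D = 0, x0 = 1, horizon = 1, n_steps = n)
    abs(euler_maruyama(p, generate_brownian_path(n, 1, 4))$positions[n + 1] - exp(1))
  }, numeric(1))
  ratios <- errs[-3] / errs[-1]
  expect_true(all(ratios > 3 & ratios < 5)) # ~4x per 4x step refinement

  # F = 0, D = 0: constant path
  p0 <- sde_params(force = 0, drag = 1, D = 0, x0 = 2, horizon = 1, n_steps = 16)
  expect_equal(euler_maruyama(p0, generate_brownian_path(16, 1, 4))$positions,
               rep(2, 17))
})

test_that("with D = 0 both solvers ignore the Brownian path", {
  p <- sde_params(force = 0.7, drag = 1, D = 0, x0 = 1, horizon = 1, n_steps = 32)
  b1 <- generate_brownian_path(32, 1, seed = 1)
  b2 <- generate_brownian_path(32, 1, seed = 999)
  expect_identical(exact_solution(p, b1)$positions,
                   exact_solution(p, b2)$positions)
  expect_identical(euler_maruyama(p, b1)$positions,
                   euler_maruyama(p, b2)$positions)
})

test_that("the overflow guard aborts unstable integrations", {
  p <- sde_params(force = 1e6, drag = 1, D = 0, x0 = 1, horizon = 10, n_steps = 5)
  expect_error(euler_maruyama(p, generate_brownian_path(5, 10, 1)),
               "overflow")
})

test_that("strong error decays with order about one half", {
  p <- sde_params(force = 0.5, drag = 1, D = 0.5, x0 = 1, horizon = 1)
  rpt <- strong_error(p, dt_levels = 2^-(4:9), n_paths = 3000, seed = 17)
  expect_true(all(rpt$table$strong_error > 0))
  expect_true(all(diff(rpt$table$dt) < 0))
  # refinement monotonicity within Monte-Carlo noise (2 standard errors)
  gaps <- diff(rpt$table$strong_error)
  slack <- 2 * (rpt$table$std_error[-1] + rpt$table$std_error[-6])
  expect_true(all(gaps < slack))
  expect_gt(rpt$fitted_order, 0.35)
  expect_lt(rpt$fitted_order, 0.65)

  # deterministic problem converges at order ~1
  pd <- sde_params(force = 0.5, drag = 1, D = 0, x0 = 1, horizon = 1)
  repd <- strong_error(pd, dt_levels = 2^-(4:8), n_paths = 1000, seed = 17)
  expect_equal(repd$fitted_order, 1, tolerance = 0.1)

  expect_error(strong_error(p, 2^-(4:5), 2000, 1), "at least 3")
  expect_error(strong_error(p, c(0.31, 0.17, 0.05), 2000, 1), "divide|powers")
  expect_error(strong_error(p, 2^-(4:8), 10, 1), ">= 1000")
})

test_that("force sweep shares one Brownian path and orders terminal means", {
  p <- sde_params(force = 1, drag = 1, D = 0.25, x0 = 1, horizon = 1,
                  n_steps = 128, seed = 5)
  sweep <- force_sweep(p, forces = c(1e-6, 1e-3, 1))
  expect_length(sweep, 3L)
  # singleton sweep is plain Euler-Maruyama on the shared path
  single <- force_sweep(p, forces = 1)
  expect_equal(single[[1]]$positions,
               euler_maruyama(p, attr(single, "path"))$positions)
  # terminal means over many paths are monotone in the force
  means <- vapply(c(1e-6, 1e-3, 1), function(f) {
    pf <- sde_params(force = f, drag = 1, D = 0.25, x0 = 1, horizon = 1)
    mean(sample_terminal_positions(pf, 1e4, seed = 8))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_error(force_sweep(p, forces = c(-1, 1)), "positive")
})
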