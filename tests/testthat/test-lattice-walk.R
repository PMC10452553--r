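test_that("single-step and deterministic walks follow the step law", {
  sym <- evolve_step(delta_distribution(walk_spec(0.5, 1)), walk_spec(0.5, 1))
  expect_equal(sym$sites, -1:1)
  expect_equal(sym$probabilities, c(0.5, 0, 0.5))

  drift <- evolve_step(delta_distribution(walk_spec(1, 1)), walk_spec(1, 1))
  expect_equal(drift$probabilities[drift$sites == 1], 1)

  # deterministic walk through every route
  det <- walk_spec(1, 3)
  for (dist in list(closed_form_distribution(det), invert_characteristic(det))) {
    expect_equal(dist$probabilities[dist$sites == 3], 1)
    expect_equal(sum(dist$probabilities), 1)
  }

  # n = 0 is the initial point mass
  zero <- closed_form_distribution(walk_spec(0.4, 0))
  expect_equal(zero$sites, 0L)
  expect_equal(zero$probabilities, 1)
})

test_that("multi-step distributions match exhaustive path enumeration", {
  for (case in list(c(0.3, 2), c(0.7, 3), c(0.5, 6))) {
    p <- case[1]; n <- case[2]
    spec <- walk_spec(p, n)
    oracle <- enumerate_walk_oracle(p, n)
    dist <- delta_distribution(spec)
    for (i in seq_len(n)) dist <- evolve_step(dist, spec)
    expect_equal(dist$probabilities, oracle$probabilities, tolerance = 1e-14)
    expect_equal(closed_form_distribution(spec)$probabilities,
                 oracle$probabilities, tolerance = 1e-14)
  }
  # the frozen two-step values for p = 0.3
  d <- closed_form_distribution(walk_spec(0.3, 2))
  expect_equal(d$probabilities[match(c(-2L, 0L, 2L), d$sites)],
               c(0.49, 0.42, 0.09))
})

test_that("iteration, closed form and Fourier inversion agree site-wise", {
  for (p in c(0.2, 0.5, 0.8)) {
    spec <- walk_spec(p, 12L)
    dist <- delta_distribution(spec)
    for (n in 1:12) {
      dist <- evolve_step(dist, spec)
      sub <- walk_spec(p, n)
      cf <- closed_form_distribution(sub)
      fi <- invert_characteristic(sub)
      expect_lt(max(abs(dist$probabilities - cf$probabilities)), 1e-10)
      expect_lt(max(abs(cf$probabilities - fi$probabilities)), 1e-10)
      expect_lt(abs(sum(dist$probabilities) - 1), 1e-12)
    }
  }
})

test_that("characteristic function obeys its normalisation anchors", {
  grid <- wavenumber_grid(33)
  expect_true(all(diff(grid) > 0))
  expect_equal(range(grid), c(-pi, pi))
  # k = 0 gives exactly 1 for any p, n
  expect_identical(characteristic_function(walk_spec(0.37, 11), 0), 1 + 0i)
  # n = 0 gives 1 at every k
  expect_equal(characteristic_function(walk_spec(0.8, 0), grid),
               rep(1 + 0i, length(grid)))
  # symmetric single step reduces to cos(k)
  expect_equal(characteristic_function(walk_spec(0.5, 1), pi / 3),
               0.5 + 0i, tolerance = 1e-15)
})

test_that("closed-form moments are n(p - q) and 4npq", {
  for (p in seq(0.1, 0.9, by = 0.2)) {
    for (n in c(1L, 7L, 20L)) {
      m <- walk_moments(closed_form_distribution(walk_spec(p, n)))
      expect_equal(m$mean, n * (2 * p - 1), tolerance = 1e-10)
      expect_equal(m$variance, 4 * n * p * (1 - p), tolerance = 1e-10)
    }
  }
})

test_that("Monte-Carlo walks are seeded and consistent with the exact law", {
  spec <- walk_spec(0.5, 20L)
  a <- sample_walks(spec, 500, seed = 11)
  b <- sample_walks(spec, 500, seed = 11)
  expect_identical(a$final_positions, b$final_positions)

  # deterministic drift puts all mass at +n
  det <- sample_walks(walk_spec(1, 5L), 100, seed = 1)
  expect_true(all(det$final_positions == 5L))

  # n = 0 leaves every walk at the origin
  still <- sample_walks(walk_spec(0.5, 0L), 50, seed = 1)
  expect_true(all(still$final_positions == 0L))

  exact <- closed_form_distribution(spec)
  mc <- sample_walks(spec, 1e5, seed = 2024)
  expect_lt(tv_distance(mc$distribution, exact), 0.02)

  # trajectory store: paths end where final_positions says
  tr <- sample_walks(walk_spec(0.4, 8L), 64, seed = 5, return_paths = TRUE)
  expect_equal(dim(tr$paths), c(9L, 64L))
  expect_identical(as.integer(tr$paths[9L, ]), tr$final_positions)

  expect_error(sample_walks(spec, 0, seed = 1), "positive")
})

test_that("continuum rescaling is probability per unit length", {
  spec <- walk_spec(0.5, 2L)
  dist <- closed_form_distribution(spec)
  res <- rescaling_params(delta_x = 0.1, delta_t = 0.05)
  expect_equal(res$D, 0.1^2 / (2 * 0.05))
  dens <- continuum_density(dist, res)
  # P = 0.5 at site 0 maps to rho = 5
  expect_equal(dens$rho[dens$x == 0], 5)
  expect_equal(dens$time, 2 * 0.05)
  # trapezoid mass over the padded support is exactly the lattice mass
  nx <- length(dens$x)
  mass <- sum(diff(dens$x) * (dens$rho[-1] + dens$rho[-nx]) / 2)
  expect_lt(abs(mass - 1), 1e-8)
  # symmetric walk gives a symmetric density
  expect_equal(dens$rho, rev(dens$rho))
  # parity-bin density also carries unit mass
  binned <- continuum_density(dist, res, bin_average = TRUE)
  expect_equal(sum(binned$rho) * 2 * res$delta_x, 1)
})

test_that("rescaled symmetric walk converges to the heat kernel", {
  errs <- vapply(c(50L, 200L, 800L), diffusion_limit_error, numeric(1),
                 D = 1, t = 1)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("invalid walk inputs are rejected", {
  expect_error(walk_spec(1.2, 5), "\\[0, 1\\]")
  expect_error(walk_spec(0.5, -1), "non-negative")
  expect_error(walk_distribution(0:1, c(0.7, 0.2), 1L), "sum")
  expect_error(walk_distribution(0:1, c(1.3, -0.3), 1L), "negative")
})
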