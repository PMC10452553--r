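#' Specify a one-dimensional nearest-neighbour random walk
#'
#' A protein hops between neighbouring sites of a one-dimensional lattice at
#' discrete time steps: one unit to the right with probability `p`, one unit
#' to the left with probability `q = 1 - p`. The degenerate cases `p = 0` and
#' `p = 1` (deterministic walks) are legal.
#'
#' @param p Right-step probability, in `[0, 1]`.
#' @param n_steps Number of time steps, a non-negative integer.
#' @param origin Initial lattice site (integer), default 0.
#' @return An object of class `walk_spec` with fields `p`, `q = 1 - p`,
#'   `n_steps` and `origin`.
#' @examples
#' walk_spec(p = 0.5, n_steps = 20)
#' @export
walk_spec <- function(p, n_steps, origin = 0L) {
  stopifnot(is.numeric(p), length(p) == 1L, is.finite(p))
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]")
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 0L) {
    stop("`n_steps` must be a non-negative integer")
  }
  origin <- as.integer(origin)
  structure(
    list(p = p, q = 1 - p, n_steps = n_steps, origin = origin),
    class = "walk_spec"
  )
}

#' Construct a walk distribution
#'
#' A probability mass function over contiguous lattice sites at a given time
#' step. Most users obtain these from [delta_distribution()],
#' [evolve_step()], [closed_form_distribution()] or [invert_characteristic()]
#' rather than building them by hand.
#'
#' @param sites Ordered, contiguous integer lattice positions.
#' @param probabilities Non-negative masses, one per site, summing to 1.
#' @param step_index Time step `n` the distribution refers to.
#' @param origin Lattice site the walk started from.
#' @return An object of class `walk_distribution`.
#' @export
walk_distribution <- function(sites, probabilities, step_index, origin = 0L) {
  dist <- structure(
    list(
      sites = as.integer(sites),
      probabilities = as.numeric(probabilities),
      step_index = as.integer(step_index),
      origin = as.integer(origin)
    ),
    class = "walk_distribution"
  )
  validate_walk_distribution(dist)
}

#' @export
print.walk_distribution <- function(x, ...) {
  cat(sprintf(
    "<walk_distribution> step %d, origin %d, %d sites on [%d, %d]\n",
    x$step_index, x$origin, length(x$sites), min(x$sites), max(x$sites)
  ))
  invisible(x)
}

validate_walk_distribution <- function(dist, tol = 1e-12) {
  p <- dist$probabilities
  if (length(p) != length(dist$sites)) {
    stop("`sites` and `probabilities` must have equal length")
  }
  if (any(diff(dist$sites) != 1L)) stop("`sites` must be contiguous integers")
  if (any(p < -tol)) stop("walk distribution has negative probabilities")
  s <- sum(p)
  if (abs(s - 1) > 1e-12 * max(1, length(p))) {
    stop(sprintf("walk probabilities sum to %.15g, not 1", s))
  }
  invisible(dist)
}

#' Point mass at the walk origin
#'
#' The step-0 distribution: all probability at `spec$origin`.
#'
#' @param spec A [walk_spec()].
#' @return A `walk_distribution` at step 0.
#' @export
delta_distribution <- function(spec) {
  walk_distribution(spec$origin, 1, 0L, spec$origin)
}

#' Advance a walk distribution by one time step
#'
#' Applies the master equation
#' `P(x, n + 1) = p P(x - 1, n) + q P(x + 1, n)`: mass at each site splits to
#' its right neighbour with probability `p` and to its left neighbour with
#' probability `q`. Total mass is conserved exactly and the support widens by
#' at most one site on each side.
#'
#' @param dist A `walk_distribution` at step `n`.
#' @param spec A [walk_spec()] supplying `p` and `q`.
#' @return The `walk_distribution` at step `n + 1`.
#' @examples
#' sp <- walk_spec(0.3, 2)
#' evolve_step(evolve_step(delta_distribution(sp), sp), sp)
#' @export
evolve_step <- function(dist, spec) {
  validate_walk_distribution(dist)
  P <- dist$probabilities
  L <- length(P)
  newP <- numeric(L + 2)
  # site s sends p*P(s) to s+1 and q*P(s) to s-1 on the widened range
  newP[3:(L + 2)] <- newP[3:(L + 2)] + spec$p * P
  newP[1:L] <- newP[1:L] + spec$q * P
  walk_distribution(
    (min(dist$sites) - 1L):(max(dist$sites) + 1L),
    newP,
    dist$step_index + 1L,
    dist$origin
  )
}

#' Binomial closed form of the walk distribution
#'
#' After `n` steps started from a point mass, the number of right steps is
#' binomial, so the mass at displacement `n - 2l` (with `l` the number of
#' left steps) is `choose(n, l) p^(n - l) q^l`. The sign convention is fixed
#' by requiring exact agreement with `n`-fold [evolve_step()] iteration.
#'
#' @param spec A [walk_spec()].
#' @return A `walk_distribution` at step `spec$n_steps`, supported on the
#'   full site range `origin - n, ..., origin + n` (sites of the wrong
#'   parity carry zero mass).
#' @examples
#' closed_form_distribution(walk_spec(0.5, 2))
#' @export
closed_form_distribution <- function(spec) {
  n <- spec$n_steps
  if (n == 0L) return(delta_distribution(spec))
  sites <- (spec$origin - n):(spec$origin + n)
  probs <- numeric(2L * n + 1L)
  # m = number of right steps -> displacement 2m - n -> site index 2m + 1
  probs[2L * (0:n) + 1L] <- dbinom(0:n, n, spec$p)
  walk_distribution(sites, probs, n, spec$origin)
}

#' Uniform wavenumber grid on \eqn{[-\pi, \pi]}
#'
#' @param n_points Number of grid points (at least 2).
#' @return A strictly increasing numeric vector of wavenumbers spanning
#'   `[-pi, pi]`.
#' @export
wavenumber_grid <- function(n_points) {
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L) stop("`n_points` must be >= 2")
  seq(-pi, pi, length.out = n_points)
}

#' Characteristic function of the lattice walk
#'
#' For a walk started from a point mass at the origin, the discrete Fourier
#' transform of the step-`n` distribution is
#' \deqn{\hat P_n(k) = (p e^{-jk} + q e^{jk})^n,}
#' with \eqn{\hat P_0(k) = 1}. The value at `k = 0` is exactly 1.
#'
#' @param spec A [walk_spec()].
#' @param k Numeric vector of wavenumbers, typically from
#'   [wavenumber_grid()]; values are expected in `[-pi, pi]`.
#' @return A complex vector, one value per wavenumber.
#' @export
characteristic_function <- function(spec, k) {
  stopifnot(is.numeric(k))
  (spec$p * exp(-1i * k) + spec$q * exp(1i * k))^spec$n_steps
}

#' Recover the walk distribution from its characteristic function
#'
#' Numerically evaluates the inversion integral
#' \deqn{P(x, n) = \frac{1}{2\pi} \int_{-\pi}^{\pi}
#'   e^{-jkx} (p e^{-jk} + q e^{jk})^n \, dk}
#' for each displacement `x` in `-n, ..., n`. The integrand is a
#' trigonometric polynomial of degree at most `2n`, so the composite
#' trapezoid rule on `4n + 4` uniformly spaced nodes over one period is
#' exact up to rounding. Imaginary residuals are checked against
#' `imag_tol` and then discarded; a residual above tolerance signals
#' quadrature failure and raises an error.
#'
#' @param spec A [walk_spec()] (walk started from a point mass at the
#'   origin).
#' @param imag_tol Maximum tolerated imaginary residual, default `1e-10`.
#' @return A `walk_distribution` matching [closed_form_distribution()].
#' @export
invert_characteristic <- function(spec, imag_tol = 1e-10) {
  n <- spec$n_steps
  if (n == 0L) return(delta_distribution(spec))
  N <- 4L * n + 4L
  # periodic trapezoid = rectangle rule on N nodes spanning one period
  k <- -pi + 2 * pi * (seq_len(N) - 1L) / N
  phi <- characteristic_function(spec, k)
  disp <- (-n):n
  # With the forward transform sum_x P(x) e^{-jkx} (the convention under
  # which the master equation becomes multiplication by p e^{-jk} + q e^{jk}),
  # the inversion kernel is e^{+jkx}.
  vals <- vapply(
    disp,
    function(d) mean(exp(1i * k * d) * phi),
    complex(1)
  )
  resid <- max(abs(Im(vals)))
  if (resid > imag_tol) {
    stop(sprintf(
      "characteristic-function inversion failed: imaginary residual %.3g exceeds %.3g",
      resid, imag_tol
    ))
  }
  probs <- pmax(Re(vals), 0)
  walk_distribution(spec$origin + disp, probs, n, spec$origin)
}

#' Monte-Carlo simulation of lattice walks
#'
#' Simulates `n_walks` independent walks of `spec$n_steps` steps each, with
#' the step law of `spec`. Output is fully determined by `seed`; the
#' caller's RNG state is left untouched.
#'
#' @param spec A [walk_spec()].
#' @param n_walks Number of independent walks, a positive integer.
#' @param seed Integer RNG seed.
#' @param return_paths If `TRUE`, also keep the full trajectory of every
#'   walk (a `(n_steps + 1) x n_walks` matrix of positions).
#' @return A list of class `walk_samples` with elements
#'   `distribution` (the empirical `walk_distribution`),
#'   `final_positions` (integer vector of terminal sites),
#'   `paths` (trajectory matrix or `NULL`), `n_walks` and `seed`.
#' @examples
#' sw <- sample_walks(walk_spec(0.5, 20), n_walks = 1000, seed = 1)
#' sum(sw$distribution$probabilities)
#' @export
sample_walks <- function(spec, n_walks, seed, return_paths = FALSE) {
  n_walks <- as.integer(n_walks)
  if (is.na(n_walks) || n_walks < 1L) {
    stop("`n_walks` must be a positive integer")
  }
  n <- spec$n_steps
  paths <- NULL
  if (n == 0L) {
    final <- rep(spec$origin, n_walks)
    if (return_paths) paths <- matrix(spec$origin, 1L, n_walks)
  } else {
    steps <- with_seed(
      seed,
      matrix(2L * rbinom(n * n_walks, 1L, spec$p) - 1L, nrow = n)
    )
    if (return_paths) {
      cum <- apply(steps, 2L, cumsum)
      paths <- rbind(rep(spec$origin, n_walks), spec$origin + cum)
    }
    final <- spec$origin + colSums(steps)
  }
  sites <- (spec$origin - n):(spec$origin + n)
  counts <- tabulate(final - min(sites) + 1L, nbins = length(sites))
  dist <- walk_distribution(sites, counts / n_walks, n, spec$origin)
  structure(
    list(
      distribution = dist,
      final_positions = as.integer(final),
      paths = paths,
      n_walks = n_walks,
      seed = seed
    ),
    class = "walk_samples"
  )
}

#' Mean and variance of a walk distribution
#'
#' Displacement moments about the walk origin. For the exact step-`n`
#' distribution these equal `n (p - q)` and `4 n p q`.
#'
#' @param dist A `walk_distribution`.
#' @return A list with `mean` (mean displacement from the origin) and
#'   `variance`.
#' @export
walk_moments <- function(dist) {
  d <- dist$sites - dist$origin
  m <- sum(d * dist$probabilities)
  list(mean = m, variance = sum((d - m)^2 * dist$probabilities))
}

#' Total-variation distance between two walk distributions
#'
#' Half the L1 distance between the two mass functions, aligned by site.
#'
#' @param a,b `walk_distribution` objects.
#' @return A number in `[0, 1]`.
#' @export
tv_distance <- function(a, b) {
  sites <- min(a$sites, b$sites):max(a$sites, b$sites)
  pa <- pb <- numeric(length(sites))
  pa[match(a$sites, sites)] <- a$probabilities
  pb[match(b$sites, sites)] <- b$probabilities
  sum(abs(pa - pb)) / 2
}

#' Lattice-to-continuum rescaling parameters
#'
#' Holds the infinitesimal step length `delta_x` and time step `delta_t`
#' together with the derived continuum drift
#' `psi = (q - p) delta_x / delta_t` and diffusivity
#' `D = delta_x^2 / (2 delta_t)`.
#'
#' @param delta_x Step length (length units), positive.
#' @param delta_t Time step (time units), positive.
#' @param N_x,N_t Spatial and temporal point counts (at least 1).
#' @param p Right-step probability used for the drift constant, default 0.5
#'   (drift-free).
#' @return An object of class `rescaling_params` with fields `delta_x`,
#'   `delta_t`, `N_x`, `N_t`, `psi` and `D`.
#' @export
rescaling_params <- function(delta_x, delta_t, N_x = 1L, N_t = 1L, p = 0.5) {
  stopifnot(delta_x > 0, delta_t > 0, N_x >= 1, N_t >= 1, p >= 0, p <= 1)
  psi <- ((1 - p) - p) * delta_x / delta_t
  D <- delta_x^2 / (2 * delta_t)
  if (!is.finite(psi) || !is.finite(D)) {
    stop("derived drift/diffusivity are not finite")
  }
  structure(
    list(
      delta_x = delta_x, delta_t = delta_t,
      N_x = as.integer(N_x), N_t = as.integer(N_t),
      psi = psi, D = D
    ),
    class = "rescaling_params"
  )
}

#' Rescale a walk distribution to a continuum probability density
#'
#' Maps lattice mass to probability per unit length, `rho = P / delta_x`,
#' at physical positions `x = site * delta_x` and time
#' `t = step_index * delta_t`. One zero-mass site is padded on each side so
#' the trapezoid integral of the returned density over its grid equals the
#' total lattice mass exactly.
#'
#' After `n` steps from a point mass the walk occupies only sites of one
#' parity, so the raw density alternates between 0 and roughly twice the
#' local continuum value. With `bin_average = TRUE` the density is instead
#' reported as `P / (2 delta_x)` at the occupied sites only — the mass of
#' each parity bin of width `2 delta_x` — which is the quantity that
#' converges pointwise to the heat kernel in the diffusion limit.
#'
#' @param dist A `walk_distribution`.
#' @param rescaling A [rescaling_params()].
#' @param bin_average If `TRUE`, return the parity-bin density at occupied
#'   sites (see Details). Default `FALSE`.
#' @return A list of class `continuum_density` with fields `x`, `rho`,
#'   `time` and `diffusivity` (the rescaling's `D`).
#' @export
continuum_density <- function(dist, rescaling, bin_average = FALSE) {
  validate_walk_distribution(dist)
  dx <- rescaling$delta_x
  if (bin_average) {
    parity <- (dist$sites - dist$origin + dist$step_index) %% 2L == 0L
    x <- dist$sites[parity] * dx
    rho <- dist$probabilities[parity] / (2 * dx)
  } else {
    sites <- c(min(dist$sites) - 1L, dist$sites, max(dist$sites) + 1L)
    x <- sites * dx
    rho <- c(0, dist$probabilities, 0) / dx
  }
  structure(
    list(
      x = x, rho = rho,
      time = dist$step_index * rescaling$delta_t,
      diffusivity = rescaling$D
    ),
    class = "continuum_density"
  )
}

#' Sup-norm distance between the rescaled symmetric walk and the heat kernel
#'
#' Runs a drift-free walk (`p = q = 1/2`) for `n_steps` steps with the time
#' step chosen as `t / n_steps` and the lattice spacing as
#' `sqrt(2 D delta_t)`, so the rescaled walk targets diffusivity `D` at
#' physical time `t`, and returns the maximum absolute difference between
#' the parity-bin density and [heat_kernel()] centred at the origin.
#' Refining `n_steps` shrinks this error, demonstrating the diffusion limit.
#'
#' @param n_steps Number of walk steps (refinement level).
#' @param D Target diffusivity, default 1.
#' @param t Physical comparison time, default 1.
#' @return The sup-norm error (a non-negative number).
#' @export
diffusion_limit_error <- function(n_steps, D = 1, t = 1) {
  delta_t <- t / n_steps
  delta_x <- sqrt(2 * D * delta_t)
  spec <- walk_spec(0.5, n_steps)
  dist <- closed_form_distribution(spec)
  dens <- continuum_density(
    dist, rescaling_params(delta_x, delta_t, p = 0.5),
    bin_average = TRUE
  )
  max(abs(dens$rho - heat_kernel(dens$x, 0, t, D)))
}
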