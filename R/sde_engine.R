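#' Parameters of the protein-position SDE
#'
#' The position `X_t` of a membrane protein under an external force `F`,
#' drag coefficient `gamma` and multiplicative noise of diffusivity `D`
#' follows the Ito equation
#' \deqn{dX_t = \frac{F}{\gamma} X_t \, dt + \sqrt{D}\, X_t \, dW_t,}
#' i.e. geometric Brownian motion with drift rate `F / gamma` and volatility
#' `sigma = sqrt(D)`. Only the ratio `F / gamma` and `D` enter the dynamics,
#' so `force` and `drag` are accepted as raw numerics (the force is quoted
#' in micro-newtons in the motivating experiments) and no unit conversion is
#' performed.
#'
#' @param force External force `F` (micro-newtons).
#' @param drag Drag coefficient `gamma` (force * time / length), positive.
#' @param D Diffusivity of the multiplicative noise (1 / time),
#'   non-negative; `sqrt(D)` is the volatility of the process.
#' @param x0 Initial position, strictly positive.
#' @param horizon Time horizon `T`, strictly positive.
#' @param n_steps Number of uniform time steps, a positive integer.
#' @param seed Integer RNG seed recorded with the parameters.
#' @return An object of class `sde_params`; the derived drift rate
#'   `mu = force / drag` is stored alongside the inputs.
#' @export
sde_params <- function(force, drag, D, x0 = 1, horizon = 1, n_steps = 1000L,
                       seed = 1L) {
  stopifnot(is.numeric(force), is.numeric(drag), is.numeric(D))
  if (drag <= 0) stop("`drag` must be strictly positive")
  if (D < 0) stop("`D` must be non-negative")
  if (x0 <= 0) stop("`x0` must be strictly positive")
  if (horizon <= 0) stop("`horizon` must be strictly positive")
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L) stop("`n_steps` must be >= 1")
  structure(
    list(
      force = force, drag = drag, D = D, x0 = x0,
      horizon = horizon, n_steps = n_steps, seed = as.integer(seed),
      mu = force / drag
    ),
    class = "sde_params"
  )
}

#' Generate a seeded Brownian path
#'
#' Draws the Wiener increments `dW_i = sqrt(dt) dZ_i`, `dZ_i ~ N(0, 1)`, on
#' a uniform grid of `n_steps` intervals covering `[0, horizon]`. The path
#' is fully determined by `seed`; the caller's RNG state is untouched.
#' Coupled refinements (for strong-error estimation) are produced by
#' [refine_brownian_path()].
#'
#' @param n_steps Number of increments, a positive integer.
#' @param horizon Final time `T`, strictly positive.
#' @param seed Integer RNG seed.
#' @return An object of class `brownian_path` with fields `times` (grid of
#'   length `n_steps + 1`), `increments`, `dt`, `seed` and `level`
#'   (refinement depth, 0 for a freshly generated path).
#' @export
generate_brownian_path <- function(n_steps, horizon, seed) {
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L) stop("`n_steps` must be >= 1")
  if (horizon <= 0) stop("`horizon` must be strictly positive")
  dt <- horizon / n_steps
  incr <- with_seed(seed, rnorm(n_steps, mean = 0, sd = sqrt(dt)))
  structure(
    list(
      times = seq(0, horizon, length.out = n_steps + 1L),
      increments = incr,
      dt = dt,
      seed = as.integer(seed),
      level = 0L
    ),
    class = "brownian_path"
  )
}

# Brownian-bridge split of an increment matrix (rows = intervals, columns =
# independent paths): each increment over dt is divided into two conditional
# halves, dW1 ~ N(dW/2, dt/4), dW2 = dW - dW1, preserving the path exactly.
split_increments <- function(M, dt) {
  n <- nrow(M)
  Z <- matrix(rnorm(n * ncol(M)), n, ncol(M))
  H <- M / 2 + (sqrt(dt) / 2) * Z
  out <- matrix(0, 2L * n, ncol(M))
  out[seq(1L, 2L * n, by = 2L), ] <- H
  out[seq(2L, 2L * n, by = 2L), ] <- M - H
  out
}

#' Refine a Brownian path by conditional midpoint sampling
#'
#' Halves the time step of a [generate_brownian_path()] result by splitting
#' every increment with a Brownian-bridge draw: the first half-increment is
#' `N(dW/2, dt/4)` conditional on the full increment `dW`, and the second
#' half is its complement. Coarse increments therefore equal the sums of the
#' corresponding fine increments exactly, so coarse and fine paths share one
#' underlying Wiener path — the coupling needed for strong-error estimates.
#' The refinement draw is seeded deterministically from the path's `seed`
#' and `level`.
#'
#' @param path A `brownian_path`.
#' @return A `brownian_path` with twice the number of increments and
#'   `level` incremented by one.
#' @export
refine_brownian_path <- function(path) {
  stopifnot(inherits(path, "brownian_path"))
  n <- length(path$increments)
  M <- matrix(path$increments, ncol = 1L)
  fine <- with_seed(
    path$seed + 7919L * (path$level + 1L),
    split_increments(M, path$dt)
  )
  horizon <- path$times[length(path$times)]
  structure(
    list(
      times = seq(0, horizon, length.out = 2L * n + 1L),
      increments = as.vector(fine),
      dt = path$dt / 2,
      seed = path$seed,
      level = path$level + 1L
    ),
    class = "brownian_path"
  )
}

check_path_grid <- function(params, path) {
  if (length(path$increments) < 1L) stop("empty Brownian path")
  horizon <- path$times[length(path$times)]
  if (abs(horizon - params$horizon) > 1e-12 * max(1, params$horizon)) {
    stop("Brownian path horizon does not match `params$horizon`")
  }
  invisible(TRUE)
}

#' Exact solution of the protein-position SDE
#'
#' Evaluates the analytic (Ito) solution
#' \deqn{X_t = x_0 \exp\!\left[\left(\frac{F}{\gamma} - \frac{D}{2}\right) t
#'   + \sqrt{D}\, W_t\right]}
#' on the grid of a given Brownian path, with `W_t` the running sum of the
#' path's increments. The noise term carries a `+` sign, the convention
#' under which the solution couples pathwise with [euler_maruyama()]
#' (replacing `W` by `-W` gives the same process in law). The solution is
#' strictly positive for `x0 > 0`.
#'
#' @param params An [sde_params()] object.
#' @param path A [generate_brownian_path()] result on the same horizon.
#' @return An object of class `sde_path` with fields `times` and
#'   `positions`.
#' @examples
#' p <- sde_params(force = 1, drag = 1, D = 0, x0 = 1, horizon = 1, n_steps = 8)
#' bp <- generate_brownian_path(8, 1, seed = 1)
#' exact_solution(p, bp)$positions[9] # exp(1), noise-free exponential
#' @export
exact_solution <- function(params, path) {
  check_path_grid(params, path)
  W <- c(0, cumsum(path$increments))
  X <- params$x0 *
    exp((params$mu - params$D / 2) * path$times + sqrt(params$D) * W)
  structure(list(times = path$times, positions = X), class = "sde_path")
}

#' Euler-Maruyama integration of the protein-position SDE
#'
#' Applies the explicit scheme
#' \deqn{X_{i+1} = X_i + \frac{F}{\gamma} X_i \,\Delta t
#'   + \sqrt{D}\, X_i \,\Delta W_i}
#' along the increments of a Brownian path, started from `x0`. The scheme
#' is strongly convergent of order 1/2 for this multiplicative-noise
#' equation (order 1 when `D = 0`). Because the noise is multiplicative,
#' the explicit update can explode for coarse steps; iteration aborts with
#' a diagnostic if `|X_i|` exceeds `overflow_bound`.
#'
#' @inheritParams exact_solution
#' @param overflow_bound Abort threshold on `|X_i|`, default `1e12`
#'   (signals an unstable step size).
#' @return An object of class `sde_path`.
#' @export
euler_maruyama <- function(params, path, overflow_bound = 1e12) {
  check_path_grid(params, path)
  n <- length(path$increments)
  dts <- diff(path$times)
  X <- numeric(n + 1L)
  X[1] <- params$x0
  sqD <- sqrt(params$D)
  for (i in seq_len(n)) {
    X[i + 1L] <- X[i] + params$mu * X[i] * dts[i] +
      sqD * X[i] * path$increments[i]
    if (!is.finite(X[i + 1L]) || abs(X[i + 1L]) > overflow_bound) {
      stop(sprintf(
        "Euler-Maruyama overflow at t = %.6g (|X| > %.3g): step size too coarse",
        path$times[i + 1L], overflow_bound
      ))
    }
  }
  structure(list(times = path$times, positions = X), class = "sde_path")
}

# Vectorised Euler-Maruyama terminal values for an increment matrix
# (rows = steps, columns = independent paths) on a uniform grid.
em_terminal <- function(mu, D, x0, dt, M, overflow_bound = 1e12) {
  X <- rep(x0, ncol(M))
  sqD <- sqrt(D)
  for (i in seq_len(nrow(M))) {
    X <- X * (1 + mu * dt + sqD * M[i, ])
    if (anyNA(X) || max(abs(X)) > overflow_bound) {
      stop("Euler-Maruyama overflow: step size too coarse")
    }
  }
  X
}

#' Sample terminal positions of the SDE
#'
#' Draws `n_paths` independent realisations of `X_T`, either from the exact
#' lognormal solution (`W_T ~ N(0, T)` is a sufficient statistic, so it is
#' drawn directly) or by running the Euler-Maruyama scheme over
#' `params$n_steps` steps per path.
#'
#' @param params An [sde_params()] object.
#' @param n_paths Number of independent realisations.
#' @param seed Integer RNG seed.
#' @param method `"exact"` or `"em"`.
#' @return Numeric vector of `n_paths` terminal positions.
#' @export
sample_terminal_positions <- function(params, n_paths, seed,
                                      method = c("exact", "em")) {
  method <- match.arg(method)
  n_paths <- as.integer(n_paths)
  if (is.na(n_paths) || n_paths < 1L) stop("`n_paths` must be >= 1")
  T <- params$horizon
  if (method == "exact") {
    WT <- with_seed(seed, rnorm(n_paths, mean = 0, sd = sqrt(T)))
    params$x0 * exp((params$mu - params$D / 2) * T + sqrt(params$D) * WT)
  } else {
    n <- params$n_steps
    dt <- T / n
    M <- with_seed(
      seed,
      matrix(rnorm(n * n_paths, sd = sqrt(dt)), nrow = n)
    )
    em_terminal(params$mu, params$D, params$x0, dt, M)
  }
}

#' Strong-convergence diagnostics for the Euler-Maruyama scheme
#'
#' Estimates the strong error `E |Y(T) - X(T)|` — the mean absolute gap at
#' the horizon between the exact solution `Y` and the Euler-Maruyama
#' approximation `X`, both driven by the SAME Wiener path — at a sequence
#' of decreasing step sizes, and fits the convergence order as the
#' least-squares slope of `log(error)` against `log(dt)`.
#'
#' All levels are coupled through Brownian-bridge refinement: increments
#' are generated at the coarsest level and split conditionally down to the
#' finest, so `W_T` (and hence the exact terminal value) is identical at
#' every level of each path.
#'
#' @param params An [sde_params()] object (its `n_steps` is ignored; the
#'   levels supply the grids).
#' @param dt_levels Strictly decreasing step sizes; each must divide the
#'   horizon into an integer number of steps, and consecutive levels must
#'   be related by a power-of-two refinement. At least 3 levels.
#' @param n_paths Independent Wiener paths per level, at least 1000.
#' @param seed Integer RNG seed.
#' @return An object of class `convergence_report`: a list with
#'   `table` (data frame with columns `dt`, `n_steps`, `strong_error`,
#'   `std_error`), `fitted_order`, `n_paths` and `seed`.
#' @examples
#' \donttest{
#' p <- sde_params(force = 0.5, drag = 1, D = 0.5, x0 = 1, horizon = 1)
#' strong_error(p, dt_levels = 2^-(4:8), n_paths = 2000, seed = 1)
#' }
#' @export
strong_error <- function(params, dt_levels, n_paths, seed) {
  dt_levels <- sort(as.numeric(dt_levels), decreasing = TRUE)
  if (length(dt_levels) < 3L) stop("need at least 3 `dt_levels`")
  if (any(diff(dt_levels) >= 0)) stop("`dt_levels` must be distinct")
  n_paths <- as.integer(n_paths)
  if (is.na(n_paths) || n_paths < 1000L) stop("`n_paths` must be >= 1000")
  T <- params$horizon
  steps <- T / dt_levels
  if (any(abs(steps - round(steps)) > 1e-9)) {
    stop("every dt level must divide the horizon evenly")
  }
  steps <- as.integer(round(steps))
  ratios <- steps[-1] / steps[-length(steps)]
  if (any(abs(log2(ratios) - round(log2(ratios))) > 1e-9)) {
    stop("consecutive dt levels must be related by powers of two")
  }

  errs <- ses <- numeric(length(dt_levels))
  with_seed(seed, {
    M <- matrix(rnorm(steps[1] * n_paths, sd = sqrt(dt_levels[1])),
                nrow = steps[1])
    YT <- params$x0 *
      exp((params$mu - params$D / 2) * T + sqrt(params$D) * colSums(M))
    cur_steps <- steps[1]
    cur_dt <- dt_levels[1]
    for (lev in seq_along(dt_levels)) {
      while (cur_steps < steps[lev]) {
        M <- split_increments(M, cur_dt)
        cur_steps <- cur_steps * 2L
        cur_dt <- cur_dt / 2
      }
      gap <- abs(YT - em_terminal(params$mu, params$D, params$x0, cur_dt, M))
      errs[lev] <- mean(gap)
      ses[lev] <- sd(gap) / sqrt(n_paths)
    }
  })

  fit <- lm(log(errs) ~ log(dt_levels))
  structure(
    list(
      table = data.frame(
        dt = dt_levels, n_steps = steps,
        strong_error = errs, std_error = ses
      ),
      fitted_order = unname(coef(fit)[2]),
      n_paths = n_paths,
      seed = as.integer(seed)
    ),
    class = "convergence_report"
  )
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf(
    "<convergence_report> fitted strong order %.3f (%d paths per level)\n",
    x$fitted_order, x$n_paths
  ))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Simulate trajectories across a sweep of external forces
#'
#' Integrates the SDE by Euler-Maruyama once per force value, holding all
#' other parameters fixed and driving every trajectory with the SAME seeded
#' Brownian path, so differences between trajectories reflect the force
#' alone. The motivating experiments sweep the force from `1e-6` to `1`
#' micro-newtons.
#'
#' @param params An [sde_params()] template; its `force` is replaced by
#'   each sweep value in turn.
#' @param forces Positive force values.
#' @param seed Integer RNG seed for the shared Brownian path (defaults to
#'   `params$seed`).
#' @return A named list of `sde_path` objects (names are the force values),
#'   with the shared `brownian_path` attached as attribute `"path"`.
#' @export
force_sweep <- function(params, forces = c(1e-6, 1e-3, 1),
                        seed = params$seed) {
  if (any(forces <= 0)) stop("`forces` must be strictly positive")
  path <- generate_brownian_path(params$n_steps, params$horizon, seed)
  out <- lapply(forces, function(f) {
    p <- params
    p$force <- f
    p$mu <- f / p$drag
    euler_maruyama(p, path)
  })
  names(out) <- format(forces, trim = TRUE)
  attr(out, "path") <- path
  out
}
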