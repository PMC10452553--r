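#' Spatially dependent membrane diffusivity
#'
#' The diffusivity inside a cell membrane grows with position as
#' \deqn{D(x) \approx \frac{e^{2x}}{\Gamma(1 + \alpha)^2},}
#' with `alpha` a shape exponent. At the maximum-diffusivity setting
#' `alpha = 1` the conventional value used throughout this package is
#' `exp(2 x) / 2`. Note that `gamma(2)^2 = 1`, so the general formula
#' evaluated at `alpha = 1` would give `exp(2 x)` instead; the two printed
#' conventions are not reconciled here — the `alpha = 1` branch returns the
#' halved form used by the transformed equation ([default_problem()]) and
#' all other `alpha` use the Gamma-function form verbatim.
#'
#' @param x Position(s), dimensionless.
#' @param alpha Exponent, must exceed -1 (Gamma pole region rejected).
#'   Default 1.
#' @return Diffusivity value(s), strictly positive and increasing in `x`.
#' @export
diffusivity_profile <- function(x, alpha = 1) {
  if (alpha <= -1) stop("`alpha` must exceed -1")
  if (isTRUE(all.equal(alpha, 1))) {
    exp(2 * x) / 2
  } else {
    exp(2 * x) / gamma(1 + alpha)^2
  }
}

#' Position-dependent force consistent with the membrane diffusivity
#'
#' The force profile \eqn{F(x) \approx \gamma e^x / 2} paired with the
#' `alpha = 1` diffusivity. The ratio `F(x) / gamma` is independent of the
#' drag coefficient.
#'
#' @param x Position(s), dimensionless.
#' @param drag Drag coefficient `gamma`, strictly positive.
#' @return Force value(s).
#' @export
force_profile <- function(x, drag) {
  if (drag <= 0) stop("`drag` must be strictly positive")
  drag * exp(x) / 2
}

#' Bulk diffusivity from force and drag
#'
#' The simple proportionality \eqn{D = 2F/\gamma^2} relating the bulk
#' diffusivity to the external force and the drag coefficient. This linear
#' form is not algebraically consistent with [diffusivity_profile()] and
#' [force_profile()] (substituting `F = gamma exp(x) / 2` yields
#' `exp(x) / gamma`, not `exp(2x) / 2`); it is provided as printed so the
#' discrepancy can be examined, not silently corrected.
#'
#' @param force External force `F`.
#' @param drag Drag coefficient `gamma`, strictly positive.
#' @return `2 * force / drag^2`.
#' @export
bulk_diffusivity <- function(force, drag) {
  if (drag <= 0) stop("`drag` must be strictly positive")
  2 * force / drag^2
}

#' Dimensionless change of variables for the membrane equation
#'
#' Holds the scaling factor `K`, volatility `sigma = sqrt(D)` and horizon
#' `T` of the transformation
#' \deqn{X = K e^x, \quad \tau = (T - t)\,\sigma^2/2, \quad \Theta = K\theta}
#' that maps the backward equation in physical variables `(X, t)` onto the
#' dimensionless advection-diffusion problem in `(x, tau)` solved by
#' [solve_pde()]. The horizon `t = T` maps to `tau = 0`.
#'
#' @param K Scaling factor, strictly positive.
#' @param sigma Volatility `sqrt(D)`, strictly positive.
#' @param horizon Time horizon `T`.
#' @return An object of class `transform_params`.
#' @export
transform_params <- function(K, sigma, horizon) {
  if (K <= 0) stop("`K` must be strictly positive")
  if (sigma <= 0) stop("`sigma` must be strictly positive")
  structure(
    list(K = K, sigma = sigma, horizon = horizon),
    class = "transform_params"
  )
}

#' Forward map to physical coordinates
#'
#' Maps dimensionless `(x, tau, theta)` to physical `(X, t, Theta)`:
#' `X = K exp(x)`, `t = T - 2 tau / sigma^2`, `Theta = K theta`.
#'
#' @param params A [transform_params()].
#' @param x Dimensionless position(s).
#' @param tau Dimensionless pseudo-time(s), default 0 (i.e. `t = T`).
#' @param theta Dimensionless field value(s), optional.
#' @return A list with `X`, `t` and (if `theta` given) `Theta`.
#' @export
transform_forward <- function(params, x, tau = 0, theta = NULL) {
  out <- list(
    X = params$K * exp(x),
    t = params$horizon - 2 * tau / params$sigma^2
  )
  if (!is.null(theta)) out$Theta <- params$K * theta
  out
}

#' Inverse map to dimensionless coordinates
#'
#' Maps physical `(X, t, Theta)` back to dimensionless `(x, tau, theta)`:
#' `x = log(X / K)`, `tau = (T - t) sigma^2 / 2`, `theta = Theta / K`.
#' Composition with [transform_forward()] is the identity to machine
#' precision.
#'
#' @param params A [transform_params()].
#' @param X Physical position(s), strictly positive.
#' @param t Physical time(s), default `params$horizon` (i.e. `tau = 0`).
#' @param Theta Physical field value(s), optional.
#' @return A list with `x`, `tau` and (if `Theta` given) `theta`.
#' @export
transform_inverse <- function(params, X, t = params$horizon, Theta = NULL) {
  if (any(X <= 0)) stop("`X` must be strictly positive for the inverse map")
  out <- list(
    x = log(X / params$K),
    tau = (params$horizon - t) * params$sigma^2 / 2
  )
  if (!is.null(Theta)) out$theta <- Theta / params$K
  out
}

#' Define an advection-diffusion problem on the unit interval
#'
#' A problem of the form
#' \deqn{\partial_\tau \theta = a(x)\,\partial_x^2 \theta
#'   + b(x)\,\partial_x \theta, \qquad x \in [0, 1],}
#' with Dirichlet boundary values and an initial profile compatible with
#' them. Coefficients are injectable so alternative parsings of the
#' membrane equation can be explored without code changes; use
#' [default_problem()] for the standard membrane problem.
#'
#' @param diffusion_coeff Function `a(x)`, strictly positive on `(0, 1)`.
#' @param advection_coeff Function `b(x)`.
#' @param initial_profile Function `theta(x, 0)`; must match the boundary
#'   values at the endpoints within `1e-12`.
#' @param n_grid Number of interior grid points, at least 3.
#' @param tau_end Final pseudo-time, non-negative.
#' @param checkpoints Increasing pseudo-times starting at 0 at which the
#'   field is stored; default 11 uniform checkpoints on `[0, tau_end]`.
#' @param boundary Dirichlet values at `x = 0` and `x = 1`, default
#'   `c(0, 0)`.
#' @param sigma Optional volatility annotation carried with the problem.
#' @return An object of class `pde_problem` with the sampled grid
#'   (including endpoints), coefficient values and initial field.
#' @export
pde_problem <- function(diffusion_coeff, advection_coeff, initial_profile,
                        n_grid = 199L, tau_end = 1, checkpoints = NULL,
                        boundary = c(0, 0), sigma = NULL) {
  n_grid <- as.integer(n_grid)
  if (is.na(n_grid) || n_grid < 3L) stop("`n_grid` must be >= 3")
  if (tau_end < 0) stop("`tau_end` must be non-negative")
  grid <- seq(0, 1, length.out = n_grid + 2L)
  interior <- grid[2:(n_grid + 1L)]
  a_vals <- diffusion_coeff(interior)
  if (any(a_vals <= 0)) {
    stop("`diffusion_coeff` must be strictly positive on (0, 1)")
  }
  theta0 <- initial_profile(grid)
  if (abs(theta0[1] - boundary[1]) > 1e-12 ||
      abs(theta0[n_grid + 2L] - boundary[2]) > 1e-12) {
    stop("initial profile is incompatible with the Dirichlet boundary values")
  }
  if (is.null(checkpoints)) {
    checkpoints <- if (tau_end == 0) 0 else seq(0, tau_end, length.out = 11L)
  }
  checkpoints <- as.numeric(checkpoints)
  if (checkpoints[1] != 0 || any(diff(checkpoints) <= 0)) {
    stop("`checkpoints` must start at 0 and increase strictly")
  }
  tau_end <- checkpoints[length(checkpoints)]
  structure(
    list(
      grid = grid,
      n_grid = n_grid,
      a = a_vals,
      b = advection_coeff(interior),
      theta0 = theta0,
      boundary = as.numeric(boundary),
      tau_end = tau_end,
      checkpoints = checkpoints,
      sigma = sigma
    ),
    class = "pde_problem"
  )
}

#' The standard membrane advection-diffusion problem
#'
#' Builds the dimensionless equation for the transformed density,
#' \deqn{\frac{\partial\theta}{\partial\tau}
#'   = \frac{e^{2x}}{2\sigma^2}\,\frac{\partial^2\theta}{\partial x^2}
#'   + \frac{e^x}{\sigma^2}\Bigl(1 - \frac{e^x}{2}\Bigr)
#'     \frac{\partial\theta}{\partial x},}
#' on `x` in `[0, 1]` with homogeneous Dirichlet boundaries
#' `theta(0, tau) = theta(1, tau) = 0` and initial condition
#' `theta(x, 0) = exp(2x) (x - x^2)`. The diffusion coefficient is the
#' log-coordinate image of the membrane diffusivity `exp(2x)/2` and drift
#' `F/gamma = exp(x)/2`; both coefficients scale as `1 / sigma^2`, so large
#' volatility freezes the field near its initial profile while small
#' volatility drives it rapidly to the boundary-imposed zero state.
#'
#' @param sigma Volatility, strictly positive.
#' @param n_grid Interior grid points, default 199 (201-point grid).
#' @param tau_end Final pseudo-time, default 1.
#' @param checkpoints Optional checkpoint times (see [pde_problem()]).
#' @return A `pde_problem`.
#' @examples
#' pr <- default_problem(sigma = 5, n_grid = 99, tau_end = 1)
#' @export
default_problem <- function(sigma, n_grid = 199L, tau_end = 1,
                            checkpoints = NULL) {
  if (sigma <= 0) stop("`sigma` must be strictly positive")
  pde_problem(
    diffusion_coeff = function(x) exp(2 * x) / (2 * sigma^2),
    advection_coeff = function(x) exp(x) / sigma^2 * (1 - exp(x) / 2),
    initial_profile = function(x) exp(2 * x) * (x - x^2),
    n_grid = n_grid,
    tau_end = tau_end,
    checkpoints = checkpoints,
    boundary = c(0, 0),
    sigma = sigma
  )
}

#' Solve an advection-diffusion problem by the method of lines
#'
#' Discretises space with second-order central differences on the problem's
#' uniform grid (boundary rows pinned to the Dirichlet data) and integrates
#' the resulting stiff ODE system with [deSolve::ode.1D()] (`lsoda`:
#' adaptive implicit/stiff switching with banded Jacobian, relative
#' tolerance `1e-8` by default). Spatial self-convergence is of order 2.
#'
#' @param problem A [pde_problem()].
#' @param rtol,atol Relative and absolute integration tolerances.
#' @return An object of class `pde_solution` with fields `grid`, `times`
#'   (the checkpoints) and `field` (matrix, one row per checkpoint, one
#'   column per grid point including endpoints; boundary columns hold the
#'   Dirichlet values exactly).
#' @examples
#' sol <- solve_pde(default_problem(sigma = 5, n_grid = 49, tau_end = 0.5))
#' @export
solve_pde <- function(problem, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(problem, "pde_problem"))
  grid <- problem$grid
  n <- problem$n_grid
  h <- grid[2] - grid[1]
  bl <- problem$boundary[1]
  br <- problem$boundary[2]
  y0 <- problem$theta0[2:(n + 1L)]
  times <- problem$checkpoints

  if (length(times) == 1L) {
    field <- matrix(problem$theta0, nrow = 1L)
  } else {
    a <- problem$a
    b <- problem$b
    rhs <- function(tau, y, parms) {
      up <- c(y[-1L], br)
      down <- c(bl, y[-n])
      list(a * (up - 2 * y + down) / h^2 + b * (up - down) / (2 * h))
    }
    out <- deSolve::ode.1D(
      y = y0, times = times, func = rhs, parms = NULL,
      nspec = 1L, method = "lsoda", rtol = rtol, atol = atol
    )
    finite_rows <- apply(out[, -1L, drop = FALSE], 1L,
                         function(r) all(is.finite(r)))
    if (nrow(out) < length(times) || !all(finite_rows)) {
      bad_tau <- if (!all(finite_rows)) out[which(!finite_rows)[1L], 1L]
                 else out[nrow(out), 1L]
      stop(sprintf(
        "PDE time stepping failed near tau = %.6g (non-finite field or step failure)",
        bad_tau
      ))
    }
    field <- cbind(bl, unname(out[, -1L, drop = FALSE]), br)
  }
  structure(
    list(grid = grid, times = times, field = field, sigma = problem$sigma),
    class = "pde_solution"
  )
}

#' @export
print.pde_solution <- function(x, ...) {
  cat(sprintf(
    "<pde_solution> %d checkpoints on tau = [%g, %g], %d grid points%s\n",
    length(x$times), min(x$times), max(x$times), length(x$grid),
    if (!is.null(x$sigma)) sprintf(", sigma = %g", x$sigma) else ""
  ))
  invisible(x)
}

#' L2 distance of the final field from the initial profile
#'
#' The trapezoid-quadrature L2 norm of `theta(., tau_end) - theta(., 0)`.
#'
#' @param solution A `pde_solution` whose first checkpoint is `tau = 0`.
#' @return A non-negative number.
#' @export
l2_distance_from_initial <- function(solution) {
  d <- solution$field[nrow(solution$field), ] - solution$field[1L, ]
  sqrt(trapz(solution$grid, d^2))
}

#' Solve the membrane problem across a sweep of volatilities
#'
#' Solves [default_problem()] once per `sigma` value and records, for each,
#' the L2 distance between the final field and the initial profile. The
#' motivating experiments sweep `sigma` from 5 to 20: because both
#' coefficients of the equation scale as `1 / sigma^2`, the distance shrinks
#' as `sigma` grows (the field stays consistent with the initial condition),
#' while small `sigma` lets the field decay rapidly to the boundary-imposed
#' zero state.
#'
#' @param sigmas Volatility values, all strictly positive; default
#'   `c(5, 10, 15, 20)`.
#' @param n_grid,tau_end,checkpoints Passed to [default_problem()].
#' @return A list of class `sigma_sweep` with `solutions` (named list of
#'   `pde_solution`) and `distances` (data frame with columns `sigma`,
#'   `l2_distance`).
#' @export
sigma_sweep <- function(sigmas = c(5, 10, 15, 20), n_grid = 199L,
                        tau_end = 1, checkpoints = NULL) {
  if (any(sigmas <= 0)) stop("`sigmas` must be strictly positive")
  sols <- lapply(sigmas, function(s) {
    solve_pde(default_problem(s, n_grid = n_grid, tau_end = tau_end,
                              checkpoints = checkpoints))
  })
  names(sols) <- format(sigmas, trim = TRUE)
  structure(
    list(
      solutions = sols,
      distances = data.frame(
        sigma = sigmas,
        l2_distance = vapply(sols, l2_distance_from_initial, numeric(1))
      )
    ),
    class = "sigma_sweep"
  )
}
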