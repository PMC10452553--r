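---
title: "Modelling membrane-protein motion: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling membrane-protein motion: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membranewalk)
```

## The physical picture

During cell-to-cell communication, messenger proteins diffuse laterally
within the fluid lipid bilayer of the cell membrane, and pass through it to
bind receptors on other cells. Between molecular collisions a protein's
motion is effectively random; at the scale of the membrane it is Brownian
motion biased by the external forces that deform the plasma membrane and
resisted by drag. `membranewalk` treats this system at three connected
levels — a discrete lattice walk, its continuum diffusion limit, and an Itô
stochastic differential equation whose transformed density obeys an
advection–diffusion equation with spatially growing diffusivity — and ships
the numerical validation of each level and of the passages between them.

This vignette records the model assumptions, the parameters that matter, the
numerical decisions, and what the test suite does and does not establish.

## Level 1: the lattice walk

A protein occupies integer lattice sites and hops once per time step: right
with probability $p$, left with probability $q = 1 - p$. The occupation
probability obeys
$$P(x, n) = p\,P(x-1, n-1) + q\,P(x+1, n-1),$$
and, for a walk started from a point mass, the step-$n$ law is binomial:
displacement $n - 2l$ (where $l$ counts left steps) carries mass
$\binom{n}{l} p^{\,n-l} q^{\,l}$. The characteristic function is
$\hat P_n(k) = (p e^{-jk} + q e^{jk})^n$ with $\hat P_0(k) = 1$.

Assumptions: one spatial dimension, unit spacing, homogeneous and
time-independent step probabilities, no boundaries. A point mass at the
origin is the canonical initial condition; arbitrary initial distributions
are supported only through repeated `evolve_step()`.

Three conventions are fixed once and verified by cross-agreement rather than
left to interpretation:

* **Binomial sign.** The closed form places mass at displacement $n - 2l$;
  the convention is pinned by demanding exact site-wise agreement with
  $n$-fold master-equation iteration, which is taken as the normative
  definition of the walk.
* **Transform pair.** With the forward transform
  $\hat P(k) = \sum_x P(x) e^{-jkx}$ — the convention under which one step
  becomes multiplication by $p e^{-jk} + q e^{jk}$ — the inversion kernel
  must be $e^{+jkx}$. The opposite pairing mirrors the distribution for
  asymmetric $p$, which the oracle-equivalence tests would catch
  immediately.
* **Quadrature.** The inversion integrand is a trigonometric polynomial of
  degree at most $2n$, so the periodic trapezoid rule on $4n + 4$ uniform
  nodes is exact up to rounding; imaginary residuals above $10^{-10}$ raise
  an error instead of being discarded silently.

Degenerate inputs are legal: $p = 0$ and $p = 1$ give deterministic walks,
$n = 0$ returns the initial point mass.

## Level 2: the continuum limit

With step length $\delta x$ and time step $\delta t$, the rescaled density
$\rho = P/\delta x$ approaches, as both shrink, the solution of
$$\frac{\partial \rho}{\partial t} = \psi \frac{\partial \rho}{\partial x}
  + D \frac{\partial^2 \rho}{\partial x^2}, \qquad
  \psi = (q - p)\frac{\delta x}{\delta t}, \quad
  D = \frac{\delta x^2}{2\,\delta t}.$$
The solved case is the drift-free one ($p = q$, $\psi = 0$); the drift
constant is exposed in `rescaling_params()` but no drifting PDE is solved.

`solve_free_diffusion()` propagates an initial density by convolution with
the heat kernel, using composite trapezoid quadrature on the caller's grid.
Two guard rails are built in, both derived from the quadrature error model:
the initial mass must be interior (edge values below $10^{-10}$ of the peak,
else truncation error is uncontrolled and a warning fires), and the grid
spacing must resolve the diffusion length $\sqrt{2Dt}$ with at least ten
points (else a resolution warning fires). The effective integration domain
is the supplied grid, which for an interior Gaussian is equivalent to
truncation beyond eight standard deviations (residual mass below
$10^{-15}$).

**A parity subtlety.** After $n$ steps from a point mass the walk occupies
only sites with $x \equiv n \pmod 2$, so the raw density $P/\delta x$
alternates between $0$ and roughly twice the continuum value and can never
converge in sup norm. `continuum_density()` therefore reports, with
`bin_average = TRUE`, the mass per parity bin of width $2\delta x$, i.e.
$P/(2\delta x)$ at occupied sites, which by the local central limit theorem
converges pointwise to the heat kernel at rate $O(1/n)$. Both versions carry
exactly unit trapezoid mass. The diffusion-limit demonstration
(`diffusion_limit_error()`) uses refinement levels $n = 100, 400, 1600$ at
$D = 1$, $t = 1$.

## Level 3: the protein-position SDE

Outside the lattice description, the position under external force $F$
(micro-newtons in the motivating experiments), drag coefficient $\gamma$ and
diffusivity $D$ follows
$$dX_t = \frac{F}{\gamma} X_t\, dt + \sqrt{D}\, X_t\, dW_t,$$
geometric Brownian motion with drift rate $F/\gamma$ and volatility
$\sigma = \sqrt D$. Only the ratio $F/\gamma$ and $D$ enter the dynamics, so
no unit conversion is performed and both are accepted as raw numerics.

The exact solution is
$X_t = x_0 \exp[(F/\gamma - D/2)t + \sqrt D\, W_t]$. Two sign conventions
for the noise term are in circulation; since $W$ and $-W$ are identical in
law, every distributional statement is unaffected, and the $+$ convention is
adopted here because it is the one under which the exact solution couples
*pathwise* with the Euler–Maruyama recursion
$$X_{i+1} = X_i + \frac{F}{\gamma} X_i \Delta t + \sqrt D\, X_i \Delta W_i$$
driven by the same increments — the coupling on which strong-error
measurement rests.

Numerical decisions:

* **Coupled refinement.** Strong error at several step sizes must be
  measured on one underlying Wiener path per realisation.
  `refine_brownian_path()` and the internal level loop of `strong_error()`
  split each increment by a Brownian-bridge draw
  ($\Delta W_1 \sim N(\Delta W/2, \Delta t/4)$ conditional on $\Delta W$),
  so coarse increments equal sums of fine ones exactly and $W_T$ — hence the
  exact terminal value — is identical at every level.
* **Overflow guard.** The explicit multiplicative update can explode when
  $\Delta t \cdot F/\gamma$ or $\Delta t \cdot D$ is large; integration
  aborts with a diagnostic when $|X_i|$ exceeds `overflow_bound`
  (default $10^{12}$). Positivity of the Euler–Maruyama path is *not*
  asserted: it holds only for steps small against $\gamma/F$ and $1/D$.
* **Order fit.** The convergence order is the least-squares slope of
  $\log E|Y(T) - X(T)|$ against $\log \Delta t$. The reference
  configuration — $F/\gamma = 0.5$, $D = 0.5$, $T = 1$,
  $\Delta t = 2^{-4} \dots 2^{-10}$, $10^4$ paths — yields a fitted order
  near $0.5$, the known strong order of the scheme under multiplicative
  noise, with an acceptance window of $[0.35, 0.65]$ to absorb Monte-Carlo
  noise in the level means.
* **Seeding.** Every stochastic entry point takes an integer seed, restores
  the caller's RNG state, and is bit-reproducible for a fixed seed;
  refinement draws are seeded deterministically from the parent path's seed
  and level.

The force sweep (`force_sweep()`) integrates one trajectory per force value
over $F = 10^{-6} \dots 1$ with all other parameters and the Brownian path
held fixed, so curves differ by the drift alone; terminal means across
independent paths are monotone in $F$ by the lognormal mean identity
$E X_T = x_0 e^{(F/\gamma)T}$.

## Level 4: the membrane advection–diffusion equation

Empirically motivated profiles make the diffusivity grow across the
membrane: $D(x) = e^{2x}/\Gamma(1+\alpha)^2$ with shape exponent $\alpha$.
The package's working convention at the maximum-diffusivity setting
$\alpha = 1$ is $D(x) = e^{2x}/2$ with the matching force profile
$F(x) = \gamma e^x/2$; note $\Gamma(2)^2 = 1$, so the general formula at
$\alpha = 1$ would give $e^{2x}$ instead — the halved convention is the one
the transformed equation below uses, the Gamma form is exposed verbatim for
all other $\alpha$, and the two are deliberately not reconciled. Similarly
the linear bulk relation $D = 2F/\gamma^2$ (`bulk_diffusivity()`) is
provided exactly as stated even though substituting $F = \gamma e^x/2$ into
it yields $e^x/\gamma$, not $e^{2x}/2$ (a squared form $2F^2/\gamma^2$ would
reconcile them); the function exists so the inconsistency can be examined,
not hidden.

The change of variables $X = K e^x$, $\tau = (T - t)\sigma^2/2$,
$\Theta = K\theta$ (`transform_params()` and friends; $t = T$ maps to
$\tau = 0$) turns the backward equation in $(X, t)$ into the dimensionless
problem
$$\frac{\partial\theta}{\partial\tau}
  = \underbrace{\frac{e^{2x}}{2\sigma^2}}_{a(x)}
    \frac{\partial^2\theta}{\partial x^2}
  + \underbrace{\frac{e^x}{\sigma^2}\Bigl(1 - \frac{e^x}{2}\Bigr)}_{b(x)}
    \frac{\partial\theta}{\partial x}$$
on $x \in [0, 1]$, $\theta(0, \tau) = \theta(1, \tau) = 0$,
$\theta(x, 0) = e^{2x}(x - x^2)$. This coefficient grouping is the standard
log-coordinate image of a diffusion with $D(x) = e^{2x}/2$ and drift
$F(x)/\gamma = e^x/2$; because typeset forms of such equations are easy to
misread, `pde_problem()` accepts arbitrary injected coefficients so
alternative groupings can be solved without code changes.

Numerical decisions:

* **Discretisation.** Uniform grid of `n_grid` interior points plus both
  endpoints; second-order central differences for both derivatives;
  boundary rows pinned to the Dirichlet data, which the stored field
  satisfies at machine precision. The cell Péclet number
  $|b|h/a = 2h\,|e^{-x}(1 - e^x/2)| \le h$ on this problem, so central
  advection differences are non-oscillatory at any practical resolution.
* **Time stepping.** `deSolve::ode.1D` with `lsoda` (adaptive implicit/
  stiff switching, banded Jacobian), default `rtol = 1e-8`,
  `atol = 1e-10`. The advection term stiffens as $\sigma$ shrinks, which is
  why a fixed-step explicit scheme was rejected.
* **Validation.** Constant-coefficient sine modes decay as
  $e^{-D_0 m^2 \pi^2 \tau}$; at 201 grid points the maximum error is below
  $10^{-4}$ (measured: $7.6 \times 10^{-6}$ at $D_0 = 1$, $\tau = 0.1$,
  $m = 1$). Richardson self-convergence on the full problem across grids of
  51/101/201 points gives spatial order $2.00$. The field obeys the
  no-source maximum bound $\max|\theta(\cdot,\tau)| \le \max|\theta(\cdot,0)|$
  up to integrator tolerance.
* **Checkpoints and horizon.** Both coefficients scale as $1/\sigma^2$, so
  $\sigma$ only rescales pseudo-time; the sweep horizon $\tau_{end} = 1$
  with 11 uniform checkpoints was chosen once so that the $\sigma = 5$
  solution loses roughly half its $L^2$ norm (clear decay toward the
  boundary-imposed zero state) while $\sigma = 20$ remains close to the
  initial profile (the freezing limit). The monotone decrease of the
  distance-from-initial-profile column across $\sigma = 5, 10, 15, 20$ is a
  direct consequence of this scaling.

## What the generators emulate — and what they do not

All test inputs are generated in code: seeded walks, Brownian paths with
exact bridge refinement, Gaussian initial densities, and the fixture bundle
of `make_fixtures()` (an exactly enumerated two-step walk table, a coupled
three-level Brownian path, a sine-mode reference solution). These emulate
the *mathematical* conditions of the model — ideal one-dimensional Brownian
motion, homogeneous step laws, smooth initial data — under which every
analytic identity asserted in the tests holds exactly.

They do not emulate real membranes: molecular crowding, anomalous
subdiffusion, two-dimensional geometry, protein–protein binding kinetics,
membrane curvature, or measurement noise in single-particle tracking. A
green suite therefore certifies the numerics and the internal consistency of
the model chain, not the biological fidelity of the model itself; fitting
the model to tracking data is out of scope.

## Known limitations

* One spatial dimension throughout; no absorbing or reflecting lattice
  boundaries; no site-dependent step probabilities.
* The drifting continuum equation ($\psi \ne 0$) is represented only by the
  constant in `rescaling_params()`.
* Euler–Maruyama only; no Milstein or higher-order schemes, no
  time-dependent forces, no jumps.
* The membrane equation is solved only with Dirichlet data on the unit
  interval; no Neumann/Robin boundaries and no stochastic PDEs.
* Test problem sizes ($10^5$ walks, $10^4$ coupled paths over
  $\Delta t = 2^{-4} \dots 2^{-10}$, 201-point grids) were chosen as the
  smallest sizes at which the asymptotic statements are comfortably
  resolved; all are single-CPU and run in seconds.
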