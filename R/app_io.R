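#' Write a data frame as CSV with full numeric precision
#'
#' Numeric columns are formatted with 17 significant digits so a subsequent
#' [read_table_csv()] recovers every value to within one unit in the last
#' place (relative error below 1e-15).
#'
#' @param df A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_table_csv()]
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_table_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read an experiment configuration file
#'
#' Configurations are YAML documents whose top-level keys are named
#' parameter blocks (`walk`, `diffusion`, `sde`, `converge`, `pde`) plus
#' optional `out_dir` and `seed`. Parameters are validated against the
#' owning module's invariants when a scenario is dispatched.
#'
#' @param path Path to a YAML file.
#' @return A named list (the configuration).
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

scenario_block <- c(
  walk = "walk", diffuse = "diffusion", sde = "sde", converge = "converge",
  pde = "pde", force_sweep = "sde", sigma_sweep = "pde"
)

block_keys <- list(
  walk = list(
    required = c("p", "steps"),
    optional = c("mode", "n_walks", "seed")
  ),
  diffusion = list(
    required = c("D", "t"),
    optional = c("ic", "ic_mean", "ic_sd", "grid_min", "grid_max",
                 "grid_points")
  ),
  sde = list(
    required = c("force", "gamma", "D"),
    optional = c("x0", "horizon", "steps", "seed", "paths", "method",
                 "forces")
  ),
  converge = list(
    required = c("force", "gamma", "D"),
    optional = c("x0", "horizon", "levels", "paths", "seed")
  ),
  pde = list(
    required = character(0),
    optional = c("sigma", "n_grid", "tau_end", "checkpoints", "seed")
  )
)

check_block <- function(config, name) {
  block <- config[[name]]
  if (is.null(block)) {
    stop(sprintf("configuration is missing the '%s' block", name))
  }
  keys <- block_keys[[name]]
  unknown <- setdiff(names(block), c(keys$required, keys$optional))
  if (length(unknown)) {
    stop(sprintf("unknown key(s) in '%s' block: %s",
                 name, paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(keys$required, names(block))
  if (length(missing)) {
    stop(sprintf("'%s' block is missing required key(s): %s",
                 name, paste(missing, collapse = ", ")))
  }
  block
}

#' Run a named simulation scenario
#'
#' Dispatches a configuration block to the owning module, writes the
#' tabular results as CSV and a JSON run manifest recording the scenario,
#' the full parameter set, the seed, the package version and the output
#' paths. Re-running a manifest (see [replay_manifest()]) reproduces every
#' stochastic output bit-for-bit.
#'
#' Available scenarios:
#' \describe{
#'   \item{`walk`}{lattice-walk distribution by mode `exact`, `fourier` or
#'     `montecarlo`; writes `site, probability`.}
#'   \item{`diffuse`}{heat-kernel propagation of a Gaussian or near-delta
#'     initial density; writes `x, rho`.}
#'   \item{`sde`}{Euler-Maruyama (or exact) trajectories; writes
#'     `time, position, path_id`.}
#'   \item{`converge`}{strong-convergence report; writes the level table as
#'     CSV and the fitted order into the manifest.}
#'   \item{`pde`}{membrane advection-diffusion solution(s); writes
#'     `sigma, tau, x, theta` plus a `sigma, l2_distance` table.}
#'   \item{`force_sweep`}{trajectories across forces 1e-6 to 1 (micro-
#'     newtons by convention) on a shared Brownian path.}
#'   \item{`sigma_sweep`}{the `pde` scenario across `sigma = 5, 10, 15, 20`.}
#' }
#'
#' @param config A configuration list (see [read_config()]) holding the
#'   block the scenario needs.
#' @param scenario Scenario name, one of `walk`, `diffuse`, `sde`,
#'   `converge`, `pde`, `force_sweep`, `sigma_sweep`.
#' @param out_dir Output directory; created if absent. Defaults to
#'   `config$out_dir`.
#' @return The run manifest (class `run_manifest`), invisibly: a list with
#'   `scenario`, `parameters`, `seed`, `version`, `outputs`, `timestamp`
#'   and `manifest_path`.
#' @export
run_scenario <- function(config, scenario, out_dir = config$out_dir) {
  if (!is.list(config) || length(config) == 0L) {
    stop("empty configuration: expected a named parameter block")
  }
  scenario <- match.arg(scenario, names(scenario_block))
  if (is.null(out_dir)) stop("no output directory: set `out_dir`")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  block_name <- scenario_block[[scenario]]
  block <- check_block(config, block_name)
  seed <- as.integer(block$seed %||% config$seed %||% 1L)
  block$seed <- seed
  message(sprintf("scenario '%s' running with seed %d", scenario, seed))

  outputs <- switch(
    scenario,
    walk = scenario_walk(block, out_dir),
    diffuse = scenario_diffuse(block, out_dir),
    sde = scenario_sde(block, out_dir),
    converge = scenario_converge(block, out_dir),
    pde = scenario_pde(block, out_dir),
    force_sweep = scenario_force_sweep(block, out_dir),
    sigma_sweep = scenario_sigma_sweep(block, out_dir)
  )

  manifest <- structure(
    list(
      scenario = scenario,
      parameters = block,
      seed = seed,
      version = as.character(packageVersion("membranewalk")),
      outputs = outputs,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    class = "run_manifest"
  )
  manifest_path <- file.path(out_dir, paste0(scenario, "_manifest.json"))
  jsonlite::write_json(unclass(manifest), manifest_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$manifest_path <- manifest_path
  invisible(manifest)
}

scenario_walk <- function(block, out_dir) {
  spec <- walk_spec(block$p, block$steps)
  mode <- block$mode %||% "exact"
  dist <- switch(
    mode,
    exact = closed_form_distribution(spec),
    fourier = invert_characteristic(spec),
    montecarlo = sample_walks(spec, block$n_walks %||% 1e4,
                              block$seed)$distribution,
    stop(sprintf("unknown walk mode '%s'", mode))
  )
  path <- file.path(out_dir, "walk.csv")
  write_table_csv(
    data.frame(site = dist$sites, probability = dist$probabilities),
    path
  )
  list(walk = path)
}

scenario_diffuse <- function(block, out_dir) {
  D <- block$D
  t <- block$t
  gmin <- block$grid_min %||% -20
  gmax <- block$grid_max %||% 20
  npts <- block$grid_points %||% 801L
  grid <- seq(gmin, gmax, length.out = npts)
  ic <- block$ic %||% "gaussian"
  f <- if (identical(ic, "gaussian")) {
    m <- block$ic_mean %||% 0
    s <- block$ic_sd %||% 1
    exp(-(grid - m)^2 / (2 * s^2)) / sqrt(2 * pi * s^2)
  } else if (identical(ic, "delta-approx")) {
    s <- block$ic_sd %||% (10 * (grid[2] - grid[1]))
    exp(-grid^2 / (2 * s^2)) / sqrt(2 * pi * s^2)
  } else if (startsWith(ic, "csv:")) {
    tab <- read_table_csv(substring(ic, 5L))
    if (!all(c("x", "rho") %in% names(tab))) {
      stop("initial-condition CSV needs columns x, rho")
    }
    grid <- tab$x
    tab$rho
  } else {
    stop(sprintf("unknown initial condition '%s'", ic))
  }
  fld <- solve_free_diffusion(f, grid, t, D)
  path <- file.path(out_dir, "diffuse.csv")
  write_table_csv(data.frame(x = fld$grid, rho = fld$density), path)
  list(diffuse = path)
}

sde_params_from_block <- function(block) {
  sde_params(
    force = block$force, drag = block$gamma, D = block$D,
    x0 = block$x0 %||% 1, horizon = block$horizon %||% 1,
    n_steps = block$steps %||% 1000L, seed = block$seed
  )
}

scenario_sde <- function(block, out_dir) {
  params <- sde_params_from_block(block)
  n_paths <- block$paths %||% 1L
  method <- block$method %||% "em"
  rows <- lapply(seq_len(n_paths), function(i) {
    bp <- generate_brownian_path(params$n_steps, params$horizon,
                                 params$seed + i - 1L)
    sol <- if (identical(method, "exact")) exact_solution(params, bp)
           else euler_maruyama(params, bp)
    data.frame(time = sol$times, position = sol$positions, path_id = i)
  })
  path <- file.path(out_dir, "sde.csv")
  write_table_csv(do.call(rbind, rows), path)
  list(sde = path)
}

scenario_converge <- function(block, out_dir) {
  params <- sde_params_from_block(block)
  levels <- block$levels %||% 2^-(4:10)
  report <- strong_error(params, levels, block$paths %||% 1e4, block$seed)
  csv_path <- file.path(out_dir, "converge.csv")
  write_table_csv(report$table, csv_path)
  json_path <- file.path(out_dir, "converge.json")
  jsonlite::write_json(
    list(fitted_order = report$fitted_order, n_paths = report$n_paths,
         seed = report$seed),
    json_path, auto_unbox = TRUE, digits = NA
  )
  list(converge_csv = csv_path, converge_json = json_path)
}

scenario_pde <- function(block, out_dir, sigmas = NULL) {
  sigmas <- sigmas %||% block$sigma %||% c(5, 10, 15, 20)
  sweep <- sigma_sweep(
    sigmas,
    n_grid = block$n_grid %||% 199L,
    tau_end = block$tau_end %||% 1,
    checkpoints = block$checkpoints
  )
  rows <- mapply(function(sol, s) {
    data.frame(
      sigma = s,
      tau = rep(sol$times, each = length(sol$grid)),
      x = rep(sol$grid, times = length(sol$times)),
      theta = as.vector(t(sol$field))
    )
  }, sweep$solutions, sigmas, SIMPLIFY = FALSE)
  field_path <- file.path(out_dir, "pde.csv")
  write_table_csv(do.call(rbind, rows), field_path)
  dist_path <- file.path(out_dir, "pde_distances.csv")
  write_table_csv(sweep$distances, dist_path)
  list(pde = field_path, distances = dist_path)
}

scenario_force_sweep <- function(block, out_dir) {
  params <- sde_params_from_block(block)
  forces <- block$forces %||% c(1e-6, 1e-3, 1)
  sols <- force_sweep(params, forces, seed = block$seed)
  rows <- mapply(function(sol, f) {
    data.frame(force = f, time = sol$times, position = sol$positions)
  }, sols, forces, SIMPLIFY = FALSE)
  path <- file.path(out_dir, "force_sweep.csv")
  write_table_csv(do.call(rbind, rows), path)
  list(force_sweep = path)
}

scenario_sigma_sweep <- function(block, out_dir) {
  scenario_pde(block, out_dir, sigmas = block$sigma %||% c(5, 10, 15, 20))
}

#' Replay a run manifest
#'
#' Re-runs the scenario recorded in a manifest with exactly its parameters
#' and seed. Stochastic outputs are reproduced bit-for-bit, which
#' [verify_manifest()] checks directly on the output files.
#'
#' @param manifest A `run_manifest` (or path to a manifest JSON file).
#' @param out_dir Directory for the replayed outputs.
#' @return The replay's `run_manifest`, invisibly.
#' @export
replay_manifest <- function(manifest, out_dir) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  config <- list()
  config[[scenario_block[[manifest$scenario]]]] <- as.list(manifest$parameters)
  run_scenario(config, manifest$scenario, out_dir = out_dir)
}

#' Check that a manifest replays bit-for-bit
#'
#' Replays `manifest` into a fresh directory and compares every output file
#' byte-by-byte with the original run.
#'
#' @param manifest A `run_manifest` as returned by [run_scenario()].
#' @param out_dir Directory for the replay, default a fresh temporary
#'   directory.
#' @return `TRUE` if all outputs are byte-identical, else `FALSE`.
#' @export
verify_manifest <- function(manifest, out_dir = tempfile("replay")) {
  replay <- replay_manifest(manifest, out_dir)
  all(mapply(function(a, b) {
    identical(readBin(a, "raw", file.size(a)),
              readBin(b, "raw", file.size(b)))
  }, unlist(manifest$outputs), unlist(replay$outputs)))
}

#' Generate the deterministic test-fixture bundle
#'
#' Writes three small plain-text fixtures used by the test suite: the
#' exactly enumerated two-step walk table (`p = 0.3`), a coupled Brownian
#' path at three refinement levels, and a reference solution of the
#' constant-coefficient sine-mode diffusion problem. For a fixed seed the
#' bundle is byte-identical across runs.
#'
#' @param seed Integer RNG seed.
#' @param dir Output directory; created if absent.
#' @return Named list of the written file paths, invisibly.
#' @export
make_fixtures <- function(seed, dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  spec <- walk_spec(0.3, 2L)
  dist <- evolve_step(evolve_step(delta_distribution(spec), spec), spec)
  walk_path <- file.path(dir, "walk_two_step.csv")
  write_table_csv(
    data.frame(site = dist$sites, probability = dist$probabilities),
    walk_path
  )

  bp <- generate_brownian_path(4L, 1, seed)
  levels <- list(bp, refine_brownian_path(bp),
                 refine_brownian_path(refine_brownian_path(bp)))
  brown <- do.call(rbind, lapply(levels, function(p) {
    data.frame(
      level = p$level,
      interval = seq_along(p$increments),
      t_start = p$times[-length(p$times)],
      t_end = p$times[-1L],
      increment = p$increments
    )
  }))
  brown_path <- file.path(dir, "brownian_refinement.csv")
  write_table_csv(brown, brown_path)

  D0 <- 1
  tau <- 0.05
  prob <- pde_problem(
    diffusion_coeff = function(x) rep(D0, length(x)),
    advection_coeff = function(x) rep(0, length(x)),
    initial_profile = function(x) sin(pi * x),
    n_grid = 39L, tau_end = tau, checkpoints = c(0, tau)
  )
  sol <- solve_pde(prob)
  pde_path <- file.path(dir, "pde_sine_reference.csv")
  write_table_csv(
    data.frame(
      x = sol$grid,
      theta_numeric = sol$field[2L, ],
      theta_exact = exp(-D0 * pi^2 * tau) * sin(pi * sol$grid)
    ),
    pde_path
  )

  invisible(list(
    walk = walk_path, brownian = brown_path, pde_sine = pde_path
  ))
}
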