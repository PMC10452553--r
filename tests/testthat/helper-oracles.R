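# Independent oracles used across the suite.

# Exhaustive enumeration of all 2^n step sequences of the nearest-neighbour
# walk; independent of the package's evolution/closed-form code paths.
enumerate_walk_oracle <- function(p, n, origin = 0L) {
  stopifnot(n >= 1, n <= 16)
  signs <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), n)))
  disp <- rowSums(signs)
  n_right <- rowSums(signs == 1L)
  path_prob <- p^n_right * (1 - p)^(n - n_right)
  agg <- tapply(path_prob, disp, sum)
  sites <- (origin - n):(origin + n)
  probs <- numeric(length(sites))
  probs[match(as.integer(names(agg)) + origin, sites)] <- as.numeric(agg)
  list(sites = sites, probabilities = probs)
}

gaussian_density <- function(x, mean = 0, sd = 1) {
  exp(-(x - mean)^2 / (2 * sd^2)) / sqrt(2 * pi * sd^2)
}

# Discrete L2 norm of a pde_solution field row by trapezoid quadrature.
field_l2_norm <- function(solution, row) {
  v <- solution$field[row, ]
  n <- length(solution$grid)
  sqrt(sum(diff(solution$grid) * (v[-1]^2 + v[-n]^2) / 2))
}
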