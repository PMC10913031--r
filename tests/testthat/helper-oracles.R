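# Brute-force oracles, deliberately independent of the analytic code paths
# they check.

# Parameter set with a prescribed effective coefficient a = a0 (T - T0),
# built so that T >= 0 always holds.
par_a <- function(a, h_int = 0, h_ext = 0, b = 1) {
  model_parameters(h_ext = h_ext, h_int = h_int, a0 = 1, b = b,
                   T = max(a, 0), T0 = max(a, 0) - a)
}

# Root bound used by the grid oracles.
phi_bound <- function(params) {
  a <- params$a0 * (params$T - params$T0)
  1 + (abs(a) + abs(params$h_int) + abs(params$h_ext)) / params$b
}

# Polynomial gradient evaluated directly (no package call).
oracle_gradient <- function(phi, params) {
  a <- params$a0 * (params$T - params$T0)
  -params$h_ext + a * phi + params$h_int * phi^2 + params$b * phi^3
}

oracle_energy <- function(phi, params) {
  a <- params$a0 * (params$T - params$T0)
  -params$h_ext * phi + a / 2 * phi^2 + params$h_int / 3 * phi^3 +
    params$b / 4 * phi^4
}

# Sign-change scan of the gradient on a dense grid: brackets of all simple
# real roots, refined by uniroot.
grid_roots <- function(params, n = 20001) {
  bound <- phi_bound(params)
  x <- seq(-bound, bound, length.out = n)
  g <- oracle_gradient(x, params)
  idx <- which(g[-1] * g[-n] < 0)
  vapply(idx, function(i) {
    stats::uniroot(oracle_gradient, c(x[i], x[i + 1]), params = params,
                   tol = 1e-12)$root
  }, numeric(1))
}

# Local minima of F located on a dense grid (positions and values).
grid_minima <- function(params, n = 40001) {
  bound <- phi_bound(params)
  x <- seq(-bound, bound, length.out = n)
  y <- oracle_energy(x, params)
  i <- which(diff(sign(diff(y))) > 0) + 1
  data.frame(phi = x[i], F = y[i])
}

mirror_params <- function(params) {
  model_parameters(h_ext = -params$h_ext, h_int = -params$h_int,
                   a0 = params$a0, b = params$b, T = params$T,
                   T0 = params$T0)
}
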