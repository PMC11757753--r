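# Shared fixtures for the test suite. Everything is generated in code;
# seeds are fixed so every run sees identical samples.

default_diff <- function() diffusion_spec(1, 10)

# single-node unregulated circuit: f(x) = b - mu x
unregulated_params <- function(b = 1, mu = 0.5) {
  top <- hill_topology(matrix(0L, 1, 1))
  hill_params(top, b = b, V = 1, K = 1, mu = mu)
}

# single self-activator, bistable for the chosen parameters
self_activator_params <- function(b = 0.05, V = 1, K = 0.5, n = 2, mu = 1) {
  top <- hill_topology(matrix(1L, 1, 1))
  hill_params(top, b = b, V = V, K = K, n = n, mu = mu)
}

# brute-force 1-d root count by sign-change scan + bisection refinement
scan_roots_1d <- function(f, lower = 1e-6, upper = 20, n_grid = 20000) {
  xs <- seq(lower, upper, length.out = n_grid)
  fx <- vapply(xs, f, numeric(1))
  sign_change <- which(fx[-1] * fx[-n_grid] < 0)
  vapply(sign_change, function(i)
    stats::uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-12)$root, numeric(1))
}

# central finite-difference Jacobian of a vector-valued function
fd_jacobian <- function(f, x, h_rel = 1e-6) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    h <- h_rel * max(abs(x[j]), 1)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}
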