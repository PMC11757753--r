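#' Closed-form oracles for the random-matrix analysis
#'
#' Small exact results used as independent checks on the numerical
#' pipeline (and exposed through [run_selftest()]).
#'
#' `outlier_trace_bound()` gives the eigenvalue sum of `J(k)` for the
#' fixed -1 diagonal ensemble, `-N - k^2 (D1 + D2)`: the trace is
#' invariant under diagonalization, so diffusion pushes outlier
#' eigenvalues towards this increasingly negative bound.
#'
#' @param n_nodes Network size N (fixed -1 diagonal assumed).
#' @param diff A [diffusion_spec()].
#' @param k Wave number(s).
#' @return Numeric vector of eigenvalue sums.
#' @examples
#' outlier_trace_bound(100, diffusion_spec(1, 10), 2)  # -144
#' @export
outlier_trace_bound <- function(n_nodes, diff, k) {
  stopifnot(inherits(diff, "diffusion_spec"))
  -n_nodes - k^2 * (diff$d1 + diff$d2)
}

#' Two-node determinant of J(k): no Turing instability for N = 2
#'
#' For the two-node ensemble with fixed -1 diagonals,
#' `Det_k = (1 + D1 k^2)(1 + D2 k^2) - g12 g21
#'        = Det_0 + (D1 + D2) k^2 + D1 D2 k^4`,
#' which stays positive whenever `Det_0 = 1 - g12 g21 > 0` (stability
#' without diffusion). A sign change of the determinant is the only route
#' to a diffusion-driven instability in two dimensions, so no Turing
#' class can ever arise at N = 2 in this ensemble.
#'
#' @param g12,g21 Off-diagonal interaction strengths.
#' @inheritParams outlier_trace_bound
#' @return `Det_k`, vectorized over `k`.
#' @examples
#' two_node_determinant(1, 0.5, diffusion_spec(1, 10), 1)  # 21.5
#' @export
two_node_determinant <- function(g12, g21, diff, k) {
  stopifnot(inherits(diff, "diffusion_spec"))
  (1 + diff$d1 * k^2) * (1 + diff$d2 * k^2) - g12 * g21
}

#' Finite-N eigenvalue density at the stability edge
#'
#' Two-term expansion of the real-axis-projected eigenvalue density at
#' `x = 0` for radius `gamma >= 1`:
#' `rho(0) ~ (1/pi) sqrt(gamma^2 - 1) (1 - 1/(2 gamma^2 N))`.
#' The negative 1/N correction suppresses marginally stable matrices at
#' small N — the finite-size effect behind the interior optimum of the
#' Turing-I frequency. For `gamma < 1` the eigenvalue disk does not reach
#' the axis and the density is 0.
#'
#' @param gamma Circular-law radius.
#' @param n_nodes Network size (use `Inf` for the asymptotic value).
#' @return Nonnegative density value.
#' @export
edge_density_rho0 <- function(gamma, n_nodes) {
  if (gamma < 1) return(0)
  (1 / pi) * sqrt(gamma^2 - 1) * (1 - 1 / (2 * gamma^2 * n_nodes))
}

#' Number of signed network topologies of size N
#'
#' Each of the N diagonal self-edges takes one of 3 states and each of
#' the `choose(N, 2)` node pairs one of 9 joint states, giving
#' `3^N * 9^choose(N, 2)` — superexponential growth that motivates the
#' statistical (random-matrix) treatment over enumeration.
#'
#' @param n_nodes Network size (N >= 1).
#' @return Exact count (numeric; exceeds integer range quickly).
#' @examples
#' topology_count(2)  # 81
#' @export
topology_count <- function(n_nodes) {
  stopifnot(n_nodes >= 1)
  3^n_nodes * 9^choose(n_nodes, 2)
}
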