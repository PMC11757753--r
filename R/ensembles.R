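#' Specify a random Jacobian ensemble
#'
#' An ensemble follows May's "neutral interaction" construction
#' \eqn{J_0 = G - I}: off-diagonal interaction strengths \eqn{g_{ij}} are
#' independent zero-mean Gaussians with variance \eqn{\sigma^2}, each kept
#' with probability `connectivity` (Bernoulli sparsity mask), and the
#' diagonal models first-order degradation. Diagonal variants cover the
#' full-Gaussian and antisymmetric (mass-conservation-like) ensembles.
#'
#' @param n_nodes Number of molecular species \eqn{N} (at least 2).
#' @param sigma2 Variance \eqn{\sigma^2} of the Gaussian off-diagonal
#'   interaction strengths (must be positive).
#' @param connectivity Probability \eqn{C} that an off-diagonal element is
#'   nonzero; `1 - connectivity` is the sparsity. Must lie in (0, 1].
#' @param diagonal_mode One of `"fixed_minus_one"` (all diagonal entries
#'   -1, the default degradation model), `"gaussian"` (Gaussian diagonal,
#'   no fixed degradation), `"gaussian_plus_fixed"` (Gaussian diagonal
#'   shifted by -1), or `"antisymmetric_fixed"` (antisymmetric
#'   off-diagonals \eqn{g_{ij} = -g_{ji}}, diagonal -1).
#' @param seed Optional integer seed recorded with the spec; surveys use it
#'   as the root of their per-cell substreams. `sample_jacobian()` itself
#'   always draws from the current RNG state.
#' @return An object of class `"ensemble_spec"`.
#' @seealso [sample_jacobian()], [predicted_radius()]
#' @examples
#' spec <- ensemble_spec(n_nodes = 5, sigma2 = 0.2)
#' predicted_radius(spec)  # 1: the circular-law radius sigma * sqrt(N C)
#' @export
ensemble_spec <- function(n_nodes, sigma2, connectivity = 1,
                          diagonal_mode = c("fixed_minus_one", "gaussian",
                                            "gaussian_plus_fixed",
                                            "antisymmetric_fixed"),
                          seed = NULL) {
  diagonal_mode <- match.arg(diagonal_mode)
  n_nodes <- as.integer(n_nodes)
  if (length(n_nodes) != 1L || is.na(n_nodes) || n_nodes < 2L)
    stop("`n_nodes` must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 <= 0)
    stop("`sigma2` must be a single positive number", call. = FALSE)
  if (!is.numeric(connectivity) || length(connectivity) != 1L ||
      connectivity <= 0 || connectivity > 1)
    stop("`connectivity` must lie in (0, 1]", call. = FALSE)
  structure(
    list(n_nodes = n_nodes, sigma2 = sigma2,
         connectivity = connectivity, diagonal_mode = diagonal_mode,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat("Random Jacobian ensemble J0 = G - I\n")
  cat(sprintf("  N = %d, sigma^2 = %g, connectivity C = %g\n",
              x$n_nodes, x$sigma2, x$connectivity))
  cat(sprintf("  diagonal: %s;  circular-law radius gamma = %.4g\n",
              x$diagonal_mode, predicted_radius(x)))
  if (!is.na(x$seed)) cat(sprintf("  root seed: %d\n", x$seed))
  invisible(x)
}

#' Specify the diffusion matrix D = diag(D1, D2, 0, ..., 0)
#'
#' Only the first two species diffuse; all remaining nodes are immobile
#' (\eqn{D_i = 0}), mirroring Turing's original two-morphogen setup
#' embedded in a larger reaction network.
#'
#' @param d1,d2 Positive diffusion constants of species 1 and 2.
#' @return An object of class `"diffusion_spec"`.
#' @examples
#' diffusion_spec()  # the default D = diag(1, 10, 0, ...)
#' @export
diffusion_spec <- function(d1 = 1, d2 = 10) {
  if (!is.numeric(d1) || !is.numeric(d2) || length(d1) != 1L ||
      length(d2) != 1L || d1 <= 0 || d2 <= 0)
    stop("diffusion constants must be single positive numbers", call. = FALSE)
  structure(list(d1 = d1, d2 = d2), class = "diffusion_spec")
}

#' @export
print.diffusion_spec <- function(x, ...) {
  cat(sprintf("Diffusion D = diag(%g, %g, 0, ...): two diffusers, rest immobile\n",
              x$d1, x$d2))
  invisible(x)
}

# full diffusion-constant vector of length N
diffusion_vector <- function(diff, n_nodes) {
  stopifnot(inherits(diff, "diffusion_spec"), n_nodes >= 2)
  c(diff$d1, diff$d2, rep(0, n_nodes - 2L))
}

#' Draw one random Jacobian from an ensemble
#'
#' Off-diagonal elements are i.i.d. `N(0, sigma2)` draws, independently
#' zeroed with probability `1 - connectivity`; the diagonal follows the
#' spec's `diagonal_mode`. The draw consumes the current R RNG state, so
#' `set.seed()` gives bit-for-bit reproducibility.
#'
#' @param spec An [ensemble_spec()].
#' @param mask Optional fixed logical `N x N` connectivity mask to use
#'   instead of resampling the Bernoulli mask per matrix (diagonal of the
#'   mask is ignored). Default `NULL` resamples per matrix.
#' @return An `N x N` numeric matrix.
#' @examples
#' set.seed(1)
#' j0 <- sample_jacobian(ensemble_spec(3, sigma2 = 0.33))
#' diag(j0)  # all -1
#' @export
sample_jacobian <- function(spec, mask = NULL) {
  stopifnot(inherits(spec, "ensemble_spec"))
  n <- spec$n_nodes
  sigma <- sqrt(spec$sigma2)
  if (spec$diagonal_mode == "antisymmetric_fixed") {
    g <- matrix(0, n, n)
    up <- upper.tri(g)
    g[up] <- rnorm(sum(up), sd = sigma)
    if (spec$connectivity < 1) {
      keep <- if (is.null(mask)) runif(sum(up)) < spec$connectivity
              else mask[up]
      g[up][!keep] <- 0
    }
    g <- g - t(g)
    diag(g) <- -1
    return(g)
  }
  g <- matrix(rnorm(n * n, sd = sigma), n, n)
  if (spec$connectivity < 1) {
    keep <- if (is.null(mask)) matrix(runif(n * n) < spec$connectivity, n, n)
            else mask
    g[!keep] <- 0
  }
  switch(spec$diagonal_mode,
    fixed_minus_one = { diag(g) <- -1 },
    gaussian = { diag(g) <- rnorm(n, sd = sigma) },
    gaussian_plus_fixed = { diag(g) <- rnorm(n, sd = sigma) - 1 })
  g
}

#' Draw a batch of random Jacobians as a 3-d array
#'
#' Equivalent to `n` successive [sample_jacobian()] calls (identical RNG
#' stream), packed into an `N x N x n` array for the batch classifiers.
#'
#' @inheritParams sample_jacobian
#' @param n Number of matrices.
#' @return An `N x N x n` numeric array.
#' @export
sample_jacobians <- function(spec, n, mask = NULL) {
  stopifnot(n >= 1)
  out <- array(0, c(spec$n_nodes, spec$n_nodes, n))
  for (s in seq_len(n)) out[, , s] <- sample_jacobian(spec, mask = mask)
  out
}

#' Circular-law radius of an ensemble
#'
#' The eigenvalues of the interaction part `G` concentrate (asymptotically
#' uniformly) in a disk of radius \eqn{\gamma = \sigma\sqrt{NC}}; with the
#' fixed -1 diagonal the disk is centred at -1, so \eqn{\gamma = 1} marks
#' the onset of marginal stability.
#'
#' @param spec An [ensemble_spec()].
#' @return The radius \eqn{\sigma\sqrt{NC}}.
#' @export
predicted_radius <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  sqrt(spec$sigma2 * spec$n_nodes * spec$connectivity)
}

#' Interaction variance giving a target circular-law radius
#'
#' Inverts [predicted_radius()]: returns \eqn{\sigma^2 = \gamma^2/(NC)}.
#'
#' @param n_nodes Network size \eqn{N}.
#' @param connectivity Connectivity \eqn{C} in (0, 1].
#' @param gamma Target radius (positive).
#' @return The variance \eqn{\sigma^2}.
#' @export
sigma2_for_radius <- function(n_nodes, connectivity = 1, gamma) {
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  nc <- n_nodes * connectivity
  if (nc <= 0) stop("n_nodes * connectivity must be positive", call. = FALSE)
  gamma^2 / nc
}

#' Read / write ensemble configurations
#'
#' Flat YAML files with keys `n_nodes`, `sigma2`, `connectivity`,
#' `diagonal_mode`, `seed`, `D1`, `D2`, round-tripping an ensemble spec
#' together with its diffusion constants.
#'
#' @param path File path.
#' @return `read_ensemble_config()` returns a list with elements `spec`
#'   (an [ensemble_spec()]) and `diff` (a [diffusion_spec()]);
#'   `write_ensemble_config()` returns `path` invisibly.
#' @export
read_ensemble_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  needed <- c("n_nodes", "sigma2", "connectivity", "diagonal_mode", "D1", "D2")
  missing <- setdiff(needed, names(cfg))
  if (length(missing))
    stop("config is missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  list(spec = ensemble_spec(cfg$n_nodes, cfg$sigma2, cfg$connectivity,
                            cfg$diagonal_mode, seed = cfg$seed),
       diff = diffusion_spec(cfg$D1, cfg$D2))
}

#' @rdname read_ensemble_config
#' @param spec An [ensemble_spec()].
#' @param diff A [diffusion_spec()].
#' @export
write_ensemble_config <- function(spec, diff, path) {
  stopifnot(inherits(spec, "ensemble_spec"), inherits(diff, "diffusion_spec"))
  yaml::write_yaml(
    list(n_nodes = spec$n_nodes, sigma2 = spec$sigma2,
         connectivity = spec$connectivity, diagonal_mode = spec$diagonal_mode,
         seed = if (is.na(spec$seed)) NULL else spec$seed,
         D1 = diff$d1, D2 = diff$d2),
    path)
  invisible(path)
}
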