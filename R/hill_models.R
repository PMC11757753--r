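#' Signed network topology for Hill-function gene circuits
#'
#' The adjacency matrix is oriented like the Jacobian: `adjacency[i, j]`
#' is the sign of the regulation of node `i` by node `j` (+1 activation,
#' -1 inhibition, 0 absent). Self-edges are permitted. Nodes 1 and 2 are
#' the diffusing species by convention.
#'
#' @param adjacency Integer matrix with entries in -1, 0, 1.
#' @param names Optional node names.
#' @return An object of class `"hill_topology"`.
#' @examples
#' topology_gierer_meinhardt()
#' @export
hill_topology <- function(adjacency, names = NULL) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency))
    stop("`adjacency` must be square", call. = FALSE)
  if (!all(adjacency %in% c(-1, 0, 1)))
    stop("adjacency entries must be -1, 0 or +1", call. = FALSE)
  storage.mode(adjacency) <- "integer"
  n <- nrow(adjacency)
  if (is.null(names)) names <- paste0("node", seq_len(n))
  dimnames(adjacency) <- list(names, names)
  structure(list(n_nodes = n, adjacency = adjacency, names = names),
            class = "hill_topology")
}

#' @export
print.hill_topology <- function(x, ...) {
  cat(sprintf("Hill-circuit topology: %d nodes, %d signed edges (%d +, %d -)\n",
              x$n_nodes, sum(x$adjacency != 0), sum(x$adjacency == 1),
              sum(x$adjacency == -1)))
  print(x$adjacency)
  invisible(x)
}

#' Example topologies
#'
#' `topology_gierer_meinhardt()` is the classic two-node
#' activator-inhibitor circuit: the activator (node 1) activates itself
#' and the inhibitor, and the inhibitor represses the activator and
#' itself. The 3- and 4-node examples extend it with immobile downstream
#' nodes closing additional feedback loops; they are illustrative
#' circuits in the same design family, not transcriptions of any
#' particular published synthetic circuit.
#'
#' @return A [hill_topology()].
#' @export
topology_gierer_meinhardt <- function() {
  hill_topology(matrix(c(1, -1,
                         1, -1), 2, 2, byrow = TRUE),
                names = c("activator", "inhibitor"))
}

#' @rdname topology_gierer_meinhardt
#' @export
topology_three_node <- function() {
  read_topology(system.file("extdata", "topology_3node.txt",
                            package = "turingnet"))
}

#' @rdname topology_gierer_meinhardt
#' @export
topology_four_node <- function() {
  read_topology(system.file("extdata", "topology_4node.txt",
                            package = "turingnet"))
}

#' Read / write topology files
#'
#' Plain-text format: a header line of whitespace-separated node names
#' followed by the signed adjacency matrix, one row per line (row i =
#' regulated node i, column j = regulator j). Lines starting with `#` are
#' comments.
#'
#' @param path File path.
#' @return `read_topology()` returns a [hill_topology()].
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  nm <- strsplit(lines[1L], "\\s+")[[1L]]
  rows <- lapply(lines[-1L], function(l) as.integer(strsplit(l, "\\s+")[[1L]]))
  adj <- do.call(rbind, rows)
  if (nrow(adj) != length(nm) || ncol(adj) != length(nm))
    stop("adjacency block does not match the header names", call. = FALSE)
  hill_topology(adj, names = nm)
}

#' @rdname read_topology
#' @param topology A [hill_topology()].
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "hill_topology"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(topology$names, collapse = "\t"), con)
  apply(topology$adjacency, 1L, function(r)
    writeLines(paste(r, collapse = "\t"), con))
  invisible(path)
}

#' Kinetic parameters of a Hill-function circuit
#'
#' Holds the parameter set theta = (b, V, K, n, mu): basal rates,
#' maximal rates, per-edge thresholds, per-edge Hill coefficients and
#' degradation rates, all strictly positive (arbitrary units).
#'
#' @param topology A [hill_topology()].
#' @param b,V,mu Positive numeric vectors, one entry per node.
#' @param K Positive matrix of thresholds, entries required wherever
#'   `topology$adjacency` is nonzero (a scalar is recycled).
#' @param n Hill coefficients, same layout as `K` (default 2 everywhere).
#' @return An object of class `"hill_params"`.
#' @export
hill_params <- function(topology, b, V, K, n = 2, mu) {
  stopifnot(inherits(topology, "hill_topology"))
  N <- topology$n_nodes
  for (v in list(b = b, V = V, mu = mu))
    if (length(v) != N || any(v <= 0))
      stop("b, V and mu must be positive vectors of length n_nodes",
           call. = FALSE)
  edge <- topology$adjacency != 0L
  if (length(K) == 1L) K <- matrix(K, N, N)
  if (length(n) == 1L) n <- matrix(n, N, N)
  if (any(K[edge] <= 0) || any(n[edge] <= 0))
    stop("K and n must be positive on every edge", call. = FALSE)
  K[!edge] <- 0
  n[!edge] <- 0
  structure(list(b = b, V = V, K = K, n = n, mu = mu, topology = topology),
            class = "hill_params")
}

#' Right-hand side of the Hill-circuit ODEs
#'
#' `f_i = b_i + V_i * prod_j h_ij(x_j) - mu_i x_i`, where each regulator
#' contributes a saturating factor `x^n/(x^n + K^n)` (activation) or
#' `K^n/(x^n + K^n)` (repression); regulators act multiplicatively
#' (non-competitive binding).
#'
#' @param params A [hill_params()].
#' @param x Strictly positive concentration vector.
#' @return Numeric vector of time derivatives.
#' @export
hill_rhs <- function(params, x) {
  stopifnot(inherits(params, "hill_params"))
  if (any(x <= 0)) stop("`x` must be strictly positive", call. = FALSE)
  as.numeric(hill_rhs_cpp(params$topology$adjacency, params$K, params$n,
                          params$b, params$V, params$mu, x))
}

#' Analytic Jacobian of the Hill-circuit ODEs
#'
#' Closed-form derivatives `J_ij = df_i/dx_j`; absent edges give exact
#' structural zeros, and the diagonal carries `-mu_i` plus any self-edge
#' term.
#'
#' @inheritParams hill_rhs
#' @return `N x N` numeric matrix.
#' @export
hill_jacobian <- function(params, x) {
  stopifnot(inherits(params, "hill_params"))
  if (any(x <= 0)) stop("`x` must be strictly positive", call. = FALSE)
  hill_jac_cpp(params$topology$adjacency, params$K, params$n,
               params$b, params$V, params$mu, x)
}

#' Steady states of a Hill circuit by multi-start Newton-Raphson
#'
#' Runs a damped Newton-Raphson root search (analytic Jacobian,
#' positivity-preserving step halving) from `n_guesses` loguniform
#' initial points in `[1e-3, 1e2]` per coordinate, keeps strictly
#' positive converged roots with residual below `tol`, and deduplicates
#' roots closer than `dedup_tol` in relative max norm.
#'
#' @inheritParams hill_rhs
#' @param n_guesses Number of initial guesses (protocol default 10).
#' @param seed Seed for the initial guesses.
#' @param tol Convergence tolerance on the max-norm residual.
#' @param dedup_tol Relative max-norm radius treated as the same root.
#' @return List with `states` (matrix, one steady state per row, possibly
#'   zero rows) and `converged` (logical per guess).
#' @examples
#' top <- hill_topology(matrix(0, 1, 1))
#' p <- hill_params(top, b = 1, V = 1, K = 1, mu = 0.5)
#' find_steady_states(p)$states  # single root at x = b / mu = 2
#' @export
find_steady_states <- function(params, n_guesses = 10, seed = 1,
                               tol = 1e-9, dedup_tol = 1e-4) {
  stopifnot(inherits(params, "hill_params"))
  N <- params$topology$n_nodes
  set.seed(seed)
  guesses <- matrix(exp(runif(n_guesses * N, log(1e-3), log(1e2))),
                    n_guesses, N)
  res <- hill_steady_states_cpp(params$topology$adjacency, params$K,
                                params$n, params$b, params$V, params$mu,
                                guesses, tol = tol, dedup_tol = dedup_tol)
  list(states = res$states, converged = as.logical(res$converged))
}

#' Latin-hypercube sample of Hill-circuit parameter sets
#'
#' Loguniform Latin-hypercube stratification: each parameter's
#' `n_samples` values occupy distinct equal-probability bins in log
#' space. Default bounds: `V in (0.1, 10)`, `K in (0.01, 1)`,
#' `b in (0.001, 0.1)`, `mu in (0.01, 1)`; Hill coefficients are fixed
#' at `n = 2` and are not sampled.
#'
#' @param topology A [hill_topology()].
#' @param n_samples Number of parameter sets.
#' @param bounds Named list of `c(lo, hi)` bounds for `b`, `V`, `K`, `mu`.
#' @param seed RNG seed.
#' @return A numeric matrix with one parameter set per row; columns are
#'   `b_1..b_N, V_1..V_N, mu_1..mu_N`, then one `K` column per edge (in
#'   the column-major order of nonzero adjacency entries, see
#'   `attr(, "edges")`).
#' @export
lhs_sample <- function(topology, n_samples, bounds = hill_bounds(), seed = 1) {
  stopifnot(inherits(topology, "hill_topology"), n_samples >= 1)
  for (nm in c("b", "V", "K", "mu")) {
    bd <- bounds[[nm]]
    if (is.null(bd) || length(bd) != 2L || bd[1L] <= 0 || bd[1L] >= bd[2L])
      stop("invalid bounds for ", nm, ": need 0 < lo < hi", call. = FALSE)
  }
  N <- topology$n_nodes
  edges <- which(topology$adjacency != 0L, arr.ind = TRUE)
  edges <- edges[order(edges[, 2L], edges[, 1L]), , drop = FALSE]
  p <- 3L * N + nrow(edges)
  set.seed(seed)
  u <- lhs::randomLHS(n_samples, p)
  lo <- log(c(rep(bounds$b[1L], N), rep(bounds$V[1L], N),
              rep(bounds$mu[1L], N), rep(bounds$K[1L], nrow(edges))))
  hi <- log(c(rep(bounds$b[2L], N), rep(bounds$V[2L], N),
              rep(bounds$mu[2L], N), rep(bounds$K[2L], nrow(edges))))
  params <- exp(sweep(sweep(u, 2L, hi - lo, "*"), 2L, lo, "+"))
  colnames(params) <- c(paste0("b_", seq_len(N)), paste0("V_", seq_len(N)),
                        paste0("mu_", seq_len(N)),
                        if (nrow(edges)) paste0("K_", edges[, 1L], "_",
                                                edges[, 2L]))
  attr(params, "edges") <- edges
  attr(params, "bounds") <- bounds
  params
}

#' @rdname lhs_sample
#' @export
hill_bounds <- function() {
  list(V = c(0.1, 10), K = c(0.01, 1), b = c(0.001, 0.1), mu = c(0.01, 1))
}

# hill_params from one row of an lhs_sample matrix
params_from_row <- function(topology, row, edges, hill_n = 2) {
  N <- topology$n_nodes
  K <- matrix(0, N, N)
  if (nrow(edges))
    K[edges] <- row[3L * N + seq_len(nrow(edges))]
  hill_params(topology, b = row[seq_len(N)], V = row[N + seq_len(N)],
              K = K, n = hill_n, mu = row[2L * N + seq_len(N)])
}

#' Screen Latin-hypercube parameter sets for Turing instabilities
#'
#' For every sampled parameter set, finds all steady states
#' (multistability included: each steady state is classified
#' independently), evaluates the analytic Jacobian there, classifies the
#' resulting reaction-diffusion system, and emits one record per nonzero
#' Jacobian element.
#'
#' @inheritParams lhs_sample
#' @param diff A [diffusion_spec()] (default D = (1, 10)).
#' @param k_max,k_step Wave-number grid used for classification.
#' @param n_guesses Newton starts per parameter set.
#' @return An object of class `"hill_screen"`: list with `records` (data
#'   frame: `set_id`, `state_id`, `i`, `j`, `value`, `class`), `summary`
#'   (counts of steady states and classes) and the run settings.
#' @export
screen_models <- function(topology, n_samples, bounds = hill_bounds(),
                          diff = diffusion_spec(), k_max = 10, k_step = 0.05,
                          n_guesses = 10, seed = 1) {
  stopifnot(inherits(topology, "hill_topology"))
  N <- topology$n_nodes
  empty <- data.frame(set_id = integer(), state_id = integer(),
                      i = integer(), j = integer(), value = numeric(),
                      class = character())
  if (n_samples == 0)
    return(structure(list(records = empty,
                          summary = list(n_sets = 0L, n_states = 0L,
                                         class_counts = table(character())),
                          topology = topology, seed = seed),
                     class = "hill_screen"))
  params <- lhs_sample(topology, n_samples, bounds, seed = seed)
  edges <- attr(params, "edges")
  set.seed(cell_seed(seed, "screen-guesses", 1L))
  guesses <- matrix(exp(runif(n_samples * n_guesses * N, log(1e-3), log(1e2))),
                    n_samples * n_guesses, N)
  scr <- hill_screen_cpp(topology$adjacency,
                         matrix(2, N, N) * (topology$adjacency != 0L),
                         params, edges[, 1L] - 1L, edges[, 2L] - 1L,
                         guesses, n_guesses)
  n_states <- length(scr$set_id)
  if (n_states == 0)
    return(structure(list(records = empty,
                          summary = list(n_sets = n_samples, n_states = 0L,
                                         class_counts = table(character())),
                          topology = topology, seed = seed),
                     class = "hill_screen"))
  jm <- array(t(scr$jacobians), c(N, N, n_states))
  cls <- classify_jacobians(jm, diff, k_grid(k_max, k_step))
  state_id <- stats::ave(scr$set_id, scr$set_id, FUN = seq_along)
  nz <- which(topology$adjacency != 0L | diag(N) == 1, arr.ind = TRUE)
  records <- data.frame(
    set_id = rep(scr$set_id, each = nrow(nz)),
    state_id = rep(state_id, each = nrow(nz)),
    i = rep(nz[, 1L], n_states), j = rep(nz[, 2L], n_states),
    value = as.numeric(apply(jm, 3L, function(m) m[nz])),
    class = rep(cls, each = nrow(nz)))
  structure(
    list(records = records,
         summary = list(n_sets = n_samples, n_states = n_states,
                        class_counts = table(cls)),
         topology = topology, diff = diff, seed = seed,
         states = scr$states, classes = cls),
    class = "hill_screen")
}

#' @export
print.hill_screen <- function(x, ...) {
  cat(sprintf("Hill-circuit screen: %d parameter sets, %d steady states\n",
              x$summary$n_sets, x$summary$n_states))
  print(x$summary$class_counts)
  invisible(x)
}

#' Write screen records as CSV
#'
#' @param screen A `"hill_screen"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_screen_csv <- function(screen, path) {
  stopifnot(inherits(screen, "hill_screen"))
  old <- options(digits = 17)
  on.exit(options(old))
  write.csv(screen$records, path, row.names = FALSE)
  invisible(path)
}
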