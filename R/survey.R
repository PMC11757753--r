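#' @title Monte-Carlo surveys of Turing instability occurrence
#' @name surveys
#' @description
#' The survey functions sample `n_samples` random Jacobians per grid cell,
#' classify each with the dispersion machinery, and tabulate counts and
#' percentages per instability class. Cells draw from independent,
#' deterministically derived RNG substreams keyed by the root seed and the
#' cell index, so any single cell can be reproduced in isolation and the
#' result is independent of execution order.
NULL

# deterministic per-cell substream seed (kept below 2^31)
cell_seed <- function(root_seed, experiment, idx) {
  h <- sum(utf8ToInt(experiment) * seq_along(utf8ToInt(experiment))) %% 99991L
  as.integer((as.double(root_seed) + 104729 * idx + 7919 * h) %% 2147483629)
}

# classify one cell's worth of samples; returns counts named by class
survey_cell_counts <- function(n_nodes, sigma2, connectivity, diagonal_mode,
                               d_values, grid, n_samples, seed) {
  spec <- ensemble_spec(n_nodes, sigma2, connectivity, diagonal_mode)
  set.seed(seed)
  jm <- sample_jacobians(spec, n_samples)
  d <- c(d_values, rep(0, n_nodes - 2L))
  s <- dispersion_summary_cpp(jm, d, grid)
  cls <- classify_summary(s)
  counts <- table(factor(cls, levels = TURING_CLASSES))
  as.integer(counts)
}

# shared driver: `cells` is a data.frame with one row per cell holding
# n_nodes, sigma2, gamma, d1, d2; returns the long-format survey_grid
run_cells <- function(cells, connectivity, diagonal_mode, n_samples,
                      k_max, k_step, seed, experiment, quiet = TRUE) {
  grid <- k_grid(k_max, k_step)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    counts <- survey_cell_counts(
      cells$n_nodes[i], cells$sigma2[i], connectivity, diagonal_mode,
      c(cells$d1[i], cells$d2[i]), grid, n_samples,
      cell_seed(seed, experiment, i))
    rows[[i]] <- data.frame(
      cells[i, , drop = FALSE], class = TURING_CLASSES, count = counts,
      percentage = 100 * counts / n_samples, row.names = NULL)
    if (!quiet)
      message(sprintf("[%s] cell %d/%d (N=%d, sigma2=%.4g) done",
                      experiment, i, nrow(cells), cells$n_nodes[i],
                      cells$sigma2[i]))
  }
  structure(
    list(cells = do.call(rbind, rows),
         experiment = experiment, n_samples = n_samples, seed = seed,
         connectivity = connectivity, diagonal_mode = diagonal_mode,
         k_max = k_max, k_step = k_step),
    class = "survey_grid")
}

#' @export
print.survey_grid <- function(x, ...) {
  n_cells <- nrow(x$cells) / length(TURING_CLASSES)
  cat(sprintf("Turing survey '%s': %d cells x %d samples (seed %d)\n",
              x$experiment, n_cells, x$n_samples, x$seed))
  cat(sprintf("  connectivity C = %g, diagonal %s, k in [0, %g] step %g\n",
              x$connectivity, x$diagonal_mode, x$k_max, x$k_step))
  ti <- x$cells[x$cells$class == "turing_I", ]
  if (nrow(ti)) {
    best <- ti[which.max(ti$percentage), ]
    cat(sprintf("  max Turing I: %.2f%% at N=%d, sigma^2=%.4g\n",
                best$percentage, best$n_nodes, best$sigma2))
  }
  invisible(x)
}

#' Stability survey over network size and circular-law radius
#'
#' Reproduces the (N, gamma) stability scan: per cell it reports the
#' percentage of matrices stable without diffusion, the percentages in
#' each Turing class out of all samples, and (via
#' [survey_percentages()]) the share of previously stable systems turning
#' unstable once diffusion is added.
#'
#' @param n_values Network sizes to scan.
#' @param gamma_values Circular-law radii; each cell uses
#'   \eqn{\sigma^2 = \gamma^2/(NC)}.
#' @param diff A [diffusion_spec()] (default D = (1, 10)).
#' @param n_samples Random matrices per cell (default 1000).
#' @param seed Root seed for the per-cell substreams.
#' @param connectivity Connectivity C of the ensemble.
#' @param diagonal_mode Diagonal variant, see [ensemble_spec()].
#' @param k_max,k_step Wave-number grid (survey default step 0.05).
#' @param quiet Suppress per-cell progress messages.
#' @return A `"survey_grid"` object; `$cells` is a long data frame with
#'   one row per cell per class (`n_nodes`, `sigma2`, `gamma`, `d1`,
#'   `d2`, `class`, `count`, `percentage`).
#' @export
run_stability_survey <- function(n_values, gamma_values,
                                 diff = diffusion_spec(), n_samples = 1000,
                                 seed = 1, connectivity = 1,
                                 diagonal_mode = "fixed_minus_one",
                                 k_max = 10, k_step = 0.05, quiet = TRUE) {
  cells <- expand.grid(n_nodes = as.integer(n_values), gamma = gamma_values)
  cells$sigma2 <- cells$gamma^2 / (cells$n_nodes * connectivity)
  cells$d1 <- diff$d1
  cells$d2 <- diff$d2
  run_cells(cells, connectivity, diagonal_mode, n_samples, k_max, k_step,
            seed, "stability", quiet)
}

#' Turing-I heat map over network size and interaction variance
#'
#' The per-N variance scan behind the optimal-network-size analysis. For
#' each N the scanned variances correspond to radii `gamma_values`
#' (default 15 log-spaced points in 0.7 to 1.5, bracketing the critical
#' radius gamma = 1 where the eigenvalue disk touches the imaginary
#' axis). The per-N robustness statistic is the peak Turing-I percentage
#' over the variance axis, extracted by [extract_optimal_size()].
#'
#' @inheritParams run_stability_survey
#' @export
run_size_variance_heatmap <- function(n_values = 2:12,
                                      gamma_values = exp(seq(log(0.7),
                                                             log(1.5),
                                                             length.out = 15)),
                                      diff = diffusion_spec(),
                                      n_samples = 1000, seed = 1,
                                      connectivity = 1,
                                      diagonal_mode = "fixed_minus_one",
                                      k_max = 10, k_step = 0.05,
                                      quiet = TRUE) {
  cells <- expand.grid(n_nodes = as.integer(n_values), gamma = gamma_values)
  cells$sigma2 <- cells$gamma^2 / (cells$n_nodes * connectivity)
  cells$d1 <- diff$d1
  cells$d2 <- diff$d2
  run_cells(cells, connectivity, diagonal_mode, n_samples, k_max, k_step,
            seed, "heatmap", quiet)
}

#' Turing-I heat map over the two diffusion constants
#'
#' Scans (D1, D2) at fixed network size and variance; used to probe how
#' immobile nodes relax the differential-diffusivity requirement. The
#' resulting map is symmetric under swapping D1 and D2 (activator /
#' inhibitor labels are arbitrary) up to sampling error.
#'
#' @inheritParams run_stability_survey
#' @param n_nodes Network size N.
#' @param sigma2 Interaction variance.
#' @param d1_values,d2_values Positive diffusion constants to scan.
#' @export
run_diffusion_grid <- function(n_nodes, sigma2, d1_values, d2_values,
                               n_samples = 1000, seed = 1, connectivity = 1,
                               diagonal_mode = "fixed_minus_one",
                               k_max = 10, k_step = 0.05, quiet = TRUE) {
  if (any(d1_values <= 0) || any(d2_values <= 0))
    stop("diffusion constants must stay strictly positive", call. = FALSE)
  cells <- expand.grid(n_nodes = as.integer(n_nodes), gamma = NA_real_,
                       d1 = d1_values, d2 = d2_values)
  cells$sigma2 <- sigma2
  cells$gamma <- sqrt(sigma2 * n_nodes * connectivity)
  run_cells(cells[, c("n_nodes", "gamma", "sigma2", "d1", "d2")],
            connectivity, diagonal_mode, n_samples, k_max, k_step, seed,
            "diffusion-grid", quiet)
}

#' Class percentages, unconditional or conditional on k = 0 stability
#'
#' `of = "all"` returns percentages of all sampled matrices (stored on
#' the grid); `of = "stable_at_k0"` returns the share of previously
#' stable systems (stable at k = 0) that end up in each class once
#' diffusion is added, the quantity plotted in diffusion-driven
#' "turning unstable" panels.
#'
#' @param grid A `"survey_grid"`.
#' @param of Denominator choice.
#' @return The `$cells` data frame with `percentage` recomputed.
#' @export
survey_percentages <- function(grid, of = c("all", "stable_at_k0")) {
  of <- match.arg(of)
  stopifnot(inherits(grid, "survey_grid"))
  cells <- grid$cells
  if (of == "all") return(cells)
  key <- interaction(cells$n_nodes, cells$sigma2, cells$d1, cells$d2,
                     drop = TRUE)
  stable0 <- cells$class != "unstable_without_diffusion"
  denom <- tapply(cells$count * stable0, key, sum)[key]
  cells$percentage <- ifelse(denom > 0, 100 * cells$count / denom, NA_real_)
  cells[cells$class != "unstable_without_diffusion", ]
}

#' Optimal network size from a size-variance heat map
#'
#' For each network size, takes the peak Turing-I percentage over the
#' scanned variance axis (and, for reference, the mean over the axis),
#' then reports the N attaining the largest peak.
#'
#' @param grid A `"survey_grid"` from [run_size_variance_heatmap()].
#' @return An object of class `"optimal_size"`: list with `per_n` (data
#'   frame of N, peak percentage, variance at the peak, mean percentage),
#'   `n_opt`, `peak_percentage`, and `interior` (whether the argmax is
#'   away from both ends of the scanned range).
#' @export
extract_optimal_size <- function(grid) {
  stopifnot(inherits(grid, "survey_grid"))
  ti <- grid$cells[grid$cells$class == "turing_I", ]
  if (!nrow(ti)) stop("grid holds no Turing-I rows", call. = FALSE)
  per_n <- do.call(rbind, lapply(split(ti, ti$n_nodes), function(d) {
    i <- which.max(d$percentage)
    data.frame(n_nodes = d$n_nodes[1L], peak_percentage = d$percentage[i],
               sigma2_at_peak = d$sigma2[i],
               mean_percentage = mean(d$percentage))
  }))
  per_n <- per_n[order(per_n$n_nodes), ]
  rownames(per_n) <- NULL
  if (all(per_n$peak_percentage == 0)) {
    return(structure(list(per_n = per_n, n_opt = NA_integer_,
                          peak_percentage = 0, interior = FALSE),
                     class = "optimal_size"))
  }
  i <- which.max(per_n$peak_percentage)
  structure(
    list(per_n = per_n, n_opt = per_n$n_nodes[i],
         peak_percentage = per_n$peak_percentage[i],
         interior = i > 1L && i < nrow(per_n)),
    class = "optimal_size")
}

#' @export
print.optimal_size <- function(x, ...) {
  if (is.na(x$n_opt)) {
    cat("No Turing-I instabilities anywhere on the grid; no optimal size.\n")
    return(invisible(x))
  }
  cat(sprintf("Optimal network size N = %d (peak Turing I %.2f%%%s)\n",
              x$n_opt, x$peak_percentage,
              if (x$interior) "" else "; at a boundary of the scanned range"))
  print(x$per_n, digits = 4)
  invisible(x)
}

#' Re-measure one survey cell at higher sampling depth
#'
#' Convenience for tightening the binomial error of a single (N, sigma2)
#' cell, e.g. the peak cell found by [extract_optimal_size()]. Uses its
#' own seeded substream, independent of the original grid.
#'
#' @inheritParams run_stability_survey
#' @param n_nodes,sigma2 Cell coordinates.
#' @return Named numeric vector of class percentages for the cell.
#' @export
survey_cell <- function(n_nodes, sigma2, diff = diffusion_spec(),
                        n_samples = 10000, seed = 1, connectivity = 1,
                        diagonal_mode = "fixed_minus_one", k_max = 10,
                        k_step = 0.05) {
  counts <- survey_cell_counts(n_nodes, sigma2, connectivity, diagonal_mode,
                               c(diff$d1, diff$d2), k_grid(k_max, k_step),
                               n_samples, cell_seed(seed, "cell", 1L))
  stats::setNames(100 * counts / n_samples, TURING_CLASSES)
}

#' Write a survey grid as long-format CSV
#'
#' One row per cell per class (axes, class, count, percentage), floats at
#' full precision; pair with [write_manifest()] for reproducibility.
#'
#' @param grid A `"survey_grid"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(grid, path) {
  stopifnot(inherits(grid, "survey_grid"))
  old <- options(digits = 17)
  on.exit(options(old))
  write.csv(grid$cells, path, row.names = FALSE)
  invisible(path)
}
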