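#' Write a run manifest
#'
#' JSON record of everything needed to regenerate a result file
#' bit-identically: experiment name, resolved configuration (ensemble,
#' diffusion, wave-number grid, grid axes, seeds), package version,
#' timestamp and output paths.
#'
#' @param experiment Experiment name.
#' @param config Named list of resolved settings.
#' @param outputs Character vector of files the run wrote.
#' @param path Manifest file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(experiment, config, outputs, path) {
  jsonlite::write_json(
    list(experiment = experiment, config = config, outputs = outputs,
         package_version = as.character(packageVersion("turingnet")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# resolve a survey config list against defaults; unknown keys error so a
# typo cannot silently fall back to a default
resolve_config <- function(config, defaults) {
  extra <- setdiff(names(config), names(defaults))
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  modifyList(defaults, config)
}

#' Run a survey from a configuration file
#'
#' Drives one of the survey experiments from a YAML config and writes the
#' long-format CSV plus a JSON manifest next to it. Recognized
#' `experiment` values: `"stability"`, `"heatmap"`, `"diffusion-grid"`.
#' Remaining keys mirror the arguments of the corresponding
#' `run_*` function (`n_values`, `gamma_values`, `sigma2`, `d1_values`,
#' `d2_values`, `n_samples`, `seed`, `connectivity`, `diagonal_mode`,
#' `k_max`, `k_step`, `D1`, `D2`).
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed overriding the config's.
#' @param quiet Suppress progress messages.
#' @return The `"survey_grid"`, invisibly; side effect: CSV + manifest,
#'   and for heatmap runs an optimal-size summary CSV.
#' @export
run_survey_config <- function(config, out_dir = ".", seed = NULL,
                              quiet = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  experiment <- config$experiment
  if (is.null(experiment) ||
      !experiment %in% c("stability", "heatmap", "diffusion-grid"))
    stop("config key `experiment` must be one of stability, heatmap, ",
         "diffusion-grid", call. = FALSE)
  config$experiment <- NULL
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  base <- list(n_samples = 1000, seed = 1, connectivity = 1,
               diagonal_mode = "fixed_minus_one", k_max = 10, k_step = 0.05,
               D1 = 1, D2 = 10)
  grid <- switch(experiment,
    stability = {
      cfg <- resolve_config(config, c(base, list(
        n_values = c(2, 3, 4, 5, 6, 8, 10, 12, 15, 20, 30, 40, 50),
        gamma_values = seq(0.25, 1.5, by = 0.25))))
      run_stability_survey(cfg$n_values, cfg$gamma_values,
                           diffusion_spec(cfg$D1, cfg$D2), cfg$n_samples,
                           cfg$seed, cfg$connectivity, cfg$diagonal_mode,
                           cfg$k_max, cfg$k_step, quiet)
    },
    heatmap = {
      cfg <- resolve_config(config, c(base, list(
        n_values = 2:12,
        gamma_values = exp(seq(log(0.7), log(1.5), length.out = 15)))))
      run_size_variance_heatmap(cfg$n_values, cfg$gamma_values,
                                diffusion_spec(cfg$D1, cfg$D2),
                                cfg$n_samples, cfg$seed, cfg$connectivity,
                                cfg$diagonal_mode, cfg$k_max, cfg$k_step,
                                quiet)
    },
    `diffusion-grid` = {
      cfg <- resolve_config(config, c(base, list(
        n_nodes = 5, sigma2 = 0.2,
        d1_values = exp(seq(log(0.1), log(10), length.out = 7)),
        d2_values = exp(seq(log(0.1), log(10), length.out = 7)))))
      run_diffusion_grid(cfg$n_nodes, cfg$sigma2, cfg$d1_values,
                         cfg$d2_values, cfg$n_samples, cfg$seed,
                         cfg$connectivity, cfg$diagonal_mode, cfg$k_max,
                         cfg$k_step, quiet)
    })

  csv <- file.path(out_dir, paste0(experiment, "_survey.csv"))
  write_survey_csv(grid, csv)
  outputs <- csv
  if (experiment == "heatmap") {
    opt <- extract_optimal_size(grid)
    opt_csv <- file.path(out_dir, "optimal_size.csv")
    write.csv(opt$per_n, opt_csv, row.names = FALSE)
    outputs <- c(outputs, opt_csv)
    if (!quiet) print(opt)
  }
  write_manifest(experiment, cfg, outputs,
                 file.path(out_dir, paste0(experiment, "_manifest.json")))
  invisible(grid)
}

#' Run a Hill-circuit screen from a configuration file
#'
#' Keys: `topology` (path to a topology file, or one of the built-in
#' names `"gierer_meinhardt"`, `"three_node"`, `"four_node"`),
#' `n_samples`, `seed`, `n_guesses`, `k_max`, `k_step`, `D1`, `D2`, and
#' optional `bounds` (named list of 2-vectors for `b`, `V`, `K`, `mu`).
#'
#' @inheritParams run_survey_config
#' @return The `"hill_screen"`, invisibly; side effect: records CSV +
#'   manifest in `out_dir`.
#' @export
run_screen_config <- function(config, out_dir = ".", seed = NULL,
                              quiet = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- resolve_config(config, list(
    topology = "gierer_meinhardt", n_samples = 1000, seed = 1,
    n_guesses = 10, k_max = 10, k_step = 0.05, D1 = 1, D2 = 10,
    bounds = NULL))
  if (!is.null(seed)) cfg$seed <- seed
  topology <- switch(cfg$topology,
    gierer_meinhardt = topology_gierer_meinhardt(),
    three_node = topology_three_node(),
    four_node = topology_four_node(),
    read_topology(cfg$topology))
  bounds <- hill_bounds()
  if (!is.null(cfg$bounds))
    bounds <- modifyList(bounds, lapply(cfg$bounds, as.numeric))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  screen <- screen_models(topology, cfg$n_samples, bounds,
                          diffusion_spec(cfg$D1, cfg$D2), cfg$k_max,
                          cfg$k_step, cfg$n_guesses, cfg$seed)
  csv <- file.path(out_dir, "screen_records.csv")
  write_screen_csv(screen, csv)
  cfg$bounds <- bounds
  write_manifest("screen-hill", cfg, csv,
                 file.path(out_dir, "screen_manifest.json"))
  if (!quiet) print(screen)
  invisible(screen)
}

#' Oracle self-test of the numerical pipeline
#'
#' Quick end-to-end consistency checks against the closed-form oracles:
#' trace conservation of the eigenvalue sum, absence of Turing classes
#' for two-node and antisymmetric ensembles, and the circular-law radius
#' of the sampled spectra. Intended as a fast smoke test of an installed
#' build.
#'
#' @param seed Seed for the sampled checks.
#' @param quiet Suppress the per-check report.
#' @return Logical: `TRUE` when every check passed. Individual results
#'   are attached as attribute `"checks"`.
#' @export
run_selftest <- function(seed = 1, quiet = FALSE) {
  checks <- c(trace_bound = NA, two_node_no_turing = NA,
              antisymmetric_no_turing = NA, circular_law_radius = NA)
  d <- diffusion_spec(1, 10)

  set.seed(seed)
  j0 <- sample_jacobian(ensemble_spec(20, sigma2 = 0.25))
  ks <- c(0, 1, 3)
  sums <- eigen_sum_cpp(j0, diffusion_vector(d, 20), ks)
  checks["trace_bound"] <-
    all(abs(sums - outlier_trace_bound(20, d, ks)) <=
          1e-8 * abs(outlier_trace_bound(20, d, ks)))

  set.seed(seed + 1)
  cls2 <- classify_jacobians(
    sample_jacobians(ensemble_spec(2, sigma2 = 0.5), 500), d)
  checks["two_node_no_turing"] <-
    !any(cls2 %in% c("turing_I", "turing_II", "turing_hopf"))

  set.seed(seed + 2)
  clsa <- classify_jacobians(
    sample_jacobians(ensemble_spec(6, sigma2 = 0.4,
                                   diagonal_mode = "antisymmetric_fixed"),
                     500), d)
  checks["antisymmetric_no_turing"] <-
    !any(clsa %in% c("turing_I", "turing_II", "turing_hopf"))

  set.seed(seed + 3)
  spec <- ensemble_spec(200, sigma2 = sigma2_for_radius(200, 1, 1))
  g <- sample_jacobian(spec) + diag(200)  # interaction part G
  ev <- eigen(g, only.values = TRUE)$values
  checks["circular_law_radius"] <- mean(Mod(ev) <= 1.1) >= 0.99

  if (!quiet) {
    for (nm in names(checks))
      message(sprintf("  %-24s %s", nm, if (checks[nm]) "ok" else "FAILED"))
  }
  structure(all(checks), checks = checks)
}
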