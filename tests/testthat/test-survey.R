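test_that("survey counts are complete, consistent and deterministic", {
  g <- run_stability_survey(n_values = c(3, 5), gamma_values = c(0.8, 1.2),
                            n_samples = 200, seed = 5)
  cells <- g$cells
  # per cell, class counts sum to n_samples and percentages are coherent
  per_cell <- tapply(cells$count, interaction(cells$n_nodes, cells$gamma), sum)
  expect_true(all(per_cell == 200))
  expect_equal(cells$percentage, 100 * cells$count / 200)
  # same seed reproduces counts exactly
  g2 <- run_stability_survey(n_values = c(3, 5), gamma_values = c(0.8, 1.2),
                             n_samples = 200, seed = 5)
  expect_identical(g$cells, g2$cells)
  # different seed agrees within 3 binomial standard errors per class
  g3 <- run_stability_survey(n_values = c(3, 5), gamma_values = c(0.8, 1.2),
                             n_samples = 200, seed = 99)
  p <- g$cells$count / 200
  se <- sqrt(pmax(p * (1 - p), 1 / 200) / 200)
  expect_true(all(abs(g3$cells$count / 200 - p) <= 3 * se + 1e-12))
})

test_that("vanishing radius gives a fully stable ensemble", {
  g <- run_stability_survey(n_values = c(4, 8), gamma_values = 0.05,
                            n_samples = 300, seed = 1)
  stable <- g$cells[g$cells$class == "stable", ]
  expect_true(all(stable$percentage == 100))
})

test_that("gamma = 0.5 at N = 200 is stable for nearly every draw", {
  # circular law: the eigenvalue disk sits well inside the left half-plane
  spec <- ensemble_spec(200, sigma2_for_radius(200, 1, 0.5))
  set.seed(14)
  stable <- replicate(60, {
    ev <- eigen(sample_jacobian(spec), only.values = TRUE)$values
    max(Re(ev)) < 0
  })
  expect_gte(mean(stable), 0.99)
})

test_that("N = 2 rows contain no Turing classes anywhere", {
  g <- run_size_variance_heatmap(n_values = 2, n_samples = 400, seed = 3)
  two <- g$cells[g$cells$class %in% c("turing_I", "turing_II", "turing_hopf"), ]
  expect_true(all(two$count == 0))
})

test_that("low-radius cells keep Turing I below 1 percent", {
  g <- run_stability_survey(n_values = c(4, 6, 10), gamma_values = c(0.3, 0.5),
                            n_samples = 500, seed = 8)
  ti <- g$cells[g$cells$class == "turing_I", ]
  expect_true(all(ti$percentage < 1))
})

test_that("conditional percentages obey the counting identity", {
  g <- run_stability_survey(n_values = c(5, 10), gamma_values = c(1.1, 1.3),
                            n_samples = 500, seed = 6)
  uncond <- survey_percentages(g, of = "all")
  cond <- survey_percentages(g, of = "stable_at_k0")
  key <- interaction(uncond$n_nodes, uncond$gamma, uncond$class)
  for (cl in c("turing_I", "turing_II", "turing_hopf")) {
    u <- uncond[uncond$class == cl, ]
    co <- cond[cond$class == cl, ]
    stable_share <- tapply(
      uncond$percentage * (uncond$class != "unstable_without_diffusion"),
      interaction(uncond$n_nodes, uncond$gamma), sum) / 100
    # conditional = unconditional / share stable at k=0
    expect_equal(co$percentage,
                 u$percentage / stable_share[interaction(u$n_nodes, u$gamma)],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("optimal-size extraction reports peaks and degenerate grids", {
  g <- run_size_variance_heatmap(n_values = c(3, 4, 5),
                                 gamma_values = c(1.1, 1.3),
                                 n_samples = 400, seed = 7)
  opt <- extract_optimal_size(g)
  expect_true(opt$n_opt %in% c(3, 4, 5))
  per_n <- opt$per_n
  expect_equal(nrow(per_n), 3)
  ti <- g$cells[g$cells$class == "turing_I", ]
  for (i in seq_len(3)) {
    expect_equal(per_n$peak_percentage[i],
                 max(ti$percentage[ti$n_nodes == per_n$n_nodes[i]]))
  }
  # antisymmetric ensembles yield an all-zero grid and no optimum
  g0 <- run_size_variance_heatmap(n_values = c(3, 5),
                                  gamma_values = c(1.0, 1.3),
                                  n_samples = 150, seed = 9,
                                  diagonal_mode = "antisymmetric_fixed")
  opt0 <- extract_optimal_size(g0)
  expect_true(is.na(opt0$n_opt))
  expect_equal(opt0$peak_percentage, 0)
})

test_that("diffusion grids are symmetric under swapping D1 and D2", {
  ds <- c(0.5, 2, 8)
  g <- run_diffusion_grid(3, sigma2 = 0.33, d1_values = ds, d2_values = ds,
                          n_samples = 600, seed = 10)
  ti <- g$cells[g$cells$class == "turing_I", ]
  for (a in ds) for (b in ds) {
    p_ab <- ti$percentage[ti$d1 == a & ti$d2 == b]
    p_ba <- ti$percentage[ti$d1 == b & ti$d2 == a]
    # 3 binomial SE on the difference of two independent cells
    se <- sqrt(2 * pmax(p_ab * (100 - p_ab), 100) / 600)
    expect_lte(abs(p_ab - p_ba), 3 * se)
  }
  expect_error(run_diffusion_grid(3, 0.33, c(0, 1), 1), "positive")
})

test_that("survey CSV round-trips the long format", {
  g <- run_stability_survey(n_values = 3, gamma_values = 1, n_samples = 100,
                            seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey_csv(g, path)
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(g$cells))
  expect_equal(back$count, g$cells$count)
  expect_true(all(c("n_nodes", "gamma", "sigma2", "d1", "d2", "class",
                    "count", "percentage") %in% names(back)))
})
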