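test_that("k grid covers [0, k_max] and validates the step", {
  g <- k_grid(10, 0.01)
  expect_equal(g[1], 0)
  expect_equal(g[length(g)], 10)
  expect_equal(length(g), 1001)
  expect_error(k_grid(10, 0.3), "divide")
  expect_error(k_grid(-1, 0.1), "positive")
})

test_that("J(k) subtracts k^2 D on the two diffusing diagonals only", {
  d <- default_diff()
  j0 <- matrix(c(-1, -2, 2, -1), 2, 2)
  expect_equal(jacobian_at_k(j0, d, 1),
               matrix(c(-2, -2, 2, -11), 2, 2))
  set.seed(1)
  ja <- matrix(rnorm(25), 5)
  expect_equal(jacobian_at_k(ja, d, 0), ja)
  expect_equal(jacobian_at_k(-diag(3), d, 2),
               diag(c(-5, -41, -1)))
  expect_error(jacobian_at_k(matrix(0, 2, 3), d, 1), "square")
})

test_that("degenerate -I Jacobians give flat or quadratic dispersions", {
  d <- default_diff()
  # N = 3: the immobile third node pins the leading eigenvalue at -1
  r3 <- dispersion_relation(-diag(3), d, k_grid(5, 0.1))
  expect_true(all(r3$lead_real == -1))
  expect_equal(r3$klass, "stable")
  # N = 2: both nodes diffuse; leading branch is -1 - k^2 min(D)
  r2 <- dispersion_relation(-diag(2), d, k_grid(5, 0.1))
  expect_equal(r2$lead_real, -1 - r2$k_values^2 * 1, tolerance = 1e-12)
})

test_that("trace is conserved at every wave number", {
  d <- default_diff()
  set.seed(8)
  j0 <- sample_jacobian(ensemble_spec(12, 0.1))
  ks <- c(0, 0.5, 2, 7)
  sums <- turingnet:::eigen_sum_cpp(j0, turingnet:::diffusion_vector(d, 12), ks)
  expect_equal(sums, -12 - ks^2 * 11, tolerance = 1e-8)
})

test_that("classification matches frozen dense-grid verified examples", {
  d <- default_diff()
  # 3-node Turing I: interior peak, real, restabilizes (seed found by
  # rejection sampling; class confirmed on a step-0.001 grid)
  set.seed(996)
  j_ti <- sample_jacobian(ensemble_spec(3, sigma2 = 1.2^2 / 3))
  r <- dispersion_relation(j_ti, d)
  expect_equal(r$klass, "turing_I")
  expect_lt(r$lead_real[1], 0)
  expect_gt(max(r$lead_real[-1]), 0)
  expect_lt(r$lead_real[length(r$lead_real)], 0)
  expect_equal(r$k_peak, 0.65, tolerance = 0.05)

  set.seed(31)
  j_tii <- sample_jacobian(ensemble_spec(10, sigma2 = 1.2^2 / 10))
  expect_equal(dispersion_relation(j_tii, d)$klass, "turing_II")

  set.seed(377)
  j_th <- sample_jacobian(ensemble_spec(10, sigma2 = 1.2^2 / 10))
  expect_equal(dispersion_relation(j_th, d)$klass, "turing_hopf")

  # any matrix unstable at k = 0 is unstable_without_diffusion
  expect_equal(dispersion_relation(diag(c(0.1, -1, -1)), d)$klass,
               "unstable_without_diffusion")
})

test_that("batch summaries agree with single-matrix curves", {
  d <- default_diff()
  set.seed(20)
  jm <- sample_jacobians(ensemble_spec(6, 1.3^2 / 6), 80)
  grid <- k_grid(10, 0.05)
  batch <- classify_jacobians(jm, d, grid)
  single <- vapply(seq_len(80), function(s)
    dispersion_relation(jm[, , s], d, grid)$klass, character(1))
  expect_identical(batch, single)
})

test_that("classification is invariant under swapping the two diffusers", {
  set.seed(21)
  jm <- sample_jacobians(ensemble_spec(5, 1.2^2 / 5), 150)
  grid <- k_grid(10, 0.05)
  c12 <- classify_jacobians(jm, diffusion_spec(1, 10), grid)
  # permute nodes 1 <-> 2 and swap (D1, D2): similarity transform
  perm <- c(2, 1, 3, 4, 5)
  jm_swap <- jm[perm, perm, , drop = FALSE]
  c21 <- classify_jacobians(jm_swap, diffusion_spec(10, 1), grid)
  expect_identical(c12, c21)
})

test_that("halving the grid step changes almost no classifications", {
  set.seed(22)
  jm <- sample_jacobians(ensemble_spec(5, 1.05^2 / 5), 1000)
  d <- default_diff()
  c_coarse <- classify_jacobians(jm, d, k_grid(10, 0.1))
  c_fine <- classify_jacobians(jm, d, k_grid(10, 0.05))
  expect_lte(mean(c_coarse != c_fine), 0.01)
})

test_that("antisymmetric ensembles never produce Turing classes", {
  d <- default_diff()
  for (N in c(3, 6, 10)) {
    set.seed(30 + N)
    spec <- ensemble_spec(N, 0.4, diagonal_mode = "antisymmetric_fixed")
    cls <- classify_jacobians(sample_jacobians(spec, 400), d)
    expect_false(any(cls %in% c("turing_I", "turing_II", "turing_hopf")),
                 label = paste0("antisymmetric N=", N))
  }
})

test_that("dispersion results export to CSV", {
  set.seed(996)
  j0 <- sample_jacobian(ensemble_spec(3, 1.2^2 / 3))
  r <- dispersion_relation(j0, default_diff(), k_grid(2, 0.1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dispersion_csv(r, path)
  back <- read.csv(path)
  expect_equal(names(back), c("k", "lead_real", "lead_imag", "class"))
  expect_equal(back$lead_real, r$lead_real)
})
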