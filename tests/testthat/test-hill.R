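test_that("rhs matches closed forms at half-saturation", {
  # unregulated node: f(x) = b - mu x, zero at b / mu
  p <- unregulated_params(b = 1, mu = 0.5)
  expect_equal(hill_rhs(p, 2), 0)
  expect_equal(hill_rhs(p, 1), 0.5)
  expect_error(hill_rhs(p, -1), "positive")

  # one activator evaluated at its threshold contributes exactly 1/2
  top <- hill_topology(matrix(c(0, 0, 1, 0), 2, 2))  # node2 activates node1
  p2 <- hill_params(top, b = c(0.1, 0.1), V = c(2, 2), K = 0.5, mu = c(1, 1))
  f <- hill_rhs(p2, c(1, 0.5))  # x2 = K
  expect_equal(f[1], 0.1 + 2 * 0.5 - 1)

  # one repressor at threshold also gives 1/2; both together give V/4
  top3 <- hill_topology(matrix(c(0, 0, 0, 1, 0, 0, -1, 0, 0), 3, 3))
  p3 <- hill_params(top3, b = rep(0.1, 3), V = rep(4, 3), K = 0.5,
                    mu = rep(1, 3))
  f3 <- hill_rhs(p3, c(1, 0.5, 0.5))  # both regulators of node 1 at K
  expect_equal(f3[1], 0.1 + 4 / 4 - 1)
})

test_that("analytic Jacobian matches finite differences", {
  set.seed(11)
  top <- topology_three_node()
  p <- hill_params(top, b = runif(3, 0.01, 0.1), V = runif(3, 0.5, 5),
                   K = matrix(runif(9, 0.1, 1), 3), mu = runif(3, 0.1, 1))
  x <- runif(3, 0.2, 3)
  J <- hill_jacobian(p, x)
  J_fd <- fd_jacobian(function(z) hill_rhs(p, z), x)
  expect_lt(max(abs(J - J_fd)), 1e-5)
  # structural zeros are exact
  expect_true(all(J[top$adjacency == 0 & !diag(3)] == 0))
  # unregulated diagonal is -mu
  p1 <- unregulated_params(mu = 0.7)
  expect_equal(hill_jacobian(p1, 3)[1, 1], -0.7)
})

test_that("steady-state search finds, dedups and bounds residuals", {
  p <- unregulated_params(b = 1, mu = 0.5)
  ss <- find_steady_states(p, n_guesses = 10, seed = 1)
  expect_equal(nrow(ss$states), 1)  # all guesses converge to one root
  expect_equal(ss$states[1, 1], 2, tolerance = 1e-9)
  expect_true(any(ss$converged))
  # residual bound holds for every accepted root of a harder model
  set.seed(12)
  top <- topology_four_node()
  pars <- hill_params(top, b = runif(4, 0.001, 0.1), V = runif(4, 0.1, 10),
                      K = matrix(runif(16, 0.01, 1), 4), mu = runif(4, 0.01, 1))
  ss4 <- find_steady_states(pars, seed = 2)
  for (r in seq_len(nrow(ss4$states))) {
    expect_lt(max(abs(hill_rhs(pars, ss4$states[r, ]))), 1e-9)
    expect_true(all(ss4$states[r, ] > 0))
  }
})

test_that("multistable root counts agree with a 1-d bisection oracle", {
  p <- self_activator_params()
  f <- function(x) hill_rhs(p, x)
  oracle_roots <- scan_roots_1d(function(x) p$b[1] +
    p$V[1] * x^2 / (x^2 + p$K[1, 1]^2) - p$mu[1] * x)
  ss <- find_steady_states(p, n_guesses = 25, seed = 3)
  expect_equal(nrow(ss$states), length(oracle_roots))
  expect_gt(nrow(ss$states), 1)  # genuinely multistable fixture
  expect_equal(sort(ss$states[, 1]), sort(oracle_roots), tolerance = 1e-6)
})

test_that("Latin hypercube sampling stratifies each marginal in log space", {
  top <- topology_gierer_meinhardt()
  s <- lhs_sample(top, 10, seed = 4)
  b <- hill_bounds()
  # one value per log-decile bin, every column
  for (cn in colnames(s)) {
    nm <- sub("_.*", "", cn)
    lo <- log(b[[nm]][1]); hi <- log(b[[nm]][2])
    bins <- floor(10 * (log(s[, cn]) - lo) / (hi - lo))
    expect_setequal(bins, 0:9)
  }
  expect_true(all(s[, "V_1"] >= 0.1 & s[, "V_1"] <= 10))
  expect_error(lhs_sample(top, 5, bounds = list(V = c(1, 0.1), K = c(0.01, 1),
                                                b = c(0.001, 0.1),
                                                mu = c(0.01, 1))),
               "bounds")
})

test_that("LHS marginals follow the loguniform law", {
  top <- hill_topology(matrix(0L, 2, 2))
  s <- lhs_sample(top, 1e4, seed = 5)
  for (cn in c("V_1", "mu_2")) {
    nm <- sub("_.*", "", cn)
    b <- hill_bounds()[[nm]]
    ks <- suppressWarnings(
      ks.test(log(s[, cn]), "punif", log(b[1]), log(b[2])))
    expect_lt(unname(ks$statistic), 0.05)
  }
})

test_that("screening labels records and respects sign constraints", {
  top <- topology_gierer_meinhardt()
  scr <- screen_models(top, n_samples = 3000, seed = 6)
  expect_gt(scr$summary$n_states, 0)
  rec <- scr$records
  expect_setequal(names(rec),
                  c("set_id", "state_id", "i", "j", "value", "class"))
  # (2,2) self-repression plus degradation: always negative
  expect_true(all(rec$value[rec$i == 2 & rec$j == 2] < 0))
  # (1,2) inhibition of the activator: always negative; (2,1) always positive
  expect_true(all(rec$value[rec$i == 1 & rec$j == 2] < 0))
  expect_true(all(rec$value[rec$i == 2 & rec$j == 1] > 0))
  # n_samples = 0 yields an empty record set, not an error
  expect_equal(nrow(screen_models(top, 0)$records), 0)
})

test_that("topology files round-trip and built-ins load", {
  top <- topology_four_node()
  expect_equal(top$n_nodes, 4)
  path <- withr::local_tempfile(fileext = ".txt")
  write_topology(top, path)
  expect_equal(read_topology(path)$adjacency, top$adjacency)
  expect_error(read_topology("/nonexistent/topo.txt"), "not found")
  expect_error(hill_topology(matrix(2, 2, 2)), "entries")
})
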