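test_that("PCE recovers in-span polynomials exactly", {
  set.seed(1)
  n <- 400
  X <- cbind(runif(n, -1, 1), runif(n, 2, 5), runif(n, 0, 10))
  dom <- rbind(c(-1, 2, 0), c(1, 5, 10))
  y <- 1.5 + 2 * X[, 1] - 0.7 * X[, 2] + 0.3 * X[, 1] * X[, 3] + 0.1 * X[, 2]^2
  m <- fit_pce(X, y, degree = 2, domains = dom)
  expect_equal(predict(m, X), y, tolerance = 1e-8)
  expect_gt(q2_loo(m), 1 - 1e-8)
  # constant output: only the constant coefficient survives, Q2 undefined
  m0 <- fit_pce(X, rep(4.2, n), degree = 2, domains = dom)
  expect_equal(m0$coef[1], 4.2, tolerance = 1e-10)
  expect_equal(max(abs(m0$coef[-1])), 0, tolerance = 1e-10)
  expect_true(is.na(m0$q2))
})

test_that("Sobol indices are analytic for additive and pure-interaction models", {
  set.seed(2)
  n <- 800
  X <- cbind(runif(n, -1, 1), runif(n, -1, 1))
  dom <- rbind(c(-1, -1), c(1, 1))
  # additive: S_i = a_i^2 V_i / sum, no interactions
  a <- 3; b <- 1.5
  m <- fit_pce(X, a * X[, 1] + b * X[, 2], degree = 3, domains = dom)
  si <- sobol_indices(m)
  expect_equal(si$S_i[1], a^2 / (a^2 + b^2), tolerance = 1e-8)
  expect_equal(si$S_i, si$S_T, tolerance = 1e-8)
  # pure interaction: main effects vanish, totals are 1
  mi <- sobol_indices(fit_pce(X, X[, 1] * X[, 2], degree = 3, domains = dom))
  expect_equal(mi$S_i, c(0, 0), tolerance = 1e-8)
  expect_equal(mi$S_T, c(1, 1), tolerance = 1e-8)
})

test_that("Ishigami indices match the analytic values within 0.01", {
  set.seed(42)
  n <- 4000
  X <- cbind(runif(n, -pi, pi), runif(n, -pi, pi), runif(n, -pi, pi))
  y <- sin(X[, 1]) + 7 * sin(X[, 2])^2 + 0.1 * X[, 3]^4 * sin(X[, 1])
  dom <- rbind(rep(-pi, 3), rep(pi, 3))
  m <- fit_pce(X, y, degree = 9, domains = dom)
  si <- sobol_indices(m)
  # closed-form variance decomposition of the Ishigami function (a=7, b=0.1)
  V1 <- 0.5 * (1 + 0.1 * pi^4 / 5)^2
  V2 <- 7^2 / 8
  V13 <- 8 * 0.1^2 * pi^8 / 225
  V <- V1 + V2 + V13
  expect_equal(si$S_i, c(V1 / V, V2 / V, 0), tolerance = 0.01)
  expect_equal(si$S_T, c((V1 + V13) / V, V2 / V, V13 / V), tolerance = 0.01)
  expect_gt(m$q2, 0.999)
  # index bounds and ordering
  expect_true(all(si$S_i >= -1e-6 & si$S_T <= 1 + 1e-6))
  expect_true(all(si$S_T - si$S_i >= -1e-6))
  expect_lt(sum(si$S_i), 1 + 1e-6)
})

test_that("pick-freeze Monte Carlo agrees with the coefficient decomposition", {
  set.seed(3)
  n <- 1500
  X <- cbind(runif(n, -1, 1), runif(n, -1, 1), runif(n, -1, 1))
  dom <- rbind(rep(-1, 3), rep(1, 3))
  y <- 2 * X[, 1] + X[, 2]^2 + 0.5 * X[, 1] * X[, 3]
  m <- fit_pce(X, y, degree = 4, domains = dom)
  si <- sobol_indices(m)
  mc <- saltelli_check(m, n_mc = 20000, seed = 7)
  expect_true(all(abs(mc$S_i - si$S_i) <= 3 * mc$se_S_i + 1e-9))
  expect_true(all(abs(mc$S_T - si$S_T) <= 3 * mc$se_S_T + 1e-9))
})

test_that("the Legendre basis is empirically orthonormal under uniform sampling", {
  set.seed(4)
  n <- 40000
  U <- cbind(runif(n, -1, 1), runif(n, -1, 1))
  idx <- hgowall:::total_degree_indices(2, 3)
  Phi <- hgowall:::pce_design(U, idx)
  G <- crossprod(Phi) / n
  expect_lt(max(abs(G - diag(nrow(idx)))), 5 / sqrt(n) * 3)
})

test_that("leave-one-out Q2 is near 1 in-span and non-positive on noise", {
  set.seed(6)
  q2s <- replicate(200, {
    X <- matrix(runif(60 * 2, -1, 1), ncol = 2)
    fit_pce(X, rnorm(60), degree = 3, domains = rbind(c(-1, -1), c(1, 1)))$q2
  })
  expect_lt(mean(q2s), 0)
})

test_that("adaptive degree stops at the lowest admissible degree and flags noise", {
  set.seed(8)
  n <- 300
  X <- cbind(runif(n, -1, 1), runif(n, -1, 1))
  dom <- rbind(c(-1, -1), c(1, 1))
  y <- 1 + X[, 1] + 0.5 * X[, 2]^2
  m <- adaptive_degree(X, y, domains = dom, degrees = 2:6)
  expect_equal(m$degree, 2)
  expect_true(m$gate_met)
  noise <- adaptive_degree(X, rnorm(n), domains = dom, degrees = 2:4)
  expect_false(noise$gate_met)
})
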