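test_that("model construction validates shapes, symmetry and definiteness", {
  m <- make_var(array(0, c(3, 3, 1)), diag(3), fs = 120)
  expect_true(m$stable)
  expect_equal(m$spectral_radius, 0)

  expect_error(make_var(array(0, c(3, 3, 1)), diag(2), 120), "3x3")
  bad <- diag(3); bad[1, 2] <- 0.5 # asymmetric
  expect_error(make_var(array(0, c(3, 3, 1)), bad, 120), "symmetric")
  npd <- diag(c(1, 1, -0.1))
  expect_error(make_var(array(0, c(3, 3, 1)), npd, 120), "positive definite")
})

test_that("an explosive AR(1) is flagged unstable but still constructed", {
  expect_warning(m <- make_var(array(1.01, c(1, 1, 1)), diag(1), 100),
                 "unstable")
  expect_false(m$stable)
  expect_equal(m$spectral_radius, 1.01)
  expect_error(simulate_var(m, 10), "unstable")
})

test_that("the 3-node benchmark is stable with the chain structure", {
  expect_true(bench3$stable)
  expect_equal(bench3$order, 3L)
  # unidirectional chain: only 1->2 and 2->3 cross terms anywhere
  cross <- bench3$coeffs
  for (k in 1:3) diag(cross[, , k]) <- 0
  nz <- which(cross != 0, arr.ind = TRUE)
  expect_setequal(paste(nz[, 1], nz[, 2]), c("2 1", "3 2"))
})

test_that("simulation is deterministic and matches white-noise moments", {
  m <- white_noise_model()
  a <- simulate_var(m, 500, seed = 7)
  b <- simulate_var(m, 500, seed = 7)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, simulate_var(m, 500, seed = 8)$data))

  s <- simulate_var(m, 1e5, seed = 1)
  expect_lt(max(abs(crossprod(s$data) / nrow(s$data) - diag(3))), 0.05)
})

test_that("sample autocovariances match the Lyapunov-equation solution", {
  G <- var_autocov(bench3, 3)
  s <- simulate_var(bench3, 5e4, seed = 11)
  x <- s$data
  n <- nrow(x)
  for (h in 0:3) {
    emp <- crossprod(x[(1 + h):n, ], x[1:(n - h), ]) / n
    # Monte Carlo error for these strongly autocorrelated processes
    expect_lt(max(abs(emp - G[, , h + 1])), 0.06 * max(abs(G[, , 1])))
  }
})

test_that("OLS recovers known coefficients and degrades gracefully", {
  s0 <- simulate_var(white_noise_model(), 1e4, seed = 2)
  f0 <- fit_var_ols(s0, 3)
  expect_lt(max(abs(f0$coeffs)), 0.05)

  s <- simulate_var(bench3, 1e4, seed = 3)
  fit <- fit_var_ols(s, 3)
  expect_lt(max(abs(fit$coeffs - bench3$coeffs)), 0.05)

  # nested least squares: residual variance cannot increase with order
  f20 <- fit_var_ols(s, 20)
  expect_true(all(diag(attr(f20, "residual_cov_ml")) <=
                    diag(attr(fit, "residual_cov_ml")) + 1e-12))

  # rank-deficient design: duplicated channel
  xdup <- cbind(s$data, s$data[, 1])
  expect_error(fit_var_ols(xdup, 2, fs = 120), "rank-deficient")
  expect_error(fit_var_ols(s$data[1:8, ], 3, fs = 120), "too short")
})

test_that("OLS coefficient error shrinks with sample size", {
  rmse <- vapply(c(1e3, 1e4, 1e5), function(n) {
    fit <- fit_var_ols(simulate_var(bench3, n, seed = 5), 3)
    sqrt(mean((fit$coeffs - bench3$coeffs)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("information criteria find the generative order", {
  hits <- vapply(1:20, function(i) {
    s <- simulate_var(bench3, 1e4, seed = 100 + i)
    select_order(s, 10, "bic")
  }, numeric(1))
  expect_gte(mean(hits == 3), 0.9)

  hits_wn <- vapply(1:20, function(i) {
    s <- simulate_var(white_noise_model(), 1e4, seed = 200 + i)
    select_order(s, 5, "bic")
  }, numeric(1))
  expect_gte(mean(hits_wn == 1), 0.9)

  # a constant criterion must break ties toward the smallest order
  s <- simulate_var(bench3, 500, seed = 1)
  expect_equal(select_order(s, 5, criterion = function(fit, t_eff) 0), 1L)
})

test_that("frequency grids are validated", {
  g <- frequency_grid(120)
  expect_length(g$freqs, 513)
  expect_equal(range(g$freqs), c(0, 60))
  expect_error(frequency_grid(120, fmax = 80), "fmax")
  expect_error(as_frequency_grid(c(0, 10, 5), 120), "increasing")
  expect_error(as_frequency_grid(c(0, 70), 120), "0, fs/2")
})
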