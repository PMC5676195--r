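test_that("VAR to state-space conversion preserves the spectrum", {
  # zero-coefficient model: constant spectrum Sigma
  m0 <- white_noise_model()
  sp0 <- ss_spectral_matrices(var_to_ss(m0), grid_default)
  expect_lt(max(abs(sp0$S - array(diag(3) + 0i, c(3, 3, 513)))), 1e-14)

  sm <- var_spectral_matrices(bench3, grid_default)
  sms <- ss_spectral_matrices(var_to_ss(bench3), grid_default)
  expect_lt(max(abs(sm$S - sms$S)), 1e-10)

  # scalar AR(1): one state, transition = the coefficient
  ar1 <- make_var(array(0.6, c(1, 1, 1)), diag(1), 50)
  ss1 <- var_to_ss(ar1)
  expect_equal(dim(ss1$A), c(1L, 1L))
  expect_equal(ss1$A[1, 1], 0.6)

  expect_error(var_to_ss(make_var(array(1.01, c(1, 1, 1)), diag(1), 50,
                                  warn_unstable = FALSE)),
               "stable")
})

test_that("keeping all channels returns the original innovations", {
  ss <- var_to_ss(bench3)
  sub <- subprocess_innovations(ss, 1:3)
  expect_lt(max(abs(sub$cov - bench3$noise_cov)), 1e-10)
  expect_lt(max(abs(sub$gain - ss$K)), 1e-10)
})

test_that("subprocess innovation covariances match an independent Riccati solver", {
  # frozen values from scipy.linalg.solve_discrete_are on the same
  # benchmark state-space matrices (dual/filter form)
  ss <- var_to_ss(bench3)
  expect_equal(subprocess_innovations(ss, 2)$cov[1, 1],
               1.3189323232461145, tolerance = 1e-10)
  expect_equal(subprocess_innovations(ss, 3)$cov[1, 1],
               1.641906313375772, tolerance = 1e-10)
  v23 <- subprocess_innovations(ss, c(2, 3))$cov
  expect_equal(v23, diag(c(1.3189323232461188, 1)), tolerance = 1e-9)
})

test_that("Riccati solutions are accurate on every benchmark subset", {
  ss <- var_to_ss(bench3)
  subsets <- list(1, 2, 3, c(1, 2), c(1, 3), c(2, 3), 1:3)
  for (keep in subsets) {
    sub <- subprocess_innovations(ss, keep)
    expect_lt(sub$residual, 1e-10)
    expect_true(all(eigen(sub$cov, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  }
  # white noise: reduced covariance is just the submatrix of Sigma
  ssw <- var_to_ss(white_noise_model())
  expect_lt(max(abs(subprocess_innovations(ssw, c(1, 3))$cov -
                      diag(2))), 1e-12)
})

test_that("reduced innovation variance matches a long Yule-Walker projection", {
  # fit a very-high-order VAR to the exact subprocess autocovariances; its
  # residual variance should approach the Riccati innovation variance
  G <- var_autocov(bench3, 200)[c(1, 2), c(1, 2), , drop = FALSE]
  yw <- specgc:::yw_var_from_autocov(G, 200)
  sub <- subprocess_innovations(var_to_ss(bench3), c(1, 2))
  expect_lt(abs(yw$sigma[2, 2] - sub$cov[2, 2]) / sub$cov[2, 2], 1e-4)
})

test_that("closed-form conditional GC is exact on the benchmark", {
  ss <- var_to_ss(bench3)
  expect_lte(max(ss_conditional_spectral_gc(ss, 3, 1, 2, grid_default)$values),
             1e-10)
  cs12 <- ss_conditional_spectral_gc(ss, 1, 2, 3, grid_default)
  cs23 <- ss_conditional_spectral_gc(ss, 2, 3, 1, grid_default)
  for (cs in list(cs12, cs23)) expect_gt(max(cs$values), 0.5)

  # bivariate restriction agrees with the dedicated bivariate formula
  m2 <- bench2[["30"]]
  a <- ss_conditional_spectral_gc(var_to_ss(m2), 1, 2, integer(0), grid_default)
  b <- bivariate_spectral_gc(m2, grid_default)
  expect_lt(max(abs(a$values - b$values)), 1e-10)
})

test_that("padding with zero lag matrices leaves the closed form unchanged", {
  base <- ss_conditional_spectral_gc(var_to_ss(bench3), 1, 2, 3, grid_default)
  padded <- ss_conditional_spectral_gc(var_to_ss(pad_var_order(bench3, 5)),
                                       1, 2, 3, grid_default)
  expect_lt(max(abs(base$values - padded$values)), 1e-10)
})

test_that("state-space estimation from data is deterministic and calibrated", {
  s <- simulate_var(white_noise_model(), 1e4, seed = 21)
  for (src in 1:3) {
    for (tgt in setdiff(1:3, src)) {
      cs <- ss_gc_from_data(s, 3, src, tgt)
      expect_lt(max(cs$values), 0.05)
    }
  }
  sb <- simulate_var(bench3, 2000, seed = 22)
  a <- ss_gc_from_data(sb, 3, 1, 2, 3, grid_default)
  b <- ss_gc_from_data(sb, 3, 1, 2, 3, grid_default)
  expect_identical(a$values, b$values)
  expect_equal(a$provenance$estimator, "ss")
})
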