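test_that("uncoupled channels have zero bivariate spectral GC", {
  m <- white_noise_model(2)
  cs <- bivariate_spectral_gc(m, grid_default)
  expect_true(all(cs$values == 0))
  expect_error(bivariate_spectral_gc(bench3), "2-channel")

  # uncoupled but individually resonant
  co <- array(0, c(2, 2, 2))
  for (i in 1:2) {
    a <- build_oscillator_var(c(20, 45)[i], 0.8, 120)
    co[i, i, ] <- a
  }
  m2 <- make_var(co, diag(2), 120)
  expect_lt(max(bivariate_spectral_gc(m2, grid_default)$values), 1e-14)
})

test_that("the GGC transmitter->receiver profile ignores receiver dynamics", {
  ggc <- lapply(bench2, function(m) bivariate_spectral_gc(m, grid_default))
  expect_lt(max(abs(ggc[["10"]]$values - ggc[["30"]]$values)), 1e-10)
  expect_lt(max(abs(ggc[["10"]]$values - ggc[["50"]]$values)), 1e-10)
  expect_gt(max(ggc[["10"]]$values), 0.1) # but the coupling is visible
})

test_that("bivariate GGC is invariant to rescaling either channel", {
  base <- bivariate_spectral_gc(bench2[["10"]], grid_default)$values
  for (ch in 1:2) {
    for (alpha in c(0.1, 10)) {
      sc <- rescale_channel(bench2[["10"]], ch, alpha)
      expect_lt(max(abs(bivariate_spectral_gc(sc, grid_default)$values - base)),
                1e-10)
    }
  }
})

test_that("bivariate GGC handles correlated innovations via partialization", {
  # correlated-innovation 2-node model: the Cholesky-normalized bivariate
  # formula must agree with the state-space closed form
  co <- array(0, c(2, 2, 2))
  co[1, 1, ] <- build_oscillator_var(50, 0.9, 120)
  co[2, 2, ] <- build_oscillator_var(10, 0.9, 120)
  co[2, 1, 1] <- 0.35
  Sig <- matrix(c(1, 0.4, 0.4, 1), 2)
  m <- make_var(co, Sig, 120)
  a <- bivariate_spectral_gc(m, grid_default)
  b <- ss_conditional_spectral_gc(var_to_ss(m), 1, 2, integer(0), grid_default)
  expect_lt(max(abs(a$values - b$values)), 1e-10)
})

test_that("theoretical conditional GC vanishes on the uncoupled direction", {
  cs <- theoretical_conditional_gc(bench3, 3, 1, 2, grid_default)
  expect_lte(max(cs$values), 1e-10)
  cs12 <- theoretical_conditional_gc(bench3, 1, 2, 3, grid_default)
  expect_gt(max(cs12$values), 0.5)
  # block-diagonal truth: every direction of an uncoupled model is zero
  m0 <- white_noise_model()
  for (d in directions3) {
    expect_lte(max(theoretical_conditional_gc(m0, d$source, d$target,
                                              d$cond, grid_default)$values),
               1e-12)
  }
})

test_that("projection and state-space routes agree on all directed pairs", {
  for (s in 1:3) {
    for (t_ in setdiff(1:3, s)) {
      a <- theoretical_conditional_gc(bench3, s, t_, grid = grid_default,
                                      route = "ss")
      b <- theoretical_conditional_gc(bench3, s, t_, grid = grid_default,
                                      route = "projection")
      expect_lt(max(abs(a$values - b$values)), 1e-6)
    }
  }
})

test_that("estimated conditional GC shows the order-dependent tradeoff", {
  # at the true order the reduced model is misspecified: bias away from the
  # zero truth on 3->1; at order 20 the percentile band inflates on coupled
  # directions (checked via a small seeded ensemble)
  n_rep <- 15
  vals3 <- matrix(0, n_rep, 513)
  spread3 <- spread20 <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    s <- simulate_var(bench3, 500, seed = 300 + i)
    suppressWarnings({
      vals3[i, ] <- conditional_spectral_gc_var(s, 3, 1, 2, order_full = 3,
                                                grid = grid_default)$values
      spread3[i] <- max(conditional_spectral_gc_var(s, 1, 2, 3,
                                                    order_full = 3,
                                                    grid = grid_default)$values)
      spread20[i] <- max(conditional_spectral_gc_var(s, 1, 2, 3,
                                                     order_full = 20,
                                                     grid = grid_default)$values)
    })
  }
  med31 <- apply(vals3, 2, median)
  expect_gt(max(med31), 0.005) # nonzero median: biased away from truth
  expect_gt(stats::sd(spread20), stats::sd(spread3)) # order-20 variability
})

test_that("time-domain GC obeys and saturates the spectral-integral identity", {
  expect_equal(time_domain_gc(white_noise_model(), 1, 2), 0)
  dense <- frequency_grid(120, 2049)
  for (d in directions3) {
    cs <- theoretical_conditional_gc(bench3, d$source, d$target, d$cond, dense)
    Fd <- time_domain_gc(bench3, d$source, d$target, d$cond)
    avg <- spectrum_time_average(cs)
    expect_lte(avg, Fd + 1e-6)
    expect_lt(abs(avg - Fd), 1e-4)
  }
})

test_that("estimated null-direction GC is indistinguishable from a permutation null", {
  s <- simulate_var(bench3, 1e4, seed = 17)
  observed <- time_domain_gc(s, 3, 1, 2, order_full = 3)
  x <- s$data
  set.seed(99)
  null_stats <- vapply(1:100, function(i) {
    shift <- sample(50:(nrow(x) - 50), 1)
    xp <- x
    xp[, 3] <- x[c((shift + 1):nrow(x), 1:shift), 3] # circularly shift source
    time_domain_gc(multichannel_series(xp, 120), 3, 1, 2, order_full = 3)
  }, numeric(1))
  expect_lt(observed, quantile(null_stats, 0.95))
})

test_that("every returned spectrum is nonnegative after clamping", {
  set.seed(4)
  for (i in 1:5) {
    m <- random_stable_var(2, 2, seed = 400 + i)
    expect_true(all(bivariate_spectral_gc(m, grid_default)$values >= 0))
  }
  s <- simulate_var(bench3, 400, seed = 5)
  suppressWarnings(cs <- conditional_spectral_gc_var(s, 2, 1, 3, order_full = 8,
                                                     grid = grid_default))
  expect_true(all(cs$values >= 0))
  expect_gte(cs$n_clamped, 0)
})
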