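# shared fixtures, built once per test run

grid_default <- frequency_grid(120)

bench3 <- make_three_node_benchmark()
bench2 <- lapply(c(10, 30, 50), make_two_node_benchmark)
names(bench2) <- c("10", "30", "50")

# the three displayed directions of the 3-node study, conditioning on the
# remaining channel
directions3 <- list(list(source = 1, target = 2, cond = 3),
                    list(source = 2, target = 3, cond = 1),
                    list(source = 3, target = 1, cond = 2))

ctranspose <- function(x) Conj(t(x))

white_noise_model <- function(M = 3, fs = 120) {
  make_var(array(0, c(M, M, 1)), diag(M), fs)
}

# rescale one channel of a VAR model by a positive factor:
# x_c -> alpha x_c transforms A_k[i,j] -> A_k[i,j] alpha^(d_ic - d_jc)
# and Sigma -> D Sigma D with D = diag(..., alpha at c, ...)
rescale_channel <- function(model, channel, alpha) {
  M <- model$n_channels
  d <- rep(1, M)
  d[channel] <- alpha
  co <- model$coeffs
  for (k in seq_len(model$order)) {
    co[, , k] <- diag(d) %*% co[, , k] %*% diag(1 / d)
  }
  make_var(co, diag(d) %*% model$noise_cov %*% diag(d), model$fs,
           model$labels, warn_unstable = FALSE)
}
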