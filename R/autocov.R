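# Discrete Lyapunov equation P = A P A' + Q by doubling:
# P_k = sum_{j < 2^k} A^j Q A'^j with A_k = A^{2^k}. Quadratic in the number
# of terms, so a handful of iterations reach machine precision for any
# stable A.
dlyap <- function(A, Q, tol = 1e-14, max_iter = 100L) {
  stopifnot(all(dim(A) == dim(Q)))
  if (spectral_radius(A) >= 1) stop("Lyapunov equation requires a stable A")
  P <- Q
  Ak <- A
  for (i in seq_len(max_iter)) {
    Pn <- P + Ak %*% P %*% t(Ak)
    delta <- max(abs(Pn - P))
    P <- Pn
    Ak <- Ak %*% Ak
    if (delta <= tol * max(1, max(abs(P))) && max(abs(Ak)) < 1e-7) break
  }
  symmetrize(P)
}

#' Autocovariance sequence of a VAR model
#'
#' Computes the exact process autocovariances
#' `Gamma(h) = E[x(t) x(t-h)']` for `h = 0 .. max_lag` by solving the
#' discrete Lyapunov equation on the companion form for the block of lags
#' `0 .. p-1` and extending with the Yule-Walker recursion
#' `Gamma(h) = sum_k A_k Gamma(h-k)`.
#'
#' @param model A stable `var_model`.
#' @param max_lag Largest lag required.
#' @return An M x M x (max_lag + 1) array; slice `h + 1` holds `Gamma(h)`.
#' @export
var_autocov <- function(model, max_lag) {
  stopifnot(inherits(model, "var_model"), max_lag >= 0L)
  if (!model$stable) stop("autocovariances require a stable model")
  M <- model$n_channels
  p <- model$order
  F <- companion_matrix(model$coeffs)
  Q <- matrix(0, M * p, M * p)
  Q[seq_len(M), seq_len(M)] <- model$noise_cov
  P <- dlyap(F, Q)

  G <- array(0, c(M, M, max_lag + 1L))
  for (h in 0:min(max_lag, p - 1L)) {
    G[, , h + 1L] <- P[seq_len(M), h * M + seq_len(M)]
  }
  if (max_lag >= p) {
    for (h in p:max_lag) {
      acc <- matrix(0, M, M)
      for (k in seq_len(p)) acc <- acc + model$coeffs[, , k] %*% G[, , h - k + 1L]
      G[, , h + 1L] <- acc
    }
  }
  G
}

# Fit a VAR(order) to an exact autocovariance sequence (multivariate
# Yule-Walker): solve [A_1 .. A_q] B = [Gamma(1) .. Gamma(q)] where B is the
# symmetric block-Toeplitz matrix with block (k, h) = Gamma(h - k). Returns
# the coefficient array and the implied innovation covariance
# Sigma = Gamma(0) - sum_k A_k Gamma(k)'.
yw_var_from_autocov <- function(G, order) {
  M <- dim(G)[1]
  stopifnot(dim(G)[3] >= order + 1L)
  q <- as.integer(order)
  B <- matrix(0, M * q, M * q)
  for (k in seq_len(q)) {
    for (h in seq_len(q)) {
      blk <- if (h >= k) G[, , h - k + 1L] else t(G[, , k - h + 1L])
      B[(k - 1) * M + seq_len(M), (h - 1) * M + seq_len(M)] <- blk
    }
  }
  RHS <- matrix(0, M, M * q)
  for (h in seq_len(q)) RHS[, (h - 1) * M + seq_len(M)] <- G[, , h + 1L]
  Astack <- t(solve(B, t(RHS)))
  coeffs <- array(0, c(M, M, q))
  Sigma <- G[, , 1L]
  for (k in seq_len(q)) {
    Ak <- Astack[, (k - 1) * M + seq_len(M), drop = FALSE]
    coeffs[, , k] <- Ak
    Sigma <- Sigma - Ak %*% t(G[, , k + 1L])
  }
  list(coeffs = coeffs, sigma = symmetrize(Sigma))
}
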