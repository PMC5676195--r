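#' Ordinary least squares VAR fit
#'
#' Estimates `A_1 .. A_p` by regressing `x(t)` on the p stacked lags
#' (no intercept; the benchmark processes are zero mean — use
#' `demean = TRUE` to subtract column means first). The innovation
#' covariance is estimated from the residuals with divisor
#' `(T_eff - M * p)`, where `T_eff = T - p` is the number of regression
#' rows, an unbiased-flavor choice.
#'
#' @param series A `multichannel_series` or numeric matrix (rows = time).
#' @param order Model order p (>= 1).
#' @param demean Subtract column means before fitting (default `FALSE`).
#' @param fs Sampling rate, required only when `series` is a bare matrix.
#' @return A `var_model` with attribute `fitted = TRUE`; its `stable` flag
#'   is informational (no warning is raised for near-unstable fits).
#' @export
fit_var_ols <- function(series, order, demean = FALSE, fs = NULL) {
  x <- as_series_matrix(series)
  fs <- if (inherits(series, "multichannel_series")) series$fs else fs
  if (is.null(fs)) stop("fs must be supplied when fitting a bare matrix")
  labels <- colnames(x) %||% paste0("ch", seq_len(ncol(x)))
  Tn <- nrow(x)
  M <- ncol(x)
  order <- as.integer(order)
  stopifnot(order >= 1L)
  if (Tn - order <= M * order) {
    stop("series too short: need more than ", order + M * order,
         " samples for an order-", order, " fit on ", M, " channels")
  }
  if (demean) x <- sweep(x, 2, colMeans(x))

  Y <- x[(order + 1):Tn, , drop = FALSE]
  X <- do.call(cbind, lapply(seq_len(order), function(k) {
    x[(order + 1 - k):(Tn - k), , drop = FALSE]
  }))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("rank-deficient regressor matrix: rank ", qx$rank, " < ",
         ncol(X), " columns (collinear or constant channels?)")
  }
  B <- qr.coef(qx, Y)
  resid <- Y - X %*% B
  t_eff <- Tn - order
  Sigma <- crossprod(resid) / (t_eff - M * order)

  coeffs <- array(0, c(M, M, order))
  for (k in seq_len(order)) {
    coeffs[, , k] <- t(B[(k - 1) * M + seq_len(M), , drop = FALSE])
  }
  fit <- make_var(coeffs, symmetrize(Sigma), fs, labels,
                  warn_unstable = FALSE)
  attr(fit, "fitted") <- TRUE
  attr(fit, "residual_cov_ml") <- symmetrize(crossprod(resid) / t_eff)
  attr(fit, "n_obs") <- Tn
  fit
}

#' Select a VAR order by information criterion
#'
#' Fits orders `1..max_order` and returns the minimizer of AIC or BIC
#' computed from the maximum-likelihood residual covariance,
#' `log det(Sigma_ML) + penalty * M^2 p / T_eff` with penalty 2 (AIC) or
#' `log(T_eff)` (BIC). Exact ties break toward the smaller order.
#'
#' @param series A `multichannel_series` or numeric matrix.
#' @param max_order Largest order to consider.
#' @param criterion `"bic"` (default), `"aic"`, or a function
#'   `f(fit, t_eff)` returning a score to minimize.
#' @param fs Sampling rate for bare matrices.
#' @return The selected order (integer).
#' @export
select_order <- function(series, max_order, criterion = "bic", fs = NULL) {
  max_order <- as.integer(max_order)
  stopifnot(max_order >= 1L)
  if (!is.function(criterion)) {
    criterion <- match.arg(criterion, c("bic", "aic"))
  }
  scores <- vapply(seq_len(max_order), function(q) {
    fit <- fit_var_ols(series, q, fs = fs)
    t_eff <- attr(fit, "n_obs") - q
    if (is.function(criterion)) {
      criterion(fit, t_eff)
    } else {
      pen <- if (criterion == "aic") 2 else log(t_eff)
      ld <- as.numeric(determinant(attr(fit, "residual_cov_ml"),
                                   logarithm = TRUE)$modulus)
      ld + pen * fit$n_channels^2 * q / t_eff
    }
  }, numeric(1))
  which.min(scores) # which.min returns the first (smallest) index on ties
}
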