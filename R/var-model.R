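#' Construct a vector autoregressive (VAR) model
#'
#' A VAR(p) process on M channels is
#' \deqn{x(t) = \sum_{k=1}^p A_k x(t-k) + e(t), \quad e(t) \sim N(0, \Sigma),}
#' with real M-by-M coefficient matrices `A_k` and a symmetric positive
#' definite innovation covariance. The model carries its sampling rate so
#' every spectral quantity can be reported in Hz.
#'
#' Stability (spectral radius of the companion matrix strictly below 1) is
#' checked on construction. An unstable model is still returned — ordinary
#' least squares fits can be near-unstable — but carries `stable = FALSE`
#' and, by default, a warning.
#'
#' @param coeffs Either an M x M x p array or a list of p M x M matrices
#'   (`A_1 .. A_p`); entry `A_k[i, j]` multiplies channel j at lag k in the
#'   equation of channel i.
#' @param noise_cov Innovation covariance, symmetric positive definite.
#' @param fs Sampling rate in Hz.
#' @param labels Optional character vector of channel names.
#' @param warn_unstable Emit a warning when the model is unstable
#'   (default `TRUE`).
#' @return An object of class `var_model` with elements `coeffs` (array),
#'   `noise_cov`, `order`, `n_channels`, `fs`, `labels`, `stable`,
#'   `spectral_radius`.
#' @examples
#' m <- make_var(array(0, c(3, 3, 1)), diag(3), fs = 120)
#' m$spectral_radius
#' @export
make_var <- function(coeffs, noise_cov, fs, labels = NULL,
                     warn_unstable = TRUE) {
  if (is.list(coeffs)) {
    p <- length(coeffs)
    stopifnot(p >= 1L)
    M <- nrow(coeffs[[1]])
    arr <- array(0, c(M, M, p))
    for (k in seq_len(p)) {
      Ak <- as.matrix(coeffs[[k]])
      if (!all(dim(Ak) == c(M, M))) {
        stop("coefficient matrix for lag ", k, " is not ", M, "x", M)
      }
      arr[, , k] <- Ak
    }
    coeffs <- arr
  }
  if (length(dim(coeffs)) == 2L) coeffs <- array(coeffs, c(dim(coeffs), 1L))
  stopifnot(length(dim(coeffs)) == 3L)
  M <- dim(coeffs)[1]
  p <- dim(coeffs)[3]
  if (dim(coeffs)[2] != M) stop("coefficient matrices must be square")
  if (M < 1L || p < 1L) stop("need M >= 1 channels and order p >= 1")

  noise_cov <- as.matrix(noise_cov)
  if (!all(dim(noise_cov) == c(M, M))) {
    stop("noise_cov must be ", M, "x", M, " to match the coefficients")
  }
  if (!is_symmetric_tol(noise_cov, 1e-12)) {
    stop("noise_cov is not symmetric (tolerance 1e-12)")
  }
  if (!is_positive_definite(noise_cov)) {
    stop("noise_cov is not positive definite")
  }
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)

  if (is.null(labels)) labels <- paste0("ch", seq_len(M))
  stopifnot(length(labels) == M)

  rho <- spectral_radius(companion_matrix(coeffs))
  stable <- rho < 1
  if (!stable && warn_unstable) {
    warning(sprintf("VAR model is unstable (companion spectral radius %.4f)",
                    rho), call. = FALSE)
  }
  structure(list(coeffs = coeffs, noise_cov = symmetrize(noise_cov),
                 order = p, n_channels = M, fs = fs,
                 labels = as.character(labels),
                 stable = stable, spectral_radius = rho),
            class = "var_model")
}

#' Companion matrix of a VAR coefficient array
#'
#' Stacks the p lag matrices of a VAR(p) into the (Mp) x (Mp) first-order
#' companion form whose spectral radius decides stability.
#'
#' @param coeffs M x M x p coefficient array (or a `var_model`).
#' @return The companion matrix.
#' @export
companion_matrix <- function(coeffs) {
  if (inherits(coeffs, "var_model")) coeffs <- coeffs$coeffs
  M <- dim(coeffs)[1]
  p <- dim(coeffs)[3]
  top <- matrix(coeffs, M, M * p)
  if (p == 1L) return(top)
  rbind(top, cbind(diag(M * (p - 1)), matrix(0, M * (p - 1), M)))
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("VAR(%d) model: %d channels, fs = %g Hz\n",
              x$order, x$n_channels, x$fs))
  cat(sprintf("  companion spectral radius %.4f (%s)\n", x$spectral_radius,
              if (x$stable) "stable" else "UNSTABLE"))
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Pad a VAR model with zero lag matrices
#'
#' Returns an equivalent model of higher nominal order obtained by appending
#' all-zero coefficient matrices. Useful for order-invariance checks: the
#' process is unchanged.
#'
#' @param model A `var_model`.
#' @param order Target order, at least `model$order`.
#' @return A `var_model` of the requested order.
#' @export
pad_var_order <- function(model, order) {
  stopifnot(inherits(model, "var_model"), order >= model$order)
  if (order == model$order) return(model)
  M <- model$n_channels
  arr <- array(0, c(M, M, order))
  arr[, , seq_len(model$order)] <- model$coeffs
  make_var(arr, model$noise_cov, model$fs, model$labels)
}

#' Random stable VAR model
#'
#' Draws a random VAR(p) with Gaussian coefficient entries, then rescales
#' lag k by `r^k` so the companion spectral radius equals a target radius
#' drawn uniformly below `max_radius` (scaling `A_k` by `c^k` scales every
#' companion eigenvalue by `c`). Used for property-style fuzzing of the
#' normalization and identity invariants.
#'
#' @param M Number of channels.
#' @param p Model order.
#' @param seed Optional integer seed.
#' @param max_radius Upper bound for the companion spectral radius.
#' @param fs Sampling rate in Hz.
#' @param sigma `"diagonal"` (independent innovations with variances drawn
#'   in `[0.5, 2]`) or `"full"` (a random correlated covariance).
#' @return A stable `var_model`.
#' @export
random_stable_var <- function(M, p, seed = NULL, max_radius = 0.92,
                              fs = 120, sigma = c("diagonal", "full")) {
  sigma <- match.arg(sigma)
  if (!is.null(seed)) set.seed(seed)
  coeffs <- array(rnorm(M * M * p, sd = 0.5), c(M, M, p))
  rho <- spectral_radius(companion_matrix(coeffs))
  target <- stats::runif(1, 0.4, max_radius)
  if (rho > 0) {
    sc <- target / rho
    for (k in seq_len(p)) coeffs[, , k] <- coeffs[, , k] * sc^k
  }
  Sig <- if (sigma == "diagonal") {
    diag(stats::runif(M, 0.5, 2), M)
  } else {
    W <- matrix(rnorm(M * M), M)
    symmetrize(W %*% t(W) / M + diag(0.2, M))
  }
  make_var(coeffs, Sig, fs)
}
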