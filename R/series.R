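#' Multichannel time series container
#'
#' A T x M matrix of samples (rows = time, columns = channels) together with
#' its sampling rate and channel labels.
#'
#' @param data Numeric T x M matrix without missing values.
#' @param fs Sampling rate in Hz.
#' @param labels Optional channel labels (defaults to column names or
#'   `ch1..chM`).
#' @return An object of class `multichannel_series`.
#' @export
multichannel_series <- function(data, fs, labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (anyNA(data)) stop("series contains missing values")
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  if (is.null(labels)) labels <- colnames(data) %||% paste0("ch", seq_len(ncol(data)))
  stopifnot(length(labels) == ncol(data))
  colnames(data) <- labels
  structure(list(data = data, fs = fs, labels = as.character(labels)),
            class = "multichannel_series")
}

#' @export
print.multichannel_series <- function(x, ...) {
  cat(sprintf("multichannel series: %d samples x %d channels, fs = %g Hz\n",
              nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

as_series_matrix <- function(series) {
  if (inherits(series, "multichannel_series")) return(series$data)
  as.matrix(series)
}

#' Simulate a VAR process
#'
#' Iterates the VAR recursion with Gaussian innovations of covariance
#' `noise_cov`, starting from a zero initial state and discarding `burn_in`
#' samples so the retained stretch is effectively stationary. A given seed
#' fixes the innovation stream entirely, so identical arguments give
#' bit-identical output.
#'
#' @param model A stable `var_model`.
#' @param n_samples Number of samples to return.
#' @param seed Optional integer seed for the innovation stream.
#' @param burn_in Number of initial samples to discard (default 1000).
#' @return A `multichannel_series` of `n_samples` rows.
#' @export
simulate_var <- function(model, n_samples, seed = NULL, burn_in = 1000L) {
  stopifnot(inherits(model, "var_model"), n_samples >= 1L, burn_in >= 0L)
  if (!model$stable) {
    stop("cannot simulate an unstable VAR model (spectral radius ",
         sprintf("%.4f", model$spectral_radius), " >= 1)")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  M <- model$n_channels
  p <- model$order
  ntot <- n_samples + burn_in
  L <- chol(model$noise_cov)
  E <- matrix(rnorm(ntot * M), ntot, M) %*% L
  A <- lapply(seq_len(p), function(k) model$coeffs[, , k])
  X <- matrix(0, ntot + p, M)
  for (t in seq_len(ntot)) {
    tt <- t + p
    acc <- E[t, ]
    for (k in seq_len(p)) acc <- acc + A[[k]] %*% X[tt - k, ]
    X[tt, ] <- acc
  }
  multichannel_series(X[p + burn_in + seq_len(n_samples), , drop = FALSE],
                      model$fs, model$labels)
}
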