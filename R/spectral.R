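# Coefficient transform A(f) = I - sum_k A_k exp(-i 2 pi f k / fs),
# returned as an M x M x nf complex array.
var_coefficient_transform <- function(model, freqs) {
  M <- model$n_channels
  p <- model$order
  E <- exp(-2i * pi * outer(seq_len(p), freqs) / model$fs) # p x nf
  Cflat <- matrix(model$coeffs, M * M, p)
  Aflat <- -Cflat %*% E
  eye <- which(diag(M) == 1)
  Aflat[eye, ] <- Aflat[eye, ] + 1
  array(Aflat, c(M, M, length(freqs)))
}

# Transfer function H(f) = A(f)^{-1} of a VAR model, via linear solves.
var_transfer <- function(model, freqs) {
  A <- var_coefficient_transform(model, freqs)
  M <- dim(A)[1]
  H <- array(0i, dim(A))
  I <- diag(M) + 0i
  for (j in seq_along(freqs)) {
    Hf <- tryCatch(solve(A[, , j], I), error = function(e) NULL)
    if (is.null(Hf)) {
      stop(sprintf("coefficient transform A(f) is singular at f = %.6g Hz",
                   freqs[j]))
    }
    H[, , j] <- Hf
  }
  H
}

#' Spectral matrices of a VAR model
#'
#' Evaluates, at every grid frequency, the coefficient transform
#' \deqn{A(f) = I - \sum_{k=1}^p A_k e^{-i 2\pi f k / f_s},}
#' the transfer function `H(f) = A(f)^{-1}` (by linear solve), and the
#' cross-spectral density `S(f) = H(f) \Sigma H(f)^H`. Spectra are in
#' per-sample units (no division by `fs`); all causality and coherence
#' measures in the package are scale-invariant ratios, so the convention
#' only affects reported raw spectra.
#'
#' @param model A `var_model`.
#' @param grid A `frequency_grid` (or numeric vector of frequencies in Hz).
#' @return An object of class `spectral_matrices` with complex arrays `A`,
#'   `H`, `S` (each M x M x nf), the grid frequencies `freqs`, `fs` and
#'   channel `labels`.
#' @export
var_spectral_matrices <- function(model, grid = frequency_grid(model$fs)) {
  grid <- as_frequency_grid(grid, model$fs)
  freqs <- grid$freqs
  A <- var_coefficient_transform(model, freqs)
  M <- model$n_channels
  H <- array(0i, dim(A))
  S <- array(0i, dim(A))
  I <- diag(M) + 0i
  Sig <- model$noise_cov
  for (j in seq_along(freqs)) {
    Hf <- tryCatch(solve(A[, , j], I), error = function(e) NULL)
    if (is.null(Hf)) {
      stop(sprintf("coefficient transform A(f) is singular at f = %.6g Hz",
                   freqs[j]))
    }
    H[, , j] <- Hf
    Sf <- Hf %*% Sig %*% ctranspose(Hf)
    S[, , j] <- (Sf + ctranspose(Sf)) / 2
  }
  structure(list(A = A, H = H, S = S, freqs = freqs, fs = model$fs,
                 labels = model$labels),
            class = "spectral_matrices")
}

#' @export
print.spectral_matrices <- function(x, ...) {
  cat(sprintf("spectral matrices: %d channels at %d frequencies on [%g, %g] Hz\n",
              dim(x$S)[1], length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Power spectral density of one channel
#'
#' Convenience extractor: the (real, nonnegative) diagonal entry
#' `S_cc(f)` of a `spectral_matrices` object.
#'
#' @param sm A `spectral_matrices` object.
#' @param channel Channel index or label.
#' @return Numeric vector aligned with `sm$freqs`.
#' @export
psd <- function(sm, channel) {
  stopifnot(inherits(sm, "spectral_matrices"))
  ch <- resolve_channels(channel, sm$labels)
  Re(sm$S[ch, ch, ])
}
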