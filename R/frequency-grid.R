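#' Frequency grid for spectral measures
#'
#' Builds a strictly increasing grid of analysis frequencies in Hz on
#' `[0, fmax]`, where `fmax` cannot exceed the Nyquist frequency `fs/2`.
#' All spectral functions in the package evaluate their measures on such a
#' grid.
#'
#' @param fs Sampling rate in Hz.
#' @param n_freq Number of grid points (default 513, endpoints included).
#' @param fmax Upper frequency in Hz; defaults to the Nyquist frequency.
#' @return An object of class `frequency_grid` with elements `freqs` and
#'   `fs`.
#' @examples
#' g <- frequency_grid(120)
#' range(g$freqs)
#' @export
frequency_grid <- function(fs, n_freq = 513L, fmax = fs / 2) {
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  n_freq <- as.integer(n_freq)
  stopifnot(n_freq >= 2L, fmax > 0, fmax <= fs / 2 + 1e-9)
  structure(list(freqs = seq(0, fmax, length.out = n_freq), fs = fs),
            class = "frequency_grid")
}

#' Coerce to a frequency grid
#'
#' Accepts an existing `frequency_grid` (returned unchanged after checking
#' it fits under the model's Nyquist frequency) or a numeric vector of
#' frequencies in Hz.
#'
#' @param x A `frequency_grid` or numeric vector of frequencies in Hz.
#' @param fs Sampling rate in Hz the grid must be compatible with.
#' @return A `frequency_grid`.
#' @export
as_frequency_grid <- function(x, fs) {
  if (inherits(x, "frequency_grid")) {
    if (max(x$freqs) > fs / 2 + 1e-9) {
      stop("frequency grid exceeds Nyquist frequency ", fs / 2, " Hz")
    }
    return(x)
  }
  x <- as.numeric(x)
  if (any(x < 0) || any(x > fs / 2 + 1e-9)) {
    stop("frequencies must lie in [0, fs/2] = [0, ", fs / 2, "] Hz")
  }
  if (any(diff(x) <= 0)) stop("frequencies must be strictly increasing")
  structure(list(freqs = x, fs = fs), class = "frequency_grid")
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf("frequency grid: %d points on [%g, %g] Hz (fs = %g Hz)\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$fs))
  invisible(x)
}
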