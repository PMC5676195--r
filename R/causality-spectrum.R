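#' Directed frequency-domain measure container
#'
#' Holds one directed measure (Granger-Geweke causality, directed coherence
#' or partial directed coherence) evaluated on a frequency grid for one
#' source/target pair, with its conditioning set and provenance.
#'
#' @param measure One of `"ggc"`, `"dc"`, `"pdc"`.
#' @param source,target Channel indices.
#' @param cond Conditioning channel indices (possibly empty).
#' @param grid A `frequency_grid`.
#' @param values Numeric vector aligned with `grid$freqs`.
#' @param provenance A list; conventionally `estimator`
#'   (`"theoretical-ss"`, `"theoretical-projection"`, `"var"`, `"ss"`),
#'   `order_full`, `order_reduced`.
#' @param n_clamped Number of grid points where a log-ratio argument below 1
#'   was clamped to 1 (value 0).
#' @param labels Channel labels of the originating model.
#' @return An object of class `causality_spectrum`.
#' @export
causality_spectrum <- function(measure, source, target, cond, grid, values,
                               provenance = list(), n_clamped = 0L,
                               labels = NULL) {
  stopifnot(length(values) == length(grid$freqs))
  structure(list(measure = measure, source = source, target = target,
                 cond = cond, freqs = grid$freqs, fs = grid$fs,
                 values = as.numeric(values), provenance = provenance,
                 n_clamped = as.integer(n_clamped), labels = labels),
            class = "causality_spectrum")
}

# Clamp a spectral log-ratio at zero. Arguments of the log below 1 give
# negative values; those are set to 0 and counted. A warning is emitted only
# when a clamp is substantial (beyond numerical slack), never silently.
clamp_nonnegative <- function(values, slack = 1e-8) {
  neg <- which(values < 0)
  if (length(neg) && min(values) < -slack) {
    warning(sprintf("clamped %d spectral GC value(s) to 0 (most negative %.3g)",
                    length(neg), min(values)), call. = FALSE)
  }
  values[neg] <- 0
  list(values = values, n_clamped = length(neg))
}

#' @export
print.causality_spectrum <- function(x, ...) {
  est <- x$provenance$estimator %||% "?"
  cat(sprintf("%s spectrum %s -> %s%s [%s]: %d frequencies, max %.4g%s\n",
              toupper(x$measure), x$source, x$target,
              if (length(x$cond)) paste0(" | {", cond_label(x$cond), "}") else "",
              est, length(x$freqs), max(x$values),
              if (x$n_clamped > 0) sprintf(" (%d clamped)", x$n_clamped) else ""))
  invisible(x)
}

#' @export
as.data.frame.causality_spectrum <- function(x, ...,
                                             realization_id = NA_integer_) {
  data.frame(measure = x$measure,
             source = x$source,
             target = x$target,
             cond_set = cond_label(x$cond),
             frequency_hz = x$freqs,
             value = x$values,
             provenance = x$provenance$estimator %||% NA_character_,
             order_full = x$provenance$order_full %||% NA_integer_,
             order_reduced = x$provenance$order_reduced %||% NA_integer_,
             realization_id = realization_id,
             stringsAsFactors = FALSE)
}

#' Time average of a causality spectrum
#'
#' Trapezoidal average of the spectrum over its grid; for Geweke spectra on
#' a full `[0, fs/2]` grid this approximates the frequency integral that
#' recovers the time-domain measure.
#'
#' @param cs A `causality_spectrum`.
#' @return A scalar.
#' @export
spectrum_time_average <- function(cs) {
  trapezoid_average(cs$freqs, cs$values)
}
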