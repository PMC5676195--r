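#' Directed coherence for all ordered channel pairs
#'
#' Squared-magnitude directed coherence (DC) from source j to target i:
#' \deqn{|\gamma_{ij}(f)|^2 = \frac{\sigma_j^2 |H_{ij}(f)|^2}
#'   {\sum_m \sigma_m^2 |H_{im}(f)|^2},}
#' the relative amount of spectral power arriving at the target from each
#' source at each frequency. Rows (fixed target) of squared magnitudes sum
#' to 1 by construction. This diagonal-`Sigma` form is the default; if the
#' innovations are noticeably correlated (any cross-correlation above 0.01)
#' a warning is raised, and `orthogonalize = "cholesky"` applies the
#' (ordering-dependent) generalized form with `H` replaced by `H L`, `L`
#' the lower Cholesky factor of `Sigma`.
#'
#' @param model A stable `var_model`.
#' @param grid A `frequency_grid`.
#' @param orthogonalize `"none"` (default) or `"cholesky"`.
#' @return An object of class `coherence_set`: list with `values`
#'   (`M x M x nf`, entry `[target, source, ]`), `measure = "dc"`, `freqs`,
#'   `labels`.
#' @export
directed_coherence <- function(model, grid = frequency_grid(model$fs),
                               orthogonalize = c("none", "cholesky")) {
  stopifnot(inherits(model, "var_model"))
  orthogonalize <- match.arg(orthogonalize)
  grid <- as_frequency_grid(grid, model$fs)
  M <- model$n_channels
  Sig <- model$noise_cov
  corr <- abs(Sig / sqrt(diag(Sig) %o% diag(Sig)))
  if (orthogonalize == "none" && max(corr[upper.tri(corr)], 0) > 0.01) {
    warning("innovations are correlated (max cross-correlation ",
            sprintf("%.3f", max(corr[upper.tri(corr)])),
            "); diagonal-Sigma DC ignores this — consider ",
            "orthogonalize = \"cholesky\"", call. = FALSE)
  }
  H <- var_transfer(model, grid$freqs)
  nf <- length(grid$freqs)
  vals <- array(0, c(M, M, nf))
  if (orthogonalize == "cholesky") {
    L <- t(chol(Sig))
    for (j in seq_len(nf)) {
      num <- Mod(H[, , j] %*% L)^2
      vals[, , j] <- num / rowSums(num)
    }
  } else {
    s2 <- diag(Sig)
    for (j in seq_len(nf)) {
      num <- Mod(H[, , j])^2 * rep(s2, each = M)
      tot <- rowSums(num)
      if (any(tot <= 0)) {
        stop(sprintf("zero total power at f = %.6g Hz", grid$freqs[j]))
      }
      vals[, , j] <- num / tot
    }
  }
  structure(list(measure = "dc", values = vals, freqs = grid$freqs,
                 fs = model$fs, labels = model$labels),
            class = "coherence_set")
}

#' Partial directed coherence for all ordered channel pairs
#'
#' Squared-magnitude partial directed coherence (PDC) from source j to
#' target i, the coefficient-based measure of *direct* directed influence:
#' \deqn{|\pi_{ij}(f)|^2 = \frac{|\bar A_{ij}(f)|^2}
#'   {\sum_m |\bar A_{mj}(f)|^2},}
#' with \eqn{\bar A(f)} the coefficient transform. Columns (fixed source)
#' of squared magnitudes sum to 1. The original coefficient-based
#' normalization is used (generalized/information variants are out of
#' scope).
#'
#' @inheritParams directed_coherence
#' @return A `coherence_set` with `measure = "pdc"`.
#' @export
partial_directed_coherence <- function(model, grid = frequency_grid(model$fs)) {
  stopifnot(inherits(model, "var_model"))
  grid <- as_frequency_grid(grid, model$fs)
  M <- model$n_channels
  A <- var_coefficient_transform(model, grid$freqs)
  nf <- length(grid$freqs)
  vals <- array(0, c(M, M, nf))
  for (j in seq_len(nf)) {
    num <- Mod(A[, , j])^2
    tot <- colSums(num)
    if (any(tot <= 0)) {
      stop(sprintf("zero coefficient-transform column at f = %.6g Hz",
                   grid$freqs[j]))
    }
    vals[, , j] <- num / rep(tot, each = M)
  }
  structure(list(measure = "pdc", values = vals, freqs = grid$freqs,
                 fs = model$fs, labels = model$labels),
            class = "coherence_set")
}

#' @export
print.coherence_set <- function(x, ...) {
  cat(sprintf("%s set: %d channels at %d frequencies\n",
              toupper(x$measure), dim(x$values)[1], length(x$freqs)))
  invisible(x)
}

#' Extract one directed pair from a coherence set
#'
#' @param set A `coherence_set` from [directed_coherence()] or
#'   [partial_directed_coherence()].
#' @param source,target Channel index or label.
#' @return A `causality_spectrum` holding the squared-magnitude values.
#' @export
coherence_pair <- function(set, source, target) {
  stopifnot(inherits(set, "coherence_set"))
  s <- resolve_channels(source, set$labels)
  t_ <- resolve_channels(target, set$labels)
  grid <- structure(list(freqs = set$freqs, fs = set$fs),
                    class = "frequency_grid")
  causality_spectrum(set$measure, s, t_, integer(0), grid,
                     set$values[t_, s, ],
                     list(estimator = "theoretical"), 0L, set$labels)
}

#' @export
as.data.frame.coherence_set <- function(x, ...) {
  M <- dim(x$values)[1]
  out <- list()
  for (s in seq_len(M)) {
    for (t_ in seq_len(M)) {
      out[[length(out) + 1L]] <- data.frame(
        measure = x$measure, source = s, target = t_, cond_set = "",
        frequency_hz = x$freqs, value = x$values[t_, s, ],
        provenance = "theoretical", order_full = NA_integer_,
        order_reduced = NA_integer_, realization_id = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Causal decomposition of a receiver's power spectrum
#'
#' Splits the target channel's power spectral density into per-source
#' partial spectra
#' \deqn{S_{t|j}(f) = S_{tt}(f) \, |\gamma_{tj}(f)|^2,}
#' using the squared-magnitude directed coherence (only the squared form
#' makes the parts sum to the total, by the DC row normalization). The part
#' with `j = target` is the autonomous (non-explained) component; the parts
#' sum to `S_tt(f)` at every frequency by construction.
#'
#' @param model A stable `var_model`.
#' @param grid A `frequency_grid`.
#' @param target Channel index or label of the receiver.
#' @param orthogonalize Passed to [directed_coherence()].
#' @return An object of class `spectral_decomposition`: list with `target`,
#'   `freqs`, `total` (the PSD `S_tt`), and `partials` (M x nf matrix, row
#'   j = `S_t|j`).
#' @export
spectral_decomposition <- function(model, grid = frequency_grid(model$fs),
                                   target,
                                   orthogonalize = c("none", "cholesky")) {
  stopifnot(inherits(model, "var_model"))
  grid <- as_frequency_grid(grid, model$fs)
  t_ <- resolve_channels(target, model$labels)
  dc <- directed_coherence(model, grid, match.arg(orthogonalize))
  sm <- var_spectral_matrices(model, grid)
  total <- Re(sm$S[t_, t_, ])
  partials <- dc$values[t_, , ] * rep(total, each = model$n_channels)
  dim(partials) <- c(model$n_channels, length(grid$freqs))
  rownames(partials) <- model$labels
  structure(list(target = t_, freqs = grid$freqs, fs = model$fs,
                 total = total, partials = partials,
                 labels = model$labels),
            class = "spectral_decomposition")
}

#' @export
print.spectral_decomposition <- function(x, ...) {
  cat(sprintf("causal spectral decomposition of channel %d (%s): %d frequencies\n",
              x$target, x$labels[x$target], length(x$freqs)))
  invisible(x)
}

#' @export
as.data.frame.spectral_decomposition <- function(x, ...) {
  M <- nrow(x$partials)
  do.call(rbind, lapply(seq_len(M), function(j) {
    data.frame(target = x$target, frequency_hz = x$freqs,
               total_psd = x$total, source = j,
               partial_psd = x$partials[j, ], stringsAsFactors = FALSE)
  }))
}
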