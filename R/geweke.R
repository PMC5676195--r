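# Shared core of every conditional spectral Granger-Geweke measure.
#
# Geweke's construction: filter the kept channels (target + conditioning
# set) of the full model's spectral factor through the inverse transfer of
# the reduced model fitted without the source. The filtered target then has
# (nominal) flat spectrum equal to the reduced innovation variance; the part
# of it attributable to the source's (partialized) innovations is the causal
# contribution. Innovations are orthogonalized by the lower Cholesky factor
# of the full innovation covariance with the channels ordered
# (target, conditioning, other, source), so the source columns are
# partialized against everything else.
#
# Hfull     M x M x nf full-model transfer, original channel order
# Sigma     full-model innovation covariance
# Binv_red  nk x nk x nf inverse transfer of the reduced model over
#           kept = c(target, cond), in that order
# V_red     reduced-model innovation covariance (kept order)
cond_gc_core <- function(Hfull, Sigma, Binv_red, V_red,
                         source, target, cond, grid,
                         provenance, labels = NULL) {
  M <- dim(Hfull)[1]
  nf <- dim(Hfull)[3]
  kept <- c(target, cond)
  nk <- length(kept)
  others <- setdiff(seq_len(M), c(kept, source))
  perm <- c(kept, others, source)
  ndc <- M - length(source) # denominator columns: all but the source's
  VL <- t(chol(symmetrize(Sigma[perm, perm, drop = FALSE])))
  log_num <- log(V_red[1, 1])

  values <- numeric(nf)
  for (j in seq_len(nf)) {
    Hk <- matrix(Hfull[kept, perm, j], nk, M)
    row1 <- (matrix(Binv_red[, , j], nk, nk) %*% (Hk %*% VL))[1, ]
    values[j] <- log_num - log(sum(Mod(row1[seq_len(ndc)])^2))
  }
  cl <- clamp_nonnegative(values)
  causality_spectrum("ggc", source, target, cond, grid, cl$values,
                     provenance, cl$n_clamped, labels)
}

# Inverse transfer of a VAR model is its coefficient transform A(f).
var_inverse_transfer <- function(model, freqs) {
  var_coefficient_transform(model, freqs)
}

#' Bivariate spectral Granger-Geweke causality
#'
#' For a 2-channel VAR model, Geweke's frequency-domain measure from
#' `source` to `target`:
#' \deqn{f_{s \to t}(f) = \ln\frac{S_{tt}(f)}
#'   {S_{tt}(f) - \tilde\sigma^2_{ss} |\tilde H_{ts}(f)|^2},}
#' where \eqn{\tilde\sigma^2_{ss} = \Sigma_{ss} - \Sigma_{ts}^2/\Sigma_{tt}}
#' is the source innovation variance partialized on the target's, and
#' \eqn{\tilde H} is the transfer function after the normalization that
#' decorrelates the innovations (identity when `Sigma` is diagonal).
#' Log-ratio arguments below 1 are clamped to 1 (value 0) and counted.
#'
#' @param model A 2-channel `var_model`.
#' @param grid A `frequency_grid` (default: 513 points up to Nyquist).
#' @param source,target Channel indices or labels (defaults 1 and 2).
#' @return A `causality_spectrum` (measure `"ggc"`).
#' @export
bivariate_spectral_gc <- function(model, grid = frequency_grid(model$fs),
                                  source = 1, target = 2) {
  stopifnot(inherits(model, "var_model"))
  if (model$n_channels != 2L) {
    stop("bivariate_spectral_gc needs a 2-channel model; see ",
         "theoretical_conditional_gc / ss_conditional_spectral_gc for M > 2")
  }
  grid <- as_frequency_grid(grid, model$fs)
  s <- resolve_channels(source, model$labels)
  t_ <- resolve_channels(target, model$labels)
  stopifnot(s != t_)
  sm <- var_spectral_matrices(model, grid)
  Sig <- model$noise_cov
  sig2_part <- Sig[s, s] - Sig[t_, s]^2 / Sig[t_, t_]
  # remove the source-on-target innovation correlation: e_s|t = e_s - b e_t
  Tm <- diag(2)
  Tm[s, t_] <- -Sig[s, t_] / Sig[t_, t_]
  Stt <- Re(sm$S[t_, t_, ])
  nf <- length(grid$freqs)
  Hts <- vapply(seq_len(nf), function(j) {
    (sm$H[, , j] %*% solve(Tm))[t_, s]
  }, complex(1))
  values <- log(Stt) - log(Stt - sig2_part * Mod(Hts)^2)
  cl <- clamp_nonnegative(values)
  causality_spectrum("ggc", s, t_, integer(0), grid, cl$values,
                     list(estimator = "theoretical-bivariate",
                          order_full = model$order),
                     cl$n_clamped, model$labels)
}

#' Conditional spectral Granger-Geweke causality from data (VAR route)
#'
#' The classical "full and reduced model" estimator: fits a full VAR on all
#' channels and a reduced VAR on the target plus conditioning channels
#' (source excluded), then forms Geweke's conditional spectral measure by
#' filtering the full spectral factor through the reduced model's inverse
#' transfer. Both models use the same order by default, matching common
#' practice; an independent reduced order can be given.
#'
#' @param series A `multichannel_series` (or matrix with `fs`).
#' @param source,target Channel index or label; must differ.
#' @param cond Conditioning channels (default: all remaining channels).
#' @param order_full Order of the full model.
#' @param order_reduced Order of the reduced model (default `order_full`).
#' @param grid A `frequency_grid` (default up to Nyquist, 513 points).
#' @param fs Sampling rate when `series` is a bare matrix.
#' @return A `causality_spectrum` with provenance `"var"`.
#' @export
conditional_spectral_gc_var <- function(series, source, target,
                                        cond = NULL,
                                        order_full,
                                        order_reduced = order_full,
                                        grid = NULL, fs = NULL) {
  x <- as_series_matrix(series)
  fs <- if (inherits(series, "multichannel_series")) series$fs else fs
  labels <- colnames(x) %||% paste0("ch", seq_len(ncol(x)))
  s <- resolve_channels(source, labels)
  t_ <- resolve_channels(target, labels)
  cond <- if (is.null(cond)) setdiff(seq_len(ncol(x)), c(s, t_))
          else resolve_channels(cond, labels)
  stopifnot(s != t_, !(s %in% cond), !(t_ %in% cond))
  grid <- if (is.null(grid)) frequency_grid(fs) else as_frequency_grid(grid, fs)

  full <- fit_var_ols(x, order_full, fs = fs)
  red <- fit_var_ols(x[, c(t_, cond), drop = FALSE], order_reduced, fs = fs)
  Hfull <- var_transfer(full, grid$freqs)
  Binv <- var_inverse_transfer(red, grid$freqs)
  cond_gc_core(Hfull, full$noise_cov, Binv, red$noise_cov,
               s, t_, cond, grid,
               list(estimator = "var", order_full = order_full,
                    order_reduced = order_reduced),
               labels)
}

#' Theoretical conditional spectral GC from true model parameters
#'
#' The reference ("true") conditional Granger-Geweke spectrum computed from
#' exact VAR parameters, with the reduced model obtained either in closed
#' form through the state-space representation (default; see
#' [ss_conditional_spectral_gc()]) or by projecting the exact subprocess
#' autocovariances onto a high-order VAR (Yule-Walker, default order 128).
#' The two routes agree to high accuracy and cross-validate each other.
#'
#' @param model A stable `var_model` (ground truth).
#' @param source,target Channel index or label.
#' @param cond Conditioning channels (default: all remaining).
#' @param grid A `frequency_grid`.
#' @param route `"ss"` (closed form, default) or `"projection"`.
#' @param reduced_order Order of the projected reduced model
#'   (`route = "projection"` only).
#' @return A `causality_spectrum`.
#' @export
theoretical_conditional_gc <- function(model, source, target, cond = NULL,
                                       grid = frequency_grid(model$fs),
                                       route = c("ss", "projection"),
                                       reduced_order = 128L) {
  stopifnot(inherits(model, "var_model"))
  route <- match.arg(route)
  grid <- as_frequency_grid(grid, model$fs)
  s <- resolve_channels(source, model$labels)
  t_ <- resolve_channels(target, model$labels)
  cond <- if (is.null(cond)) setdiff(seq_len(model$n_channels), c(s, t_))
          else resolve_channels(cond, model$labels)
  stopifnot(s != t_, !(s %in% cond), !(t_ %in% cond))

  if (route == "ss") {
    cs <- ss_conditional_spectral_gc(var_to_ss(model), s, t_, cond, grid)
    cs$provenance$estimator <- "theoretical-ss"
    return(cs)
  }
  kept <- c(t_, cond)
  G <- var_autocov(model, reduced_order)
  red <- yw_var_from_autocov(G[kept, kept, , drop = FALSE], reduced_order)
  red_model <- make_var(red$coeffs, red$sigma, model$fs,
                        model$labels[kept], warn_unstable = FALSE)
  Hfull <- var_transfer(model, grid$freqs)
  Binv <- var_inverse_transfer(red_model, grid$freqs)
  cond_gc_core(Hfull, model$noise_cov, Binv, red$sigma,
               s, t_, cond, grid,
               list(estimator = "theoretical-projection",
                    order_full = model$order,
                    order_reduced = reduced_order),
               model$labels)
}

#' Time-domain Granger-Geweke causality
#'
#' Geweke's time-domain measure
#' `F = ln(det Sigma_reduced[target] / det Sigma_full[target])`, from
#' residual covariances of the reduced (source excluded) and full models.
#' Given a `var_model`, the exact reduced innovation variance comes from the
#' state-space subprocess solution; given a series, both models are fitted
#' by OLS at the supplied order(s).
#'
#' @param x A `var_model` (theoretical route) or `multichannel_series` /
#'   matrix (estimated route).
#' @param source,target Channel index or label.
#' @param cond Conditioning channels (default: all remaining).
#' @param order_full,order_reduced Fit orders (estimated route only).
#' @param fs Sampling rate for bare matrices.
#' @return A nonnegative scalar (negative estimates are clamped at 0).
#' @export
time_domain_gc <- function(x, source, target, cond = NULL,
                           order_full = NULL, order_reduced = order_full,
                           fs = NULL) {
  if (inherits(x, "var_model")) {
    s <- resolve_channels(source, x$labels)
    t_ <- resolve_channels(target, x$labels)
    cond <- if (is.null(cond)) setdiff(seq_len(x$n_channels), c(s, t_))
            else resolve_channels(cond, x$labels)
    kept <- c(t_, cond)
    sub <- subprocess_innovations(var_to_ss(x), kept)
    val <- log(sub$cov[1, 1] / x$noise_cov[t_, t_])
  } else {
    xm <- as_series_matrix(x)
    fs <- if (inherits(x, "multichannel_series")) x$fs else fs
    if (is.null(order_full)) stop("order_full is required for fitted GC")
    labels <- colnames(xm) %||% paste0("ch", seq_len(ncol(xm)))
    s <- resolve_channels(source, labels)
    t_ <- resolve_channels(target, labels)
    cond <- if (is.null(cond)) setdiff(seq_len(ncol(xm)), c(s, t_))
            else resolve_channels(cond, labels)
    full <- fit_var_ols(xm, order_full, fs = fs)
    red <- fit_var_ols(xm[, c(t_, cond), drop = FALSE], order_reduced, fs = fs)
    if (!is_positive_definite(full$noise_cov) ||
        !is_positive_definite(red$noise_cov)) {
      stop("residual covariance not positive definite")
    }
    val <- log(red$noise_cov[1, 1] / full$noise_cov[t_, t_])
  }
  max(val, 0)
}
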