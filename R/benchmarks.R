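#' AR(2) oscillator coefficients by pole placement
#'
#' Places a complex-conjugate pole pair at radius `radius` and angle
#' `2 pi freq_hz / fs`, giving the scalar AR(2)
#' `a1 = 2 rho cos(2 pi f / fs)`, `a2 = -rho^2` whose spectrum peaks near
#' `freq_hz`.
#'
#' @param freq_hz Resonance frequency in Hz, strictly inside `(0, fs/2)`.
#' @param radius Pole radius in `(0, 1)`.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector `c(a1, a2)`.
#' @export
build_oscillator_var <- function(freq_hz, radius, fs) {
  stopifnot(freq_hz > 0, freq_hz < fs / 2, radius > 0, radius < 1)
  c(2 * radius * cos(2 * pi * freq_hz / fs), -radius^2)
}

#' Benchmark configuration
#'
#' Loads the version-pinned defaults shipped with the package
#' (`extdata/benchmark_defaults.yaml`) for one of the two simulated
#' systems and applies any overrides.
#'
#' @param example `"three_node"` or `"two_node"`.
#' @param ... Named overrides of the default fields (`fs`, `resonance_hz` /
#'   `transmitter_hz` + `receiver_hz`, `pole_radius`, `order`, `couplings`,
#'   `innovation_var`, `n_samples`, `n_realizations`).
#' @param file Optional alternative YAML file with the same structure.
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(example = c("three_node", "two_node"), ...,
                             file = NULL) {
  example <- match.arg(example)
  path <- file %||% system.file("extdata", "benchmark_defaults.yaml",
                                package = "specgc", mustWork = TRUE)
  defaults <- yaml::read_yaml(path)[[example]]
  if (is.null(defaults)) stop("no '", example, "' section in ", path)
  cfg <- defaults
  overrides <- list(...)
  # plain replacement, not a recursive merge: an override like
  # couplings = list() must win wholesale
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg$example <- example
  fs <- cfg$fs
  res <- if (example == "three_node") cfg$resonance_hz
         else c(cfg$transmitter_hz, cfg$receiver_hz)
  if (any(res >= fs / 2)) stop("resonance frequencies must be below fs/2")
  if (any(cfg$pole_radius <= 0 | cfg$pole_radius >= 1)) {
    stop("pole radii must lie in (0, 1)")
  }
  structure(cfg, class = "benchmark_config")
}

# assemble a VAR benchmark: AR(2) oscillator on each diagonal, listed
# cross couplings, diagonal innovation covariance
assemble_benchmark_var <- function(res_hz, cfg) {
  M <- length(res_hz)
  radius <- rep(cfg$pole_radius, length.out = M)
  order <- max(cfg$order, 2L, vapply(cfg$couplings, function(cc) cc$lag,
                                     numeric(1)))
  co <- array(0, c(M, M, order))
  for (i in seq_len(M)) {
    a <- build_oscillator_var(res_hz[i], radius[i], cfg$fs)
    co[i, i, 1] <- a[1]
    co[i, i, 2] <- a[2]
  }
  for (cc in cfg$couplings) {
    co[cc$to, cc$from, cc$lag] <- cc$value
  }
  model <- make_var(co, diag(as.numeric(cfg$innovation_var), M), cfg$fs,
                    warn_unstable = FALSE)
  if (!model$stable) {
    stop("benchmark model unstable (spectral radius ",
         sprintf("%.4f", model$spectral_radius),
         "); reduce pole radii or coupling values")
  }
  model
}

#' Three-node oscillator chain benchmark
#'
#' A stable 3-channel VAR(3): each channel is an AR(2) oscillator (defaults:
#' resonances 40, 10 and 50 Hz, pole radius 0.9, fs = 120 Hz) and
#' unidirectional couplings are imposed along the chain 1 -> 2 -> 3 only;
#' every other cross-coefficient is exactly zero and the innovation
#' covariance is diagonal. The direction 3 -> 1 therefore carries no
#' coupling, and its true conditional GC spectrum is identically zero.
#'
#' @param config A `benchmark_config` (defaults to the shipped
#'   `three_node` section).
#' @return A stable `var_model`.
#' @export
make_three_node_benchmark <- function(config = benchmark_config("three_node")) {
  assemble_benchmark_var(config$resonance_hz, config)
}

#' Two-node transmitter/receiver benchmark
#'
#' A stable 2-channel VAR with unidirectional coupling 1 -> 2: channel 1
#' (the transmitter) is an AR(2) oscillator at 50 Hz by default, channel 2
#' (the receiver) resonates at `receiver_hz`. The coupling coefficients are
#' identical across receiver configurations, which is what makes the
#' directed coherence and Granger-Geweke profiles 1 -> 2 invariant to the
#' receiver's own resonance.
#'
#' @param receiver_hz Receiver resonance frequency in Hz (default 10).
#' @param config A `benchmark_config` (defaults to the shipped `two_node`
#'   section).
#' @return A stable `var_model`.
#' @export
make_two_node_benchmark <- function(receiver_hz = 10,
                                    config = benchmark_config("two_node")) {
  stopifnot(receiver_hz > 0, receiver_hz < config$fs / 2)
  assemble_benchmark_var(c(config$transmitter_hz, receiver_hz), config)
}
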