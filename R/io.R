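#' Write a multichannel series to CSV
#'
#' One row per sample, header row of channel labels. The sampling rate is
#' written to a JSON sidecar `<path>.meta.json` so the file pair is
#' self-describing; readers may also supply `fs` explicitly.
#'
#' @param series A `multichannel_series`.
#' @param path Output CSV path.
#' @param sidecar Write the sampling-rate sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path, sidecar = TRUE) {
  stopifnot(inherits(series, "multichannel_series"))
  df <- as.data.frame(apply(series$data, 2, fmt_num))
  colnames(df) <- series$labels
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    jsonlite::write_json(list(fs = series$fs, labels = series$labels),
                         paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a multichannel series from CSV
#'
#' @param path CSV path (header row of channel labels, one row per sample).
#' @param fs Sampling rate in Hz; if `NULL`, read from the
#'   `<path>.meta.json` sidecar.
#' @return A `multichannel_series`.
#' @export
read_series_csv <- function(path, fs = NULL) {
  if (is.null(fs)) {
    meta_path <- paste0(path, ".meta.json")
    if (!file.exists(meta_path)) {
      stop("no sampling rate: supply fs or provide ", meta_path)
    }
    fs <- jsonlite::read_json(meta_path)$fs
  }
  df <- read.csv(path, check.names = FALSE)
  multichannel_series(as.matrix(df), fs, colnames(df))
}

#' Write a VAR model to JSON
#'
#' Fields: `order`, `coeffs` (nested arrays, lag-major: `coeffs[[k]]` is
#' `A_k` row-major by row lists), `noise_cov`, `fs`, `labels`.
#'
#' @param model A `var_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "var_model"))
  M <- model$n_channels
  mat_rows <- function(m) lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
  coeffs <- lapply(seq_len(model$order), function(k) {
    mat_rows(matrix(model$coeffs[, , k], M, M))
  })
  obj <- list(order = model$order,
              coeffs = coeffs,
              noise_cov = mat_rows(model$noise_cov),
              fs = model$fs,
              labels = model$labels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a VAR model from JSON
#'
#' @param path Path to a model JSON written by [write_model_json()] (or the
#'   same schema produced elsewhere).
#' @return A `var_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- obj$order
  coeffs <- if (is.list(obj$coeffs)) {
    arr <- array(0, c(dim(obj$coeffs[[1]]), p))
    for (k in seq_len(p)) arr[, , k] <- obj$coeffs[[k]]
    arr
  } else {
    # simplified to a p x M x M array (lag-major)
    aperm(obj$coeffs, c(2, 3, 1))
  }
  make_var(coeffs, as.matrix(obj$noise_cov), obj$fs, obj$labels,
           warn_unstable = FALSE)
}

#' Write causality spectra to long-format CSV
#'
#' Columns: measure, source, target, cond_set, frequency_hz, value,
#' provenance, order_full, order_reduced, realization_id. Numeric values
#' are serialized with 12 significant digits so repeated runs are
#' byte-identical.
#'
#' @param spectra A `causality_spectrum`, a list of them, or a data frame
#'   already in the long schema.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  df <- if (is.data.frame(spectra)) {
    spectra
  } else if (inherits(spectra, "causality_spectrum")) {
    as.data.frame(spectra)
  } else {
    do.call(rbind, lapply(spectra, as.data.frame))
  }
  for (col in c("frequency_hz", "value", "total_psd", "partial_psd",
                "p05", "median", "p95", "reference")) {
    if (col %in% names(df)) df[[col]] <- fmt_num(df[[col]])
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Every command-line run writes exactly one `manifest.json` into its
#' output directory: the command, a hash of the serialized configuration,
#' the master seed, package version, timestamp, and warning/clamp counters.
#' A seeded run is reproducible from its manifest alone.
#'
#' @param dir Output directory.
#' @param command Command name.
#' @param config List of configuration values (hashed into `config_hash`).
#' @param seed Master seed (may be `NULL`).
#' @param counters Named list of warning/clamp counters.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, command, config, seed = NULL,
                           counters = list()) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  manifest <- list(command = command,
                   config = config,
                   config_hash = unname(tools::md5sum(tmp)),
                   master_seed = seed,
                   package_version = as.character(packageVersion("specgc")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   counters = counters)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
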