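`%||%` <- function(a, b) if (is.null(a)) b else a

ctranspose <- function(x) Conj(t(x))

spectral_radius <- function(x) {
  if (length(x) == 0L) return(0)
  max(Mod(eigen(x, only.values = TRUE)$values))
}

is_symmetric_tol <- function(x, tol = 1e-12) {
  is.matrix(x) && nrow(x) == ncol(x) &&
    max(abs(x - t(x))) <= tol * max(1, max(abs(x)))
}

symmetrize <- function(x) (x + t(x)) / 2

# min eigenvalue check; input assumed (numerically) symmetric
is_positive_definite <- function(x) {
  ev <- eigen(symmetrize(x), symmetric = TRUE, only.values = TRUE)$values
  all(ev > 0)
}

# trapezoidal average of y over x (equals the integral divided by the span)
trapezoid_average <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 2L, length(y) == n)
  sum(diff(x) * (y[-1] + y[-n]) / 2) / (x[n] - x[1])
}

# 12-significant-digit formatting used for all CSV output so repeated runs
# are byte-identical
fmt_num <- function(x) {
  out <- sprintf("%.12g", x)
  out[is.na(x)] <- "NA"
  out
}

resolve_channels <- function(idx, labels) {
  if (is.null(idx)) return(integer(0))
  M <- length(labels)
  if (is.character(idx)) {
    pos <- match(idx, labels)
    if (anyNA(pos)) {
      stop("unknown channel(s) ", paste(idx[is.na(pos)], collapse = ", "),
           "; available: ", paste(labels, collapse = ", "), call. = FALSE)
    }
    return(pos)
  }
  idx <- as.integer(idx)
  if (any(idx < 1L | idx > M)) {
    stop("channel index out of range 1..", M, call. = FALSE)
  }
  idx
}

cond_label <- function(cond) {
  if (length(cond) == 0L) "" else paste(cond, collapse = ";")
}
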