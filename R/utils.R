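# internal numeric helpers

# Moore-Penrose pseudoinverse via SVD. Tolerance follows the usual
# max(dim) * eps * max(singular value) convention.
pinv <- function(A, tol = NULL) {
  A <- as.matrix(A)
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(s$d, 0)
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# clamp with an optional warning naming the offending quantity
clamp <- function(x, lo, hi, what = NULL, warn = FALSE) {
  out <- pmin(pmax(x, lo), hi)
  if (warn && !is.null(what)) {
    n_low <- sum(x < lo, na.rm = TRUE)
    n_high <- sum(x > hi, na.rm = TRUE)
    if (n_low + n_high > 0L) {
      warning(sprintf("%s: clamped %d value(s) to [%g, %g]",
                      what, n_low + n_high, lo, hi), call. = FALSE)
    }
  }
  out
}

stop_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# coerce a colour argument to an n x 3 numeric matrix
as_matrix3 <- function(x, what = "colour") {
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop_input("%s must have 3 components", what)
    x <- matrix(as.numeric(x), 1L, 3L)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != 3L) stop_input("%s must have 3 columns, got %d", what, ncol(x))
    storage.mode(x) <- "double"
  }
  x
}

# coerce spectra input (vector, matrix, or list of vectors) to n x 401
as_spectra_matrix <- function(x, what = "spectra") {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, lapply(x, as.numeric))
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != N_BANDS) {
    stop_input("%s must be on the %d-point 380-780 nm grid, got %d columns",
               what, N_BANDS, ncol(x))
  }
  x
}

# round half-up to `digits` decimals (printed-table comparison convention;
# base round() uses banker's rounding)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# force doubles through 32-bit float representation (cube storage dtype)
as_float32 <- function(x) {
  d <- dim(x)
  out <- readBin(writeBin(as.numeric(x), raw(), size = 4L),
                 "double", n = length(x), size = 4L)
  dim(out) <- d
  out
}
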