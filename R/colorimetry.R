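# Colorimetric front end: sRGB decoding, XYZ conversion, CIELAB, CIEDE2000.

#' Standard sRGB (D65) linear-RGB to XYZ matrix
#'
#' The IEC 61966-2-1 primaries. Multiplying a linear-light RGB column vector
#' by this matrix gives CIE 1931 XYZ on a 0-1 scale (the package works on a
#' scale where the reference white has Y = 100, i.e. 100 * M * rgb).
#'
#' @return A 3x3 numeric matrix.
#' @export
srgb_xyz_matrix <- function() {
  matrix(c(0.4124564, 0.3575761, 0.1804375,
           0.2126729, 0.7151522, 0.0721750,
           0.0193339, 0.1191920, 0.9503041),
         3, 3, byrow = TRUE,
         dimnames = list(c("X", "Y", "Z"), c("R", "G", "B")))
}

#' Decode 8-bit sRGB code values to linear light
#'
#' Applies the standard sRGB electro-optical transfer function: code values
#' are scaled to \eqn{[0,1]} and decoded with the piecewise IEC 61966-2-1
#' curve (linear segment below 0.04045, else \eqn{((v+0.055)/1.055)^{2.4}}).
#'
#' @param rgb Integer code values in 0-255: a length-3 vector or an n x 3
#'   matrix (columns R, G, B).
#' @return Linear-light fractions in \eqn{[0,1]}, same shape as the input.
#' @export
#' @examples
#' srgb_to_linear(c(0, 128, 255))
srgb_to_linear <- function(rgb) {
  vec <- is.null(dim(rgb))
  m <- as_matrix3(rgb, "sRGB input")
  if (any(m < 0 | m > 255)) {
    stop_input("sRGB code values must lie in [0, 255] (got range [%g, %g])",
               min(m), max(m))
  }
  u <- m / 255
  out <- ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
  if (vec) as.numeric(out) else out
}

# sRGB opto-electronic transfer function (encode); simulator-side inverse
linear_to_srgb_encode <- function(v) {
  v <- clamp(v, 0, 1)
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}

#' Convert linear RGB to CIE XYZ (white Y = 100 scale)
#'
#' Computes \eqn{XYZ = 100 \, M \, rgb}. The default matrix assumes sRGB/D65
#' primaries; supply `m` for other camera models.
#'
#' @param rgb Linear-light RGB, length-3 vector or n x 3 matrix.
#' @param m 3x3 conversion matrix (rows X, Y, Z).
#' @return XYZ values, same shape convention as the input.
#' @export
#' @examples
#' linear_to_xyz(c(1, 1, 1))  # the D65 white point, Y = 100
linear_to_xyz <- function(rgb, m = srgb_xyz_matrix()) {
  vec <- is.null(dim(rgb))
  rgbm <- as_matrix3(rgb, "linear RGB")
  m <- as.matrix(m)
  if (!all(dim(m) == c(3L, 3L)) || !all(is.finite(m))) {
    stop_input("conversion matrix must be a finite 3x3 matrix")
  }
  if (abs(det(m)) < 1e-12) stop_input("conversion matrix is singular")
  out <- 100 * rgbm %*% t(m)
  colnames(out) <- c("X", "Y", "Z")
  if (vec) {
    out <- as.numeric(out); names(out) <- c("X", "Y", "Z")
  }
  out
}

#' Convert XYZ to CIELAB
#'
#' Uses the classic piecewise companding function with cube-root branch for
#' \eqn{n > 0.008856} and linear branch \eqn{7.787 n + 0.137931} otherwise
#' (the 16/116 intercept written to six decimals, as commonly printed).
#'
#' @param xyz XYZ values (white Y = 100 scale), length-3 vector or n x 3 matrix.
#' @param white Reference white XYZ (strictly positive), default D65 at Y = 100.
#' @return Lab values (`L`, `a`, `b`), same shape convention as the input.
#' @export
#' @examples
#' xyz_to_lab(c(95.047, 100, 108.883))  # the white point: L* = 100, neutral
xyz_to_lab <- function(xyz, white = d65_white()) {
  vec <- is.null(dim(xyz))
  m <- as_matrix3(xyz, "XYZ")
  white <- as.numeric(white)
  if (length(white) != 3L || any(!is.finite(white)) || any(white <= 0)) {
    stop_input("white point must have 3 strictly positive components")
  }
  f <- function(n) ifelse(n > 0.008856, n^(1 / 3), 7.787 * n + 0.137931)
  fx <- f(m[, 1] / white[1])
  fy <- f(m[, 2] / white[2])
  fz <- f(m[, 3] / white[3])
  out <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  if (vec) {
    out <- as.numeric(out); names(out) <- c("L", "a", "b")
  }
  out
}

#' D65 white point at Y = 100
#' @return Length-3 numeric vector (X, Y, Z).
#' @export
d65_white <- function() c(X = 95.047, Y = 100, Z = 108.883)

#' CIEDE2000 colour difference
#'
#' The CIE DE2000 formula with parametric factors kL = kC = kH = 1.
#' Symmetric in its arguments and zero iff the two colours are identical.
#'
#' @param lab1,lab2 Lab colours: length-3 vectors or aligned n x 3 matrices.
#' @return Numeric vector of colour differences.
#' @export
#' @examples
#' ciede2000(c(50, 2.6772, -79.7751), c(50, 0, -82.7485))  # approx. 2.0425
ciede2000 <- function(lab1, lab2) {
  a1m <- as_matrix3(lab1, "lab1"); a2m <- as_matrix3(lab2, "lab2")
  if (nrow(a1m) != nrow(a2m)) stop_input("lab1 and lab2 must be aligned")
  L1 <- a1m[, 1]; a1 <- a1m[, 2]; b1 <- a1m[, 3]
  L2 <- a2m[, 1]; a2 <- a2m[, 2]; b2 <- a2m[, 3]

  C1 <- sqrt(a1^2 + b1^2); C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1; a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2); C2p <- sqrt(a2p^2 + b2^2)
  h1p <- ifelse(C1p == 0, 0, (atan2(b1, a1p) * 180 / pi) %% 360)
  h2p <- ifelse(C2p == 0, 0, (atan2(b2, a2p) * 180 / pi) %% 360)

  dLp <- L2 - L1
  dCp <- C2p - C1p
  dhp <- ifelse(C1p * C2p == 0, 0,
         ifelse(abs(h2p - h1p) <= 180, h2p - h1p,
         ifelse(h2p - h1p > 180, h2p - h1p - 360, h2p - h1p + 360)))
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp / 2 * pi / 180)

  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hsum <- h1p + h2p
  hbp <- ifelse(C1p * C2p == 0, hsum,
         ifelse(abs(h1p - h2p) <= 180, hsum / 2,
         ifelse(hsum < 360, (hsum + 360) / 2, (hsum - 360) / 2)))

  T <- 1 - 0.17 * cos((hbp - 30) * pi / 180) +
           0.24 * cos(2 * hbp * pi / 180) +
           0.32 * cos((3 * hbp + 6) * pi / 180) -
           0.20 * cos((4 * hbp - 63) * pi / 180)
  dTheta <- 30 * exp(-((hbp - 275) / 25)^2)
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * T
  RT <- -sin(2 * dTheta * pi / 180) * RC

  sqrt((dLp / SL)^2 + (dCp / SC)^2 + (dHp / SH)^2 +
       RT * (dCp / SC) * (dHp / SH))
}

#' Per-patch XYZ root-mean-square error
#'
#' For each aligned pair of XYZ triplets, the RMSE over the three components;
#' plus the mean over patches.
#'
#' @param set_a,set_b Aligned n x 3 XYZ matrices (or length-3 vectors).
#' @return A list with `per_patch` (numeric vector) and `mean`.
#' @export
xyz_rmse <- function(set_a, set_b) {
  a <- as_matrix3(set_a, "set_a"); b <- as_matrix3(set_b, "set_b")
  if (nrow(a) != nrow(b)) {
    stop_input("XYZ sets must be aligned (%d vs %d rows)", nrow(a), nrow(b))
  }
  per <- sqrt(rowMeans((a - b)^2))
  list(per_patch = per, mean = mean(per))
}
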