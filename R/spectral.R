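# Spectral reconstruction: PCA basis over calibration reflectances plus a
# polynomial regression from corrected XYZ to principal-component scores.
# The combined transform S = mean + EV (M_reg V) is the "basis x regression"
# product applied to the expanded colour features.

#' Fit a PCA basis to reflectance spectra
#'
#' Mean-centred principal component analysis of the calibration reflectance
#' set (percent units, 401-band grid). Loadings are sign-fixed so the
#' largest-magnitude element of each component is positive, which makes
#' serialized models reproducible.
#'
#' @param spectra n x 401 matrix (or list of vectors) of reflectance spectra
#'   in percent (0-100).
#' @param n_pc Number of components to retain (default 6).
#' @return A `spectral_basis` object: `mean_spectrum` (length 401),
#'   `loadings` (401 x n_pc, orthonormal columns), `explained_variance_ratio`
#'   (all sample components), `cumulative_explained` (percent, first n_pc),
#'   `n_pc`, `wavelengths`.
#' @export
fit_pca <- function(spectra, n_pc = 6) {
  R <- as_spectra_matrix(spectra)
  n <- nrow(R)
  if (n_pc > n - 1L) {
    stop_input("n_pc = %d exceeds the sample limit (%d spectra allow at most %d)",
               n_pc, n, n - 1L)
  }
  pc <- stats::prcomp(R, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  load <- pc$rotation[, seq_len(n_pc), drop = FALSE]
  # sign convention: largest-magnitude loading element positive
  for (j in seq_len(n_pc)) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) load[, j] <- -load[, j]
  }
  structure(
    list(mean_spectrum = as.numeric(pc$center),
         loadings = unname(load),
         explained_variance_ratio = as.numeric(evr),
         cumulative_explained = 100 * sum(evr[seq_len(n_pc)]),
         n_pc = as.integer(n_pc),
         wavelengths = hsi_wavelengths()),
    class = "spectral_basis")
}

# scores of spectra in a fitted basis (n x n_pc)
project_spectra <- function(basis, spectra) {
  R <- as_spectra_matrix(spectra)
  sweep(R, 2, basis$mean_spectrum) %*% basis$loadings
}

#' Fit the regression from corrected XYZ to PCA scores
#'
#' Least-squares fit (via pseudoinverse) of the principal-component scores of
#' the calibration spectra on the polynomial expansion of the corrected XYZ
#' values, producing the matrix `M_reg` whose product with the basis loadings
#' is the combined colour-to-spectrum transform.
#'
#' @param xyz_correct n x 3 matrix of corrected XYZ values, aligned with
#'   `spectra`.
#' @param basis A [fit_pca()] basis.
#' @param spectra The same calibration reflectance spectra the basis was
#'   fitted to (n x 401, percent units).
#' @param term_spec [term_preset()] name or object; by convention the same
#'   set used for the camera correction.
#' @param feature_scale Divisor applied to XYZ before expansion (keep equal
#'   to the camera-correction model's value; default 100).
#' @return A `spectral_regression` object with `M_reg` (n_pc x n_terms),
#'   `term_spec` and `feature_scale`.
#' @export
fit_spectral_regression <- function(xyz_correct, basis, spectra,
                                    term_spec = "poly3", feature_scale = 100) {
  xyz <- as_matrix3(xyz_correct, "xyz_correct")
  R <- as_spectra_matrix(spectra)
  if (nrow(xyz) != nrow(R)) {
    stop_input("xyz_correct and spectra must be aligned (%d vs %d rows)",
               nrow(xyz), nrow(R))
  }
  ts <- as_term_spec(term_spec)
  n_terms <- nrow(ts$exponents)
  if (nrow(xyz) < n_terms) {
    stop_input("rank deficiency: %d samples cannot determine %d terms",
               nrow(xyz), n_terms)
  }
  scores <- project_spectra(basis, R)                    # n x n_pc
  V <- t(expand_features(xyz / feature_scale, ts))       # n_terms x n
  M_reg <- t(scores) %*% pinv(V)                         # n_pc x n_terms
  structure(list(M_reg = M_reg, term_spec = ts,
                 feature_scale = as.numeric(feature_scale)),
            class = "spectral_regression")
}

#' Reconstruct an analog spectrum from corrected XYZ
#'
#' Evaluates `S = mean + EV (M_reg V(xyz))` on the 401-band grid and clamps
#' the result to the physical 0-100 percent range (with a warning when
#' clamping occurs).
#'
#' @param xyz_correct Length-3 vector or n x 3 matrix of corrected XYZ.
#' @param basis A [fit_pca()] basis.
#' @param reg A [fit_spectral_regression()] model with matching `n_pc`.
#' @param clamp Clamp output to \eqn{[0, 100]} (default TRUE).
#' @return Reflectance spectrum: length-401 vector, or n x 401 matrix for
#'   matrix input.
#' @export
reconstruct_spectrum <- function(xyz_correct, basis, reg, clamp = TRUE) {
  if (!inherits(basis, "spectral_basis")) stop_input("basis must come from fit_pca()")
  if (!inherits(reg, "spectral_regression")) {
    stop_input("reg must come from fit_spectral_regression()")
  }
  if (ncol(basis$loadings) != nrow(reg$M_reg)) {
    stop_input("basis (%d components) and regression (%d) do not match",
               ncol(basis$loadings), nrow(reg$M_reg))
  }
  vec <- is.null(dim(xyz_correct))
  xyz <- as_matrix3(xyz_correct, "xyz_correct")
  V <- t(expand_features(xyz / reg$feature_scale, reg$term_spec))
  S <- t(basis$loadings %*% (reg$M_reg %*% V)) +
       matrix(basis$mean_spectrum, nrow(xyz), N_BANDS, byrow = TRUE)
  if (clamp) S <- clamp(S, 0, 100, what = "reconstructed reflectance", warn = TRUE)
  if (vec) as.numeric(S) else S
}

#' Per-patch spectral RMSE
#'
#' RMSE over the 401 bands between reconstructed (analog) and measured
#' spectra, in percent-reflectance units, plus the mean over patches.
#'
#' @param analog,measured Aligned n x 401 spectra matrices (percent units).
#' @return List with `per_patch` and `mean`.
#' @export
spectral_rmse <- function(analog, measured) {
  a <- as_spectra_matrix(analog, "analog")
  b <- as_spectra_matrix(measured, "measured")
  if (nrow(a) != nrow(b)) {
    stop_input("spectra sets must be aligned (%d vs %d rows)", nrow(a), nrow(b))
  }
  per <- sqrt(rowMeans((a - b)^2))
  list(per_patch = per, mean = mean(per))
}

#' Colour-fidelity report (CIEDE2000 between analog and measured spectra)
#'
#' Integrates both spectra sets to XYZ under an illuminant, converts to Lab
#' against the given white, and reports the per-patch CIEDE2000 difference.
#'
#' @param analog,measured Aligned n x 401 reflectance matrices (percent).
#' @param white Reference white XYZ; defaults to the illuminant's own white.
#' @param illuminant An [illuminant()] spectrum (default equal-energy).
#' @return List with `per_patch` (delta E00 values) and `mean`.
#' @export
validate_color_fidelity <- function(analog, measured, white = NULL,
                                    illuminant = endohsi::illuminant("E")) {
  a <- as_spectra_matrix(analog, "analog")
  b <- as_spectra_matrix(measured, "measured")
  if (nrow(a) != nrow(b)) stop_input("spectra sets must be aligned")
  if (is.null(white)) white <- spectrum_to_xyz(rep(100, N_BANDS), illuminant)
  lab_a <- xyz_to_lab(spectrum_to_xyz(a, illuminant), white)
  lab_b <- xyz_to_lab(spectrum_to_xyz(b, illuminant), white)
  de <- ciede2000(lab_a, lab_b)
  list(per_patch = de, mean = mean(de))
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat(sprintf("<spectral_basis: %d components, %.2f%% variance explained>\n",
              x$n_pc, x$cumulative_explained))
  invisible(x)
}

#' @export
print.spectral_regression <- function(x, ...) {
  cat(sprintf("<spectral_regression: %d components x %d '%s' terms>\n",
              nrow(x$M_reg), ncol(x$M_reg), x$term_spec$name))
  invisible(x)
}
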