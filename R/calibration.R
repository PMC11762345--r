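# Camera XYZ error correction: C = XYZ_Spectrum x pinv(V), XYZ_Correct = C V.

#' Fit a polynomial camera-correction model
#'
#' Learns the correction matrix C mapping polynomial features of the
#' camera-derived XYZ onto the spectrometer-derived reference XYZ by a
#' Moore-Penrose pseudoinverse least-squares solve:
#' \deqn{C = XYZ_{Spectrum} \, \mathrm{pinv}(V), \qquad
#'       XYZ_{Correct} = C \, V,}
#' where each column of V holds the monomial expansion of one patch. For
#' numerical conditioning the monomials are evaluated on white-normalised
#' XYZ (values divided by `feature_scale`, default 100, so that cubic terms
#' stay O(1)); the scale is stored in the model and reapplied on prediction,
#' leaving the fitted mapping unchanged.
#'
#' @param camera_xyz n x 3 matrix of camera-derived XYZ (white Y = 100 scale).
#' @param reference_xyz n x 3 matrix of spectrometer-derived XYZ, aligned by
#'   patch.
#' @param term_spec A [term_preset()] name or object (default `"poly3"`).
#' @param m The 3x3 linear-RGB to XYZ matrix the camera path used (metadata).
#' @param white_point Reference white XYZ (metadata; used for Lab reports).
#' @param brightness_ratio The scalar k tying the camera and spectrometer
#'   brightness scales (metadata).
#' @param feature_scale Divisor applied to XYZ before monomial expansion.
#' @return A `camera_correction` object with elements `C` (3 x n_terms),
#'   `term_spec`, `m`, `white_point`, `brightness_ratio`, `feature_scale`,
#'   and the training-set `residual_rmse`.
#' @export
fit_correction <- function(camera_xyz, reference_xyz, term_spec = "poly3",
                           m = srgb_xyz_matrix(), white_point = d65_white(),
                           brightness_ratio = 1, feature_scale = 100) {
  cam <- as_matrix3(camera_xyz, "camera_xyz")
  ref <- as_matrix3(reference_xyz, "reference_xyz")
  if (nrow(cam) != nrow(ref)) {
    stop_input("camera and reference lists must be aligned (%d vs %d patches)",
               nrow(cam), nrow(ref))
  }
  ts <- as_term_spec(term_spec)
  n_terms <- nrow(ts$exponents)
  if (nrow(cam) < n_terms) {
    stop_input(paste0("rank deficiency: %d patches cannot determine %d ",
                      "polynomial terms; use more patches or a smaller ",
                      "term set"), nrow(cam), n_terms)
  }
  V <- t(expand_features(cam / feature_scale, ts))       # n_terms x n
  C <- t(ref) %*% pinv(V)                                # 3 x n_terms
  fitted <- t(C %*% V)
  model <- structure(
    list(C = C, term_spec = ts, m = as.matrix(m),
         white_point = as.numeric(white_point),
         brightness_ratio = as.numeric(brightness_ratio),
         feature_scale = as.numeric(feature_scale),
         residual_rmse = xyz_rmse(fitted, ref)$mean),
    class = "camera_correction")
  model
}

#' Apply a fitted camera-correction model
#'
#' Evaluates `XYZ_Correct = C V(xyz)`. Negative corrected components are
#' physically impossible and are clamped to zero with a warning.
#'
#' @param model A fitted [fit_correction()] model.
#' @param xyz Length-3 vector or n x 3 matrix of camera-derived XYZ.
#' @return Corrected XYZ, same shape convention as the input.
#' @export
apply_correction <- function(model, xyz) {
  if (!inherits(model, "camera_correction") || is.null(model$C)) {
    stop_input("apply_correction() requires a fitted camera_correction model")
  }
  vec <- is.null(dim(xyz))
  m <- as_matrix3(xyz, "XYZ")
  V <- t(expand_features(m / model$feature_scale, model$term_spec))
  out <- t(model$C %*% V)
  out <- clamp(out, 0, Inf, what = "corrected XYZ", warn = TRUE)
  colnames(out) <- c("X", "Y", "Z")
  if (vec) {
    out <- as.numeric(out); names(out) <- c("X", "Y", "Z")
  }
  out
}

#' @export
print.camera_correction <- function(x, ...) {
  cat(sprintf(
    "<camera_correction: term set '%s' (%d terms), training XYZ RMSE %.4g>\n",
    x$term_spec$name, nrow(x$term_spec$exponents), x$residual_rmse))
  invisible(x)
}
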