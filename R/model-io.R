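# The conversion-model bundle (camera correction + PCA basis + spectral
# regression) and its JSON serialization.

#' Calibrate a full RGB-to-spectrum conversion model
#'
#' Runs the complete calibration workflow on a colour-target set: decode the
#' camera sRGB values, convert to XYZ, fit the polynomial XYZ correction
#' against the spectrometer reference, fit the PCA basis to the measured
#' reflectances, fit the regression from corrected XYZ to component scores,
#' and assemble the quality report (corrected and uncorrected XYZ RMSE,
#' spectral RMSE, cumulative explained variance, mean CIEDE2000).
#'
#' @param patch_set A `color_patch_set` from [build_calibration_fixture()],
#'   or any list with `rgb` (n x 3, 8-bit), `reflectance` (n x 401, percent)
#'   and optionally `xyz_reference`, `white_point`, `illuminant`, `m`.
#' @param term_spec [term_preset()] name or object (default `"poly3"`).
#' @param n_pc Number of principal components (default 6).
#' @return A `conversion_model`: list with `correction`, `basis`,
#'   `regression`, `white_point`, `m`, `report`.
#' @export
calibrate_patch_set <- function(patch_set, term_spec = "poly3", n_pc = 6) {
  if (is.null(patch_set$rgb) || is.null(patch_set$reflectance)) {
    stop_input("patch_set needs 'rgb' and 'reflectance' entries")
  }
  ill <- if (!is.null(patch_set$illuminant)) as_illuminant(patch_set$illuminant)
         else illuminant("E")
  m <- if (!is.null(patch_set$m)) patch_set$m else srgb_xyz_matrix()
  refl <- as_spectra_matrix(patch_set$reflectance)
  xyz_ref <- if (!is.null(patch_set$xyz_reference)) {
    as_matrix3(patch_set$xyz_reference)
  } else {
    spectrum_to_xyz(refl, ill)
  }
  white <- if (!is.null(patch_set$white_point)) as.numeric(patch_set$white_point)
           else spectrum_to_xyz(rep(100, N_BANDS), ill)

  camera_xyz <- linear_to_xyz(srgb_to_linear(patch_set$rgb), m)
  correction <- fit_correction(camera_xyz, xyz_ref, term_spec = term_spec,
                               m = m, white_point = white,
                               brightness_ratio = brightness_ratio(ill))
  xyz_cor <- apply_correction(correction, camera_xyz)
  basis <- fit_pca(refl, n_pc = n_pc)
  regression <- fit_spectral_regression(xyz_cor, basis, refl,
                                        term_spec = term_spec)
  analog <- reconstruct_spectrum(xyz_cor, basis, regression)
  fidelity <- validate_color_fidelity(analog, refl, white = white,
                                      illuminant = ill)
  report <- list(
    n_patches = nrow(refl),
    xyz_rmse_corrected = xyz_rmse(xyz_cor, xyz_ref)$mean,
    xyz_rmse_uncorrected = xyz_rmse(camera_xyz, xyz_ref)$mean,
    spectral_rmse = spectral_rmse(analog, refl)$mean,
    cumulative_explained = basis$cumulative_explained,
    mean_delta_e00 = fidelity$mean)
  structure(list(correction = correction, basis = basis,
                 regression = regression, white_point = white, m = m,
                 report = report),
            class = "conversion_model")
}

#' @export
print.conversion_model <- function(x, ...) {
  r <- x$report
  cat("<conversion_model>\n")
  cat(sprintf("  patches:                 %d\n", r$n_patches))
  cat(sprintf("  XYZ RMSE (corrected):    %.4f  (uncorrected %.4f)\n",
              r$xyz_rmse_corrected, r$xyz_rmse_uncorrected))
  cat(sprintf("  spectral RMSE:           %.4f %% reflectance\n", r$spectral_rmse))
  cat(sprintf("  explained variance (%d PC): %.2f %%\n",
              x$basis$n_pc, r$cumulative_explained))
  cat(sprintf("  mean dE00:               %.4f\n", r$mean_delta_e00))
  invisible(x)
}

#' Serialize / restore a conversion model as JSON
#'
#' One self-contained JSON document holding the correction matrix, term
#' specification, PCA basis, regression matrix, white point and provenance
#' metadata. Numbers are written at full precision, so saving the same
#' fitted model twice produces byte-identical files.
#'
#' @param model A [calibrate_patch_set()] result.
#' @param path Output path.
#' @return `read_conversion_model()` returns the restored `conversion_model`.
#' @export
write_conversion_model <- function(model, path) {
  if (!inherits(model, "conversion_model")) stop_input("not a conversion_model")
  doc <- list(
    format = "endohsi-conversion-model",
    version = as.character(utils::packageVersion("endohsi")),
    term_spec = list(name = model$correction$term_spec$name,
                     exponents = unname(model$correction$term_spec$exponents)),
    C = unname(model$correction$C),
    m = unname(model$m),
    white_point = model$white_point,
    brightness_ratio = model$correction$brightness_ratio,
    feature_scale = model$correction$feature_scale,
    residual_rmse = model$correction$residual_rmse,
    mean_spectrum = model$basis$mean_spectrum,
    loadings = unname(model$basis$loadings),
    explained_variance_ratio = model$basis$explained_variance_ratio,
    n_pc = model$basis$n_pc,
    M_reg = unname(model$regression$M_reg),
    report = model$report)
  json <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_conversion_model
#' @export
read_conversion_model <- function(path) {
  if (!file.exists(path)) stop_input("model file not found: %s", path)
  doc <- jsonlite::fromJSON(path)
  if (!identical(doc$format, "endohsi-conversion-model")) {
    stop_input("%s is not an endohsi conversion-model document", path)
  }
  ts <- term_preset(as.matrix(doc$term_spec$exponents))
  ts$name <- doc$term_spec$name
  correction <- structure(
    list(C = as.matrix(doc$C), term_spec = ts, m = as.matrix(doc$m),
         white_point = as.numeric(doc$white_point),
         brightness_ratio = doc$brightness_ratio,
         feature_scale = doc$feature_scale,
         residual_rmse = doc$residual_rmse),
    class = "camera_correction")
  basis <- structure(
    list(mean_spectrum = as.numeric(doc$mean_spectrum),
         loadings = as.matrix(doc$loadings),
         explained_variance_ratio = as.numeric(doc$explained_variance_ratio),
         cumulative_explained =
           100 * sum(doc$explained_variance_ratio[seq_len(doc$n_pc)]),
         n_pc = as.integer(doc$n_pc),
         wavelengths = hsi_wavelengths()),
    class = "spectral_basis")
  regression <- structure(
    list(M_reg = as.matrix(doc$M_reg), term_spec = ts,
         feature_scale = doc$feature_scale),
    class = "spectral_regression")
  structure(list(correction = correction, basis = basis,
                 regression = regression,
                 white_point = as.numeric(doc$white_point),
                 m = as.matrix(doc$m), report = doc$report),
            class = "conversion_model")
}
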