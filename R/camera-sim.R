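# Synthetic camera/spectrometer simulator: analytic observer functions,
# illuminants, a colour-target generator, ideal tristimulus integration and a
# distortable virtual camera. Everything upstream is testable against this
# module without any instrument data.

#' Analytic CIE 1931 colour-matching functions
#'
#' Multi-lobe piecewise-Gaussian approximation of the CIE 1931 2-degree
#' standard observer (the Wyman-Sloan-Shirley fit), clamped to be
#' nonnegative. Maximum deviation from the tabulated observer is below 0.02
#' on each function; no external data table is required.
#'
#' @param wavelength_nm Wavelengths in nanometres, within 380-780.
#' @return Matrix with columns `xbar`, `ybar`, `zbar`.
#' @export
#' @examples
#' cmf(555)[, "ybar"]  # near the photopic peak, approx. 1
cmf <- function(wavelength_nm) {
  l <- as.numeric(wavelength_nm)
  if (any(!is.finite(l)) || any(l < 380 | l > 780)) {
    stop_input("wavelength must lie within [380, 780] nm")
  }
  g <- function(x, mu, s1, s2) {
    s <- ifelse(x < mu, s1, s2)
    exp(-0.5 * ((x - mu) / s)^2)
  }
  xb <- 1.056 * g(l, 599.8, 37.9, 31.0) +
        0.362 * g(l, 442.0, 16.0, 26.7) -
        0.065 * g(l, 501.1, 20.4, 26.2)
  yb <- 0.821 * g(l, 568.8, 46.9, 40.5) +
        0.286 * g(l, 530.9, 16.3, 31.1)
  zb <- 1.217 * g(l, 437.0, 11.8, 36.0) +
        0.681 * g(l, 459.0, 26.0, 13.8)
  cbind(xbar = pmax(xb, 0), ybar = pmax(yb, 0), zbar = pmax(zb, 0))
}

#' Illuminant spectra on the standard grid
#'
#' * `"E"` (default): equal-energy illuminant -- flat spectral power.
#' * `"D65"`: analytic daylight-like approximation (Planckian radiator at
#'   6504 K, normalised to unit mean), offered because the endoscope light
#'   source is generally unspecified.
#'
#' @param name `"E"`, `"D65"`, or a numeric vector of length 401 used as a
#'   custom spectral power distribution.
#' @return An `illuminant` object: list with `power` (length 401) and `name`.
#' @export
illuminant <- function(name = "E") {
  if (is.numeric(name)) {
    p <- as.numeric(name)
    if (length(p) != N_BANDS) stop_input("custom illuminant must have 401 values")
    if (any(p < 0) || all(p == 0)) stop_input("illuminant power must be nonnegative and not all zero")
    return(structure(list(power = p, name = "custom"), class = "illuminant"))
  }
  wl <- hsi_wavelengths()
  p <- switch(match.arg(name, c("E", "D65")),
    E = rep(1, N_BANDS),
    D65 = {
      # Planck's law at T = 6504 K, wavelength in metres
      lm <- wl * 1e-9
      h <- 6.62607015e-34; c0 <- 299792458; kb <- 1.380649e-23
      b <- (2 * h * c0^2) / (lm^5 * (exp(h * c0 / (lm * kb * 6504)) - 1))
      b / mean(b)
    })
  structure(list(power = p, name = name), class = "illuminant")
}

as_illuminant <- function(x) {
  if (inherits(x, "illuminant")) x else illuminant(x)
}

#' Integrate a reflectance spectrum to CIE XYZ
#'
#' Riemann-sum tristimulus integration of reflectance times illuminant times
#' the analytic colour-matching functions, normalised so that the perfect
#' reflector (100 percent everywhere) has Y = 100 exactly. The normaliser
#' \eqn{k = 100 / \sum E(\lambda)\,\bar y(\lambda)} is the brightness ratio
#' tying the spectrometer scale to the colorimetric scale.
#'
#' @param reflectance Length-401 vector or n x 401 matrix, percent (0-100).
#' @param ill An [illuminant()] (or name).
#' @return XYZ triplet (vector input) or n x 3 matrix.
#' @export
#' @examples
#' spectrum_to_xyz(rep(100, 401))["Y"]  # exactly 100
spectrum_to_xyz <- function(reflectance, ill = illuminant("E")) {
  ill <- as_illuminant(ill)
  vec <- is.null(dim(reflectance))
  R <- as_spectra_matrix(reflectance, "reflectance")
  obs <- cmf(hsi_wavelengths())
  k <- 100 / sum(ill$power * obs[, "ybar"])
  W <- obs * ill$power                     # 401 x 3 weighted observer
  out <- k * (R / 100) %*% W
  colnames(out) <- c("X", "Y", "Z")
  if (vec) {
    out <- as.numeric(out); names(out) <- c("X", "Y", "Z")
  }
  out
}

# brightness-ratio normaliser for an illuminant
brightness_ratio <- function(ill = illuminant("E")) {
  ill <- as_illuminant(ill)
  100 / sum(ill$power * cmf(hsi_wavelengths())[, "ybar"])
}

#' Generate synthetic colour-target reflectance spectra
#'
#' Emulates a Macbeth-style 24-patch chart: an achromatic gray ramp
#' (spectrally flat patches at graded reflectance levels with a slight
#' random tilt) plus chromatic patches built as a baseline and a clipped sum
#' of broad Gaussian pigment lobes with random centres and amplitudes -- one
#' dominant lobe and smaller secondary lobes. Broad lobes (FWHM well above
#' `min_fwhm`) reproduce the empirical smoothness and low effective
#' dimensionality of printed-pigment reflectances, which is what makes
#' tristimulus-based spectral recovery possible. If a chromatic patch would
#' exceed 95 percent reflectance it is rescaled (pigment saturation) rather
#' than flat-clipped, preserving smoothness.
#'
#' @param n Number of spectra (>= 1).
#' @param seed Integer RNG seed; identical seeds give identical spectra.
#' @param n_lobes Candidate pigment-lobe counts per chromatic patch
#'   (default 2-4).
#' @param min_fwhm Hard lower floor on lobe FWHM in nm (default 50).
#' @param fwhm_range Sampling range for lobe FWHM in nm (default 250-450;
#'   must respect `min_fwhm`).
#' @param amp_primary,amp_secondary Amplitude ranges (percent reflectance)
#'   for the dominant and the secondary lobes.
#' @param baseline Range of the flat baseline reflectance (percent).
#' @param neutral_levels Reflectance levels of the gray-ramp patches.
#' @param include_neutrals Include the gray ramp (roughly a quarter of the
#'   patches, at most `length(neutral_levels)`); the defining structural
#'   feature of a real colour checker.
#' @return n x 401 matrix of reflectance spectra in percent (rows = patches).
#' @export
generate_reflectances <- function(n, seed, n_lobes = 2:4, min_fwhm = 50,
                                  fwhm_range = c(250, 450),
                                  amp_primary = c(25, 60),
                                  amp_secondary = c(4, 16),
                                  baseline = c(4, 12),
                                  neutral_levels = c(3.1, 9.0, 19.8, 36.2, 59.1, 88.0),
                                  include_neutrals = TRUE) {
  if (n < 1) stop_input("n must be at least 1")
  if (min_fwhm <= 0 || fwhm_range[1] < min_fwhm || fwhm_range[2] < fwhm_range[1]) {
    stop_input("invalid FWHM configuration (min_fwhm %g, range [%g, %g])",
               min_fwhm, fwhm_range[1], fwhm_range[2])
  }
  if (any(n_lobes < 1)) stop_input("n_lobes must be positive")
  set.seed(as.integer(seed))
  wl <- hsi_wavelengths()
  R <- matrix(0, n, N_BANDS)
  n_neutral <- if (include_neutrals) min(length(neutral_levels), n %/% 4L) else 0L
  for (i in seq_len(n_neutral)) {
    tilt <- stats::runif(1, -2e-4, 2e-4)   # up to ~4% slope across the grid
    R[i, ] <- clamp(neutral_levels[i] * (1 + tilt * (wl - 580)), 0, 100)
  }
  for (i in seq_len(n)[-seq_len(n_neutral)]) {
    nl <- if (length(n_lobes) == 1L) n_lobes else sample(n_lobes, 1)
    s <- stats::runif(1, baseline[1], baseline[2])
    for (j in seq_len(nl)) {
      mu <- stats::runif(1, 410, 690)
      fw <- stats::runif(1, fwhm_range[1], fwhm_range[2])
      a <- if (j == 1L) stats::runif(1, amp_primary[1], amp_primary[2])
           else stats::runif(1, amp_secondary[1], amp_secondary[2])
      s <- s + a * exp(-0.5 * ((wl - mu) / (fw / 2.3548200450309493))^2)
    }
    m <- max(s)
    if (m > 95) s <- s * (95 / m)
    R[i, ] <- clamp(s, 0, 100)
  }
  R
}

#' Describe a virtual camera's systematic defects
#'
#' The distortion applied between the true scene colour and the stored 8-bit
#' sRGB file: encoding-gamma mismatch (nonlinear response), channel
#' crosstalk (imprecise colour separation / colour shift), dark offset
#' (dark current), optional Gaussian noise, and an exposure gain.
#'
#' @param gamma_encode Encoding exponent: code value = v^(1/gamma). `NA`
#'   means the camera encodes with the true sRGB curve (no gamma mismatch).
#' @param crosstalk Either a scalar symmetric mixing fraction f (each channel
#'   keeps 1-2f and leaks f into each neighbour) or an explicit 3x3 matrix
#'   whose rows must sum to 1 within 0.2.
#' @param dark_offset Additive offset per channel in linear-RGB units.
#' @param noise_sd Gaussian noise standard deviation in linear-RGB units.
#' @param exposure Linear gain applied before the nonlinearity; `"auto"` is
#'   resolved by [build_calibration_fixture()] so that the scene white sits
#'   just below clipping.
#' @param seed Optional seed making noisy captures reproducible.
#' @return A `camera_distortion` object.
#' @export
camera_distortion <- function(gamma_encode = 2.2, crosstalk = 0.05,
                              dark_offset = 0.02, noise_sd = 0,
                              exposure = 1, seed = NULL) {
  if (length(crosstalk) == 1L) {
    f <- as.numeric(crosstalk)
    crosstalk <- diag(3) * (1 - 3 * f) + matrix(f, 3, 3)
  }
  crosstalk <- as.matrix(crosstalk)
  if (!all(dim(crosstalk) == c(3L, 3L))) stop_input("crosstalk must be 3x3")
  if (any(abs(rowSums(crosstalk) - 1) > 0.2)) {
    stop_input("crosstalk rows must sum to 1 within 0.2")
  }
  if (noise_sd < 0) stop_input("noise_sd must be nonnegative")
  structure(list(gamma_encode = gamma_encode, crosstalk = crosstalk,
                 dark_offset = as.numeric(dark_offset),
                 noise_sd = as.numeric(noise_sd),
                 exposure = exposure, seed = seed),
            class = "camera_distortion")
}

#' The identity (defect-free) camera
#' @return A [camera_distortion()] with true sRGB encoding, no crosstalk,
#'   no dark current, no noise, unit exposure.
#' @export
identity_distortion <- function() {
  camera_distortion(gamma_encode = NA, crosstalk = 0, dark_offset = 0,
                    noise_sd = 0, exposure = 1)
}

#' Capture a true XYZ colour with the virtual camera
#'
#' Runs the inverse of the ideal decoding path plus the injected defects:
#' XYZ to linear RGB through the inverse of `m`, exposure gain, crosstalk,
#' dark offset, optional noise, clamping to \eqn{[0,1]}, nonlinear encoding
#' (distorted gamma or true sRGB), and 8-bit quantisation.
#'
#' @param xyz_true Length-3 vector or n x 3 matrix of scene XYZ
#'   (white Y = 100 scale).
#' @param distortion A [camera_distortion()].
#' @param m The 3x3 linear-RGB to XYZ matrix of the ideal path.
#' @return 8-bit sRGB code values (integer), same shape convention.
#' @export
simulate_camera <- function(xyz_true, distortion = camera_distortion(),
                            m = srgb_xyz_matrix()) {
  if (!inherits(distortion, "camera_distortion")) {
    stop_input("distortion must be a camera_distortion object")
  }
  vec <- is.null(dim(xyz_true))
  xyz <- as_matrix3(xyz_true, "xyz_true")
  exposure <- distortion$exposure
  if (identical(exposure, "auto")) {
    stop_input("exposure 'auto' must be resolved against a white point first")
  }
  v <- (xyz / 100) %*% t(solve(m)) * exposure
  v <- v %*% t(distortion$crosstalk)
  v <- v + distortion$dark_offset
  if (distortion$noise_sd > 0) {
    if (!is.null(distortion$seed)) set.seed(as.integer(distortion$seed))
    v <- v + stats::rnorm(length(v), 0, distortion$noise_sd)
  }
  v <- clamp(v, 0, 1)
  enc <- if (is.na(distortion$gamma_encode)) linear_to_srgb_encode(v)
         else v^(1 / distortion$gamma_encode)
  out <- round(255 * clamp(enc, 0, 1))
  storage.mode(out) <- "integer"
  colnames(out) <- c("R", "G", "B")
  if (vec) {
    out <- as.integer(out); names(out) <- c("R", "G", "B")
  }
  out
}

#' Build a complete synthetic calibration set
#'
#' Generates a 24-patch synthetic colour target ([generate_reflectances()]),
#' integrates the true (spectrometer-side) XYZ under the illuminant, and
#' captures each patch with the distorted virtual camera. Patch values are
#' noiseless region averages, so only systematic camera defects enter. The
#' default distortion is a gamma-2.2 encode (against the pipeline's sRGB
#' decode), 5 percent symmetric crosstalk and a 0.02 dark offset; `"auto"`
#' exposure places the illuminant white at 95 percent of clipping, as a
#' camera's exposure control would.
#'
#' @param seed Integer seed driving the reflectance generator.
#' @param n Number of patches (default 24).
#' @param distortion A [camera_distortion()]; default as described. The
#'   string `"identity"` selects the defect-free camera.
#' @param ill An [illuminant()] or name (default equal-energy).
#' @param ... Passed to [generate_reflectances()].
#' @return A `color_patch_set`: list with `rgb` (n x 3 integer), `reflectance`
#'   (n x 401 percent), `xyz_reference` (n x 3), `white_point`, `k`
#'   (brightness ratio), `illuminant`, `distortion`, `m`, `seed`.
#' @export
build_calibration_fixture <- function(seed, n = 24,
                                      distortion = camera_distortion(exposure = "auto"),
                                      ill = illuminant("E"), ...) {
  if (identical(distortion, "identity")) distortion <- identity_distortion()
  ill <- as_illuminant(ill)
  m <- srgb_xyz_matrix()
  R <- generate_reflectances(n, seed, ...)
  xyz_ref <- spectrum_to_xyz(R, ill)
  white <- spectrum_to_xyz(rep(100, N_BANDS), ill)
  if (identical(distortion$exposure, "auto")) {
    distortion$exposure <- 0.95 / max(solve(m) %*% (white / 100))
  }
  rgb <- simulate_camera(xyz_ref, distortion, m)
  structure(
    list(rgb = rgb, reflectance = R, xyz_reference = xyz_ref,
         white_point = white, k = brightness_ratio(ill),
         illuminant = ill, distortion = distortion, m = m,
         seed = as.integer(seed)),
    class = "color_patch_set")
}

#' @export
print.color_patch_set <- function(x, ...) {
  cat(sprintf("<color_patch_set: %d patches, illuminant %s, seed %d>\n",
              nrow(x$rgb), x$illuminant$name, x$seed))
  invisible(x)
}

#' Build a synthetic scene image with its ground-truth cube
#'
#' Tiles patches from a calibration set into an image: the layout matrix
#' assigns a patch index to each grid cell, each cell is rendered as a
#' uniform block of that patch's camera sRGB colour, and the ground-truth
#' hypercube carries the patch's true reflectance spectrum at every pixel.
#'
#' @param patch_set A [build_calibration_fixture()] result.
#' @param layout Integer matrix of patch indices (default 4 x 6, patches in
#'   order). `NA` cells are not allowed: the layout must cover the image.
#' @param size Output image side length in pixels (default 608, the detector
#'   convention); may be a length-2 vector (rows, cols).
#' @return A `synthetic_scene`: list with `rgb` (H x W x 3 integer array),
#'   `truth` (a [hypercube()]), and `layout`.
#' @export
build_scene <- function(patch_set, layout = matrix(1:24, 4, 6, byrow = TRUE),
                        size = 608) {
  if (!inherits(patch_set, "color_patch_set")) {
    stop_input("patch_set must be a color_patch_set")
  }
  layout <- as.matrix(layout)
  if (any(is.na(layout))) stop_input("layout has gaps: every cell needs a patch index")
  if (any(layout < 1 | layout > nrow(patch_set$rgb))) {
    stop_input("layout indexes patches outside 1..%d", nrow(patch_set$rgb))
  }
  if (length(size) == 1L) size <- c(size, size)
  H <- size[1]; W <- size[2]
  row_of <- pmin(ceiling(seq_len(H) / (H / nrow(layout))), nrow(layout))
  col_of <- pmin(ceiling(seq_len(W) / (W / ncol(layout))), ncol(layout))
  idx <- matrix(layout[cbind(rep(row_of, W), rep(col_of, each = H))], H, W)
  rgb <- array(0L, c(H, W, 3L))
  for (ch in 1:3) rgb[, , ch] <- matrix(patch_set$rgb[idx, ch], H, W)
  truth <- array(0, c(H, W, N_BANDS))
  for (b in seq_len(N_BANDS)) {
    truth[, , b] <- matrix(patch_set$reflectance[idx, b], H, W)
  }
  structure(list(rgb = rgb,
                 truth = hypercube(truth, provenance = "synthetic scene truth"),
                 layout = layout, patch_index = idx),
            class = "synthetic_scene")
}

#' Write / read a calibration CSV
#'
#' Tabular text interchange format for calibration sets: columns `patch_id`,
#' `R`, `G`, `B`, then the reflectance at each wavelength (`refl_380` ..
#' `refl_780`, 401 columns, percent units). Header row mandatory.
#'
#' @param patch_set A `color_patch_set` (only rgb + reflectance are written).
#' @param path File path.
#' @return `read_patch_csv()` returns a list with `rgb` (n x 3 integer) and
#'   `reflectance` (n x 401).
#' @export
write_patch_csv <- function(patch_set, path) {
  df <- data.frame(patch_id = seq_len(nrow(patch_set$rgb)),
                   R = patch_set$rgb[, 1], G = patch_set$rgb[, 2],
                   B = patch_set$rgb[, 3])
  refl <- as.data.frame(patch_set$reflectance)
  names(refl) <- paste0("refl_", hsi_wavelengths())
  utils::write.csv(cbind(df, refl), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patch_csv
#' @export
read_patch_csv <- function(path) {
  if (!file.exists(path)) stop_input("calibration CSV not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("patch_id", "R", "G", "B", paste0("refl_", hsi_wavelengths()))
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop_input("calibration CSV is missing column(s): %s",
               paste(utils::head(missing, 5), collapse = ", "))
  }
  rgb <- as.matrix(df[, c("R", "G", "B")])
  storage.mode(rgb) <- "integer"
  refl <- as.matrix(df[, paste0("refl_", hsi_wavelengths())])
  storage.mode(refl) <- "double"
  list(rgb = rgb, reflectance = unname(refl))
}
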