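# Hypercube container, per-pixel conversion, narrow-band synthesis and
# cube/image I/O.

#' Hyperspectral reflectance cube
#'
#' Container for an H x W x 401 reflectance cube on the standard grid.
#' Values are reflectance percent in \eqn{[0, 100]} and are stored at 32-bit
#' float precision (quantised on construction), which is the on-disk ENVI
#' data type -- so write/read round trips are bit-exact.
#'
#' @param data Numeric array H x W x 401.
#' @param wavelengths Band-centre wavelengths; must be the standard grid.
#' @param provenance Free-text provenance string (model id, source hash).
#' @return A `hypercube` object.
#' @export
hypercube <- function(data, wavelengths = hsi_wavelengths(), provenance = "") {
  if (length(dim(data)) != 3L || dim(data)[3] != N_BANDS) {
    stop_input("cube data must be H x W x %d", N_BANDS)
  }
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != N_BANDS || any(wavelengths != hsi_wavelengths())) {
    stop_input("wavelengths must be the standard 380-780 nm grid (401 bands, 1 nm step)")
  }
  data <- as_float32(clamp(data, 0, 100))
  structure(list(data = data, wavelengths = wavelengths,
                 provenance = as.character(provenance)),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube %d x %d x %d, %g-%g nm%s>\n", d[1], d[2], d[3],
              min(x$wavelengths), max(x$wavelengths),
              if (nzchar(x$provenance)) paste0(", ", x$provenance) else ""))
  invisible(x)
}

#' Convert an RGB image to a hyperspectral cube
#'
#' Applies the fitted conversion model per pixel: sRGB decode, XYZ
#' conversion, polynomial correction, spectral reconstruction. Identical
#' pixel colours yield identical spectra, so the conversion is computed once
#' per unique 24-bit colour and broadcast -- bit-identical to the per-pixel
#' path but far faster on natural images.
#'
#' @param rgb_image H x W x 3 array of 8-bit code values (integer 0-255, or
#'   0-1 doubles as returned by PNG readers), or a path to a PNG/JPEG file.
#' @param model A [calibrate_patch_set()] `conversion_model`.
#' @return A [hypercube()].
#' @export
convert_image <- function(rgb_image, model) {
  if (!inherits(model, "conversion_model")) {
    stop_input("model must be a conversion_model")
  }
  img <- as_image_array(rgb_image)
  H <- dim(img)[1]; W <- dim(img)[2]
  key <- img[, , 1] * 65536L + img[, , 2] * 256L + img[, , 3]
  uk <- unique(as.vector(key))
  lut_rgb <- cbind((uk %/% 65536L) %% 256L, (uk %/% 256L) %% 256L, uk %% 256L)
  xyz <- linear_to_xyz(srgb_to_linear(lut_rgb), model$m)
  xyz_cor <- apply_correction(model$correction, xyz)
  spectra <- reconstruct_spectrum(xyz_cor, model$basis, model$regression)
  idx <- match(as.vector(key), uk)
  cube <- array(0, c(H, W, N_BANDS))
  for (b in seq_len(N_BANDS)) cube[, , b] <- matrix(spectra[idx, b], H, W)
  hypercube(cube, provenance = "convert_image")
}

# accept an in-memory array (integer 0-255 or double 0-1) or a PNG/JPEG path
as_image_array <- function(x) {
  if (is.character(x)) x <- read_image(x)
  if (length(dim(x)) == 3L && dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  if (length(dim(x)) != 3L || dim(x)[3] != 3L) {
    stop_input("image must be a 3-channel (H x W x 3) array")
  }
  if (is.double(x) && max(x) <= 1) x <- round(x * 255)
  if (any(x < 0 | x > 255)) stop_input("image values must be 8-bit (0-255)")
  storage.mode(x) <- "integer"
  x
}

#' Read / write an 8-bit RGB image file
#'
#' Thin PNG/JPEG wrappers (the `png` / `jpeg` packages must be installed).
#' Images are H x W x 3 integer arrays of 0-255 code values.
#'
#' @param path File path; format chosen by extension (.png, .jpg, .jpeg).
#' @param img For writing: H x W x 3 array, 0-255.
#' @return `read_image()` returns the integer array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_input("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = { requireNamespace("png"); png::readPNG(path) },
    jpg = , jpeg = { requireNamespace("jpeg"); jpeg::readJPEG(path) },
    stop_input("unsupported image extension '.%s' (use png/jpg)", ext))
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3), c(dim(raw), 3L))
  as_image_array(raw)
}

#' @rdname read_image
#' @export
write_image <- function(img, path) {
  img <- as_image_array(img)
  ext <- tolower(tools::file_ext(path))
  arr <- img / 255
  switch(ext,
    png = { requireNamespace("png"); png::writePNG(arr, path) },
    jpg = , jpeg = { requireNamespace("jpeg"); jpeg::writeJPEG(arr, path, quality = 1) },
    stop_input("unsupported image extension '.%s' (use png/jpg)", ext))
  invisible(path)
}

#' Extract one spectral band
#'
#' Returns the H x W slice at the band nearest the requested wavelength
#' (snap within 0.5 nm).
#'
#' @param cube A [hypercube()].
#' @param wavelength_nm Wavelength in nm, within the cube's grid.
#' @return H x W numeric matrix.
#' @export
extract_band <- function(cube, wavelength_nm) {
  stopifnot(inherits(cube, "hypercube"))
  wl <- cube$wavelengths
  if (wavelength_nm < min(wl) - 0.5 || wavelength_nm > max(wl) + 0.5) {
    stop_input("wavelength %g nm outside the cube grid [%g, %g] nm",
               wavelength_nm, min(wl), max(wl))
  }
  cube$data[, , which.min(abs(wl - wavelength_nm))]
}

#' Simulate a narrow-band image from a cube
#'
#' Each narrow band is a Gaussian-weighted average of cube bands centred on
#' the filter wavelength (weights normalised to sum to one), mimicking the
#' blue (415 nm) and green (540 nm) interference filters of clinical
#' narrow-band endoscopy. The default display mapping feeds the 415 nm band
#' into the blue and green display channels and the 540 nm band into red,
#' matching the red-shifted rendering of superficial vasculature. Channels
#' are encoded to 8 bits by the fixed affine map from \eqn{[0, 100]}
#' reflectance.
#'
#' @param cube A [hypercube()].
#' @param centers Filter centre wavelengths in nm (default `c(415, 540)`).
#' @param fwhm Filter full width at half maximum in nm (default 30).
#' @param channel_map Length-3 integer vector: for each display channel
#'   (R, G, B), the index into `centers` of the band feeding it. Default
#'   `c(2, 1, 1)` (540 to R; 415 to G and B).
#' @return An `nbi_composite`: list with `image` (H x W x 3 integer array),
#'   `band_images` (list of H x W matrices), `centers`, `fwhm`,
#'   `channel_map`.
#' @export
simulate_nbi <- function(cube, centers = c(415, 540), fwhm = 30,
                         channel_map = c(2, 1, 1)) {
  stopifnot(inherits(cube, "hypercube"))
  wl <- cube$wavelengths
  if (any(centers < min(wl) | centers > max(wl))) {
    stop_input("narrow-band centers must lie within [%g, %g] nm", min(wl), max(wl))
  }
  if (length(channel_map) != 3L || any(!channel_map %in% seq_along(centers))) {
    stop_input("channel_map must assign one of the %d bands to each display channel",
               length(centers))
  }
  sigma <- fwhm / 2.3548200450309493
  H <- dim(cube$data)[1]; W <- dim(cube$data)[2]
  band_images <- lapply(centers, function(cc) {
    w <- exp(-0.5 * ((wl - cc) / sigma)^2)
    w <- w / sum(w)
    out <- matrix(0, H, W)
    nz <- which(w > 1e-12)
    for (b in nz) out <- out + w[b] * cube$data[, , b]
    out
  })
  img <- array(0L, c(H, W, 3L))
  for (ch in 1:3) {
    img[, , ch] <- matrix(as.integer(round(clamp(
      band_images[[channel_map[ch]]] * 2.55, 0, 255))), H, W)
  }
  structure(list(image = img, band_images = band_images, centers = centers,
                 fwhm = fwhm, channel_map = channel_map),
            class = "nbi_composite")
}

#' Render a cube to a 3-channel detector-input image
#'
#' The 3-channel representation used to feed a 401-band cube to an RGB
#' object detector is not standardised; two deterministic candidates are
#' provided:
#'
#' * `"bands-415-540-700"`: R, G, B = the 700, 540 and 415 nm bands, each
#'   affinely encoded from \eqn{[0, 100]} reflectance.
#' * `"pc-composite"`: per-pixel scores on the first three basis components,
#'   each channel min-max scaled over the image.
#'
#' @param cube A [hypercube()].
#' @param mode `"bands-415-540-700"` or `"pc-composite"`.
#' @param basis A [fit_pca()] basis (required for `"pc-composite"`).
#' @return H x W x 3 integer array (0-255).
#' @export
render_detector_view <- function(cube, mode = c("bands-415-540-700", "pc-composite"),
                                 basis = NULL) {
  stopifnot(inherits(cube, "hypercube"))
  mode <- match.arg(mode)
  H <- dim(cube$data)[1]; W <- dim(cube$data)[2]
  img <- array(0L, c(H, W, 3L))
  if (mode == "bands-415-540-700") {
    bands <- c(700, 540, 415)
    for (ch in 1:3) {
      img[, , ch] <- matrix(as.integer(round(clamp(
        extract_band(cube, bands[ch]) * 2.55, 0, 255))), H, W)
    }
  } else {
    if (!inherits(basis, "spectral_basis")) {
      stop_input("'pc-composite' mode needs a fitted spectral_basis")
    }
    flat <- matrix(cube$data, H * W, N_BANDS)
    scores <- project_spectra(basis, flat)[, 1:3, drop = FALSE]
    for (ch in 1:3) {
      s <- scores[, ch]
      rng <- range(s)
      s <- if (diff(rng) == 0) rep(0, length(s)) else (s - rng[1]) / diff(rng)
      img[, , ch] <- matrix(as.integer(round(255 * s)), H, W)
    }
  }
  img
}

#' Write / read a hypercube
#'
#' Two on-disk forms:
#'
#' * `"envi"`: classic ENVI pair -- a text header (`.hdr`: samples, lines,
#'   bands, `data type = 4` (32-bit float), `interleave = bsq`, byte order,
#'   wavelengths) plus the raw band-sequential binary. Bit-exact round trip
#'   (the cube is stored at float32 precision).
#' * `"archive"`: a single gzip stream holding a JSON metadata line
#'   (dimensions, wavelengths, provenance) followed by the float32 data.
#'
#' @param cube A [hypercube()].
#' @param path Output path. For ENVI this is the header path (`.hdr`); the
#'   binary drops the extension (`.raw` appended when path has no `.hdr`).
#' @param format `"envi"` or `"archive"`.
#' @return `read_cube()` returns the restored [hypercube()].
#' @export
write_cube <- function(cube, path, format = c("envi", "archive")) {
  stopifnot(inherits(cube, "hypercube"))
  format <- match.arg(format)
  d <- dim(cube$data)
  if (format == "envi") {
    hdr_path <- if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
    raw_path <- sub("\\.hdr$", ".raw", hdr_path)
    hdr <- c("ENVI",
             "description = {endohsi reflectance cube}",
             sprintf("samples = %d", d[2]),
             sprintf("lines = %d", d[1]),
             sprintf("bands = %d", d[3]),
             "header offset = 0",
             "file type = ENVI Standard",
             "data type = 4",
             "interleave = bsq",
             "byte order = 0",
             "wavelength units = Nanometers",
             paste0("wavelength = {",
                    paste(format(cube$wavelengths, trim = TRUE), collapse = ", "),
                    "}"))
    writeLines(hdr, hdr_path)
    con <- file(raw_path, "wb")
    on.exit(close(con))
    # BSQ: band-major, within band row-major (line by line)
    writeBin(as.numeric(aperm(cube$data, c(2, 1, 3))), con,
             size = 4L, endian = "little")
    return(invisible(hdr_path))
  }
  con <- gzfile(path, "wb")
  on.exit(close(con))
  meta <- jsonlite::toJSON(list(format = "endohsi-cube", dims = d,
                                wavelengths = cube$wavelengths,
                                provenance = cube$provenance),
                           digits = NA, auto_unbox = TRUE)
  writeLines(as.character(meta), con)
  writeBin(as.numeric(cube$data), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path, format = c("envi", "archive")) {
  format <- match.arg(format)
  if (format == "envi") {
    hdr_path <- if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
    if (!file.exists(hdr_path)) stop_input("ENVI header not found: %s", hdr_path)
    lines <- readLines(hdr_path, warn = FALSE)
    get_field <- function(name, required = TRUE) {
      hit <- grep(paste0("^", name, "\\s*="), lines, value = TRUE)
      if (length(hit) == 0L) {
        if (required) stop_input("malformed ENVI header: missing field '%s'", name)
        return(NULL)
      }
      trimws(sub("^[^=]*=", "", hit[1]))
    }
    samples <- as.integer(get_field("samples"))
    nlines <- as.integer(get_field("lines"))
    bands <- as.integer(get_field("bands"))
    dtype <- as.integer(get_field("data type"))
    interleave <- tolower(get_field("interleave"))
    if (is.na(samples) || is.na(nlines) || is.na(bands)) {
      stop_input("malformed ENVI header: non-numeric dimension field")
    }
    if (dtype != 4L) stop_input("unsupported ENVI data type %d (expected 4)", dtype)
    if (interleave != "bsq") stop_input("unsupported interleave '%s' (expected bsq)", interleave)
    wl_txt <- paste(lines[grep("wavelength = \\{", lines):length(lines)], collapse = " ")
    wl <- as.numeric(strsplit(gsub(".*\\{|\\}.*", "", wl_txt), ",")[[1]])
    raw_path <- sub("\\.hdr$", ".raw", hdr_path)
    if (!file.exists(raw_path)) stop_input("ENVI binary not found: %s", raw_path)
    n <- samples * nlines * bands
    expected <- n * 4
    actual <- file.size(raw_path)
    if (actual != expected) {
      stop_input("ENVI binary %s is %d bytes but the header implies %d",
                 raw_path, actual, expected)
    }
    con <- file(raw_path, "rb")
    on.exit(close(con))
    vals <- readBin(con, "double", n = n, size = 4L, endian = "little")
    data <- aperm(array(vals, c(samples, nlines, bands)), c(2, 1, 3))
    return(hypercube(data, wavelengths = wl, provenance = "envi"))
  }
  con <- gzfile(path, "rb")
  on.exit(close(con))
  meta <- jsonlite::fromJSON(readLines(con, n = 1L))
  if (!identical(meta$format, "endohsi-cube")) {
    stop_input("%s is not an endohsi cube archive", path)
  }
  d <- as.integer(meta$dims)
  vals <- readBin(con, "double", n = prod(d), size = 4L, endian = "little")
  if (length(vals) != prod(d)) {
    stop_input("cube archive %s holds %d values but the metadata implies %d",
               path, length(vals), prod(d))
  }
  hypercube(array(vals, d), wavelengths = as.numeric(meta$wavelengths),
            provenance = as.character(meta$provenance))
}
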