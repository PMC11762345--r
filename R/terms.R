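# Polynomial feature expansion of XYZ ("variable matrix" V construction).

#' Polynomial term-set presets
#'
#' Named monomial sets used to expand an XYZ triplet into the feature column
#' of the variable matrix V. The constant term always comes first and the
#' ordering is fixed so that fitted models serialize reproducibly.
#'
#' * `affine`: 1, X, Y, Z (4 terms)
#' * `poly2`: adds XY, XZ, YZ, X^2, Y^2, Z^2 (10 terms)
#' * `poly3` (default elsewhere): adds XYZ, X^2 Y, X^2 Z, Y^2 X, Y^2 Z,
#'   Z^2 X, Z^2 Y, X^3, Y^3, Z^3 (20 terms) -- fewer terms than the 24
#'   calibration patches, keeping the pseudoinverse fit well-posed.
#'
#' @param name One of `"affine"`, `"poly2"`, `"poly3"`, or an explicit
#'   integer matrix of exponent triples (columns X, Y, Z) which is validated
#'   and returned as-is.
#' @return A `term_spec` object: list with `name` and `exponents`
#'   (n_terms x 3 integer matrix, first row all zero).
#' @export
#' @examples
#' term_preset("affine")$exponents
term_preset <- function(name = c("poly3", "poly2", "affine")) {
  if (is.matrix(name)) {
    ex <- name
    if (ncol(ex) != 3L) stop_input("exponent matrix must have 3 columns")
    if (nrow(ex) < 1L) stop_input("term_spec must contain at least one term")
    if (any(ex < 0) || any(ex != round(ex))) {
      stop_input("exponents must be nonnegative integers")
    }
    if (!all(ex[1, ] == 0L)) stop_input("the first term must be the constant 1")
    storage.mode(ex) <- "integer"
    return(structure(list(name = "custom", exponents = ex),
                     class = "term_spec"))
  }
  name <- match.arg(name)
  affine <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  poly2 <- rbind(affine,
                 c(1, 1, 0), c(1, 0, 1), c(0, 1, 1),
                 c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  poly3 <- rbind(poly2,
                 c(1, 1, 1),
                 c(2, 1, 0), c(2, 0, 1), c(1, 2, 0), c(0, 2, 1),
                 c(1, 0, 2), c(0, 1, 2),
                 c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  ex <- switch(name, affine = affine, poly2 = poly2, poly3 = poly3)
  storage.mode(ex) <- "integer"
  colnames(ex) <- c("X", "Y", "Z")
  structure(list(name = name, exponents = ex), class = "term_spec")
}

as_term_spec <- function(term_spec) {
  if (inherits(term_spec, "term_spec")) return(term_spec)
  term_preset(term_spec)
}

#' Expand XYZ values into polynomial features
#'
#' Evaluates the monomials of a term specification at each XYZ triplet,
#' constant term first. This builds one column of the variable matrix V per
#' sample (returned transposed: one row per sample).
#'
#' @param xyz Length-3 vector or n x 3 matrix of XYZ values.
#' @param term_spec A [term_preset()] name or object.
#' @return n x n_terms numeric matrix (a plain vector for vector input).
#' @export
#' @examples
#' expand_features(c(2, 1, 0), "poly3")  # the X^2 Y term evaluates to 4
expand_features <- function(xyz, term_spec = "poly3") {
  ts <- as_term_spec(term_spec)
  vec <- is.null(dim(xyz))
  m <- as_matrix3(xyz, "XYZ")
  ex <- ts$exponents
  out <- matrix(1, nrow(m), nrow(ex))
  for (j in seq_len(nrow(ex))) {
    e <- ex[j, ]
    out[, j] <- m[, 1]^e[1] * m[, 2]^e[2] * m[, 3]^e[3]
  }
  if (vec) as.numeric(out) else out
}

#' @export
print.term_spec <- function(x, ...) {
  cat(sprintf("<term_spec '%s': %d terms>\n", x$name, nrow(x$exponents)))
  invisible(x)
}
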