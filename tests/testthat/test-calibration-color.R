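# colorimetric front end: sRGB decode, XYZ, polynomial correction, Lab, dE00

test_that("srgb_to_linear implements the standard EOTF", {
  expect_equal(srgb_to_linear(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(srgb_to_linear(c(255, 255, 255)), c(1, 1, 1))
  # mid-gray: direct evaluation of the IEC 61966-2-1 decoding formula
  expect_equal(srgb_to_linear(c(128, 128, 128)),
               rep(((128 / 255 + 0.055) / 1.055)^2.4, 3),
               tolerance = 1e-12)
  expect_equal(srgb_to_linear(c(128, 128, 128)), rep(0.2158, 3),
               tolerance = 1e-3)  # exact value 0.215861
  # monotone in input
  v <- srgb_to_linear(cbind(0:255, 0:255, 0:255))[, 1]
  expect_true(all(diff(v) > 0))
  expect_error(srgb_to_linear(c(-1, 0, 0)), "0, 255")
  expect_error(srgb_to_linear(c(0, 300, 0)), "0, 255")
})

test_that("linear_to_xyz is the scaled matrix map", {
  expect_equal(linear_to_xyz(c(0, 0, 0)), c(X = 0, Y = 0, Z = 0))
  # white -> row sums of the bundled matrix, scaled to Y = 100
  w <- linear_to_xyz(c(1, 1, 1))
  expect_equal(unname(w), unname(100 * rowSums(srgb_xyz_matrix())), tolerance = 1e-12)
  expect_equal(unname(w["Y"]), 100.00001, tolerance = 1e-5)
  # linearity
  v <- c(0.2, 0.4, 0.1)
  expect_equal(linear_to_xyz(2 * v), 2 * linear_to_xyz(v))
  expect_error(linear_to_xyz(c(1, 1, 1), matrix(1, 3, 3)), "singular")
  expect_error(linear_to_xyz(c(1, 1, 1), matrix(1, 2, 3)), "3x3")
})

test_that("expand_features evaluates monomials, constant first", {
  expect_equal(expand_features(c(0, 0, 0), "poly3"),
               c(1, rep(0, 19)))
  for (preset in c("affine", "poly2", "poly3")) {
    ts <- term_preset(preset)
    expect_equal(expand_features(c(1, 1, 1), preset),
                 rep(1, nrow(ts$exponents)))
  }
  # X^2 Y at (2, 1, 0) is 4 (12th term of the poly3 ordering)
  f <- expand_features(c(2, 1, 0), "poly3")
  ex <- term_preset("poly3")$exponents
  j <- which(ex[, 1] == 2 & ex[, 2] == 1 & ex[, 3] == 0)
  expect_equal(f[j], 4)
  expect_error(term_preset(matrix(numeric(0), 0, 3)), "at least one term")
  expect_error(term_preset(rbind(c(1, 0, 0))), "constant")
})

test_that("fit_correction recovers exactly representable distortions", {
  set.seed(1)
  ref <- matrix(runif(72, 5, 95), 24, 3)
  # identity: zero residual
  m0 <- fit_correction(ref, ref, "affine")
  expect_lt(m0$residual_rmse, 1e-9)
  expect_equal(apply_correction(m0, ref[3, ]), ref[3, ],
               tolerance = 1e-9, ignore_attr = TRUE)
  # affine map A x + b lies in the affine model class: machine-precision fit
  A <- matrix(c(1.1, 0.05, -0.02, 0.03, 0.95, 0.01, 0, 0.04, 1.02), 3, 3)
  b <- c(1, -2, 0.5)
  cam <- t(A %*% t(ref) + b)
  ma <- fit_correction(cam, ref, "affine")
  expect_lt(ma$residual_rmse, 1e-8)
  # held-out point also reproduced (the map itself is recovered)
  x_new <- c(40, 55, 20)
  expect_equal(apply_correction(ma, t(A %*% x_new + b)),
               matrix(x_new, 1), tolerance = 1e-7, ignore_attr = TRUE)
  expect_error(fit_correction(ref[1:10, ], ref[1:10, ], "poly3"),
               "10 patches.*20")
  expect_error(fit_correction(ref[1:10, ], ref, "affine"), "aligned")
  expect_error(apply_correction(structure(list(), class = "camera_correction"),
                                ref), "fitted")
})

test_that("pseudoinverse fit agrees with a normal-equations oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    cam <- matrix(runif(72, 2, 98), 24, 3)
    ref <- cam + matrix(rnorm(72, 0, 3), 24, 3)
    model <- fit_correction(cam, ref, "poly3")
    V <- t(expand_features(cam / model$feature_scale, "poly3"))
    C_oracle <- normal_equations_fit(V, t(ref))
    expect_equal(model$C, C_oracle, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("correction never increases training RMSE and helps held-out points", {
  ps <- default_fixture()
  cam <- linear_to_xyz(srgb_to_linear(ps$rgb))
  model <- fit_correction(cam, ps$xyz_reference, "poly3")
  cor <- apply_correction(model, cam)
  expect_lte(xyz_rmse(cor, ps$xyz_reference)$mean,
             xyz_rmse(cam, ps$xyz_reference)$mean)
  # held-out 25th patch under the same camera: corrected beats uncorrected
  ps25 <- build_calibration_fixture(42, n = 25)
  cam25 <- linear_to_xyz(srgb_to_linear(ps25$rgb))
  m24 <- fit_correction(cam25[1:24, ], ps25$xyz_reference[1:24, ], "poly3")
  held_cor <- apply_correction(m24, cam25[25, , drop = FALSE])
  err_cor <- xyz_rmse(held_cor, ps25$xyz_reference[25, , drop = FALSE])$mean
  err_unc <- xyz_rmse(cam25[25, , drop = FALSE],
                      ps25$xyz_reference[25, , drop = FALSE])$mean
  expect_lt(err_cor, err_unc)
})

test_that("negative corrected XYZ is clamped with a warning", {
  set.seed(3)
  cam <- matrix(runif(72, 5, 95), 24, 3)
  ref <- cam - 20           # pushes dark colours negative
  model <- fit_correction(cam, ref, "affine")
  expect_warning(out <- apply_correction(model, c(1, 1, 1)), "clamped")
  expect_true(all(out >= 0))
})

test_that("xyz_to_lab uses the printed piecewise constants", {
  w <- d65_white()
  expect_equal(xyz_to_lab(w), c(L = 100, a = 0, b = 0), tolerance = 1e-4)
  # black evaluates the linear branch at n = 0: L = 116*0.137931 - 16
  lab0 <- xyz_to_lab(c(0, 0, 0))
  expect_equal(unname(lab0["L"]), 116 * 0.137931 - 16, tolerance = 1e-12)
  expect_lt(abs(lab0["L"]), 0.01)
  expect_equal(unname(lab0[c("a", "b")]), c(0, 0), tolerance = 1e-12)
  # 18% neutral gray: closed-form cube-root branch
  lab18 <- xyz_to_lab(0.18 * w)
  expect_equal(unname(lab18["L"]), 116 * 0.18^(1 / 3) - 16, tolerance = 1e-12)
  expect_equal(round(unname(lab18["L"]), 2), 49.5)
  expect_equal(unname(lab18[c("a", "b")]), c(0, 0), tolerance = 1e-10)
  # branch continuity at the 0.008856 threshold
  n <- 0.008856
  expect_lt(abs(n^(1 / 3) - (7.787 * n + 0.137931)), 1e-3)
  expect_error(xyz_to_lab(w, white = c(0, 100, 100)), "positive")
})

test_that("ciede2000 matches independently computed reference pairs", {
  # reference values computed with an independent implementation
  # (scikit-image deltaE_ciede2000) on standard verification pairs
  pairs <- list(
    list(c(50, 2.6772, -79.7751), c(50, 0, -82.7485), 2.0425),
    list(c(50, 3.1571, -77.2803), c(50, 0, -82.7485), 2.8615),
    list(c(50, 2.8361, -74.0200), c(50, 0, -82.7485), 3.4412),
    list(c(50, -1.3802, -84.2814), c(50, 0, -82.7485), 1.0000),
    list(c(50, 2.5, 0), c(73, 25, -18), 27.1492),
    list(c(2.0776, 0.0795, -1.1350), c(0.9033, -0.0636, -0.5514), 0.9082))
  for (p in pairs) {
    expect_equal(ciede2000(p[[1]], p[[2]]), p[[3]], tolerance = 1e-4)
  }
})

test_that("ciede2000 is nonnegative, symmetric and zero on identity", {
  set.seed(7)
  for (i in 1:25) {
    a <- c(runif(1, 0, 100), runif(2, -60, 60))
    b <- c(runif(1, 0, 100), runif(2, -60, 60))
    expect_gte(ciede2000(a, b), 0)
    expect_equal(ciede2000(a, b), ciede2000(b, a), tolerance = 1e-12)
    expect_identical(ciede2000(a, a), 0)
  }
})

test_that("xyz_rmse matches hand arithmetic and is permutation consistent", {
  a <- matrix(c(10, 20, 30), 1, 3)
  expect_equal(xyz_rmse(a, a)$per_patch, 0)
  b <- a + matrix(c(3, 0, 0), 1, 3)
  expect_equal(xyz_rmse(a, b)$mean, sqrt(3))
  set.seed(11)
  x <- matrix(runif(30), 10, 3); y <- matrix(runif(30), 10, 3)
  p <- sample(10)
  expect_equal(xyz_rmse(x, y)$mean, xyz_rmse(x[p, ], y[p, ])$mean)
  expect_error(xyz_rmse(x, y[1:5, ]), "aligned")
})
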