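test_that("cone dose model has flat top, half dose at the edge, and normal-quantile penumbra levels", {
  # D(r) = peak * pnorm((R - r)/sigma): direct closed-form checks
  expect_equal(cone_radial_dose(0, 10, 1, 0.5), 1, tolerance = 1e-6)
  expect_equal(cone_radial_dose(5, 10, 1, 0.5), 0.5)
  q <- qnorm(0.8)
  expect_equal(cone_radial_dose(5 - q * 0.5, 10, 1, 0.5), 0.8,
               tolerance = 1e-12)
  expect_equal(cone_radial_dose(5 + q * 0.5, 10, 1, 0.5), 0.2,
               tolerance = 1e-12)

  fld <- cone_dose_field(10, 1, 0.5, grid = field_grid(0.05, 10))
  i0 <- which.min(abs(fld$x))
  expect_equal(fld$values[i0, i0], 1, tolerance = 1e-3)
  expect_true(all(fld$values >= 0))
})

test_that("cone field rejects a grid that cannot hold its footprint", {
  expect_error(cone_dose_field(15, grid = field_grid(0.1, 5)), "footprint")
})

test_that("square fields respect the 4-fold symmetry and keep the interior at peak dose", {
  g <- field_grid(0.05, 9)
  f0 <- square_dose_field(10, angle = 0, grid = g)
  f90 <- square_dose_field(10, angle = 90, grid = g)
  expect_equal(f0$values, f90$values, tolerance = 1e-9)
  i0 <- which.min(abs(g$x))
  off <- which.min(abs(g$x - 3))
  expect_equal(f0$values[i0, i0], 1)
  expect_equal(f0$values[off, off], 1)
})

test_that("effective fiber comb across staggered layers samples at half the layer pitch", {
  fx <- fiber_positions(detector_geometry())
  d <- diff(fx)
  expect_equal(max(abs(d - 0.1375)), 0, tolerance = 1e-9)
  expect_true(0 %in% round(fx, 9))
})

test_that("flat-disk projection matches the analytic chord formula", {
  # near-sharp disk, fine grid: per-fiber signal = 2 D sqrt(R^2 - x^2)
  Rd <- 10
  fld <- cone_dose_field(2 * Rd, 1, 1e-6, grid = field_grid(0.02, 13))
  sig <- project_field(fld)
  chord <- ifelse(abs(sig$fiber_x) < Rd,
                  2 * sqrt(pmax(Rd^2 - sig$fiber_x^2, 0)), 0)
  sel <- abs(sig$fiber_x) < Rd - 2 * 0.02
  expect_lt(max(abs(sig$signal - chord)[sel]) / (2 * Rd), 0.005)
})

test_that("projection of a radial Gaussian is a Gaussian of the same width", {
  s <- 3
  g <- field_grid(0.05, 15)
  r2 <- outer(g$x^2, g$z^2, "+")
  fld <- dose_field(exp(-r2 / (2 * s^2)), g)
  sig <- project_field(fld)
  prof <- make_profile(sig$fiber_x, sig$signal)
  expect_equal(fwhm(prof), 2 * sqrt(2 * log(2)) * s, tolerance = 0.1375 /
                 (2 * sqrt(2 * log(2)) * s))
})

test_that("projection of a sharp 45-degree square is triangular", {
  side <- 8
  g <- field_grid(0.02, 9)
  fld <- square_dose_field(side, angle = 45, grid = g)
  sig <- project_field(fld)
  a <- side / sqrt(2)
  tri <- 2 * pmax(a - abs(sig$fiber_x), 0)
  expect_lt(max(abs(sig$signal - tri)) / max(tri), 0.015)
})

test_that("projection is linear in the dose field", {
  g <- field_grid(0.05, 10)
  f1 <- cone_dose_field(6, 1, 0.8, grid = g)
  f2 <- cone_dose_field(10, 0.5, 0.5, grid = g)
  comb <- dose_field(2 * f1$values + 3 * f2$values, g)
  s1 <- project_field(f1)$signal
  s2 <- project_field(f2)$signal
  sc <- project_field(comb)$signal
  expect_equal(sc, 2 * s1 + 3 * s2, tolerance = 1e-10)
  # zero field projects to zero
  z <- project_field(dose_field(matrix(0, length(g$x), length(g$z)), g))
  expect_true(all(z$signal == 0))
})

test_that("rendering conserves per-fiber and total intensity and is linear", {
  fx <- fiber_positions(xlim = c(-3, 3))
  sig <- scifidose:::new_fiber_signals(fx, rep(1, length(fx)))
  img <- render_detector_image(sig)
  expect_equal(sum(img$pixels), sum(sig$signal), tolerance = 1e-9)
  # single hot fiber -> one stripe whose column-sum equals the signal
  one <- scifidose:::new_fiber_signals(fx, replace(numeric(length(fx)), 10, 2.5))
  img1 <- render_detector_image(one)
  expect_equal(sum(img1$pixels), 2.5, tolerance = 1e-9)
  lit <- which(colSums(img1$pixels) > 1e-12 * max(img1$pixels))
  expect_lte(length(lit), 7)           # one stripe: the kernel footprint
  expect_equal(lit, seq(min(lit), max(lit)))
  # linearity
  two <- scifidose:::new_fiber_signals(fx, 2 * one$signal)
  expect_equal(render_detector_image(two)$pixels, 2 * img1$pixels,
               tolerance = 1e-12)
})

test_that("equal fiber signals give a flat y-integrated profile over the irradiated comb", {
  fx <- fiber_positions(xlim = c(-3, 3))
  sig <- scifidose:::new_fiber_signals(fx, rep(1, length(fx)))
  prof <- integrate_y(bin_5x5(render_detector_image(sig)))
  core <- prof$p[prof$x > min(fx) + 0.5 & prof$x < max(fx) - 0.5]
  expect_lt((max(core) - min(core)) / max(core), 0.001)
})

test_that("noise injection is seed-deterministic, identity at zero settings, and has the right impulse rate", {
  fx <- fiber_positions(xlim = c(-2, 2))
  sig <- scifidose:::new_fiber_signals(fx, rep(1, length(fx)))
  img <- render_detector_image(sig)
  expect_equal(add_noise(img, noise_model(0, 0, 0, seed = 5))$pixels,
               img$pixels)
  n1 <- add_noise(img, noise_model(0.01, 0.001, 10, seed = 7))
  n2 <- add_noise(img, noise_model(0.01, 0.001, 10, seed = 7))
  expect_identical(n1$pixels, n2$pixels)
  # impulse count ~ Binomial(npix, rate) on a large blank image
  blank <- scifidose:::new_detector_image(matrix(0, 1000, 1000), 0.01)
  hit <- add_noise(blank, noise_model(0, 0.001, 1, seed = 11))
  nhit <- sum(hit$pixels > 0.5)
  expect_gt(nhit, 1000 - 4 * sqrt(1000))
  expect_lt(nhit, 1000 + 4 * sqrt(1000))
  expect_error(noise_model(-1, 0, 0), "gaussian_sigma")
})
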