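test_that("a fixed seed makes noisy images bit-reproducible", {
  fm <- field_model(noise_sd = 0.01, seed = 99L)
  a <- fast_open(fm = fm)
  b <- fast_open(fm = fm)
  expect_identical(a$pixels, b$pixels)
  fm2 <- field_model(noise_sd = 0.01, seed = 100L)
  expect_false(identical(a$pixels, fast_open(fm = fm2)$pixels))
})

test_that("an unperturbed noise-free field is mirror-symmetric in x", {
  img <- fast_open()
  flipped <- img$pixels[, rev(seq_len(ncol(img$pixels)))]
  expect_equal(img$pixels, flipped, tolerance = 1e-12)
  s <- symmetry(img)
  expect_equal(s$axial, 0, tolerance = 1e-10)
  expect_equal(s$transverse, 0, tolerance = 1e-10)
})

test_that("output scaling multiplies the central reading exactly", {
  base <- fast_open()
  up <- fast_open(error_spec(output_scale = 1.02))
  r <- roi_spec("circle", radius = 5)
  expect_equal(roi_mean(up, r) / roi_mean(base, r), 1.02,
               tolerance = 1e-12)
})

test_that("tilt injection produces the closed-form transverse asymmetry", {
  k <- 0.02
  s <- symmetry(fast_open(error_spec(tilt_x = k)))
  expect_equal(s$transverse, tilt_symmetry_true(k), tolerance = 1e-3)
  expect_equal(s$axial, 0, tolerance = 1e-10)
})

test_that("wedge gradient behaves as specified over the angle range", {
  expect_equal(wedge_factor_true(30),
               exp(-0.002 * tan(30 * pi / 180) * 90))
  angles <- seq(10, 60, by = 10)
  wfs <- vapply(angles, wedge_factor_true, numeric(1))
  expect_true(all(diff(wfs) < 0))          # monotone decreasing
  expect_lt(wfs[length(wfs)], wfs[1])
  expect_equal(wedge_factor_true(1e-9), 1, tolerance = 1e-9)
  expect_error(make_wedge_field(field_model(), 0), "0, 60")
  expect_error(make_wedge_field(field_model(), 61), "0, 60")
})

test_that("the four focal-spot fields share a common center when unshifted", {
  set <- make_focal_spot_set(field_model(), shift = c(0, 0),
                             npix = fast_npix, pitch = fast_pitch)
  expect_named(set, c("mlc_0", "mlc_180", "jaw_0", "jaw_180"))
  m <- magnification(beam_geometry())
  centers <- vapply(set, function(img)
    detect_edges(image_profile(img, "x"), magnification = m)$center,
    numeric(1))
  expect_equal(unname(centers), rep(0, 4), tolerance = 1e-6)
})

test_that("a displaced source moves a device's apparent center by s(1 - sid/h)", {
  g <- beam_geometry()
  s <- 0.4
  set <- make_focal_spot_set(field_model(), shift = c(s, 0), geom = g,
                             npix = fast_npix, pitch = fast_pitch)
  m <- magnification(g)
  # ray-trace oracle: panel = s + (e_dev - s) * sid / h for each edge
  oracle_center <- function(h) {
    e <- 90 * h / g$sad
    panel <- s + (c(-e, e) - s) * g$sid / h
    mean(panel)
  }
  for (dev in c("mlc", "jaw")) {
    h <- if (dev == "mlc") g$h_mlc else g$h_jaw_x
    measured <- detect_edges(image_profile(set[[paste0(dev, "_0")]], "x"),
                             magnification = m)$center * m
    expect_lt(abs(measured - oracle_center(h)), 0.01)
    expect_equal(oracle_center(h), s * (1 - g$sid / h), tolerance = 1e-12)
  }
})

test_that("VMAT pair construction reproduces the requested band pattern", {
  fr <- c(0.16, 0.21, 0.29, 0.34)
  pair <- make_vmat_pair("leafspeed", fr, scale = "none",
                         npix = fast_npix, pitch = fast_pitch)
  centers <- pair$dynamic$meta$centers
  r <- vapply(seq_along(centers), function(i) {
    roi <- roi_spec("band", center = c(centers[i], 0), width = 10,
                    height = 160)
    roi_mean(pair$dynamic, roi) / roi_mean(pair$open, roi)
  }, numeric(1))
  expect_equal(r, fr, tolerance = 1e-9)          # bands proportional
  # baseline scaling: equal fractions reproduce the open field
  eq <- make_vmat_pair("drgs", scale = "baseline",
                       npix = fast_npix, pitch = fast_pitch)
  expect_equal(eq$dynamic$pixels[, 150:250], eq$open$pixels[, 150:250],
               tolerance = 1e-12)
  expect_error(make_vmat_pair("drgs", fractions = c(0.5, 0.5)),
               "one fraction per band")
  expect_error(make_vmat_pair("leafspeed", c(0.3, 0.3, 0.3, 0.3)),
               "sum to 1")
})

test_that("fields larger than the panel are rejected", {
  expect_error(make_open_field(field_model(field_size = c(40, 40)),
                               npix = fast_npix, pitch = fast_pitch),
               "exceeds the panel")
})
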