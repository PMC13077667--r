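geom_fix <- beam_geometry()

test_that("wedge factor is the wedged/open central band ratio", {
  open_ <- fast_open()
  expect_equal(wedge_factor(open_, open_)$wf, 1, tolerance = 1e-12)
  halved <- epid_image(open_$pixels / 2, open_$pixel_pitch, open_$sid)
  expect_equal(wedge_factor(halved, open_)$wf, 0.5, tolerance = 1e-12)
  wedged <- make_wedge_field(field_model(), 30, geom = geom_fix,
                             npix = fast_npix, pitch = fast_pitch)
  wf <- wedge_factor(wedged, open_, geom_fix, wedge_angle_deg = 30)
  expect_equal(wf$wf, wedge_factor_true(30), tolerance = 1e-5)
  expect_gt(wf$wf, 0)
  expect_lte(wf$wf, 1.05)
  # geometry mismatch is refused
  other <- epid_image(open_$pixels, open_$pixel_pitch * 2, open_$sid)
  expect_error(wedge_factor(other, open_), "same geometry")
})

test_that("wedge factors from the simulator fall with nominal angle", {
  open_ <- fast_open()
  wfs <- vapply(c(10, 35, 60), function(a) {
    wedge_factor(make_wedge_field(field_model(), a, npix = fast_npix,
                                  pitch = fast_pitch),
                 open_, geom_fix)$wf
  }, numeric(1))
  expect_true(all(diff(wfs) < 0))
  expect_equal(wfs, wedge_factor_true(c(10, 35, 60)), tolerance = 1e-5)
})

test_that("central axis dose tracks injected output changes", {
  img <- fast_open()
  base <- central_axis_dose(img, geom = geom_fix)
  expect_gt(base$cu_mean, 0)
  expect_equal(central_axis_dose(img, base,
                                 geom = geom_fix)$percent_change_from_baseline,
               0, tolerance = 1e-12)
  # 54 MU delivered against a 50 MU baseline: +8.00%
  up <- fast_open(error_spec(output_scale = 54 / 50))
  expect_equal(central_axis_dose(up, base,
                                 geom = geom_fix)$percent_change_from_baseline,
               8, tolerance = 1e-9)
  flat <- epid_image(matrix(0.62, 64, 64), 1, sid = 1500)
  expect_equal(central_axis_dose(flat)$cu_mean, 0.62, tolerance = 1e-12)
})

test_that("symmetry applies the cardinal-ROI formulas directly", {
  # top half 1.02 CU, bottom half 1.00 CU: axial exactly +2%
  px <- matrix(1.00, 240, 240)
  px[1:120, ] <- 1.02
  img <- epid_image(px, 1, sid = 1500)
  s <- symmetry(img)
  expect_equal(s$axial, 2, tolerance = 1e-9)
  expect_equal(s$transverse, 0, tolerance = 1e-12)
  expect_equal(unname(s$roi_means["top"]), 1.02, tolerance = 1e-12)
  # invariant: the reported numbers satisfy the defining equations
  expect_equal(s$axial,
               100 * (s$roi_means[["top"]] - s$roi_means[["bottom"]]) /
                 s$roi_means[["bottom"]])
})

test_that("flipping the image in y mirrors the axial ratio", {
  img <- fast_open(error_spec(tilt_y = 0.02))
  s <- symmetry(img)
  flipped <- epid_image(img$pixels[rev(seq_len(nrow(img$pixels))), ],
                        img$pixel_pitch, img$sid)
  sf <- symmetry(flipped)
  t <- s$roi_means[["top"]]
  b <- s$roi_means[["bottom"]]
  expect_equal(sf$axial, 100 * (b - t) / t, tolerance = 1e-9)
  expect_lt(sf$axial * s$axial, 0)
})

test_that("injected tilts are recovered linearly across the 10% range", {
  tilts <- tilt_for_symmetry(seq(0, 10, length.out = 6))
  injected <- tilt_symmetry_true(tilts)
  measured <- vapply(tilts, function(k)
    symmetry(fast_open(error_spec(tilt_x = k)))$transverse, numeric(1))
  fit <- sensitivity_fit(injected, measured)
  expect_equal(fit$slope, 1, tolerance = 0.01)
  expect_gt(fit$r, 0.9999)
})

test_that("two-field focal spot formula and its antisymmetry", {
  expect_equal(focal_spot_twofield(0.2, 0.2), 0)
  expect_equal(focal_spot_twofield(0.1, 0.3), 0.1)
  expect_equal(focal_spot_twofield(0.3, 0.1), -0.1)
  expect_equal(focal_spot_twofield(c(0.1, -0.4), c(0.3, 0.2)),
               c(0.1, 0.3))
  expect_equal(focal_spot_twofield(0.3, 0.1),
               -focal_spot_twofield(0.1, 0.3))
})

test_that("four-field analysis recovers injected focal shifts", {
  set0 <- make_focal_spot_set(field_model(), shift = c(0, 0),
                              npix = fast_npix, pitch = fast_pitch)
  fs0 <- focal_spot_epid(set0, geom_fix)
  expect_equal(c(fs0$sx, fs0$sy), c(0, 0), tolerance = 1e-6)

  set1 <- make_focal_spot_set(field_model(), shift = c(0.4, -0.2),
                              npix = fast_npix, pitch = fast_pitch)
  fs1 <- focal_spot_epid(set1, geom_fix)
  expect_lt(abs(fs1$sx - 0.4), 0.01)
  expect_lt(abs(fs1$sy + 0.2), 0.01)
})

test_that("opposing-collimator averaging cancels device miscentering", {
  set <- make_focal_spot_set(field_model(), shift = c(0, 0),
                             miscenter = c(mlc = 1.2, jaw = 0.7),
                             npix = fast_npix, pitch = fast_pitch)
  fs <- focal_spot_epid(set, geom_fix)
  expect_equal(c(fs$sx, fs$sy), c(0, 0), tolerance = 1e-3)
})

test_that("degenerate focal-spot geometry is refused", {
  g_bad <- beam_geometry(h_jaw_x = 509, h_jaw_y = 509)
  set <- make_focal_spot_set(field_model(), shift = c(0.1, 0),
                             geom = g_bad, npix = fast_npix,
                             pitch = fast_pitch)
  expect_error(focal_spot_epid(set, g_bad), "unsolvable")
  expect_error(focal_spot_epid(set[1:3], g_bad), "length")
})

test_that("VMAT band metrics follow the Rcorr/Diff arithmetic", {
  fr <- c(0.16, 0.21, 0.29, 0.34)
  pair <- make_vmat_pair("leafspeed", fr, scale = "none",
                         npix = fast_npix, pitch = fast_pitch)
  v <- vmat_analysis(pair$dynamic, pair$open, "leafspeed")
  expect_equal(v$rcorr, 100 * fr, tolerance = 1e-6)
  expect_equal(v$diff, c(-9, -4, 4, 9), tolerance = 1e-6)
  expect_equal(sum(v$diff), 0, tolerance = 1e-9)
  expect_false(any(v$passed))  # all bands outside the 2% tolerance

  eq <- make_vmat_pair("drgs", npix = fast_npix, pitch = fast_pitch)
  veq <- vmat_analysis(eq$dynamic, eq$open, "drgs")
  expect_equal(veq$diff, rep(0, 7), tolerance = 1e-9)
  expect_true(all(veq$passed))
})

test_that("the modified DRGS fractions keep Diff summing to zero", {
  fr <- c(0.08, 0.14, 0.15, 0.15, 0.16, 0.16, 0.16)
  pair <- make_vmat_pair("drgs", fr, scale = "baseline",
                         npix = fast_npix, pitch = fast_pitch)
  v <- vmat_analysis(pair$dynamic, pair$open, "drgs")
  expect_equal(v$rcorr, 700 * fr, tolerance = 1e-6)
  expect_equal(sum(v$diff), 0, tolerance = 1e-9)
})

test_that("band pass/fail flips exactly at the tolerance", {
  fr <- c(0.16, 0.21, 0.29, 0.34)
  pair <- make_vmat_pair("leafspeed", fr, scale = "none",
                         npix = fast_npix, pitch = fast_pitch)
  v <- vmat_analysis(pair$dynamic, pair$open, "leafspeed")
  d <- max(abs(v$diff))
  at <- vmat_analysis(pair$dynamic, pair$open, "leafspeed", tolerance = d)
  expect_true(all(at$passed))
  below <- vmat_analysis(pair$dynamic, pair$open, "leafspeed",
                         tolerance = d * (1 - 1e-9))
  expect_false(all(below$passed))
})

test_that("ratio metrics are invariant to a global image rescaling", {
  img <- fast_open(error_spec(tilt_x = 0.015))
  scaled <- epid_image(2.5 * img$pixels, img$pixel_pitch, img$sid)
  expect_equal(symmetry(scaled)$transverse, symmetry(img)$transverse,
               tolerance = 1e-10)
  fr <- c(0.3, 0.3, 0.2, 0.2)
  pair <- make_vmat_pair("leafspeed", fr, npix = fast_npix,
                         pitch = fast_pitch)
  dyn2 <- epid_image(2.5 * pair$dynamic$pixels, fast_pitch,
                     pair$dynamic$sid, meta = pair$dynamic$meta)
  open2 <- epid_image(2.5 * pair$open$pixels, fast_pitch, pair$open$sid)
  expect_equal(vmat_analysis(dyn2, open2, "leafspeed")$rcorr,
               vmat_analysis(pair$dynamic, pair$open, "leafspeed")$rcorr,
               tolerance = 1e-10)
})
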