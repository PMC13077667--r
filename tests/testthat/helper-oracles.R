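# Shared fixtures and independent oracles.

# Fast simulation raster used throughout the suite (38.4 cm panel at 1 mm
# pitch keeps every projected field and band on the panel).
fast_npix <- 384L
fast_pitch <- 1

fast_open <- function(err = error_spec(), fm = field_model(),
                      geom = beam_geometry(), ...) {
  make_open_field(fm, err, geom, npix = fast_npix, pitch = fast_pitch, ...)
}

# Monte-Carlo area-integration oracle for roi_mean: stratified jittered
# sampling of the projected ROI, looking up the piecewise-constant pixel
# raster at each point.  Independent of the supersampling path under test.
mc_roi_mean <- function(img, roi, geom = NULL, n_side = 1000) {
  if (is.null(geom)) geom <- beam_geometry(sid = img$sid)
  m <- magnification(geom)
  cx <- roi$center[1] * m
  cy <- roi$center[2] * m
  if (roi$shape == "circle") {
    hx <- hy <- roi$radius * m
  } else {
    hx <- roi$width * m / 2
    hy <- roi$height * m / 2
  }
  g <- (seq_len(n_side) - 1) / n_side
  px <- rep(g, times = n_side) + stats::runif(n_side^2) / n_side
  py <- rep(g, each = n_side) + stats::runif(n_side^2) / n_side
  x <- cx - hx + 2 * hx * px
  y <- cy - hy + 2 * hy * py
  if (roi$shape == "circle") {
    keep <- (x - cx)^2 + (y - cy)^2 <= (roi$radius * m)^2
    x <- x[keep]; y <- y[keep]
  }
  col <- round(img$origin[2] + x / img$pixel_pitch)
  row <- round(img$origin[1] - y / img$pixel_pitch)
  mean(img$pixels[cbind(row, col)])
}

# Closed-form transverse symmetry produced by a linear fluence tilt k
# (fraction per 100 mm) sampled at +/- `off` mm: the even radial profile
# cancels between the two ROIs.
tilt_symmetry_true <- function(k, off = 75) {
  p <- k * off / 100
  100 * (2 * p) / (1 - p)
}

# Inverse: tilt producing a requested symmetry percentage.
tilt_for_symmetry <- function(sym, off = 75) {
  p <- sym / (200 + sym)
  p * 100 / off
}

# simple trapezoid profile for edge-detection tests
trapezoid_profile <- function(pos, center = 0, half_width = 90,
                              ramp = 10, plateau = 1) {
  lo <- center - half_width
  hi <- center + half_width
  v <- pmin(1, pmax(0, (pos - (lo - ramp / 2)) / ramp)) *
    pmin(1, pmax(0, ((hi + ramp / 2) - pos) / ramp))
  plateau * v
}
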