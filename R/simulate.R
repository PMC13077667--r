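#' Beam / field model for the synthetic portal-image generator
#'
#' Describes the ideal delivered field that the simulator renders onto the
#' panel: size, flattened or flattening-filter-free (FFF) cross-profile
#' shape, plateau level, penumbra width and pixel noise.  All error
#' injection (output change, asymmetry tilt, focal-spot displacement, wedge,
#' per-segment MU fractions) lives in [error_spec()], so a `field_model` is
#' the machine's baseline state.
#'
#' @param field_size `(x, y)` field size in cm at the isocenter plane.
#' @param mode `"flattened"` (shallow off-axis horns) or `"fff"` (central
#'   peak falling off with off-axis distance).
#' @param plateau_cu Central-axis CU of the baseline field.
#' @param horn_coeff Quadratic off-axis coefficient: the profile is
#'   `1 + horn_coeff * (r / r_field)^2` when flattened and
#'   `1 - horn_coeff * (r / r_field)^2` for FFF, with `r_field` the mean
#'   field half-size.
#' @param penumbra_sigma Penumbra width in mm at the panel plane, defined as
#'   the 25%--75% distance of the logistic edge (the edge crosses 50% of the
#'   local plateau exactly at the projected collimator edge).
#' @param noise_sd Additive Gaussian pixel noise SD in CU (0 = noise-free).
#' @param seed Integer seed; with a fixed seed the generated images are
#'   bit-reproducible.
#' @return An object of class `field_model`.
#' @export
field_model <- function(field_size = c(18, 18),
                        mode = c("flattened", "fff"),
                        plateau_cu = 1,
                        horn_coeff = NULL,
                        penumbra_sigma = 3,
                        noise_sd = 0,
                        seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(horn_coeff)) horn_coeff <- if (mode == "flattened") 0.03 else 0.10
  field_size <- rep_len(as.numeric(field_size), 2)
  stopifnot(all(field_size > 0), plateau_cu > 0, penumbra_sigma > 0,
            noise_sd >= 0, horn_coeff >= 0)
  structure(list(field_size = field_size, mode = mode,
                 plateau_cu = plateau_cu, horn_coeff = horn_coeff,
                 penumbra_sigma = penumbra_sigma, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "field_model")
}

#' Error injection for the synthetic generator
#'
#' Each field mirrors one of the deliberate machine or plan perturbations
#' the analyses are meant to detect.
#'
#' @param output_scale Multiplicative output factor (1 = baseline; e.g.
#'   delivering 54 MU instead of a 50 MU baseline is `54 / 50`).
#' @param tilt_x,tilt_y Fractional linear fluence asymmetry per 100 mm
#'   off-axis (isocenter plane): the fluence is multiplied by
#'   `1 + tilt_x * x / 100 + tilt_y * y / 100`.
#' @param focal_shift `(sx, sy)` lateral displacement of the focal spot in
#'   mm at the target plane.
#' @param wedge_angle Nominal enhanced-dynamic-wedge angle in degrees
#'   (0 = open field); used by [make_wedge_field()].
#' @param segment_fractions Per-segment MU fractions for the VMAT band
#'   tests; must sum to 1.
#' @return An object of class `error_spec`.
#' @export
error_spec <- function(output_scale = 1, tilt_x = 0, tilt_y = 0,
                       focal_shift = c(0, 0), wedge_angle = 0,
                       segment_fractions = NULL) {
  stopifnot(is.numeric(output_scale), length(output_scale) == 1,
            output_scale > 0, is.finite(tilt_x), is.finite(tilt_y))
  focal_shift <- rep_len(as.numeric(focal_shift), 2)
  if (!is.null(segment_fractions)) {
    if (any(segment_fractions <= 0) ||
        abs(sum(segment_fractions) - 1) > 1e-12)
      stop("segment_fractions must be positive and sum to 1", call. = FALSE)
  }
  structure(list(output_scale = output_scale, tilt_x = tilt_x,
                 tilt_y = tilt_y, focal_shift = focal_shift,
                 wedge_angle = wedge_angle,
                 segment_fractions = segment_fractions),
            class = "error_spec")
}

# Run code under a given RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# logistic scale so that penumbra_sigma is the 25-75% edge width
logistic_scale <- function(penumbra_sigma) penumbra_sigma / (2 * log(3))

# Projected panel position of a collimating-device edge.  The edge sits at
# device-plane position (e_iso + c_iso) * h / sad (so that a centered source
# projects it to e_iso at the isocenter plane); a source displaced by s
# projects it along the ray from (s, 0) through the edge:
#   panel = s + (edge_dev - s) * sid / h
project_edge <- function(e_iso, c_iso, h, s, geom) {
  e_dev <- (e_iso + c_iso) * h / geom$sad
  s + (e_dev - s) * geom$sid / h
}

# Shared raster builder.  h_x / h_y: device heights collimating each axis;
# c_x / c_y: device miscentering (isocenter-plane mm) per axis.
build_field_image <- function(fm, err, geom, npix, pitch,
                              h_x, h_y, c_x = 0, c_y = 0,
                              wedge = NULL, seed_offset = 0L,
                              meta = list()) {
  m <- magnification(geom)
  xs <- (seq_len(npix) - (npix + 1) / 2) * pitch
  ys <- rev(xs)                      # row 1 at +y
  half_x <- fm$field_size[1] * 10 / 2
  half_y <- fm$field_size[2] * 10 / 2
  sx <- err$focal_shift[1]
  sy <- err$focal_shift[2]
  eL_x <- project_edge(-half_x, c_x, h_x, sx, geom)
  eR_x <- project_edge( half_x, c_x, h_x, sx, geom)
  eL_y <- project_edge(-half_y, c_y, h_y, sy, geom)
  eR_y <- project_edge( half_y, c_y, h_y, sy, geom)
  k <- logistic_scale(fm$penumbra_sigma)
  margin <- 6 * k
  if (max(abs(c(eL_x, eR_x, eL_y, eR_y))) + margin > max(xs))
    stop("field exceeds the panel", call. = FALSE)

  Sx <- stats::plogis((xs - eL_x) / k) * stats::plogis((eR_x - xs) / k)
  Sy <- stats::plogis((ys - eL_y) / k) * stats::plogis((eR_y - ys) / k)
  xi <- xs / m
  yi <- ys / m
  rf <- mean(c(half_x, half_y))
  R2 <- outer(yi^2, xi^2, `+`) / rf^2
  P <- if (fm$mode == "flattened") 1 + fm$horn_coeff * R2
       else 1 - fm$horn_coeff * R2
  Tilt <- 1 + outer(err$tilt_y * yi, err$tilt_x * xi, `+`) / 100
  px <- err$output_scale * fm$plateau_cu * P * Tilt * outer(Sy, Sx)
  if (!is.null(wedge)) {
    g <- exp(-wedge$gamma * tan(wedge$angle_deg * pi / 180) *
               (yi - wedge$y_heel))
    px <- px * matrix(g, nrow = npix, ncol = npix)
  }
  if (fm$noise_sd > 0) {
    px <- px + with_seed(fm$seed + seed_offset,
                         matrix(stats::rnorm(npix * npix, 0, fm$noise_sd),
                                npix, npix))
  }
  px[px < 0] <- 0
  epid_image(px, pixel_pitch = pitch, sid = geom$sid, meta = meta)
}

#' Simulate an open-field portal image with injected errors
#'
#' Renders the divergent-beam projection of a rectangular field onto the
#' panel: a flattened or FFF cross-profile, logistic penumbra at the
#' projected collimator edges (traced from the — possibly displaced — focal
#' spot through the collimating device's plane), an optional linear
#' asymmetry tilt, an output scale factor and seeded additive Gaussian
#' noise.
#'
#' @param fm A [field_model()].
#' @param err An [error_spec()].
#' @param geom A [beam_geometry()].
#' @param npix Image size in pixels (square).
#' @param pitch Pixel pitch in mm at the panel.
#' @param device Which collimating device defines the field edges
#'   (determines the projection heights used for the focal-shift geometry).
#' @return An [epid_image()].
#' @examples
#' img <- make_open_field(field_model(), npix = 256, pitch = 1.5)
#' @export
make_open_field <- function(fm, err = error_spec(), geom = beam_geometry(),
                            npix = 768, pitch = 0.5,
                            device = c("jaw", "mlc")) {
  stopifnot(inherits(fm, "field_model"), inherits(err, "error_spec"))
  device <- match.arg(device)
  h_x <- if (device == "mlc") geom$h_mlc else geom$h_jaw_x
  h_y <- if (device == "mlc") geom$h_mlc else geom$h_jaw_y
  build_field_image(fm, err, geom, npix, pitch, h_x, h_y,
                    meta = list(kind = "open", device = device))
}

#' Simulate an enhanced-dynamic-wedge portal image
#'
#' Multiplies the open-field fluence by an exponential wedge gradient along
#' the inplane (y) axis, `G(y) = exp(-gamma * tan(theta) * (y - y_heel))`,
#' normalised to 1 at the heel.  The ground-truth wedge factor is the
#' gradient evaluated on the central axis, [wedge_factor_true()].
#'
#' @inheritParams make_open_field
#' @param angle_deg Nominal wedge angle in degrees, in (0, 60].
#' @param gamma Gradient strength per mm per unit `tan(angle)`.
#' @param y_heel Heel position in mm (isocenter plane) where the gradient
#'   equals 1.
#' @return An [epid_image()].
#' @export
make_wedge_field <- function(fm, angle_deg, err = error_spec(),
                             geom = beam_geometry(),
                             gamma = 0.002, y_heel = -90,
                             npix = 768, pitch = 0.5) {
  stopifnot(inherits(fm, "field_model"))
  if (!is.numeric(angle_deg) || angle_deg <= 0 || angle_deg > 60)
    stop("wedge angle must lie in (0, 60] degrees", call. = FALSE)
  build_field_image(fm, err, geom, npix, pitch,
                    h_x = geom$h_jaw_x, h_y = geom$h_jaw_y,
                    wedge = list(angle_deg = angle_deg, gamma = gamma,
                                 y_heel = y_heel),
                    meta = list(kind = "wedge", angle_deg = angle_deg))
}

#' @rdname make_wedge_field
#' @return `wedge_factor_true` returns the ground-truth central-axis wedge
#'   factor of the simulated gradient, `exp(gamma * tan(theta) * y_heel)`.
#' @export
wedge_factor_true <- function(angle_deg, gamma = 0.002, y_heel = -90) {
  exp(-gamma * tan(angle_deg * pi / 180) * (0 - y_heel))
}

#' Simulate the four-field focal-spot acquisition
#'
#' Generates the two opposing-collimator fields collimated by the MLC and
#' the two collimated by the jaws.  Because the MLC and jaws sit at
#' different heights in the treatment head, a lateral focal-spot
#' displacement moves the projected field centers of the two device pairs
#' by different amounts, which [focal_spot_epid()] inverts.  Rotating the
#' collimator by 180 degrees flips any device miscentering in the lab frame
#' (the focal-spot term does not rotate), so averaging the opposing pair
#' cancels miscentering.
#'
#' @inheritParams make_open_field
#' @param shift `(sx, sy)` focal-spot displacement in mm.
#' @param miscenter Device miscentering in mm (isocenter-plane equivalent),
#'   named vector with elements `mlc` and `jaw`; flips sign under the
#'   180-degree collimator rotation.
#' @return Named list of four [epid_image()]s: `mlc_0`, `mlc_180`, `jaw_0`,
#'   `jaw_180`, each tagged in `meta` with its device and orientation.
#' @export
make_focal_spot_set <- function(fm, shift = c(0, 0), geom = beam_geometry(),
                                miscenter = c(mlc = 0, jaw = 0),
                                npix = 768, pitch = 0.5) {
  stopifnot(inherits(fm, "field_model"))
  shift <- rep_len(as.numeric(shift), 2)
  mis <- c(mlc = 0, jaw = 0)
  mis[names(miscenter)] <- miscenter
  err <- error_spec(focal_shift = shift)
  out <- list()
  i <- 0L
  for (dev in c("mlc", "jaw")) {
    h_x <- if (dev == "mlc") geom$h_mlc else geom$h_jaw_x
    h_y <- if (dev == "mlc") geom$h_mlc else geom$h_jaw_y
    for (orient in c(0L, 180L)) {
      sgn <- if (orient == 0L) 1 else -1
      i <- i + 1L
      out[[paste(dev, orient, sep = "_")]] <-
        build_field_image(fm, err, geom, npix, pitch, h_x, h_y,
                          c_x = sgn * mis[[dev]], c_y = sgn * mis[[dev]],
                          seed_offset = i,
                          meta = list(kind = "focal", device = dev,
                                      collimator = orient))
    }
  }
  out
}

#' Simulate a VMAT band-test image pair
#'
#' The dose-rate/gantry-speed (DRGS) and MLC leaf-speed tests deliver a
#' dynamic field of adjacent bands plus a uniform open field.  Each band's
#' CU is proportional to its segment's MU fraction; with
#' `scale = "baseline"` the bands are additionally scaled by the segment
#' count so an equal-fraction (baseline) plan reproduces the open field
#' exactly (Rcorr = 100 everywhere), while `scale = "none"` leaves band CU
#' at `fraction * plateau`.
#'
#' @inheritParams make_open_field
#' @param kind `"drgs"` (seven bands) or `"leafspeed"` (four bands).
#' @param fractions Per-segment MU fractions summing to 1; default equal.
#' @param centers Band center x positions in mm at the isocenter plane.
#'   Defaults: leaf speed -45, -15, 15, 45; DRGS -51, -31, ..., 69 (the
#'   published detector positions, with the first position read as -5.1 cm).
#' @param band_width Band width in mm (isocenter plane); default the band
#'   spacing, giving adjacent bands.
#' @param scale `"baseline"` or `"none"` (see Details).
#' @return List with elements `dynamic` and `open`, both [epid_image()]s.
#' @export
make_vmat_pair <- function(kind = c("drgs", "leafspeed"), fractions = NULL,
                           fm = field_model(), geom = beam_geometry(),
                           centers = NULL, band_width = NULL,
                           scale = c("baseline", "none"),
                           npix = 768, pitch = 0.5) {
  kind <- match.arg(kind)
  scale <- match.arg(scale)
  if (is.null(centers))
    centers <- if (kind == "drgs") seq(-51, 69, by = 20)
               else c(-45, -15, 15, 45)
  n <- length(centers)
  if (is.null(band_width))
    band_width <- if (n > 1) min(diff(sort(centers))) else 20
  if (is.null(fractions)) fractions <- rep(1 / n, n)
  if (length(fractions) != n)
    stop("need one fraction per band", call. = FALSE)
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-12)
    stop("fractions must be positive and sum to 1", call. = FALSE)

  base <- field_model(field_size = fm$field_size, mode = fm$mode,
                      plateau_cu = fm$plateau_cu, horn_coeff = fm$horn_coeff,
                      penumbra_sigma = fm$penumbra_sigma, noise_sd = 0,
                      seed = fm$seed)
  open_clean <- make_open_field(base, geom = geom, npix = npix, pitch = pitch)
  m <- magnification(geom)
  xi <- panel_x(open_clean) / m
  mod <- numeric(length(xi))
  amp <- fractions * if (scale == "baseline") n else 1
  for (i in seq_len(n)) {
    inb <- xi >= centers[i] - band_width / 2 & xi < centers[i] + band_width / 2
    mod[inb] <- amp[i]
  }
  dyn_px <- open_clean$pixels * matrix(mod, nrow = npix, ncol = npix,
                                       byrow = TRUE)
  open_px <- open_clean$pixels
  if (fm$noise_sd > 0) {
    dyn_px <- dyn_px + with_seed(fm$seed,
      matrix(stats::rnorm(npix^2, 0, fm$noise_sd), npix, npix))
    open_px <- open_px + with_seed(fm$seed + 1L,
      matrix(stats::rnorm(npix^2, 0, fm$noise_sd), npix, npix))
    dyn_px[dyn_px < 0] <- 0
    open_px[open_px < 0] <- 0
  }
  meta <- list(kind = kind, centers = centers, band_width = band_width,
               fractions = fractions, scale = scale)
  list(dynamic = epid_image(dyn_px, pitch, geom$sid, meta = meta),
       open = epid_image(open_px, pitch, geom$sid,
                         meta = list(kind = "open")))
}
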