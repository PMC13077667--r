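#' Enhanced dynamic wedge factor from a wedged/open image pair
#'
#' The wedge factor (WF) is the ratio of the wedged to the open central
#' reading.  The reading is taken over a narrow central band: 5 mm wide
#' along the wedge-gradient axis so the exponential gradient is sampled at
#' the central axis, and spanning the central 80% of the field along the
#' unwedged axis.  Band dimensions and orientation are configurable.
#'
#' @param wedged,open_ [epid_image()]s of the wedged and open deliveries,
#'   acquired with identical geometry.
#' @param geom Optional [beam_geometry()].
#' @param wedge_angle_deg Nominal wedge angle recorded in the result.
#' @param band_width Band width along the gradient axis, mm (isocenter
#'   plane).
#' @param field_size Field size in cm along the unwedged axis (sets the
#'   band length).
#' @param band_length_frac Fraction of the field spanned by the band along
#'   the unwedged axis.
#' @param gradient_axis Axis of the wedge gradient, `"y"` (default) or
#'   `"x"`.
#' @return Object of class `wedge_factor_result` with elements `wf` and
#'   `wedge_angle_deg`.
#' @export
wedge_factor <- function(wedged, open_, geom = NULL, wedge_angle_deg = NA,
                         band_width = 5, field_size = 18,
                         band_length_frac = 0.8,
                         gradient_axis = c("y", "x")) {
  stopifnot(inherits(wedged, "epid_image"), inherits(open_, "epid_image"))
  gradient_axis <- match.arg(gradient_axis)
  check_same_geometry(wedged, open_)
  len <- field_size * 10 * band_length_frac
  roi <- if (gradient_axis == "y")
    roi_spec("rect", width = len, height = band_width)
  else
    roi_spec("rect", width = band_width, height = len)
  w <- roi_mean(wedged, roi, geom)
  o <- roi_mean(open_, roi, geom)
  if (o <= 0) stop("open-field reading is not positive", call. = FALSE)
  structure(list(wf = w / o, wedge_angle_deg = wedge_angle_deg),
            class = "wedge_factor_result")
}

#' @export
print.wedge_factor_result <- function(x, ...) {
  cat(sprintf("Wedge factor: %.5f (nominal angle %s deg)\n", x$wf,
              format(x$wedge_angle_deg)))
  invisible(x)
}

#' Central axis dose from a portal image
#'
#' Averages the CU within a central circle (default 5 mm radius in the
#' isocenter plane, configurable to match the ion chamber used for
#' comparison) and, when a baseline is supplied, reports the percent change
#' from it.
#'
#' @param img An [epid_image()].
#' @param baseline A previous `central_dose_result`, or a numeric baseline
#'   CU, or `NULL`.
#' @param radius ROI radius in mm (isocenter plane).
#' @param geom Optional [beam_geometry()].
#' @return Object of class `central_dose_result` with `cu_mean` and
#'   `percent_change_from_baseline` (NA without a baseline).
#' @export
central_axis_dose <- function(img, baseline = NULL, radius = 5,
                              geom = NULL) {
  cu <- roi_mean(img, roi_spec("circle", radius = radius), geom)
  if (cu <= 0) stop("central reading is not positive", call. = FALSE)
  pc <- NA_real_
  if (!is.null(baseline)) {
    b <- if (inherits(baseline, "central_dose_result")) baseline$cu_mean
         else as.numeric(baseline)
    if (!is.finite(b) || b <= 0)
      stop("baseline CU must be positive", call. = FALSE)
    pc <- 100 * (cu / b - 1)
  }
  structure(list(cu_mean = cu, percent_change_from_baseline = pc,
                 radius = radius),
            class = "central_dose_result")
}

#' @export
print.central_dose_result <- function(x, ...) {
  cat(sprintf("Central axis dose: %.5f CU (r = %g mm ROI)\n",
              x$cu_mean, x$radius))
  if (is.finite(x$percent_change_from_baseline))
    cat(sprintf("  change from baseline: %+.3f%%\n",
                x$percent_change_from_baseline))
  invisible(x)
}

#' Beam symmetry from five circular regions
#'
#' Samples five circles (default 5 mm diameter): one at the central axis
#' and four at `offset` mm (default 75, about 83.33% of the
#' central-axis-to-edge distance of an 18 x 18 cm field) in the four
#' cardinal directions, and computes
#' `axial = 100 * (top - bottom) / bottom` (inplane / radial, y) and
#' `transverse = 100 * (right - left) / left` (crossplane, x).
#'
#' @param img An [epid_image()].
#' @param field_size Field size in cm (used only when
#'   `scale_offset_with_field` is `TRUE`).
#' @param offset Off-axis distance of the four outer circles, mm
#'   (isocenter plane).
#' @param roi_diameter Circle diameter, mm.
#' @param scale_offset_with_field If `TRUE`, scale `offset` so it keeps the
#'   same fraction (5/6) of the field half-width; off by default.
#' @param geom Optional [beam_geometry()].
#' @return Object of class `symmetry_result` with `axial`, `transverse`
#'   (percent) and the five `roi_means`.
#' @export
symmetry <- function(img, field_size = 18, offset = 75, roi_diameter = 5,
                     scale_offset_with_field = FALSE, geom = NULL) {
  if (scale_offset_with_field) offset <- (5 / 6) * field_size * 10 / 2
  r <- roi_diameter / 2
  sample_at <- function(x, y)
    roi_mean(img, roi_spec("circle", center = c(x, y), radius = r), geom)
  means <- c(center = sample_at(0, 0),
             top = sample_at(0, offset), bottom = sample_at(0, -offset),
             left = sample_at(-offset, 0), right = sample_at(offset, 0))
  structure(list(axial = 100 * (means[["top"]] - means[["bottom"]]) /
                   means[["bottom"]],
                 transverse = 100 * (means[["right"]] - means[["left"]]) /
                   means[["left"]],
                 roi_means = means, offset = offset),
            class = "symmetry_result")
}

#' @export
print.symmetry_result <- function(x, ...) {
  cat(sprintf("Symmetry (ROIs at +/-%g mm): axial %+.4f%%, transverse %+.4f%%\n",
              x$offset, x$axial, x$transverse))
  invisible(x)
}

#' Focal spot from two-field profile offsets
#'
#' Two profiles are acquired at collimator 90 and 270 degrees; the
#' focal-spot position per axis is `-(CA90 - CA270) / 2`, where `CA90` and
#' `CA270` are the profile-center offsets from the central axis.
#'
#' @param ca90,ca270 Profile-center offsets in mm at the two collimator
#'   angles; numeric vectors (e.g. `c(x, y)`), matched element-wise.
#' @return Focal-spot position(s) in mm, same length as the inputs.
#' @examples
#' focal_spot_twofield(0.1, 0.3)  # 0.1
#' @export
focal_spot_twofield <- function(ca90, ca270) {
  stopifnot(is.numeric(ca90), is.numeric(ca270),
            length(ca90) == length(ca270))
  -(ca90 - ca270) / 2
}

#' Focal spot from the four-field EPID method
#'
#' Uses two opposing-collimator fields collimated by the MLC and two by the
#' jaws.  A lateral focal-spot displacement `s` moves the projected field
#' center of a device at height `h` to `s * (1 - sid / h)` on the panel, so
#' devices at different heights separate: per axis,
#' `s = (A_mlc - A_jaw) / (sid * (1 / h_jaw - 1 / h_mlc))`, where `A_D` is
#' the mean projected field center of device `D` over the two opposing
#' collimator orientations (the average cancels device miscentering, which
#' flips sign under the 180-degree rotation).
#'
#' @param images List of four [epid_image()]s tagged in `meta` with
#'   `device` (`"mlc"` / `"jaw"`) and `collimator` orientation, as produced
#'   by [make_focal_spot_set()].
#' @param geom A [beam_geometry()] supplying `sid` and the device heights.
#' @param height_floor Minimum `|1/h_jaw - 1/h_mlc|` (per mm) below which
#'   the geometry cannot separate the devices and an error is raised.
#' @return Object of class `focal_spot_result` with `sx`, `sy` (mm) and
#'   the per-device apparent centers (mm at the panel).
#' @export
focal_spot_epid <- function(images, geom = beam_geometry(),
                            height_floor = 1e-6) {
  stopifnot(is.list(images), length(images) == 4)
  m <- magnification(geom)
  centers <- list(mlc = list(), jaw = list())
  for (img in images) {
    stopifnot(inherits(img, "epid_image"))
    dev <- img$meta$device
    if (is.null(dev) || !dev %in% c("mlc", "jaw"))
      stop("each image must be tagged with meta$device ('mlc' or 'jaw')",
           call. = FALSE)
    cx <- detect_edges(image_profile(img, "x", geom = geom),
                       magnification = m)$center
    cy <- detect_edges(image_profile(img, "y", geom = geom),
                       magnification = m)$center
    centers[[dev]] <- c(centers[[dev]], list(c(x = cx, y = cy) * m))
  }
  if (length(centers$mlc) != 2 || length(centers$jaw) != 2)
    stop("need two MLC-collimated and two jaw-collimated images",
         call. = FALSE)
  A <- lapply(centers, function(z) (z[[1]] + z[[2]]) / 2)  # panel mm
  solve_axis <- function(axis, h_jaw) {
    denom <- geom$sid * (1 / h_jaw - 1 / geom$h_mlc)
    if (abs(1 / h_jaw - 1 / geom$h_mlc) < height_floor)
      stop("jaw and MLC heights too close to separate; geometry unsolvable",
           call. = FALSE)
    (A$mlc[[axis]] - A$jaw[[axis]]) / denom
  }
  structure(list(sx = solve_axis("x", geom$h_jaw_x),
                 sy = solve_axis("y", geom$h_jaw_y),
                 apparent_centers = A),
            class = "focal_spot_result")
}

#' @export
print.focal_spot_result <- function(x, ...) {
  cat(sprintf("Focal spot displacement: sx %+.4f mm, sy %+.4f mm\n",
              x$sx, x$sy))
  cat(sprintf("  apparent centers (panel mm): MLC (%+.3f, %+.3f), jaws (%+.3f, %+.3f)\n",
              x$apparent_centers$mlc[["x"]], x$apparent_centers$mlc[["y"]],
              x$apparent_centers$jaw[["x"]], x$apparent_centers$jaw[["y"]]))
  invisible(x)
}

#' VMAT dose-rate/gantry-speed and MLC leaf-speed band analysis
#'
#' Normalizes the dynamic band delivery to the open field: for each band,
#' `Rcorr = 100 * R_LS / R_open` where `R_LS` and `R_open` are the mean CU
#' of the band ROI in the dynamic and open image, and
#' `Diff = Rcorr - mean(Rcorr)`.  A band passes when `|Diff|` is within the
#' tolerance (default 2 percentage points).  Band ROIs use fractional pixel
#' weighting and must not extend beyond the field edge.
#'
#' @param dynamic,open_ [epid_image()]s of the dynamic band delivery and
#'   the open field.
#' @param kind `"drgs"` or `"leafspeed"`; sets the default band centers and
#'   ROI size (leaf speed: 1 x 16 cm ROIs at x = -4.5, -1.5, 1.5, 4.5 cm;
#'   DRGS: 0.75 x 17 cm ROIs at x = -5.1, -3.1, ..., 6.9 cm).
#' @param tolerance Pass/fail tolerance on `|Diff|`, percentage points.
#' @param centers Band-center x positions, mm (isocenter plane); defaults
#'   to the centers recorded by the simulator in `dynamic$meta`, else the
#'   test's published positions.
#' @param roi_width,roi_length ROI extent along x and y, mm (isocenter
#'   plane).
#' @param geom Optional [beam_geometry()].
#' @return Object of class `vmat_band_result`: a data frame with one row
#'   per band (`center`, `r_ls`, `r_open`, `rcorr`, `diff`, `passed`) and a
#'   `tolerance` attribute.
#' @export
vmat_analysis <- function(dynamic, open_, kind = c("drgs", "leafspeed"),
                          tolerance = 2, centers = NULL,
                          roi_width = NULL, roi_length = NULL, geom = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(dynamic, "epid_image"), inherits(open_, "epid_image"))
  check_same_geometry(dynamic, open_)
  if (is.null(centers)) {
    centers <- dynamic$meta$centers
    if (is.null(centers))
      centers <- if (kind == "drgs") seq(-51, 69, by = 20)
                 else c(-45, -15, 15, 45)
  }
  if (is.null(roi_width)) roi_width <- if (kind == "drgs") 7.5 else 10
  if (is.null(roi_length)) roi_length <- if (kind == "drgs") 170 else 160
  rows <- lapply(centers, function(cx) {
    roi <- roi_spec("band", center = c(cx, 0),
                    width = roi_width, height = roi_length)
    r_ls <- roi_mean(dynamic, roi, geom)
    r_open <- roi_mean(open_, roi, geom)
    if (r_open <= 0)
      stop("open-field band mean is not positive", call. = FALSE)
    data.frame(center = cx, r_ls = r_ls, r_open = r_open,
               rcorr = 100 * r_ls / r_open)
  })
  out <- do.call(rbind, rows)
  out$diff <- out$rcorr - mean(out$rcorr)
  out$passed <- abs(out$diff) <= tolerance
  structure(out, class = c("vmat_band_result", "data.frame"),
            kind = kind, tolerance = tolerance)
}

#' @export
print.vmat_band_result <- function(x, ...) {
  cat(sprintf("VMAT %s band analysis (tolerance %g%%):\n",
              attr(x, "kind"), attr(x, "tolerance")))
  df <- as.data.frame(x)
  df$center <- sprintf("%+g", df$center)
  print(format(df, digits = 5), row.names = FALSE)
  cat(if (all(x$passed)) "All bands within tolerance.\n"
      else sprintf("%d band(s) OUT of tolerance.\n", sum(!x$passed)))
  invisible(x)
}

check_same_geometry <- function(a, b) {
  if (!identical(dim(a$pixels), dim(b$pixels)) ||
      abs(a$pixel_pitch - b$pixel_pitch) > 1e-9 ||
      abs(a$sid - b$sid) > 1e-6 ||
      max(abs(a$origin - b$origin)) > 1e-9)
    stop("images were not acquired with the same geometry", call. = FALSE)
  invisible(TRUE)
}
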