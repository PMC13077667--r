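#' Calibrated-unit EPID image
#'
#' The basic raster container shared by every analysis: a 2-D grid of
#' calibrated units (CU, the panel's dimensionless dose-response unit) plus
#' the panel geometry needed to interpret it.
#'
#' Coordinate convention (declared once, consumed everywhere): continuous
#' panel coordinates in mm with the origin at the projection of the beam
#' central axis / collimator rotation axis; `x` is crossplane (transverse),
#' increasing with column index; `y` is inplane (radial), increasing with
#' *decreasing* row index (row 1 sits at +y, toward the gantry).  Distances
#' declared in the isocenter plane are magnified by `sid / sad` at the panel.
#'
#' @param pixels Numeric matrix of CU values; all finite and non-negative.
#' @param pixel_pitch Pixel pitch in mm at the panel plane.
#' @param sid Source-to-imager distance in mm.
#' @param origin Continuous `(row, col)` position of the beam central axis,
#'   in pixel units (1-based).  Defaults to the image center.
#' @param meta Optional named list of metadata (e.g. collimating device and
#'   collimator orientation tags for focal-spot field sets).
#' @return An object of class `epid_image`.
#' @export
epid_image <- function(pixels, pixel_pitch, sid = 1500, origin = NULL,
                       meta = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("pixels must be finite and non-negative", call. = FALSE)
  if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1 || pixel_pitch <= 0)
    stop("pixel_pitch must be a positive scalar (mm)", call. = FALSE)
  if (!is.numeric(sid) || length(sid) != 1 || sid <= 0)
    stop("sid must be a positive scalar (mm)", call. = FALSE)
  if (is.null(origin)) origin <- (dim(pixels) + 1) / 2
  origin <- as.numeric(origin)
  if (length(origin) != 2 ||
      origin[1] < 1 || origin[1] > nrow(pixels) ||
      origin[2] < 1 || origin[2] > ncol(pixels))
    stop("origin (row, col) must lie inside the image bounds", call. = FALSE)
  structure(list(pixels = pixels, pixel_pitch = pixel_pitch, sid = sid,
                 origin = origin, meta = meta),
            class = "epid_image")
}

#' @export
print.epid_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<epid_image> %d x %d px, pitch %.4g mm (%.3g x %.3g cm), SID %g mm\n",
    d[1], d[2], x$pixel_pitch,
    d[1] * x$pixel_pitch / 10, d[2] * x$pixel_pitch / 10, x$sid))
  cat(sprintf("  origin (row, col): (%.2f, %.2f); CU range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], min(x$pixels), max(x$pixels)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.epid_image <- function(x, ...) {
  xc <- panel_x(x)
  yc <- panel_y(x)
  # image() wants ascending axes; flip rows so +y plots upward
  graphics::image(x = xc, y = rev(yc), z = t(x$pixels[nrow(x$pixels):1, ]),
                  xlab = "x (crossplane, mm at panel)",
                  ylab = "y (inplane, mm at panel)",
                  col = grDevices::gray.colors(128, 0, 1), asp = 1, ...)
  invisible(x)
}

# Panel-plane x coordinate (mm) of every column / y coordinate of every row.
panel_x <- function(img) (seq_len(ncol(img$pixels)) - img$origin[2]) * img$pixel_pitch
panel_y <- function(img) (img$origin[1] - seq_len(nrow(img$pixels))) * img$pixel_pitch

# Default geometry consistent with an image when the caller supplies none.
default_geom <- function(img, geom = NULL) {
  if (is.null(geom)) return(beam_geometry(sid = img$sid))
  stopifnot(inherits(geom, "beam_geometry"))
  if (abs(geom$sid - img$sid) > 1e-6)
    warning("beam_geometry sid differs from image sid; using the geometry's")
  geom
}

#' Extract a 1-D beam profile through the central axis
#'
#' Samples the image row (for an `x` profile) or column (for a `y` profile)
#' nearest to the requested perpendicular offset from the beam axis.
#'
#' @param img An [epid_image()].
#' @param axis `"x"` for a crossplane profile, `"y"` for inplane.
#' @param offset_iso Perpendicular offset of the profile line from the beam
#'   axis, mm in the isocenter plane.
#' @param geom Optional [beam_geometry()]; defaults to one matching the
#'   image's SID.
#' @return A data frame with `pos` (mm at the panel, along the profile) and
#'   `cu`.
#' @export
image_profile <- function(img, axis = c("x", "y"), offset_iso = 0,
                          geom = NULL) {
  stopifnot(inherits(img, "epid_image"))
  axis <- match.arg(axis)
  geom <- default_geom(img, geom)
  off_panel <- offset_iso * magnification(geom)
  if (axis == "x") {
    r <- round(img$origin[1] - off_panel / img$pixel_pitch)
    if (r < 1 || r > nrow(img$pixels))
      stop("profile offset outside the image", call. = FALSE)
    data.frame(pos = panel_x(img), cu = img$pixels[r, ])
  } else {
    c_ <- round(img$origin[2] + off_panel / img$pixel_pitch)
    if (c_ < 1 || c_ > ncol(img$pixels))
      stop("profile offset outside the image", call. = FALSE)
    data.frame(pos = panel_y(img), cu = img$pixels[, c_])
  }
}

#' Read and write the plain raster interchange format
#'
#' A tab-separated grid of CU values plus a JSON sidecar
#' (`{pixel_pitch_mm, sid_mm, origin_rc}`) with the same base name.  This is
#' the package's on-disk image format.
#'
#' @param img An [epid_image()].
#' @param path Path of the raster file; the sidecar replaces its extension
#'   with `.json`.
#' @return `write_epid_raster` returns `path` invisibly; `read_epid_raster`
#'   returns an [epid_image()].
#' @export
write_epid_raster <- function(img, path) {
  stopifnot(inherits(img, "epid_image"))
  utils::write.table(img$pixels, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  side <- list(pixel_pitch_mm = img$pixel_pitch, sid_mm = img$sid,
               origin_rc = img$origin)
  if (length(img$meta)) side$meta <- img$meta
  jsonlite::write_json(side, sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_epid_raster
#' @export
read_epid_raster <- function(path) {
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  px <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(px) <- NULL
  epid_image(px, pixel_pitch = side$pixel_pitch_mm, sid = side$sid_mm,
             origin = side$origin_rc,
             meta = if (is.null(side$meta)) list() else as.list(side$meta))
}

sidecar_path <- function(path) paste0(sub("\\.[^./]*$", "", path), ".json")
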