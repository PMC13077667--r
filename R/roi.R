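#' Region-of-interest specification in the isocenter plane
#'
#' ROIs are declared where a physicist thinks about them — in the isocenter
#' plane — and projected onto the panel by the beam magnification when they
#' are sampled.  A "5 mm radius circle" therefore covers a 7.5 mm radius of
#' panel at SID 150 cm / SAD 100 cm.
#'
#' @param shape `"circle"`, `"rect"` or `"band"` (an alias for `"rect"`,
#'   used by the VMAT band tests).
#' @param center `(x, y)` center in mm, isocenter plane.
#' @param radius Circle radius in mm (isocenter plane).
#' @param width,height Rectangle extents in mm along x and y (isocenter
#'   plane).
#' @return An object of class `roi_spec`.
#' @examples
#' roi_spec("circle", radius = 5)              # central-dose ROI
#' roi_spec("rect", width = 10, height = 160)  # a leaf-speed band ROI
#' @export
roi_spec <- function(shape = c("circle", "rect", "band"), center = c(0, 0),
                     radius = NULL, width = NULL, height = NULL) {
  shape <- match.arg(shape)
  if (shape == "band") shape <- "rect"
  center <- as.numeric(center)
  stopifnot(length(center) == 2, all(is.finite(center)))
  if (shape == "circle") {
    if (is.null(radius) || !is.finite(radius) || radius <= 0)
      stop("circle ROI needs a positive radius", call. = FALSE)
    out <- list(shape = "circle", center = center, radius = radius)
  } else {
    if (is.null(width) || is.null(height) || width <= 0 || height <= 0)
      stop("rect ROI needs positive width and height", call. = FALSE)
    out <- list(shape = "rect", center = center,
                width = width, height = height)
  }
  structure(out, class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  dims <- if (x$shape == "circle") sprintf("radius %g mm", x$radius)
          else sprintf("%g x %g mm", x$width, x$height)
  cat(sprintf("<roi_spec> %s at (%g, %g) mm [isocenter plane], %s\n",
              x$shape, x$center[1], x$center[2], dims))
  invisible(x)
}

#' Area-weighted mean CU over a region of interest
#'
#' Pixels fully inside the projected ROI carry weight 1; pixels cut by the
#' ROI boundary are weighted by the fraction of their area inside it
#' (analytic overlap for rectangles, subpixel supersampling for circles), so
#' the result is the true area average of the piecewise-constant pixel
#' raster over the ROI.
#'
#' @param img An [epid_image()].
#' @param roi An [roi_spec()]; dimensions are interpreted in the isocenter
#'   plane and projected by `sid / sad`.
#' @param geom Optional [beam_geometry()]; defaults to one matching the
#'   image SID.
#' @param supersample Subpixel grid order for boundary pixels of circular
#'   ROIs (default 16, i.e. 256 subsamples per pixel).
#' @return The weighted mean CU (scalar).
#' @export
roi_mean <- function(img, roi, geom = NULL, supersample = 16) {
  stopifnot(inherits(img, "epid_image"), inherits(roi, "roi_spec"))
  geom <- default_geom(img, geom)
  m <- magnification(geom)
  p <- img$pixel_pitch
  cx <- roi$center[1] * m
  cy <- roi$center[2] * m
  if (roi$shape == "circle") {
    hx <- hy <- roi$radius * m
  } else {
    hx <- roi$width  * m / 2
    hy <- roi$height * m / 2
  }
  xs <- panel_x(img)
  ys <- panel_y(img)
  half <- p / 2
  if (cx - hx < min(xs) - half || cx + hx > max(xs) + half ||
      cy - hy < min(ys) - half || cy + hy > max(ys) + half)
    stop("projected ROI extends beyond the image", call. = FALSE)

  jj <- which(xs >= cx - hx - half & xs <= cx + hx + half)
  ii <- which(ys >= cy - hy - half & ys <= cy + hy + half)
  dx <- xs[jj] - cx
  dy <- ys[ii] - cy
  DX <- matrix(rep(dx, each = length(dy)), nrow = length(dy))
  DY <- matrix(rep(dy, times = length(dx)), nrow = length(dy))

  if (roi$shape == "rect") {
    # analytic overlap of axis-aligned rectangles
    wx <- pmax(0, pmin(dx + half, hx) - pmax(dx - half, -hx)) / p
    wy <- pmax(0, pmin(dy + half, hy) - pmax(dy - half, -hy)) / p
    W <- outer(wy, wx)
  } else {
    R <- roi$radius * m
    near <- sqrt(pmax(abs(DX) - half, 0)^2 + pmax(abs(DY) - half, 0)^2)
    far  <- sqrt((abs(DX) + half)^2 + (abs(DY) + half)^2)
    W <- matrix(0, nrow(DX), ncol(DX))
    W[far <= R] <- 1
    bnd <- which(near < R & far > R)
    if (length(bnd)) {
      n <- as.integer(supersample)
      off <- ((seq_len(n) - 0.5) / n - 0.5) * p
      OX <- rep(off, times = n)
      OY <- rep(off, each = n)
      for (k in bnd) {
        W[k] <- mean((DX[k] + OX)^2 + (DY[k] + OY)^2 <= R^2)
      }
    }
  }
  tw <- sum(W)
  if (tw <= 0) stop("zero-area ROI after projection", call. = FALSE)
  vals <- img$pixels[ii, jj, drop = FALSE]
  if (all(vals[W > 0] == 0))
    stop("ROI covers only zero-valued pixels; is it inside the field?",
         call. = FALSE)
  sum(W * vals) / tw
}
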