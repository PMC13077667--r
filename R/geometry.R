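#' Beam geometry of a C-arm linac and its portal imager
#'
#' Holds the distances that drive all divergent-beam projection math: the
#' source-to-axis distance (SAD), the source-to-imager distance (SID), and the
#' target-to-device distances of the collimating devices (MLC plane and the
#' two jaw pairs).  Jaws and MLC sit at different heights in the treatment
#' head, which is what makes focal-spot triangulation from projected field
#' edges possible.
#'
#' The default device heights are typical C-arm values and are user
#' configurable; they are not measured quantities of any particular machine.
#'
#' @param sad Source-to-axis distance in mm.
#' @param sid Source-to-imager distance in mm.  The projection magnification
#'   from the isocenter plane to the panel is `sid / sad`.
#' @param h_mlc Target-to-MLC-plane distance in mm.
#' @param h_jaw_x,h_jaw_y Target-to-jaw-plane distances in mm for the X
#'   (crossplane) and Y (inplane) jaw pairs.
#' @return An object of class `beam_geometry`.
#' @examples
#' g <- beam_geometry()
#' magnification(g)  # 1.5
#' @export
beam_geometry <- function(sad = 1000, sid = 1500,
                          h_mlc = 509, h_jaw_x = 367, h_jaw_y = 279) {
  stopifnot(is.numeric(sad), is.numeric(sid),
            length(sad) == 1, length(sid) == 1)
  h <- c(h_mlc = h_mlc, h_jaw_x = h_jaw_x, h_jaw_y = h_jaw_y)
  if (any(!is.finite(h)) || any(h <= 0) || any(h >= sad))
    stop("device heights must satisfy 0 < h < sad", call. = FALSE)
  if (!(sad > 0 && sid > sad))
    stop("require 0 < sad < sid", call. = FALSE)
  structure(list(sad = sad, sid = sid,
                 h_mlc = h_mlc, h_jaw_x = h_jaw_x, h_jaw_y = h_jaw_y),
            class = "beam_geometry")
}

#' @rdname beam_geometry
#' @param geom A `beam_geometry` object.
#' @export
magnification <- function(geom) {
  stopifnot(inherits(geom, "beam_geometry"))
  geom$sid / geom$sad
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("<beam_geometry> SAD %g mm, SID %g mm (magnification %.4g)\n",
              x$sad, x$sid, magnification(x)))
  cat(sprintf("  device heights: MLC %g mm, X jaws %g mm, Y jaws %g mm\n",
              x$h_mlc, x$h_jaw_x, x$h_jaw_y))
  invisible(x)
}

#' Project an isocenter-plane length onto the imager panel
#'
#' Lengths and off-axis distances throughout the package are declared in the
#' isocenter plane; the divergent beam magnifies them by `sid / sad` at the
#' panel.
#'
#' @param length_iso Length in mm in the isocenter plane; must be positive.
#' @param geom A [beam_geometry()].
#' @return Length in mm at the panel plane.
#' @examples
#' project_length(5, beam_geometry())    # 7.5
#' project_length(180, beam_geometry())  # 270
#' @export
project_length <- function(length_iso, geom) {
  stopifnot(inherits(geom, "beam_geometry"))
  if (!is.numeric(length_iso) || any(!is.finite(length_iso)) ||
      any(length_iso <= 0))
    stop("length_iso must be positive and finite", call. = FALSE)
  length_iso * magnification(geom)
}
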