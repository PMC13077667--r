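#' Detect radiation field edges on a 1-D profile
#'
#' The field edge is the standard 50%-of-plateau crossing: the plateau is
#' estimated as the mean of the central 50% of the above-threshold region,
#' and each edge is the linearly interpolated position where the profile
#' crosses `threshold_frac` times that plateau.
#'
#' @param pos Sample positions along the profile, mm at the panel plane.
#' @param cu Profile values (CU) at `pos`.
#' @param threshold_frac Edge threshold as a fraction of the plateau
#'   (default 0.5, the conventional radiation field edge).
#' @param magnification Panel magnification `sid / sad` used to report edge
#'   positions in isocenter-plane mm (default 1 reports panel mm).
#' @return An object of class `edge_set`: list with `left`, `right`,
#'   `center`, `width` (mm, isocenter plane) and the `plateau` CU.
#' @export
detect_edges <- function(pos, cu, threshold_frac = 0.5, magnification = 1) {
  if (is.data.frame(pos)) { cu <- pos$cu; pos <- pos$pos }
  stopifnot(length(pos) == length(cu), length(pos) >= 5,
            threshold_frac > 0, threshold_frac < 1)
  o <- order(pos)
  pos <- pos[o]; cu <- cu[o]
  if (max(cu) <= 0) stop("profile has no signal", call. = FALSE)

  # provisional field region from the profile maximum, then refine the
  # plateau from its central half
  above <- cu >= threshold_frac * max(cu)
  runs <- rle(above)
  big <- which(runs$values & runs$lengths >= 3)
  if (length(big) == 0) stop("no field plateau found", call. = FALSE)
  if (length(big) > 1)
    stop("multiple plateaus found; expected a single field", call. = FALSE)
  ends <- cumsum(runs$lengths)
  hi <- ends[big]
  lo <- hi - runs$lengths[big] + 1
  qlen <- (hi - lo + 1) / 4
  core <- seq(ceiling(lo + qlen), floor(hi - qlen))
  plateau <- mean(cu[core])
  thr <- threshold_frac * plateau

  interp <- function(i) pos[i] + (thr - cu[i]) / (cu[i + 1] - cu[i]) *
    (pos[i + 1] - pos[i])
  # left edge: last upward crossing at or before the plateau region
  iL <- which(cu[-length(cu)] < thr & cu[-1] >= thr)
  iL <- iL[iL < lo + qlen]
  # right edge: first downward crossing at or after the plateau region
  iR <- which(cu[-length(cu)] >= thr & cu[-1] < thr)
  iR <- iR[iR > hi - qlen]
  if (length(iL) == 0 || length(iR) == 0)
    stop("field edge not found within the profile", call. = FALSE)
  left  <- interp(max(iL)) / magnification
  right <- interp(min(iR)) / magnification
  structure(list(left = left, right = right,
                 center = (left + right) / 2, width = right - left,
                 plateau = plateau),
            class = "edge_set")
}

#' @export
print.edge_set <- function(x, ...) {
  cat(sprintf(
    "<edge_set> edges %.3f / %.3f mm, center %.3f mm, width %.3f mm (plateau %.4g CU)\n",
    x$left, x$right, x$center, x$width, x$plateau))
  invisible(x)
}
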