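#' Control-point segments of a VMAT QA plan
#'
#' Holds a beam's ordered control points with their cumulative meterset
#' weights (the monotone 0 to 1 fraction of the beam MU delivered by each
#' control point) plus the control-point index ranges that form the test's
#' segments.  VMAT band-test errors are injected by rescaling the weight
#' span of each segment.
#'
#' @param beam_id Beam identifier.
#' @param cumulative_weights Numeric vector of cumulative meterset weights:
#'   non-decreasing, first 0, last 1.
#' @param n_segments Number of segments; segment boundaries default to an
#'   equal partition of `[0, 1]` in weight (the baseline tests use equally
#'   spaced segments).
#' @param boundaries Optional explicit segment boundaries in weight space,
#'   length `n_segments + 1`, from 0 to 1.
#' @param total_mu Total beam monitor units.
#' @param payload Optional list (one element per control point) of
#'   non-meterset data (MLC positions, gantry angles, ...) carried through
#'   unchanged by [redistribute()].
#' @return Object of class `plan_segments`.
#' @export
plan_segments <- function(beam_id, cumulative_weights, n_segments = 1,
                          boundaries = NULL, total_mu = 100,
                          payload = NULL) {
  w <- as.numeric(cumulative_weights)
  if (length(w) < 2)
    stop("need at least two control points", call. = FALSE)
  if (any(diff(w) < 0))
    stop("cumulative meterset weights must be non-decreasing", call. = FALSE)
  if (abs(w[1]) > 1e-12 || abs(w[length(w)] - 1) > 1e-12)
    stop("cumulative weights must run from 0 to 1", call. = FALSE)
  if (is.null(boundaries))
    boundaries <- seq(0, 1, length.out = n_segments + 1)
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2 || any(diff(boundaries) <= 0) ||
      abs(boundaries[1]) > 1e-12 ||
      abs(boundaries[length(boundaries)] - 1) > 1e-12)
    stop("boundaries must increase strictly from 0 to 1", call. = FALSE)
  if (!is.null(payload) && length(payload) != length(w))
    stop("payload needs one element per control point", call. = FALSE)
  structure(list(beam_id = beam_id, cumulative_weights = w,
                 boundaries = boundaries, total_mu = total_mu,
                 payload = payload),
            class = "plan_segments")
}

#' @export
print.plan_segments <- function(x, ...) {
  ns <- length(x$boundaries) - 1
  cat(sprintf("<plan_segments> beam '%s': %d control points, %d segment(s), %g MU\n",
              x$beam_id, length(x$cumulative_weights), ns, x$total_mu))
  cat("  segment fractions:",
      paste(sprintf("%.4f", segment_fractions(x)), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname plan_segments
#' @param plan A `plan_segments` object.
#' @return `segment_fractions` returns the fraction of the beam MU each
#'   segment delivers (the diff of the segment boundaries).
#' @export
segment_fractions <- function(plan) {
  stopifnot(inherits(plan, "plan_segments"))
  diff(plan$boundaries)
}

#' Read / write a QA plan's control points
#'
#' Plans are stored as plain-text JSON carrying the beam id, total MU, the
#' control points' cumulative meterset weights, segment boundaries and any
#' per-control-point payload.  Read and write round-trip exactly.
#'
#' @param path File path.
#' @param n_segments Segment count used when the file does not record
#'   boundaries (segments are then inferred as an equal partition of the
#'   weight range, matching the equally spaced baseline tests).
#' @return `read_plan` returns a [plan_segments()]; `write_plan` returns
#'   `path` invisibly.
#' @export
read_plan <- function(path, n_segments = NULL) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$control_points))
    stop("no control-point sequence in plan file", call. = FALSE)
  w <- as.numeric(j$control_points$cumulative_meterset_weight)
  payload <- NULL
  extra <- setdiff(names(j$control_points),
                   c("index", "cumulative_meterset_weight"))
  if (length(extra)) {
    cols <- j$control_points[extra]
    payload <- lapply(seq_along(w), function(i)
      lapply(cols, function(col) col[[i]]))
  }
  bounds <- j$segment_boundaries
  if (is.null(bounds) && !is.null(n_segments))
    bounds <- seq(0, 1, length.out = n_segments + 1)
  if (is.null(bounds)) bounds <- c(0, 1)
  plan_segments(beam_id = if (is.null(j$beam_id)) "beam" else j$beam_id,
                cumulative_weights = w, boundaries = as.numeric(bounds),
                total_mu = if (is.null(j$total_mu)) 100 else j$total_mu,
                payload = payload)
}

#' @rdname read_plan
#' @param plan A [plan_segments()].
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "plan_segments"))
  cp <- data.frame(index = seq_along(plan$cumulative_weights) - 1L,
                   cumulative_meterset_weight = plan$cumulative_weights)
  if (!is.null(plan$payload)) {
    keys <- unique(unlist(lapply(plan$payload, names)))
    for (k in keys)
      cp[[k]] <- vapply(plan$payload, function(p)
        if (is.null(p[[k]])) NA_real_ else as.numeric(p[[k]]), numeric(1))
  }
  jsonlite::write_json(
    list(beam_id = plan$beam_id, total_mu = plan$total_mu,
         segment_boundaries = plan$boundaries, control_points = cp),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Redistribute segment MU fractions of a VMAT QA plan
#'
#' Rescales each segment's cumulative-weight span to a requested MU
#' fraction, mapping interior control points affinely within their segment
#' so the relative delivery shape inside each segment is preserved.  All
#' non-meterset payload (MLC positions, gantry angles, ...) and the
#' control-point count are untouched; the total beam MU is left unchanged.
#'
#' @param plan A [plan_segments()].
#' @param fractions Requested MU fraction per segment; positive, summing to
#'   1, one per segment.
#' @return A new [plan_segments()] whose segment boundaries are
#'   `cumsum(c(0, fractions))`.
#' @examples
#' p <- plan_segments("ls", seq(0, 1, by = 0.25), n_segments = 4)
#' redistribute(p, c(0.16, 0.21, 0.29, 0.34))$boundaries
#' @export
redistribute <- function(plan, fractions) {
  stopifnot(inherits(plan, "plan_segments"))
  ns <- length(plan$boundaries) - 1
  fractions <- as.numeric(fractions)
  if (length(fractions) != ns)
    stop(sprintf("plan has %d segments but %d fractions were given",
                 ns, length(fractions)), call. = FALSE)
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be positive and sum to 1", call. = FALSE)
  old <- plan$boundaries
  new <- cumsum(c(0, fractions))
  new[length(new)] <- 1  # guard accumulated rounding
  w <- plan$cumulative_weights
  seg <- findInterval(w, old, rightmost.closed = TRUE, all.inside = TRUE)
  rel <- (w - old[seg]) / (old[seg + 1] - old[seg])
  w_new <- new[seg] + rel * (new[seg + 1] - new[seg])
  plan_segments(plan$beam_id, w_new, boundaries = new,
                total_mu = plan$total_mu, payload = plan$payload)
}
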