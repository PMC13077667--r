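#' Measurement reproducibility
#'
#' Sample standard deviation (n - 1 denominator) of repeated measurements
#' acquired without altering the setup; the usual protocol takes five
#' consecutive acquisitions.
#'
#' @param values Numeric vector of repeated measurements (length >= 2).
#' @return Object of class `repro_result` with `n`, `mean` and `sd`.
#' @examples
#' reproducibility(c(1, 2, 3, 4, 5))$sd  # 1.5811
#' @export
reproducibility <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2 || any(!is.finite(values)))
    stop("need at least two finite measurements", call. = FALSE)
  structure(list(n = length(values), mean = mean(values),
                 sd = stats::sd(values)),
            class = "repro_result")
}

#' @export
print.repro_result <- function(x, ...) {
  cat(sprintf("Reproducibility over %d repeats: mean %.6g, SD %.4g\n",
              x$n, x$mean, x$sd))
  invisible(x)
}

#' Standard error propagation through a ratio or difference
#'
#' For uncorrelated inputs, the SD of `a / b` is
#' `(a / b) * sqrt((a_sd / a)^2 + (b_sd / b)^2)` and the SD of `a - b` is
#' `sqrt(a_sd^2 + b_sd^2)`.  These are the first-order propagation formulas
#' used to attach uncertainties to ratio metrics (wedge factor, Rcorr,
#' relative output) and difference metrics.
#'
#' @param a_mean,b_mean Means of the two inputs.
#' @param a_sd,b_sd Their standard deviations (non-negative).
#' @return The propagated standard deviation (scalar).
#' @export
propagate_ratio <- function(a_mean, a_sd, b_mean, b_sd) {
  stopifnot(a_sd >= 0, b_sd >= 0)
  if (a_mean == 0 || b_mean == 0)
    stop("ratio propagation needs non-zero means", call. = FALSE)
  abs(a_mean / b_mean) * sqrt((a_sd / a_mean)^2 + (b_sd / b_mean)^2)
}

#' @rdname propagate_ratio
#' @export
propagate_difference <- function(a_sd, b_sd) {
  stopifnot(a_sd >= 0, b_sd >= 0)
  sqrt(a_sd^2 + b_sd^2)
}

#' Sensitivity linearity between injected and measured deviations
#'
#' Ordinary least squares of measured on injected deviations with Pearson
#' correlation, after subtracting each series' first (baseline) value —
#' mirroring how relative EPID metrics are compared against a reference
#' detector during error-injection studies.  A slope below 1 means the
#' method under-reports changes: e.g. a slope of 0.83 turns a 2% reference
#' change into a reported 1.66% change.
#'
#' @param injected,measured Numeric vectors of equal length (>= 3 after
#'   pairwise removal of missing values).
#' @param baseline_subtract Subtract the first element of each vector
#'   before fitting (default `TRUE`).
#' @return Object of class `linearity_result` with `slope`, `intercept`,
#'   `r`, `n` and `degenerate` (`TRUE` when either vector is constant and
#'   `r` is undefined).
#' @export
sensitivity_fit <- function(injected, measured, baseline_subtract = TRUE) {
  stopifnot(length(injected) == length(measured))
  ok <- is.finite(injected) & is.finite(measured)
  if (!all(ok)) warning("dropping ", sum(!ok), " incomplete pair(s)")
  x <- injected[ok]
  y <- measured[ok]
  if (length(x) < 3) stop("need at least three pairs", call. = FALSE)
  if (baseline_subtract) { y <- y - y[1]; x <- x - x[1] }
  if (stats::sd(x) == 0)
    stop("injected values are constant; nothing to regress on",
         call. = FALSE)
  degenerate <- stats::sd(y) == 0
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = if (degenerate) NA_real_ else stats::cor(x, y),
                 n = length(x), degenerate = degenerate),
            class = "linearity_result")
}

#' @export
print.linearity_result <- function(x, ...) {
  cat(sprintf("Sensitivity fit (n = %d): slope %.4f, intercept %.4g, r %s\n",
              x$n, x$slope, x$intercept,
              if (x$degenerate) "undefined (constant response)"
              else sprintf("%.6f", x$r)))
  invisible(x)
}

#' @rdname sensitivity_fit
#' @param object A `linearity_result`.
#' @param newdata Injected deviations at which to predict the reported
#'   change (slope and intercept applied on the baseline-subtracted scale).
#' @param ... Unused.
#' @examples
#' fit <- sensitivity_fit(0:5, 0.83 * (0:5))
#' predict(fit, 2)  # 1.66
#' @export
predict.linearity_result <- function(object, newdata, ...) {
  object$intercept + object$slope * as.numeric(newdata)
}

#' Longitudinal baseline-relative concordance
#'
#' Each device's series is normalized to its first (baseline) entry,
#' `delta_t = 100 * (m_t / m_1 - 1)` in percent, and devices are compared
#' through paired differences of those deltas — so two systems that drift
#' together stay concordant even if their absolute readings differ.
#'
#' @param timestamps Vector of time points (any orderable type), common to
#'   all devices.
#' @param ... Named numeric vectors, one per device, same length as
#'   `timestamps`.
#' @param reference Name of the reference device for paired differences;
#'   defaults to the last device given.
#' @return Object of class `trend_series`: list with `timestamps`, the
#'   per-device `deltas` (percent from baseline; first entry 0), the
#'   `differences` of each non-reference device minus the reference, and a
#'   `summary` data frame of mean +/- SD per comparison (empty with a
#'   single time point).
#' @export
trend <- function(timestamps, ..., reference = NULL) {
  devices <- list(...)
  if (length(devices) < 1 || is.null(names(devices)) ||
      any(!nzchar(names(devices))))
    stop("supply named per-device value vectors", call. = FALSE)
  nt <- length(timestamps)
  deltas <- lapply(devices, function(v) {
    v <- as.numeric(v)
    if (length(v) != nt)
      stop("every device needs one value per timestamp", call. = FALSE)
    if (any(!is.finite(v)) )
      warning("missing time points are dropped pairwise in comparisons")
    100 * (v / v[1] - 1)
  })
  if (is.null(reference)) reference <- names(devices)[length(devices)]
  if (!reference %in% names(devices))
    stop("unknown reference device", call. = FALSE)
  others <- setdiff(names(devices), reference)
  differences <- lapply(others, function(d) deltas[[d]] - deltas[[reference]])
  names(differences) <- others
  summary <- if (nt < 2) {
    data.frame(device = character(), mean_diff = numeric(),
               sd_diff = numeric())
  } else {
    do.call(rbind, lapply(others, function(d) {
      x <- differences[[d]]
      x <- x[is.finite(x)]
      data.frame(device = d, mean_diff = mean(x),
                 sd_diff = if (length(x) > 1) stats::sd(x) else NA_real_)
    }))
  }
  structure(list(timestamps = timestamps, deltas = deltas,
                 differences = differences, reference = reference,
                 summary = summary),
            class = "trend_series")
}

#' @export
print.trend_series <- function(x, ...) {
  cat(sprintf("Trend over %d time point(s), baseline-relative, reference '%s'\n",
              length(x$timestamps), x$reference))
  if (nrow(x$summary)) {
    for (i in seq_len(nrow(x$summary)))
      cat(sprintf("  %s - %s: %+.3f%% +/- %.3f%%\n",
                  x$summary$device[i], x$reference,
                  x$summary$mean_diff[i], x$summary$sd_diff[i]))
  } else cat("  (single time point; no drift summary)\n")
  invisible(x)
}

#' Read a long-format measurement series for concordance analysis
#'
#' Ingests a CSV with columns `timestamp`, `device`, `metric`, `value` and
#' returns, for one metric, the arguments [trend()] expects.
#'
#' @param path CSV path.
#' @param metric Metric name to extract.
#' @param reference Optional reference device, passed through.
#' @return A `trend_series` (see [trend()]).
#' @export
trend_from_csv <- function(path, metric, reference = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "device", "metric", "value")
  if (!all(need %in% names(df)))
    stop("CSV must have columns timestamp, device, metric, value",
         call. = FALSE)
  df <- df[df$metric == metric, ]
  if (!nrow(df)) stop("metric not found in CSV", call. = FALSE)
  ts <- sort(unique(df$timestamp))
  devs <- unique(df$device)
  args <- lapply(devs, function(d) {
    sub <- df[df$device == d, ]
    sub$value[match(ts, sub$timestamp)]
  })
  names(args) <- devs
  do.call(trend, c(list(timestamps = ts), args, list(reference = reference)))
}
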