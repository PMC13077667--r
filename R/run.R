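#' Configuration for a reproducible simulate-and-analyze run
#'
#' Validates a run configuration (from a YAML file or an R list): unknown
#' keys are rejected so typos fail loudly rather than silently falling back
#' to defaults.
#'
#' @param config A named list, or a path to a YAML file containing one.
#' @return A validated configuration list of class `run_config`.
#' @section Keys:
#' \describe{
#'   \item{tests}{Subset of `wedge`, `output`, `symmetry`, `focalspot`,
#'     `vmat-drgs`, `vmat-leafspeed` (default: all).}
#'   \item{seed}{Integer RNG seed (default 1).}
#'   \item{noise_sd}{Simulated pixel noise SD in CU (default 0).}
#'   \item{tolerance}{Pass tolerance in percent for ratio metrics
#'     (default 2).}
#'   \item{tolerance_mm}{Pass tolerance in mm for the focal spot
#'     (default 0.1).}
#'   \item{npix, pitch}{Simulated panel raster (default 768 px, 0.5 mm).}
#'   \item{wedge_angle}{Wedge angle in degrees for the wedge test
#'     (default 30).}
#'   \item{out_dir}{Report directory; `NULL` writes no files.}
#'   \item{geometry}{Named overrides passed to [beam_geometry()].}
#' }
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(tests = c("wedge", "output", "symmetry", "focalspot",
                             "vmat-drgs", "vmat-leafspeed"),
                   seed = 1L, noise_sd = 0, tolerance = 2,
                   tolerance_mm = 0.1, npix = 768, pitch = 0.5,
                   wedge_angle = 30, out_dir = NULL, geometry = list())
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  cfg$tests <- unlist(cfg$tests)
  cfg$geometry <- as.list(cfg$geometry)
  bad <- setdiff(cfg$tests, defaults$tests)
  if (length(bad))
    stop("unknown test(s): ", paste(bad, collapse = ", "), call. = FALSE)
  stopifnot(cfg$tolerance >= 0, cfg$tolerance_mm >= 0, cfg$noise_sd >= 0)
  structure(cfg, class = "run_config")
}

#' Run the QA demo cycle: simulate, analyze, report
#'
#' Generates baseline synthetic acquisitions for the selected tests at the
#' configured noise level, runs each analysis, and checks the recovered
#' metrics against the configured tolerances (a noise-free baseline should
#' recover zero deviation everywhere).  Deterministic for a fixed seed.
#'
#' @param config A [run_config()], a named list, or a YAML path.
#' @return Invisibly, a list of class `qa_run` with the config echo,
#'   per-test results, and an overall `passed` flag.  When
#'   `config$out_dir` is set, writes `report.json` and `report.md` there.
#' @export
run_qa <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  geom <- do.call(beam_geometry, cfg$geometry)
  fm <- field_model(noise_sd = cfg$noise_sd, seed = cfg$seed)
  sim <- list(npix = cfg$npix, pitch = cfg$pitch)
  results <- list()

  if ("wedge" %in% cfg$tests) {
    open_ <- make_open_field(fm, geom = geom, npix = sim$npix,
                             pitch = sim$pitch)
    wed <- make_wedge_field(field_model(noise_sd = cfg$noise_sd,
                                        seed = cfg$seed + 101L),
                            cfg$wedge_angle, geom = geom,
                            npix = sim$npix, pitch = sim$pitch)
    wf <- wedge_factor(wed, open_, geom, wedge_angle_deg = cfg$wedge_angle)
    dev <- 100 * abs(wf$wf - wedge_factor_true(cfg$wedge_angle))
    results$wedge <- list(value = wf$wf,
                          expected = wedge_factor_true(cfg$wedge_angle),
                          deviation_pct = dev,
                          passed = dev <= cfg$tolerance)
  }
  if ("output" %in% cfg$tests) {
    base <- make_open_field(fm, geom = geom, npix = sim$npix,
                            pitch = sim$pitch)
    img <- make_open_field(field_model(noise_sd = cfg$noise_sd,
                                       seed = cfg$seed + 202L),
                           geom = geom, npix = sim$npix, pitch = sim$pitch)
    res <- central_axis_dose(img, central_axis_dose(base, geom = geom),
                             geom = geom)
    results$output <- list(value = res$cu_mean,
                           deviation_pct =
                             abs(res$percent_change_from_baseline),
                           passed = abs(res$percent_change_from_baseline) <=
                             cfg$tolerance)
  }
  if ("symmetry" %in% cfg$tests) {
    img <- make_open_field(field_model(noise_sd = cfg$noise_sd,
                                       seed = cfg$seed + 303L),
                           geom = geom, npix = sim$npix, pitch = sim$pitch)
    s <- symmetry(img, geom = geom)
    dev <- max(abs(s$axial), abs(s$transverse))
    results$symmetry <- list(axial = s$axial, transverse = s$transverse,
                             deviation_pct = dev,
                             passed = dev <= cfg$tolerance)
  }
  if ("focalspot" %in% cfg$tests) {
    set <- make_focal_spot_set(field_model(noise_sd = cfg$noise_sd,
                                           seed = cfg$seed + 404L),
                               geom = geom, npix = sim$npix,
                               pitch = sim$pitch)
    fs <- focal_spot_epid(set, geom)
    dev <- max(abs(fs$sx), abs(fs$sy))
    results$focalspot <- list(sx = fs$sx, sy = fs$sy, deviation_mm = dev,
                              passed = dev <= cfg$tolerance_mm)
  }
  for (kind in c("drgs", "leafspeed")) {
    key <- paste0("vmat-", kind)
    if (!key %in% cfg$tests) next
    pair <- make_vmat_pair(kind, fm = field_model(noise_sd = cfg$noise_sd,
                                                  seed = cfg$seed + 505L),
                           geom = geom, npix = sim$npix, pitch = sim$pitch)
    v <- vmat_analysis(pair$dynamic, pair$open, kind,
                       tolerance = cfg$tolerance, geom = geom)
    results[[key]] <- list(rcorr = v$rcorr, diff = v$diff,
                           deviation_pct = max(abs(v$diff)),
                           passed = all(v$passed))
  }

  run <- structure(list(config = unclass(cfg), results = results,
                        passed = all(vapply(results, `[[`, TRUE, "passed"))),
                   class = "qa_run")
  if (!is.null(cfg$out_dir)) write_qa_report(run, cfg$out_dir)
  invisible(run)
}

#' @export
print.qa_run <- function(x, ...) {
  cat("QA run:", if (x$passed) "ALL TESTS PASSED" else "FAILURES PRESENT",
      "\n")
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    dev <- if (!is.null(r$deviation_pct))
      sprintf("deviation %.4g%%", r$deviation_pct)
    else sprintf("deviation %.4g mm", r$deviation_mm)
    cat(sprintf("  %-14s %s  [%s]\n", nm, dev,
                if (r$passed) "pass" else "FAIL"))
  }
  invisible(x)
}

#' @rdname run_qa
#' @param run A `qa_run` object.
#' @param dir Output directory (created if missing).
#' @export
write_qa_report <- function(run, dir) {
  stopifnot(inherits(run, "qa_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  run$config$out_dir <- NULL   # the report's own location, not a parameter
  jsonlite::write_json(list(config = run$config, results = run$results,
                            passed = run$passed),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  md <- c("# EPID QA run report", "",
          sprintf("Overall: **%s**", if (run$passed) "PASS" else "FAIL"), "",
          "| test | deviation | result |", "|---|---|---|")
  for (nm in names(run$results)) {
    r <- run$results[[nm]]
    dev <- if (!is.null(r$deviation_pct))
      sprintf("%.4g%%", r$deviation_pct) else sprintf("%.4g mm",
                                                      r$deviation_mm)
    md <- c(md, sprintf("| %s | %s | %s |", nm, dev,
                        if (r$passed) "pass" else "FAIL"))
  }
  nd <- run$config[vapply(names(run$config), function(k)
    !identical(run$config[[k]], unclass(run_config())[[k]]), TRUE)]
  if (length(nd)) {
    md <- c(md, "", "Non-default parameters:",
            paste0("- `", names(nd), "`: ",
                   vapply(nd, function(v) paste(format(v), collapse = ", "),
                          "")))
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(file.path(dir, "report.json"))
}
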