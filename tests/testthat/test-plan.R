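# a 7-segment DRGS-style beam: 3 control points per segment with uneven
# interior spacing, plus geometry payload that must survive editing
make_drgs_plan <- function() {
  bounds <- seq(0, 1, length.out = 8)
  w <- sort(unique(c(bounds, bounds[-8] + diff(bounds) * 0.3,
                     bounds[-8] + diff(bounds) * 0.8)))
  payload <- lapply(seq_along(w), function(i)
    list(gantry_angle = 180 - 2 * i, mlc_x1 = -50 + i * 0.25))
  plan_segments("drgs", w, n_segments = 7, total_mu = 100,
                payload = payload)
}

test_that("plan invariants: monotone cumulative weights from 0 to 1", {
  p <- make_drgs_plan()
  expect_equal(segment_fractions(p), rep(1 / 7, 7), tolerance = 1e-12)
  expect_error(plan_segments("b", c(0, 0.6, 0.4, 1)), "non-decreasing")
  expect_error(plan_segments("b", c(0.1, 0.5, 1)), "from 0 to 1")
  expect_error(plan_segments("b", c(0, 0.5, 0.9)), "from 0 to 1")
  expect_silent(plan_segments("toy", c(0, 1)))
})

test_that("redistribute hits requested fractions and preserves payloads", {
  p <- plan_segments("ls", seq(0, 1, by = 0.125), n_segments = 4,
                     payload = lapply(1:9, function(i) list(ga = i * 10)))
  fr <- c(0.16, 0.21, 0.29, 0.34)
  q <- redistribute(p, fr)
  expect_equal(q$boundaries, c(0, 0.16, 0.37, 0.66, 1.00),
               tolerance = 1e-12)
  expect_equal(segment_fractions(q), fr, tolerance = 1e-9)
  expect_true(all(diff(q$cumulative_weights) >= 0))
  expect_length(q$cumulative_weights, length(p$cumulative_weights))
  expect_identical(q$payload, p$payload)        # bit-exact payload
  expect_identical(q$total_mu, p$total_mu)
  # interior points keep their relative position within each segment
  expect_equal(q$cumulative_weights[2], 0.16 / 2)
})

test_that("redistribute validates its inputs", {
  p <- make_drgs_plan()
  expect_error(redistribute(p, rep(1 / 4, 4)), "7 segments")
  expect_error(redistribute(p, rep(0.15, 7)), "sum to 1")
  expect_error(redistribute(p, c(0.5, 0.6, -0.1, rep(0, 4))), "positive")
})

test_that("equal-fraction redistribution is the identity and composes back", {
  p <- make_drgs_plan()
  same <- redistribute(p, rep(1 / 7, 7))
  expect_equal(same$cumulative_weights, p$cumulative_weights,
               tolerance = 1e-12)
  fr <- c(0.08, 0.14, 0.15, 0.15, 0.16, 0.16, 0.16)
  round_trip <- redistribute(redistribute(p, fr), rep(1 / 7, 7))
  expect_equal(round_trip$cumulative_weights, p$cumulative_weights,
               tolerance = 1e-12)
})

test_that("plan files round-trip exactly through JSON", {
  p <- make_drgs_plan()
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "plan.json")
  write_plan(p, f1)
  back <- read_plan(f1)
  expect_equal(back$cumulative_weights, p$cumulative_weights,
               tolerance = 1e-15)
  expect_equal(back$boundaries, p$boundaries, tolerance = 1e-15)
  expect_equal(length(back$payload), length(p$payload))
  expect_equal(back$payload[[5]]$gantry_angle, p$payload[[5]]$gantry_angle)
  # idempotence: a second round trip writes an identical file
  f2 <- file.path(dir, "plan2.json")
  write_plan(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a modified plan differs from the input only in meterset weights
  q <- redistribute(p, c(0.08, 0.14, 0.15, 0.15, 0.16, 0.16, 0.16))
  expect_identical(q$payload, p$payload)
  expect_false(isTRUE(all.equal(q$cumulative_weights,
                                p$cumulative_weights)))
})

test_that("reading infers equal segments and rejects bad sequences", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "toy.json")
  jsonlite::write_json(list(beam_id = "toy", total_mu = 50,
                            control_points = data.frame(
                              index = 0:1,
                              cumulative_meterset_weight = c(0, 1))),
                       f, auto_unbox = TRUE, dataframe = "columns")
  p <- read_plan(f)
  expect_equal(length(p$boundaries) - 1, 1)     # one segment
  p7 <- read_plan(f, n_segments = 7)
  expect_equal(length(segment_fractions(p7)), 7)
  jsonlite::write_json(list(control_points = data.frame(
    index = 0:2, cumulative_meterset_weight = c(0, 0.8, 0.5))),
    f, auto_unbox = TRUE, dataframe = "columns")
  expect_error(read_plan(f), "non-decreasing")
  jsonlite::write_json(list(beam_id = "x"), f, auto_unbox = TRUE)
  expect_error(read_plan(f), "control-point")
})
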