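test_that("run bounds found from zero-crossings around sustained motion", {
  fs <- 240
  v <- c(rep(0, 2 * fs), rep(3.3, 10 * fs), rep(0, 2 * fs))
  b <- detect_run_bounds(v, fs)
  expect_lt(abs(b[["start"]] - 2 * fs), 0.1 * fs)
  expect_lt(abs(b[["end"]] - 12 * fs), 0.1 * fs)

  expect_error(detect_run_bounds(rep(0, 5 * fs), fs),
               class = "no_run_detected")
  expect_error(detect_run_bounds(rep(0, 10), fs), "shorter")
})

test_that("run bounds on a synthetic session match generator truth", {
  sim <- demo_session()
  fs <- sim$recording$sampling_rate
  runs <- detect_runs(sim$recording$pelvis_velocity, fs)
  expect_equal(nrow(runs), 2)
  expect_true(all(abs(runs - sim$truth$run_bounds) <= 0.5 * fs))
})

test_that("stride events: sinusoid count, noise rejection, error cases", {
  fs <- 240
  t <- seq(0, 10, by = 1 / fs)
  v <- 3 + 0.5 * sin(2 * pi * 1.3 * t)
  pk <- detect_strides(v, fs, c(1L, length(v) + 1L))
  expect_true(abs(length(pk) - 13) <= 1)

  expect_error(detect_strides(rep(3, 10 * fs), fs, c(1L, 10L * fs)),
               class = "segmentation_error")
})

test_that("detected strides on a synthetic session match truth within 1%", {
  sim <- demo_session()
  fs <- sim$recording$sampling_rate
  runs <- detect_runs(sim$recording$pelvis_velocity, fs)
  n_true <- c(sum(sim$truth$strides$run == 1), sum(sim$truth$strides$run == 3))
  for (r in 1:2) {
    pk <- detect_strides(sim$recording$pelvis_velocity, fs, runs[r, ])
    expect_lte(abs(length(pk) - n_true[r]), ceiling(0.01 * n_true[r]))
  }
})

test_that("initial contacts: timing accuracy, alternation, degenerate knee", {
  sim <- demo_session()
  fs <- sim$recording$sampling_rate
  runs <- detect_runs(sim$recording$pelvis_velocity, fs)
  pk <- detect_strides(sim$recording$pelvis_velocity, fs, runs[1, ])
  ics <- detect_initial_contacts(sim$recording$joints$knee_right, pk, fs)

  # sides strictly alternate among usable contacts
  sides <- ics$side[ics$usable]
  expect_true(all(sides[-1] != sides[-length(sides)]))

  # right-IC timing error vs ground truth: median within 2 samples
  ric <- ics$index[ics$side == "right" & ics$usable]
  err <- vapply(ric, function(i) min(abs(sim$truth$right_ics - i)),
                numeric(1))
  expect_lte(stats::median(err), 2)

  # flat knee angle -> all strides flagged unusable
  flat <- detect_initial_contacts(rep(15, length(sim$recording$joints$knee_right)),
                                  pk, fs)
  expect_false(any(flat$usable))
})

test_that("cycles are 150 points with endpoints and extrema preserved", {
  sim <- demo_session()
  fs <- sim$recording$sampling_rate
  runs <- detect_runs(sim$recording$pelvis_velocity, fs)
  pk <- detect_strides(sim$recording$pelvis_velocity, fs, runs[1, ])
  ics <- detect_initial_contacts(sim$recording$joints$knee_right, pk, fs)
  cycles <- segment_and_normalize(sim$recording, ics)

  expect_true(all(vapply(cycles, function(c) nrow(c$curves), 0L) == 150L))
  expect_true(all(vapply(cycles, function(c) ncol(c$curves), 0L) == 22L))

  # stride count conservation: cycles per side = usable ICs per side - 1
  for (sd in c("right", "left")) {
    n_ic <- sum(ics$side == sd & ics$usable)
    n_cyc <- sum(vapply(cycles, `[[`, "", "side") == sd)
    expect_lte(abs(n_cyc - (n_ic - 1)), 2)  # allow dropped short cycles
  }

  # endpoint preservation and interpolation bounds for one cycle
  cyc <- cycles[[10]]
  raw <- sim$recording$joints$knee_right[cyc$start:(cyc$end - 1)]
  curve <- cyc$curves[, "knee_right_angle"]
  expect_equal(curve[1], raw[1])
  expect_equal(curve[150], raw[length(raw)])
  expect_lte(max(curve), max(raw))
  expect_gte(min(curve), min(raw))

  # recovered stride-time distribution matches the generating one (2%)
  st <- vapply(cycles, `[[`, numeric(1), "stride_time")
  expect_lt(abs(mean(st) - 0.75) / 0.75, 0.02)
})

test_that("resampling is exact on constant and 150-sample inputs", {
  sim <- mini_session()
  rec <- sim$recording
  # construct two ICs exactly 150 samples apart in a quiet region
  ics <- data.frame(index = c(10L, 160L, 310L), side = "right",
                    stride = 1:3, usable = TRUE)
  ics <- rbind(ics, data.frame(index = c(85L, 235L), side = "left",
                               stride = 1:2, usable = TRUE))
  cycles <- segment_and_normalize(rec, ics)
  rc <- cycles[[which(vapply(cycles, `[[`, "", "side") == "right")[1]]]
  raw <- rec$joints$knee_right[rc$start:(rc$end - 1)]
  expect_equal(rc$curves[, "knee_right_angle"], raw, tolerance = 1e-12)

  # constant signal -> constant 150-point curve
  rec2 <- rec
  rec2$joints$knee_right <- rep(33, length(rec$pelvis_velocity))
  cycles2 <- segment_and_normalize(rec2, ics)
  expect_true(all(abs(cycles2[[1]]$curves[, "knee_right_angle"] - 33) < 1e-12))
})
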