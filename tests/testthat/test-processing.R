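test_that("labels map the protocol segments to conditions", {
  expect_equal(assign_label(1, 3), "no_fatigue")
  expect_equal(assign_label(1, 2), "no_fatigue")
  expect_equal(assign_label(1, 8), "mild_fatigue")
  expect_equal(assign_label(1, 10), "mild_fatigue")
  expect_equal(assign_label(3, 1), "heavy_fatigue")
  expect_equal(assign_label(3, 2), "heavy_fatigue")
  expect_equal(assign_label(1, 6), "excluded")
  expect_equal(assign_label(1, 1), "excluded")
  expect_equal(assign_label(2, 1), "excluded")
  expect_equal(assign_label(3, 4), "excluded")
  expect_error(assign_label(4, 1), "run_id")
  expect_error(assign_label(1, 0), "out of range")
})

test_that("moving average: constants, step response, degenerate input", {
  d <- seq(0, 1200, by = 2.5)
  n <- length(d)
  const <- matrix(5, n, 1, dimnames = list(NULL, "f"))
  sm <- lap_moving_average(const, d, 400)
  expect_true(all(abs(sm$values - 5) < 1e-12))
  expect_true(all(d[sm$keep] >= d[1] + 400))

  # step from 0 to 1 at 600 m -> linear ramp over the following 400 m
  step <- matrix(as.numeric(d >= 600), n, 1, dimnames = list(NULL, "f"))
  sm <- lap_moving_average(step, d, 400)
  ds <- d[sm$keep]
  # brute-force windowed means as the oracle
  oracle <- vapply(ds, function(di)
    mean(step[d > di - 400 & d <= di, 1]), numeric(1))
  expect_equal(unname(sm$values[, 1]), oracle, tolerance = 1e-12)
  ramp <- ds > 600 & ds < 1000
  expect_true(all(diff(sm$values[ramp, 1]) > 0))
  expect_true(all(sm$values[ds >= 1000, 1] == 1))

  expect_warning(out <- lap_moving_average(const[1:10, , drop = FALSE],
                                           d[1:10], 400), "no smoothed rows")
  expect_equal(nrow(out$values), 0)
  expect_error(lap_moving_average(const, d, 0), "window_m")
  expect_error(lap_moving_average(const, rev(d)), "non-decreasing")
})

test_that("moving average is linear in its inputs", {
  withr::with_seed(2, {
    d <- cumsum(stats::runif(300, 2, 3))
    x <- matrix(stats::rnorm(300), ncol = 1, dimnames = list(NULL, "f"))
    y <- matrix(stats::rnorm(300), ncol = 1, dimnames = list(NULL, "f"))
  })
  a <- 2.5; b <- -1.2
  lhs <- lap_moving_average(a * x + b * y, d, 400)$values
  rhs <- a * lap_moving_average(x, d, 400)$values +
    b * lap_moving_average(y, d, 400)$values
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("z-scoring normalizes each subject and is idempotent", {
  withr::with_seed(3, {
    tbl <- data.frame(subject_id = rep(c("A", "B"), each = 40),
                      L6_acc_peak = c(stats::rnorm(40, 50, 5),
                                      stats::rnorm(40, 80, 9)),
                      L6_acc_std = 7)  # constant feature
  })
  z <- zscore_per_subject(tbl, c("L6_acc_peak", "L6_acc_std"))
  for (s in c("A", "B")) {
    expect_lt(abs(mean(z$L6_acc_peak[z$subject_id == s])), 1e-9)
    expect_lt(abs(stats::sd(z$L6_acc_peak[z$subject_id == s]) - 1), 1e-9)
  }
  expect_true(all(z$L6_acc_std == 0))
  z2 <- zscore_per_subject(z, c("L6_acc_peak", "L6_acc_std"))
  expect_equal(z2$L6_acc_peak, z$L6_acc_peak, tolerance = 1e-9)

  expect_error(zscore_per_subject(tbl[1, ]), "fewer than 2")
})

test_that("prepared table keeps only labeled laps with full-lap history", {
  sf <- demo_features()
  # before smoothing: rows from exactly 9 labeled laps, 3 per class
  labeled <- sf[sf$label != "excluded", ]
  expect_equal(length(unique(labeled$lap)), 9)
  expect_equal(as.integer(table(unique(labeled[, c("lap", "label")])$label)),
               c(3L, 3L, 3L))

  prep <- prepare_feature_table(sf)
  expect_s3_class(prep$label, "factor")
  expect_equal(levels(prep$label), fatigue_levels())
  # run-3 lap 1 lacks one lap of history and is dropped by the smoother
  expect_false(11 %in% prep$lap)
  expect_true(all(c(12, 13) %in% prep$lap))
  # z-score post-condition on the prepared table
  m <- as.matrix(prep[, intersect(feature_names(), names(prep))])
  expect_lt(max(abs(colMeans(m))), 1e-9)
  expect_lt(max(abs(apply(m, 2, stats::sd) - 1)), 1e-9)

  # alternative order: z-score before smoothing still yields labeled rows
  prep2 <- prepare_feature_table(sf, order = "zscore_first")
  expect_equal(sort(unique(prep2$lap)), sort(unique(prep$lap)))
})
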