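test_that("acceleration magnitude is the root-sum-of-squares", {
  expect_equal(accel_magnitude(3, 4, 0), 5)
  expect_equal(accel_magnitude(0, 0, 0), 0)
  expect_equal(accel_magnitude(1, 1, 1), sqrt(3))
  expect_equal(accel_magnitude(c(3, 1), c(4, 1), c(0, 1)), c(5, sqrt(3)))
  expect_error(accel_magnitude(1:3, 1:2, 1:3), "equal length")
})

make_cycle <- function(curves, side = "right", stride_time = 0.75) {
  structure(list(side = side, start = 1L, end = 151L, stride = 1L,
                 stride_time = stride_time, curves = curves),
            class = "gait_cycle")
}

test_that("segment features: 12 values with degenerate-input conventions", {
  curves <- cbind(L6_acc_mag = rep(7, 150), L6_gyr_pitch = rep(-2, 150))
  sf <- segment_features(make_cycle(curves), "L6")
  expect_length(sf, 12)
  expect_equal(unname(sf["L6_acc_peak"]), 7)
  expect_equal(unname(sf["L6_acc_mean"]), 7)
  expect_equal(unname(sf["L6_acc_std"]), 0)
  expect_equal(unname(sf["L6_acc_iqr"]), 0)
  expect_equal(unname(sf["L6_acc_skew"]), 0)
  expect_equal(unname(sf["L6_acc_kurt"]), 0)
  expect_equal(unname(sf["L6_gyr_peak"]), -2)
})

test_that("segment statistics recover known distribution moments", {
  withr::with_seed(4, {
    x <- stats::rnorm(150 * 400)
    m <- matrix(x, 150)
    stats_all <- t(apply(m, 2, function(col) {
      sf <- segment_features(
        make_cycle(cbind(L6_acc_mag = col, L6_gyr_pitch = col)), "L6")
      sf[c("L6_acc_mean", "L6_acc_std", "L6_acc_iqr")]
    }))
    expect_lt(abs(mean(stats_all[, 1])), 0.01)
    expect_lt(abs(mean(stats_all[, 2]) - 1), 0.01)
    expect_lt(abs(mean(stats_all[, 3]) - 1.349), 0.02)
  })
})

test_that("shock attenuation follows (1 - PSA/PTA) * 100", {
  expect_equal(shock_attenuation(rep(10, 5), rep(10, 5)), 0)
  expect_equal(shock_attenuation(rep(10, 5), rep(5, 5)), 50)
  expect_lt(shock_attenuation(rep(10, 5), rep(12, 5)), 0)
  expect_true(is.na(shock_attenuation(rep(0, 5), rep(1, 5))))
})

test_that("joint event features: counts, windows and degenerate input", {
  u <- (0:149) / 150
  expect_length(joint_event_features(sin(2 * pi * u), "knee_left"), 5)
  expect_length(joint_event_features(sin(2 * pi * u), "ankle_right"), 3)
  expect_length(joint_event_features(sin(2 * pi * u), "hip_left"), 3)
  expect_error(joint_event_features(u, "elbow_left"), "unknown joint")

  const <- joint_event_features(rep(12, 150), "knee_right")
  expect_true(all(const == 12))

  # planted extrema are recovered: bump at 20% (midstance max), dip at 40%
  curve <- 30 + 20 * exp(-((u - 0.20) / 0.05)^2) - 25 * exp(-((u - 0.40) / 0.04)^2)
  ev <- joint_event_features(curve, "knee_right")
  expect_equal(unname(ev["knee_right_midstance"]), max(curve))
  expect_equal(unname(ev["knee_right_toeoff"]), min(curve))

  # left+right event features over both sides total 22
  n_ev <- sum(vapply(joint_names(), function(j)
    length(joint_event_features(curve, j)), 0L))
  expect_equal(n_ev, 22)
})

test_that("symmetry and spatiotemporal features follow their definitions", {
  expect_equal(symmetry_feature(10, 7), 3)
  expect_equal(symmetry_feature(5, 5), 0)
  expect_true(is.na(symmetry_feature(NA, 5)))

  sp <- spatiotemporal_features(0.75, 0.75, 12 / 3.6)
  expect_length(sp, 4)
  expect_equal(unname(sp["stride_time_left"]), 0.75)
  expect_equal(unname(sp["stride_length_left"]), 2.5)
  expect_error(spatiotemporal_features(0.75, 0.75, 0), "speed")
})

test_that("full extraction yields 157 canonical values with family counts", {
  sf <- demo_features()
  expect_true(all(feature_names() %in% names(sf)))
  cat <- feature_catalogue()
  expect_equal(sum(cat$family == "biomechanical"), 43)
  expect_equal(sum(cat$family == "spatiotemporal"), 4)
  # no missing values on a clean full-sensor session
  expect_false(anyNA(sf[, feature_names()]))
})

test_that("extractor agrees with an independent brute-force oracle", {
  sim <- demo_session()
  fs <- sim$recording$sampling_rate
  runs <- detect_runs(sim$recording$pelvis_velocity, fs)
  pk <- detect_strides(sim$recording$pelvis_velocity, fs, runs[1, ])
  ics <- detect_initial_contacts(sim$recording$joints$knee_right, pk, fs)
  cycles <- segment_and_normalize(sim$recording, ics)
  sides <- vapply(cycles, `[[`, "", "side")
  rcyc <- cycles[sides == "right"]
  lcyc <- cycles[sides == "left"]
  withr::with_seed(9, idx <- sample(seq_len(min(length(rcyc), length(lcyc)) - 1), 5))
  for (k in idx) {
    got <- extract_feature_vector(rcyc[[k]], lcyc[[k]], speed = 12 / 3.6)
    want <- oracle_feature_vector(rcyc[[k]], lcyc[[k]], speed = 12 / 3.6)
    expect_equal(got[feature_names()], want[feature_names()],
                 tolerance = 1e-9)
  }
})

test_that("batch extraction equals the per-stride extractor", {
  sim <- demo_session()
  fs <- sim$recording$sampling_rate
  runs <- detect_runs(sim$recording$pelvis_velocity, fs)
  pk <- detect_strides(sim$recording$pelvis_velocity, fs, runs[2, ])
  ics <- detect_initial_contacts(sim$recording$joints$knee_right, pk, fs)
  cycles <- segment_and_normalize(sim$recording, ics)
  sides <- vapply(cycles, `[[`, "", "side")
  rcyc <- cycles[sides == "right"][1:20]
  lcyc <- cycles[sides == "left"][1:20]
  batch <- runfatigue:::extract_features_batch(rcyc, lcyc, 12 / 3.6)
  for (k in c(1, 7, 20)) {
    expect_equal(batch[k, ], extract_feature_vector(rcyc[[k]], lcyc[[k]],
                                                    12 / 3.6),
                 tolerance = 1e-12)
  }
})

test_that("statistics are scale-equivariant and order-free", {
  withr::with_seed(5, x <- stats::rnorm(150, 3, 2))
  curves <- cbind(L6_acc_mag = x, L6_gyr_pitch = x)
  base <- segment_features(make_cycle(curves), "L6")
  k <- 3.7
  scaled <- segment_features(make_cycle(k * curves), "L6")
  for (s in c("peak", "mean", "std", "iqr")) {
    expect_equal(unname(scaled[paste0("L6_acc_", s)]),
                 k * unname(base[paste0("L6_acc_", s)]))
  }
  expect_equal(scaled["L6_acc_skew"], base["L6_acc_skew"])
  expect_equal(scaled["L6_acc_kurt"], base["L6_acc_kurt"])

  withr::with_seed(6, perm <- sample(150))
  shuffled <- segment_features(
    make_cycle(cbind(L6_acc_mag = x[perm], L6_gyr_pitch = x[perm])), "L6")
  for (s in c("mean", "std", "iqr", "skew", "kurt")) {
    expect_equal(shuffled[paste0("L6_acc_", s)], base[paste0("L6_acc_", s)])
  }
})
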