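# Shared fixtures, built once per test run and cached so several test files
# can reuse the expensive ones (full synthetic sessions and cohorts).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# One full default-protocol session (13 laps of 400 m at 240 Hz).
demo_session <- function() {
  fixture("demo_session", function() {
    generate_session(
      subject_profile("S001", speed = 12, stride_time_mean = 0.75),
      fatigue_effect_model(), seed = 7)
  })
}

# Its stride-level feature table.
demo_features <- function() {
  fixture("demo_features", function() session_features(demo_session()$recording))
}

# A miniature session (short laps) for fast IO / structural tests.
mini_session <- function() {
  fixture("mini_session", function() {
    generate_session(
      subject_profile("S900", speed = 12, stride_time_mean = 0.75),
      fatigue_effect_model(), seed = 3,
      lap_length_m = 15, n_laps_run1 = 2, n_laps_run3 = 1,
      gap_s = 3, pad_s = 1.5)
  })
}

# Prepared modelling tables for the two cohort-level study conditions:
# a null cohort (effect_size = 0) and a strong-effect cohort (effect
# shifts scaled up, homogeneous across subjects).
zero_effect_table <- function() {
  fixture("zero_effect_table", function() {
    cohort_features(8, fatigue_effect_model(effect_size = 0), seed = 11)
  })
}

strong_effect_table <- function() {
  fixture("strong_effect_table", function() {
    cohort_features(8, fatigue_effect_model(effect_size = 4), seed = 11,
                    subject_effect_sd = 0.1)
  })
}

# Constructed modelling table with known class structure: `signal_sd` = 0
# makes the informative feature a perfect class indicator; large values
# drown it in noise.
constructed_table <- function(n_subjects = 4, n_per_class = 30,
                              config = c("L4", "L6"),
                              informative = "L6_acc_std",
                              signal_sd = 0.1, strengths = NULL, seed = 1) {
  withr::with_seed(seed, {
    feats <- feature_mask(config)
    do.call(rbind, lapply(seq_len(n_subjects), function(s) {
      n <- 3 * n_per_class
      lab <- factor(rep(fatigue_levels(), each = n_per_class),
                    levels = fatigue_levels())
      f <- matrix(stats::rnorm(n * length(feats)), n, length(feats),
                  dimnames = list(NULL, feats))
      if (!is.null(strengths)) {
        for (nm in names(strengths))
          f[, nm] <- strengths[[nm]] * as.integer(lab) + stats::rnorm(n)
      } else if (!is.null(informative)) {
        f[, informative] <- as.integer(lab) + stats::rnorm(n, 0, signal_sd)
      }
      cbind(data.frame(subject_id = sprintf("P%02d", s), label = lab),
            as.data.frame(f))
    }))
  })
}

# --- independent brute-force feature oracle ---------------------------
# A from-scratch re-coding of the 157-feature definitions used only to
# cross-check extract_feature_vector(): plain loops, sort-based quantiles,
# and explicit moment sums, sharing no code with the implementation.

oracle_quantile7 <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_stats <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  ss <- sum((x - mu)^2)
  sdv <- sqrt(ss / (n - 1))
  m2 <- ss / n
  if (m2 <= .Machine$double.eps * max(1, mu^2)) {
    sk <- 0; ku <- 0
  } else {
    sk <- (sum((x - mu)^3) / n) / m2^1.5
    ku <- (sum((x - mu)^4) / n) / m2^2 - 3
  }
  c(mean = mu, std = sdv,
    iqr = oracle_quantile7(x, 0.75) - oracle_quantile7(x, 0.25),
    skew = sk, kurt = ku)
}

oracle_feature_vector <- function(right_cycle, left_cycle, speed) {
  vals <- numeric(0)
  pick <- function(loc_or_joint) {
    left <- grepl("left", loc_or_joint) || loc_or_joint %in% c("L4", "L6", "L8")
    if (left) left_cycle else right_cycle
  }
  for (loc in paste0("L", 1:8)) {
    cyc <- pick(loc)
    acc <- cyc$curves[, paste0(loc, "_acc_mag")]
    gyr <- cyc$curves[, paste0(loc, "_gyr_pitch")]
    sa <- oracle_stats(acc); sg <- oracle_stats(gyr)
    v <- c(max(acc), max(gyr), sa, sg)
    names(v) <- c(paste0(loc, "_acc_peak"), paste0(loc, "_gyr_peak"),
                  paste0(loc, "_acc_", names(sa)),
                  paste0(loc, "_gyr_", names(sg)))
    vals <- c(vals, v)
  }
  for (side in c("left", "right")) {
    cyc <- if (side == "left") left_cycle else right_cycle
    tib <- cyc$curves[, paste0(if (side == "left") "L6" else "L5", "_acc_mag")]
    pel <- cyc$curves[, "L2_acc_mag"]
    vals[paste0("shock_att_", side)] <- 100 * (1 - max(pel) / max(tib))
  }
  windows <- list(
    ankle = list(ic = c("max", 0, .05), midstance = c("max", .05, .35),
                 toeoff = c("min", .30, .45)),
    knee = list(ic = c("min", 0, .05), midstance = c("max", .05, .35),
                toeoff = c("min", .30, .45), midswing = c("max", .50, .75),
                endswing = c("min", .85, 1)),
    hip = list(ic = c("max", 0, .05), toeoff = c("min", .30, .45),
               midswing = c("max", .50, .75)))
  for (jn in c("ankle_left", "ankle_right", "knee_left", "knee_right",
               "hip_left", "hip_right")) {
    cyc <- pick(jn)
    ang <- cyc$curves[, paste0(jn, "_angle")]
    n <- length(ang)
    u <- (0:(n - 1)) / n
    kind <- sub("_(left|right)$", "", jn)
    for (e in names(windows[[kind]])) {
      w <- windows[[kind]][[e]]
      seg <- ang[u >= as.numeric(w[2]) & u <= as.numeric(w[3])]
      vals[paste0(jn, "_", e)] <- if (w[1] == "max") max(seg) else min(seg)
    }
    st <- oracle_stats(ang)
    for (s in names(st)) vals[paste0(jn, "_", s)] <- st[[s]]
  }
  for (kind in c("ankle", "knee", "hip")) {
    vals[paste0(kind, "_sym_ic")] <-
      vals[paste0(kind, "_left_ic")] - vals[paste0(kind, "_right_ic")]
  }
  vals["stride_time_left"] <- left_cycle$stride_time
  vals["stride_length_left"] <- speed * left_cycle$stride_time
  vals["stride_time_right"] <- right_cycle$stride_time
  vals["stride_length_right"] <- speed * right_cycle$stride_time
  vals
}
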