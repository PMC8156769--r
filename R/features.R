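#' Acceleration magnitude
#'
#' Root-sum-of-squares of the three acceleration axes,
#' `sqrt(ax^2 + ay^2 + az^2)`, computed pointwise.
#'
#' @param ax,ay,az Numeric vectors of equal length, m/s^2.
#' @return Numeric vector, m/s^2.
#' @export
#' @examples
#' accel_magnitude(3, 4, 0)  # 5
accel_magnitude <- function(ax, ay, az) {
  if (length(ay) != length(ax) || length(az) != length(ax))
    stop("acceleration axes must have equal length", call. = FALSE)
  sqrt(ax^2 + ay^2 + az^2)
}

# The five distribution statistics shared by all "statistical" features.
# IQR uses the default type-7 quantile; skewness/kurtosis are the sample
# conventions from utils.R (0 on zero-variance input).
curve_stats <- function(x) {
  c(mean = mean(x), std = stats::sd(x),
    iqr = stats::IQR(x), skew = sample_skewness(x),
    kurt = sample_kurtosis(x))
}

#' Segment features for one location
#'
#' The 12 per-location features: peak (maximum) of the acceleration
#' magnitude, peak of the pitch angular velocity, and the mean, STD, IQR,
#' skewness and kurtosis of each of the two curves.
#'
#' @param cycle A `gait_cycle` from [segment_and_normalize()].
#' @param location Location code (L1..L8).
#' @return Named numeric vector of 12 values (names follow the canonical
#'   catalogue, e.g. `L6_acc_peak`).
#' @export
segment_features <- function(cycle, location) {
  assert_location_codes(location)
  acc <- cycle$curves[, paste0(location, "_acc_mag")]
  gyr <- cycle$curves[, paste0(location, "_gyr_pitch")]
  sa <- curve_stats(acc); sg <- curve_stats(gyr)
  stats::setNames(
    c(max(acc), max(gyr), sa, sg),
    c(paste0(location, "_acc_peak"), paste0(location, "_gyr_peak"),
      paste0(location, "_acc_", names(sa)),
      paste0(location, "_gyr_", names(sg))))
}

#' Shock attenuation between tibia and pelvis
#'
#' `SA = (1 - peak_pelvis / peak_tibia) * 100` (percent). Values can be
#' negative when the pelvis peak exceeds the tibial peak. Undefined (NA)
#' when the tibial peak is zero.
#'
#' @param tibia_accel_mag,pelvis_accel_mag Numeric curves, m/s^2.
#' @return Percent, scalar.
#' @export
shock_attenuation <- function(tibia_accel_mag, pelvis_accel_mag) {
  pt <- max(tibia_accel_mag)
  pp <- max(pelvis_accel_mag)
  if (pt == 0) return(NA_real_)
  (1 - pp / pt) * 100
}

#' Joint-angle event extrema
#'
#' Extremum of the sagittal joint angle inside fixed percent-of-cycle
#' windows (see [joint_event_windows()]): 3 events for the ankle and hip, 5
#' for the knee; maxima for flexion-type events, minima for extension-type
#' events.
#'
#' @param angle_curve Numeric vector of `n_points` (the normalized cycle).
#' @param joint_name One of [joint_names()].
#' @return Named numeric vector (e.g. `knee_left_ic`, ...).
#' @export
joint_event_features <- function(angle_curve, joint_name) {
  if (!joint_name %in% joint_names())
    stop("unknown joint: ", joint_name, call. = FALSE)
  kind <- sub("_(left|right)$", "", joint_name)
  ev <- joint_event_windows()
  ev <- ev[ev$joint == kind, , drop = FALSE]
  n <- length(angle_curve)
  u <- (seq_len(n) - 1) / n
  vals <- vapply(seq_len(nrow(ev)), function(i) {
    w <- angle_curve[u >= ev$lo[i] & u <= ev$hi[i]]
    if (ev$extremum[i] == "max") max(w) else min(w)
  }, numeric(1))
  stats::setNames(vals, paste0(joint_name, "_", ev$event))
}

#' Left-right symmetry feature
#'
#' Signed left-minus-right difference of the initial-contact event feature
#' at one joint level, in degrees.
#'
#' @param left_peak,right_peak IC-event angles, degrees.
#' @return Degrees (NA if either side is missing).
#' @export
symmetry_feature <- function(left_peak, right_peak) {
  if (is.null(left_peak) || is.null(right_peak) ||
      is.na(left_peak) || is.na(right_peak)) return(NA_real_)
  left_peak - right_peak
}

#' Spatiotemporal features
#'
#' Per side: stride time (the side's IC-to-IC interval, s) and stride
#' length (nominal speed x stride time, m).
#'
#' @param stride_time_left,stride_time_right Stride times, s.
#' @param speed Running speed, m/s (> 0).
#' @return Named numeric vector of 4 values.
#' @export
spatiotemporal_features <- function(stride_time_left, stride_time_right,
                                    speed) {
  if (!is.numeric(speed) || speed <= 0)
    stop("speed must be > 0", call. = FALSE)
  c(stride_time_left = stride_time_left,
    stride_length_left = speed * stride_time_left,
    stride_time_right = stride_time_right,
    stride_length_right = speed * stride_time_right)
}

#' Extract the full 157-feature vector for one stride
#'
#' Combines a right-side and a left-side gait cycle of the same stride:
#' side-specific curves (thigh/tibia/foot segments, joints) are read from
#' the cycle of their own side, trunk segments (sternum, pelvis) from the
#' right cycle, and shock attenuation pairs each tibia with the pelvis
#' curve of the same cycle. Features whose curves are absent are emitted as
#' NA; an error is raised only if more than `max_missing_frac` of the
#' catalogue is missing.
#'
#' @param right_cycle,left_cycle `gait_cycle` objects from
#'   [segment_and_normalize()].
#' @param speed Nominal running speed, m/s.
#' @param max_missing_frac Error threshold on the missing fraction.
#' @return Named numeric vector of 157 features in canonical order.
#' @export
extract_feature_vector <- function(right_cycle, left_cycle, speed,
                                   max_missing_frac = 0.1) {
  cat_names <- feature_names()
  vals <- stats::setNames(rep(NA_real_, length(cat_names)), cat_names)

  cyc_for <- function(loc_or_joint) {
    if (grepl("left", loc_or_joint) ||
        loc_or_joint %in% c("L4", "L6", "L8")) left_cycle else right_cycle
  }
  has_curve <- function(cyc, col) col %in% colnames(cyc$curves)

  for (loc in names(location_codes())) {
    cyc <- cyc_for(loc)
    if (has_curve(cyc, paste0(loc, "_acc_mag")) &&
        has_curve(cyc, paste0(loc, "_gyr_pitch"))) {
      sf <- segment_features(cyc, loc)
      vals[names(sf)] <- sf
    }
  }

  for (side in c("left", "right")) {
    cyc <- if (side == "left") left_cycle else right_cycle
    tib <- paste0(if (side == "left") "L6" else "L5", "_acc_mag")
    if (has_curve(cyc, tib) && has_curve(cyc, "L2_acc_mag")) {
      vals[paste0("shock_att_", side)] <-
        shock_attenuation(cyc$curves[, tib], cyc$curves[, "L2_acc_mag"])
    }
  }

  for (jn in joint_names()) {
    cyc <- cyc_for(jn)
    col <- paste0(jn, "_angle")
    if (has_curve(cyc, col)) {
      curve <- cyc$curves[, col]
      je <- joint_event_features(curve, jn)
      vals[names(je)] <- je
      st <- curve_stats(curve)
      vals[paste0(jn, "_", names(st))] <- st
    }
  }

  for (kind in c("ankle", "knee", "hip")) {
    vals[paste0(kind, "_sym_ic")] <- symmetry_feature(
      vals[[paste0(kind, "_left_ic")]], vals[[paste0(kind, "_right_ic")]])
  }

  vals[c("stride_time_left", "stride_length_left",
         "stride_time_right", "stride_length_right")] <-
    spatiotemporal_features(left_cycle$stride_time,
                            right_cycle$stride_time, speed)[
      c("stride_time_left", "stride_length_left",
        "stride_time_right", "stride_length_right")]

  miss <- mean(is.na(vals))
  if (miss > max_missing_frac)
    stop(sprintf("%.0f%% of features missing (limit %.0f%%)",
                 100 * miss, 100 * max_missing_frac), call. = FALSE)
  vals
}

# --- batch extraction --------------------------------------------------
# Vectorized twin of extract_feature_vector(): features for all paired
# cycles at once, operating on n_points x n_cycles matrices per signal.
# Numerically equivalent to the per-cycle path (tested against it).

# column-wise mean/std/iqr/skew/kurt for an n x N matrix, matching
# curve_stats() including the type-7 IQR and zero-variance conventions
col_curve_stats <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  c2 <- sweep(m, 2, mu)
  m2 <- colMeans(c2^2)
  std <- sqrt(colSums(c2^2) / (n - 1))
  ms <- matrix(m[order(col(m), m)], n)   # column-wise sort in one pass
  q7 <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    ms[lo, ] + (h - lo) * (ms[pmin(lo + 1, n), ] - ms[lo, ])
  }
  iqr <- q7(0.75) - q7(0.25)
  degenerate <- m2 <= .Machine$double.eps * pmax(1, mu^2)
  skew <- ifelse(degenerate, 0, colMeans(c2^3) / m2^1.5)
  kurt <- ifelse(degenerate, 0, colMeans(c2^4) / m2^2 - 3)
  list(mean = mu, std = std, iqr = iqr, skew = skew, kurt = kurt)
}

col_max <- function(m) apply(m, 2, max)
col_min <- function(m) apply(m, 2, min)

extract_features_batch <- function(rcyc, lcyc, speed) {
  stopifnot(length(rcyc) == length(lcyc))
  n_pairs <- length(rcyc)
  out <- matrix(NA_real_, n_pairs, length(feature_names()),
                dimnames = list(NULL, feature_names()))
  stack <- function(cycles, col) {
    vapply(cycles, function(c) c$curves[, col], numeric(nrow(rcyc[[1]]$curves)))
  }
  cyc_set <- function(key) {
    if (grepl("left", key) || key %in% c("L4", "L6", "L8")) lcyc else rcyc
  }

  pelvis_peak <- list(right = col_max(stack(rcyc, "L2_acc_mag")),
                      left = col_max(stack(lcyc, "L2_acc_mag")))
  for (loc in names(location_codes())) {
    cycles <- cyc_set(loc)
    acc <- stack(cycles, paste0(loc, "_acc_mag"))
    gyr <- stack(cycles, paste0(loc, "_gyr_pitch"))
    out[, paste0(loc, "_acc_peak")] <- col_max(acc)
    out[, paste0(loc, "_gyr_peak")] <- col_max(gyr)
    sa <- col_curve_stats(acc); sg <- col_curve_stats(gyr)
    for (s in names(sa)) {
      out[, paste0(loc, "_acc_", s)] <- sa[[s]]
      out[, paste0(loc, "_gyr_", s)] <- sg[[s]]
    }
    if (loc %in% c("L5", "L6")) {
      side <- if (loc == "L6") "left" else "right"
      pt <- col_max(acc)
      out[, paste0("shock_att_", side)] <-
        ifelse(pt == 0, NA_real_, (1 - pelvis_peak[[side]] / pt) * 100)
    }
  }

  ev <- joint_event_windows()
  n_pts <- nrow(rcyc[[1]]$curves)
  u <- (seq_len(n_pts) - 1) / n_pts
  for (jn in joint_names()) {
    cycles <- cyc_set(jn)
    ang <- stack(cycles, paste0(jn, "_angle"))
    kind <- sub("_(left|right)$", "", jn)
    evj <- ev[ev$joint == kind, , drop = FALSE]
    for (i in seq_len(nrow(evj))) {
      w <- ang[u >= evj$lo[i] & u <= evj$hi[i], , drop = FALSE]
      out[, paste0(jn, "_", evj$event[i])] <-
        if (evj$extremum[i] == "max") col_max(w) else col_min(w)
    }
    st <- col_curve_stats(ang)
    for (s in names(st)) out[, paste0(jn, "_", s)] <- st[[s]]
  }

  for (kind in c("ankle", "knee", "hip")) {
    out[, paste0(kind, "_sym_ic")] <-
      out[, paste0(kind, "_left_ic")] - out[, paste0(kind, "_right_ic")]
  }

  st_l <- vapply(lcyc, `[[`, numeric(1), "stride_time")
  st_r <- vapply(rcyc, `[[`, numeric(1), "stride_time")
  out[, "stride_time_left"] <- st_l
  out[, "stride_length_left"] <- speed * st_l
  out[, "stride_time_right"] <- st_r
  out[, "stride_length_right"] <- speed * st_r
  out
}

#' Segment a session and extract its stride-level feature table
#'
#' Runs the full front end on one recording: run detection, stride-event
#' detection, initial contacts, 150-point cycle normalization, and
#' extraction of the 157-feature vector per stride. Right and left cycles
#' are paired by stride: the left cycle starting within the right cycle's
#' span. Each row carries subject, run, lap, cumulative distance (from the
#' nominal speed) and the fatigue-condition label.
#'
#' @param rec A [session_recording()].
#' @return data.frame: metadata columns (`subject_id`, `run`, `lap`,
#'   `lap_in_run`, `start`, `distance_m`, `label`) plus the 157 features.
#' @export
session_features <- function(rec) {
  fs <- rec$sampling_rate
  v <- rec$nominal_speed / 3.6
  runs <- detect_runs(rec$pelvis_velocity, fs)
  run_rows <- lapply(seq_len(nrow(runs)), function(r) {
    bounds <- runs[r, ]
    peaks <- detect_strides(rec$pelvis_velocity, fs, bounds)
    ics <- detect_initial_contacts(rec$joints$knee_right, peaks, fs)
    cycles <- segment_and_normalize(rec, ics)
    if (length(cycles) == 0L) return(NULL)
    sides <- vapply(cycles, `[[`, character(1), "side")
    rcyc <- cycles[sides == "right"]
    lcyc <- cycles[sides == "left"]
    if (length(rcyc) == 0L || length(lcyc) == 0L) return(NULL)
    lstart <- vapply(lcyc, `[[`, numeric(1), "start")
    rstart <- vapply(rcyc, `[[`, numeric(1), "start")
    rend <- vapply(rcyc, `[[`, numeric(1), "end")

    # pair each right cycle with the left cycle starting inside its span
    pair <- findInterval(lstart, rstart)
    pair_of_right <- rep(NA_integer_, length(rcyc))
    ok <- pair >= 1L & lstart < rend[pmax(pair, 1L)]
    pair_of_right[pair[ok]] <- which(ok)

    keep <- which(!is.na(pair_of_right))
    if (length(keep) == 0L) return(NULL)
    fmat <- extract_features_batch(rcyc[keep], lcyc[pair_of_right[keep]],
                                   speed = v)

    starts <- rstart[keep]
    lap_idx <- findInterval(starts, rec$laps$start)
    in_lap <- lap_idx >= 1L & starts < rec$laps$end[pmax(lap_idx, 1L)]
    keep <- keep[in_lap]; fmat <- fmat[in_lap, , drop = FALSE]
    lap_idx <- lap_idx[in_lap]; starts <- starts[in_lap]
    if (length(keep) == 0L) return(NULL)

    run_id <- rec$laps$run[lap_idx]
    run_start <- vapply(run_id, function(rr)
      min(rec$laps$start[rec$laps$run == rr]), numeric(1))
    run_offset <- vapply(run_id, function(rr)
      (min(rec$laps$lap[rec$laps$run == rr]) - 1) * rec$lap_length_m,
      numeric(1))
    lap_in_run <- rec$laps$lap_in_run[lap_idx]
    meta <- data.frame(
      subject_id = rec$subject_id, run = run_id,
      lap = rec$laps$lap[lap_idx], lap_in_run = lap_in_run,
      start = starts,
      distance_m = run_offset + (starts - run_start) / fs * v,
      label = mapply(assign_label, run_id, lap_in_run))
    cbind(meta, as.data.frame(fmat))
  })
  out <- do.call(rbind, run_rows)
  rownames(out) <- NULL
  out
}
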