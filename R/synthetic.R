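#' Subject profile for the session generator
#'
#' Describes one synthetic runner: constant running speed, stride timing,
#' baseline waveform amplitudes, and per-family multipliers that scale how
#' strongly the fatigue effect model expresses itself in this subject
#' (fatigue responses are strongly subject-dependent, so both magnitude and
#' — if the cohort generator is configured to allow it — direction vary
#' between subjects).
#'
#' @param subject_id Character scalar.
#' @param speed Running speed in km/h (> 0).
#' @param stride_time_mean Mean stride (full gait cycle) duration in
#'   seconds, within `[0.5, 1.2]`.
#' @param stride_time_sd Baseline stride-to-stride SD of stride time, s.
#' @param amplitudes Named list of baseline waveform amplitudes; defaults
#'   from [default_amplitudes()] (peak accelerations in m/s^2, angular
#'   velocities in deg/s, joint amplitudes in degrees).
#' @param effect_multipliers Named numeric vector, one per fatigue-effect
#'   family (see [fatigue_effect_model()]); 1 = the nominal effect.
#'
#' @return Object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, speed = 10.6,
                            stride_time_mean = 0.75,
                            stride_time_sd = 0.012,
                            amplitudes = default_amplitudes(),
                            effect_multipliers = NULL) {
  if (!is.numeric(speed) || speed <= 0)
    stop("speed must be > 0", call. = FALSE)
  if (stride_time_mean < 0.5 || stride_time_mean > 1.2)
    stop("stride_time_mean must lie in [0.5, 1.2] s", call. = FALSE)
  if (stride_time_sd < 0) stop("stride_time_sd must be >= 0", call. = FALSE)
  fams <- effect_families()
  if (is.null(effect_multipliers))
    effect_multipliers <- stats::setNames(rep(1, length(fams)), fams)
  if (!all(fams %in% names(effect_multipliers)))
    stop("effect_multipliers must cover all effect families", call. = FALSE)
  structure(list(subject_id = as.character(subject_id), speed = speed,
                 stride_time_mean = stride_time_mean,
                 stride_time_sd = stride_time_sd,
                 amplitudes = amplitudes,
                 effect_multipliers = effect_multipliers),
            class = "subject_profile")
}

#' Baseline waveform amplitudes
#'
#' Defaults chosen to resemble recreational over-ground running: tibial
#' impact peaks of several g, pelvis/sternum peaks of 2-4 g, knee flexion
#' to ~100 degrees in swing, hip excursion of ~40 degrees, and segment
#' pitch angular velocities of a few hundred deg/s.
#'
#' @return Named list of amplitudes.
#' @export
default_amplitudes <- function() {
  list(
    acc_tibia = 60,      # impact amplitude above rest, m/s^2
    acc_foot = 90,
    acc_thigh = 30,
    acc_pelvis = 22,
    acc_sternum = 15,
    gyr_tibia = 420,     # pitch angular velocity amplitude, deg/s
    gyr_foot = 600,
    gyr_thigh = 250,
    gyr_pelvis = 60,
    gyr_sternum = 40,
    knee_ic = 20,        # knee angle at IC (baseline offset), deg
    knee_midstance = 27, # bump heights above baseline, deg
    knee_midswing = 77,
    hip_ic = 22,
    hip_extension = 18,
    hip_midswing = 20,
    ankle_ic = 5,
    ankle_midstance = 15,
    ankle_toeoff = 20,
    vel_dip = 0.38       # right-step dip depth of pelvis velocity, m/s
  )
}

effect_families <- function() {
  c("pta", "psa", "tibia_gyr_std", "hip_ic", "knee_flex", "stride_time_sd")
}

#' Fatigue effect model
#'
#' Per-condition shifts applied to the stride waveform parameters, scaled by
#' a global `effect_size` and by each subject's per-family multipliers.
#' Families follow reported fatigue responses in running: peak tibial
#' acceleration (PTA) and peak sacral/pelvis acceleration (PSA) increase,
#' the variability of tibial pitch angular velocity increases, hip flexion
#' at initial contact decreases, knee flexion extrema shift, and
#' stride-time variability grows. With `effect_size = 0` the three
#' conditions share one generating distribution.
#'
#' @param effect_size Global scalar multiplying every shift (0 = null model).
#' @param mild,heavy Named lists of shifts at the mild/heavy condition:
#'   `pta`, `psa`, `tibia_gyr_std`, `stride_time_sd` are relative
#'   (fractional) changes; `hip_ic` and `knee_flex` are additive, degrees.
#' @param noise Named list of white measurement-noise SDs: `acc` (m/s^2),
#'   `gyr` (deg/s), `angle` (deg), `vel` (m/s).
#' @param stride_amp_cv Stride-to-stride coefficient of variation of the
#'   waveform amplitudes (biological variability).
#'
#' @return Object of class `fatigue_effect_model`.
#' @export
fatigue_effect_model <- function(effect_size = 1,
                                 mild = list(pta = 0.05, psa = 0.04,
                                             tibia_gyr_std = 0.06,
                                             hip_ic = -2, knee_flex = 1.5,
                                             stride_time_sd = 0.3),
                                 heavy = list(pta = 0.10, psa = 0.08,
                                              tibia_gyr_std = 0.14,
                                              hip_ic = -4, knee_flex = 3,
                                              stride_time_sd = 0.7),
                                 noise = list(acc = 0.8, gyr = 4,
                                              angle = 0.3, vel = 0.04),
                                 stride_amp_cv = 0.03) {
  fams <- effect_families()
  for (cond in list(mild = mild, heavy = heavy)) {
    bad <- setdiff(names(cond), fams)
    if (length(bad) > 0L)
      stop("invalid effect-model condition key(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  full <- function(x) {
    out <- stats::setNames(rep(0, length(fams)), fams)
    out[names(x)] <- unlist(x)
    out
  }
  structure(list(effect_size = effect_size, mild = full(mild),
                 heavy = full(heavy), noise = noise,
                 stride_amp_cv = stride_amp_cv),
            class = "fatigue_effect_model")
}

# Shift for one family at a continuous fatigue level in [0, 2]
# (0 = fresh, 1 = mild, 2 = heavy), linear between the condition anchors.
shift_at_level <- function(effects, family, level) {
  m <- effects$mild[[family]]
  h <- effects$heavy[[family]]
  raw <- ifelse(level <= 1, level * m, m + (level - 1) * (h - m))
  raw * effects$effect_size
}

# Continuous fatigue level along the session. Run 1 (10 laps): 0 over laps
# 1-4, a smooth ramp over laps 5-7, 1 (mild) over laps 8-10, interpolated
# linearly between lap midpoints so the level also drifts smoothly within a
# lap. Run 3 (post fatiguing protocol): 2 (heavy) throughout.
fatigue_level <- function(distance_m, run, lap_length_m = 400) {
  lvl <- numeric(length(distance_m))
  lvl[run == 3] <- 2
  r1 <- run == 1
  if (any(r1)) {
    mids <- (seq_len(10) - 0.5) * lap_length_m
    y <- c(0, 0, 0, 0, 0.25, 0.5, 0.75, 1, 1, 1)
    lvl[r1] <- stats::approx(mids, y, xout = distance_m[r1], rule = 2)$y
  }
  lvl
}

# Fixed per-segment unit direction cosines used to split the acceleration
# magnitude template over the x/y/z axes (so that |a| equals the template
# exactly before measurement noise).
segment_axis_split <- function() {
  u <- c(x = 0.30, y = 0.20, z = 0.9327379)  # unit norm
  lapply(stats::setNames(names(location_codes()), names(location_codes())),
         function(loc) u)
}

# --- stride timeline ---------------------------------------------------

# Draw consecutive strides covering one run of `run_length_m` metres at
# constant speed. Returns per-stride duration, sample count, start distance
# and fatigue level (evaluated at the stride midpoint).
draw_stride_timeline <- function(profile, effects, fs, run, run_offset_m,
                                 run_length_m, lap_length_m) {
  v <- profile$speed / 3.6
  d <- run_offset_m
  durs <- numeric(0); dists <- numeric(0); levels <- numeric(0)
  repeat {
    lev <- fatigue_level(d + v * profile$stride_time_mean / 2, run,
                         lap_length_m)
    sd_mult <- 1 + shift_at_level(effects, "stride_time_sd", lev) *
      profile$effect_multipliers[["stride_time_sd"]]
    Tk <- rnorm_min(1, profile$stride_time_mean,
                    profile$stride_time_sd * max(sd_mult, 0), 0.45)
    durs <- c(durs, Tk); dists <- c(dists, d); levels <- c(levels, lev)
    d <- d + v * Tk
    if (d >= run_offset_m + run_length_m) break
  }
  data.frame(duration = durs, n = pmax(2L, as.integer(round(durs * fs))),
             start_dist = dists, level = levels)
}

# --- waveform synthesis ------------------------------------------------

# Build all streams for one run from its stride timeline. Phase u runs
# 0 -> 1 over each stride with u = 0 at the RIGHT initial contact; left-side
# signals are the same templates shifted by half a cycle.
synthesize_run <- function(strides, profile, effects, fs) {
  amp <- profile$amplitudes
  mult <- profile$effect_multipliers
  cv <- effects$stride_amp_cv
  ns <- strides$n
  total <- sum(ns)
  idx <- rep(seq_len(nrow(strides)), ns)
  u <- unlist(lapply(ns, function(n) (seq_len(n) - 1) / n), use.names = FALSE)

  lev <- strides$level
  jit <- function() rep(1 + stats::rnorm(nrow(strides), 0, cv), ns)
  per_stride <- function(x) rep(rep_len(x, length(ns)), ns)

  sh <- function(fam) shift_at_level(effects, fam, lev) * mult[[fam]]

  # per-sample amplitude tracks (stride-constant, with biological jitter)
  a_pta  <- per_stride(amp$acc_tibia * (1 + sh("pta"))) * jit()
  a_psa  <- per_stride(amp$acc_pelvis * (1 + sh("psa"))) * jit()
  a_ster <- per_stride(amp$acc_sternum * (1 + 0.5 * sh("psa"))) * jit()
  a_foot <- per_stride(amp$acc_foot) * jit()
  a_thi  <- per_stride(amp$acc_thigh) * jit()
  g_tib  <- per_stride(amp$gyr_tibia * (1 + sh("tibia_gyr_std"))) * jit()
  g_foot <- per_stride(amp$gyr_foot) * jit()
  g_thi  <- per_stride(amp$gyr_thigh) * jit()
  g_pel  <- per_stride(amp$gyr_pelvis) * jit()
  g_ster <- per_stride(amp$gyr_sternum) * jit()
  hip_ic <- per_stride(amp$hip_ic + sh("hip_ic")) * jit()
  knee_ms <- per_stride(amp$knee_midstance + sh("knee_flex")) * jit()
  knee_sw <- per_stride(amp$knee_midswing + sh("knee_flex")) * jit()
  ankle_ms <- per_stride(amp$ankle_midstance) * jit()
  dip <- per_stride(amp$vel_dip) * jit()

  bump <- function(c, w) phase_bump(u, c, w)
  # mirrored phase for left-side signals (templates shifted half a cycle)
  ul <- u + 0.5 - floor(u + 0.5)
  bump_l <- function(c, w) phase_bump(ul, c, w)

  # --- joint angles (deg, flexion positive); the narrow negative bump at
  # u = 0 plants a sharp knee-extension minimum exactly at initial contact,
  # the landmark the IC detector keys on ---
  joints <- list(
    knee_right = amp$knee_ic + knee_ms * bump(0.20, 0.07) +
      knee_sw * bump(0.625, 0.09) - 4 * bump(0.0, 0.02),
    knee_left = amp$knee_ic + knee_ms * bump_l(0.20, 0.07) +
      knee_sw * bump_l(0.625, 0.09) - 4 * bump_l(0.0, 0.02),
    hip_right = 5 + hip_ic * bump(0.02, 0.10) -
      amp$hip_extension * bump(0.38, 0.10) +
      amp$hip_midswing * bump(0.70, 0.12),
    hip_left = 5 + hip_ic * bump_l(0.02, 0.10) -
      amp$hip_extension * bump_l(0.38, 0.10) +
      amp$hip_midswing * bump_l(0.70, 0.12),
    ankle_right = amp$ankle_ic * bump(0.02, 0.03) +
      ankle_ms * bump(0.18, 0.08) - amp$ankle_toeoff * bump(0.40, 0.06),
    ankle_left = amp$ankle_ic * bump_l(0.02, 0.03) +
      ankle_ms * bump_l(0.18, 0.08) - amp$ankle_toeoff * bump_l(0.40, 0.06)
  )

  # --- acceleration magnitudes (m/s^2): impact spike + active peak ---
  g0 <- 9.81
  acc_mag <- list(
    L5 = g0 + a_pta * (bump(0.03, 0.015) + 0.35 * bump(0.25, 0.06)),
    L6 = g0 + a_pta * (bump_l(0.03, 0.015) + 0.35 * bump_l(0.25, 0.06)),
    L7 = g0 + a_foot * (bump(0.035, 0.02) + 0.25 * bump(0.6, 0.05)),
    L8 = g0 + a_foot * (bump_l(0.035, 0.02) + 0.25 * bump_l(0.6, 0.05)),
    L3 = g0 + a_thi * (bump(0.05, 0.03) + 0.4 * bump(0.35, 0.08)),
    L4 = g0 + a_thi * (bump_l(0.05, 0.03) + 0.4 * bump_l(0.35, 0.08)),
    # trunk segments feel both steps; the contralateral impact is damped
    L2 = g0 + a_psa * (bump(0.03, 0.02) + 0.85 * bump(0.53, 0.02)),
    L1 = g0 + a_ster * (bump(0.04, 0.025) + 0.85 * bump(0.54, 0.025))
  )

  # --- pitch angular velocities (deg/s) ---
  two_pi <- 2 * pi
  gyr_pitch <- list(
    L5 = g_tib * (sin(two_pi * (u - 0.12)) + 0.8 * bump(0.07, 0.03)),
    L6 = g_tib * (sin(two_pi * (ul - 0.12)) + 0.8 * bump_l(0.07, 0.03)),
    L7 = g_foot * (sin(two_pi * (u - 0.05)) + 0.9 * bump(0.62, 0.05)),
    L8 = g_foot * (sin(two_pi * (ul - 0.05)) + 0.9 * bump_l(0.62, 0.05)),
    L3 = g_thi * sin(two_pi * (u - 0.2)),
    L4 = g_thi * sin(two_pi * (ul - 0.2)),
    L2 = g_pel * sin(2 * two_pi * u),
    L1 = g_ster * sin(2 * two_pi * (u - 0.1))
  )

  # --- sagittal pelvis velocity: one downward dip per step, the
  #     contralateral (left-step) dip much shallower so stride events are
  #     detectable as the dominant per-stride minima ---
  v <- profile$speed / 3.6
  velocity <- v - dip * bump(0.02, 0.05) - 0.25 * dip * bump(0.52, 0.05) +
    0.03 * v * sin(2 * two_pi * u)

  list(joints = joints, acc_mag = acc_mag, gyr_pitch = gyr_pitch,
       velocity = velocity, u = u, stride_index = idx, total = total)
}

# Streams for a standing (non-running) block of `n` samples.
standing_block <- function(n, profile) {
  amp <- profile$amplitudes
  joints <- list(knee_right = rep(25, n), knee_left = rep(25, n),
                 hip_right = rep(8, n), hip_left = rep(8, n),
                 ankle_right = rep(0, n), ankle_left = rep(0, n))
  acc_mag <- lapply(stats::setNames(nm = names(location_codes())),
                    function(loc) rep(9.81, n))
  gyr_pitch <- lapply(stats::setNames(nm = names(location_codes())),
                      function(loc) rep(0, n))
  list(joints = joints, acc_mag = acc_mag, gyr_pitch = gyr_pitch,
       velocity = rep(0, n), total = n)
}

#' Generate one synthetic running session
#'
#' Emulates the study protocol: a first run of 10 laps of 400 m at the
#' subject's constant speed, a standing gap where the (variable-length,
#' excluded) fatiguing run would be, and a third run of 3 laps, all sampled
#' at `fs` Hz. Strides are built from closed-form waveform templates (sums
#' of periodic Gaussian bumps and sinusoids) carrying the named extrema the
#' feature set measures; fatigue shifts are applied per stride as a smooth
#' function of distance (see [fatigue_level()]). The sagittal pelvis
#' velocity dips once per step, with the right-step dip dominant.
#'
#' @param profile A [subject_profile()].
#' @param effects A [fatigue_effect_model()].
#' @param seed Integer seed; the same seed reproduces the session exactly.
#' @param fs Sampling rate, Hz.
#' @param lap_length_m Lap length, m.
#' @param n_laps_run1,n_laps_run3 Laps in the first/third run.
#' @param gap_s Standing gap between the runs, s.
#' @param pad_s Standing padding before/after the session, s.
#'
#' @return A list of class `session_sim` with elements `recording` (a
#'   [session_recording()]) and `truth` (ground truth: per-stride table with
#'   start/end samples, lap and fatigue level; right/left initial-contact
#'   sample indices; pelvis-dip indices; run sample spans; per-lap condition).
#' @export
generate_session <- function(profile, effects = fatigue_effect_model(),
                             seed = 1, fs = 240, lap_length_m = 400,
                             n_laps_run1 = 10, n_laps_run3 = 3,
                             gap_s = 30, pad_s = 5) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(effects, "fatigue_effect_model"))
  with_local_seed(seed, {
    v <- profile$speed / 3.6
    run1_len <- n_laps_run1 * lap_length_m
    run3_len <- n_laps_run3 * lap_length_m

    st1 <- draw_stride_timeline(profile, effects, fs, run = 1,
                                run_offset_m = 0, run_length_m = run1_len,
                                lap_length_m = lap_length_m)
    st3 <- draw_stride_timeline(profile, effects, fs, run = 3,
                                run_offset_m = run1_len,
                                run_length_m = run3_len,
                                lap_length_m = lap_length_m)
    run1 <- synthesize_run(st1, profile, effects, fs)
    run3 <- synthesize_run(st3, profile, effects, fs)

    n_pad <- as.integer(round(pad_s * fs))
    n_gap <- as.integer(round(gap_s * fs))
    pad1 <- standing_block(n_pad, profile)
    gap <- standing_block(n_gap, profile)
    pad2 <- standing_block(n_pad, profile)

    blocks <- list(pad1, run1, gap, run3, pad2)
    cat_stream <- function(pick) {
      unlist(lapply(blocks, pick), use.names = FALSE)
    }
    noise <- effects$noise
    n_total <- sum(vapply(blocks, `[[`, integer(1) + 0, "total"))

    joints <- lapply(stats::setNames(nm = joint_names()), function(jn) {
      cat_stream(function(b) b$joints[[jn]]) +
        stats::rnorm(n_total, 0, noise$angle)
    })
    split <- segment_axis_split()
    segments <- lapply(stats::setNames(nm = names(location_codes())),
                       function(loc) {
      mag <- cat_stream(function(b) b$acc_mag[[loc]])
      gyr_y <- cat_stream(function(b) b$gyr_pitch[[loc]])
      d <- split[[loc]]
      acc <- cbind(x = mag * d[["x"]] + stats::rnorm(n_total, 0, noise$acc),
                   y = mag * d[["y"]] + stats::rnorm(n_total, 0, noise$acc),
                   z = mag * d[["z"]] + stats::rnorm(n_total, 0, noise$acc))
      gyr <- cbind(x = 0.12 * gyr_y + stats::rnorm(n_total, 0, noise$gyr),
                   y = gyr_y + stats::rnorm(n_total, 0, noise$gyr),
                   z = -0.08 * gyr_y + stats::rnorm(n_total, 0, noise$gyr))
      list(acc = acc, gyr = gyr)
    })
    velocity <- cat_stream(function(b) b$velocity) +
      stats::rnorm(n_total, 0, noise$vel)

    # --- sample bookkeeping ---
    run1_start <- n_pad + 1L
    run1_end <- run1_start + run1$total          # half-open
    run3_start <- run1_end + n_gap
    run3_end <- run3_start + run3$total

    stride_table <- function(st, run_start, run) {
      start <- run_start + c(0L, cumsum(st$n[-nrow(st)]))
      data.frame(run = run, start = start, end = start + st$n,
                 n = st$n, duration = st$duration,
                 start_dist = st$start_dist, level = st$level,
                 lap = floor(st$start_dist / lap_length_m) + 1L)
    }
    tr1 <- stride_table(st1, run1_start, 1L)
    tr3 <- stride_table(st3, run3_start, 3L)
    strides <- rbind(tr1, tr3)
    strides$lap <- pmin(strides$lap, n_laps_run1 + n_laps_run3)

    # lap start samples: locate the stride containing each lap-start
    # distance and interpolate within it
    lap_start_sample <- function(target_d, tr) {
      k <- findInterval(target_d, tr$start_dist)
      k <- pmax(k, 1L)
      frac <- (target_d - tr$start_dist[k]) / (v * tr$duration[k])
      as.integer(tr$start[k] + round(pmin(pmax(frac, 0), 1) * tr$n[k]))
    }
    laps1 <- lap_start_sample((seq_len(n_laps_run1) - 1) * lap_length_m, tr1)
    laps3 <- lap_start_sample(run1_len +
                                (seq_len(n_laps_run3) - 1) * lap_length_m,
                              tr3)
    lap_tbl <- data.frame(
      lap = seq_len(n_laps_run1 + n_laps_run3),
      run = c(rep(1L, n_laps_run1), rep(3L, n_laps_run3)),
      lap_in_run = c(seq_len(n_laps_run1), seq_len(n_laps_run3)),
      start = c(laps1, laps3),
      end = c(laps1[-1], run1_end, laps3[-1], run3_end))

    rec <- session_recording(
      subject_id = profile$subject_id, sampling_rate = fs,
      segments = segments, joints = joints, pelvis_velocity = velocity,
      laps = lap_tbl, nominal_speed = profile$speed,
      lap_length_m = lap_length_m)

    right_ics <- strides$start
    left_ics <- strides$start + as.integer(round(0.5 * strides$n))
    dip_idx <- strides$start + as.integer(round(0.02 * strides$n))
    truth <- list(
      strides = strides,
      right_ics = right_ics, left_ics = left_ics,
      stride_peaks = dip_idx,
      run_bounds = rbind(c(run1_start, run1_end), c(run3_start, run3_end)),
      lap_conditions = data.frame(
        lap = lap_tbl$lap, run = lap_tbl$run,
        lap_in_run = lap_tbl$lap_in_run,
        condition = mapply(assign_label, lap_tbl$run, lap_tbl$lap_in_run)))
    structure(list(recording = rec, truth = truth), class = "session_sim")
  })
}

#' Generate a synthetic cohort
#'
#' Draws `n_subjects` subject profiles around the study cohort's
#' characteristics (speeds near 10.6 +/- 1.4 km/h, stride times near
#' 0.75 s) and generates one full session per subject. Per-subject effect
#' multipliers are drawn with SD `subject_effect_sd` around 1, so effect
#' magnitude (and, for large SDs, direction) varies between subjects.
#'
#' @param n_subjects Number of subjects (>= 2; study default 8).
#' @param effects A [fatigue_effect_model()] shared by the cohort.
#' @param seed Master seed; per-subject seeds are derived deterministically.
#' @param subject_effect_sd SD of the per-family effect multipliers.
#' @param ... Passed on to [generate_session()] (e.g. `fs`, `gap_s`).
#'
#' @return List of `session_sim` objects (one per subject, each with
#'   `$recording` and `$truth`).
#' @export
generate_cohort <- function(n_subjects = 8, effects = fatigue_effect_model(),
                            seed = 1, subject_effect_sd = 0.3, ...) {
  if (!is.numeric(n_subjects) || n_subjects < 2)
    stop("n_subjects must be >= 2", call. = FALSE)
  lapply(seq_len(n_subjects), function(i) {
    generate_cohort_subject(i, n_subjects, effects, seed,
                            subject_effect_sd, ...)
  })
}

# Cohort subject profiles: speeds and stride times drawn around the study
# cohort's characteristics, baseline amplitudes jittered per subject, and
# per-family fatigue-effect multipliers drawn around 1.
draw_cohort_profiles <- function(n_subjects, seed, subject_effect_sd) {
  with_local_seed(derive_seed(seed, 1), {
    lapply(seq_len(n_subjects), function(j) {
      speed <- rnorm_range(10.6, 1.4, 8.5, 13.5)
      stm <- rnorm_range(0.75, 0.05, 0.6, 0.9)
      amps <- default_amplitudes()
      amps <- lapply(amps, function(a) a * (1 + stats::rnorm(1, 0, 0.08)))
      mult <- stats::setNames(
        stats::rnorm(length(effect_families()), 1, subject_effect_sd),
        effect_families())
      subject_profile(sprintf("S%03d", j), speed = speed,
                      stride_time_mean = stm,
                      stride_time_sd = 0.016 * stm / 0.75,
                      amplitudes = amps, effect_multipliers = mult)
    })
  })
}

# One subject of the cohort, generated without materializing the others.
generate_cohort_subject <- function(i, n_subjects,
                                    effects = fatigue_effect_model(),
                                    seed = 1, subject_effect_sd = 0.3, ...) {
  profiles <- draw_cohort_profiles(n_subjects, seed, subject_effect_sd)
  generate_session(profiles[[i]], effects, seed = derive_seed(seed, 2, i),
                   ...)
}
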