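#' Detect the bounds of a run from the pelvis velocity
#'
#' The start is the last upward zero-crossing of the sagittal pelvis
#' velocity before sustained forward motion; the end is the first downward
#' zero-crossing after it. "Sustained" means the smoothed velocity stays
#' above `min_speed` for at least `min_duration_s`.
#'
#' @param pelvis_velocity Numeric vector, m/s.
#' @param fs Sampling rate, Hz.
#' @param min_speed Minimum sustained speed regarded as running, m/s.
#' @param min_duration_s Minimum sustained duration, s.
#' @return Integer vector `c(start, end)`, half-open sample span of the
#'   first run found. Errors with class `no_run_detected` if none exists.
#' @seealso [detect_runs()] for all runs in a recording.
#' @export
detect_run_bounds <- function(pelvis_velocity, fs, min_speed = 0.5,
                              min_duration_s = 2) {
  runs <- detect_runs(pelvis_velocity, fs, min_speed, min_duration_s)
  runs[1, ]
}

#' Detect all runs in a velocity stream
#'
#' @inheritParams detect_run_bounds
#' @return Integer matrix, one row per run, columns `start`, `end`
#'   (half-open sample spans).
#' @export
detect_runs <- function(pelvis_velocity, fs, min_speed = 0.5,
                        min_duration_s = 2) {
  v <- pelvis_velocity
  n <- length(v)
  if (n < 2 * fs)
    stop("velocity stream shorter than 2 s", call. = FALSE)
  # smooth over ~0.5 s to identify sustained-motion cores
  k <- max(1L, as.integer(round(0.5 * fs)))
  vs <- stats::filter(v, rep(1 / k, k), sides = 2)
  vs[is.na(vs)] <- 0
  core <- vs > min_speed
  r <- rle(as.vector(core))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration_s * fs
  if (!any(keep)) {
    stop(structure(list(message = "no sustained run found in pelvis velocity",
                        call = NULL),
                   class = c("no_run_detected", "error", "condition")))
  }
  out <- t(vapply(which(keep), function(i) {
    cs <- starts[i]; ce <- ends[i]
    # first raw sample inside the core that is genuinely moving, then the
    # last upward zero-crossing before it
    i0 <- cs + min(which(v[cs:ce] > min_speed)) - 1L
    up <- which(v[seq_len(i0 - 1L)] <= 0)
    s <- if (length(up) > 0L) max(up) + 1L else 1L
    # last genuinely-moving sample, then the first downward zero-crossing
    # after it (half-open end)
    i1 <- cs + max(which(v[cs:ce] > min_speed)) - 1L
    after <- if (i1 < n) which(v[(i1 + 1L):n] <= 0) else integer(0)
    e <- if (length(after) > 0L) i1 + min(after) else n + 1L
    c(start = s, end = e)
  }, integer(2)))
  colnames(out) <- c("start", "end")
  out
}

#' Detect stride events from the pelvis velocity
#'
#' Stride events are the dominant downward peaks (local minima) of the
#' sagittal pelvis velocity, one per gait cycle. Candidate minima are gated
#' by prominence (`prominence_frac` x the IQR of the in-run signal) and
#' pruned depth-first to a minimum separation of `min_sep_frac` x the
#' stride period, which is itself estimated from the autocorrelation of the
#' in-run velocity (searched between 0.4 and 1.6 s). The separation gate
#' removes the shallower contralateral-step dip that sits half a stride
#' from its neighbours.
#'
#' @param pelvis_velocity Numeric vector, m/s.
#' @param fs Sampling rate, Hz.
#' @param bounds Integer `c(start, end)` half-open run span, e.g. from
#'   [detect_run_bounds()].
#' @param min_sep_frac Minimum event separation, fraction of the estimated
#'   stride period.
#' @param prominence_frac Minimum prominence, fraction of the signal IQR.
#' @return Integer vector of stride-event sample indices (absolute, sorted).
#'   Errors with class `segmentation_error` if fewer than 2 events survive.
#' @export
detect_strides <- function(pelvis_velocity, fs, bounds,
                           min_sep_frac = 0.6, prominence_frac = 0.2) {
  seg_error <- function(msg) {
    stop(structure(list(message = msg, call = NULL),
                   class = c("segmentation_error", "error", "condition")))
  }
  s <- bounds[[1]]; e <- bounds[[2]]
  v <- pelvis_velocity[s:(e - 1L)]
  n <- length(v)

  period <- estimate_stride_period(v, fs)
  if (is.na(period)) seg_error("no periodicity found in pelvis velocity")

  cand <- which(diff(sign(diff(v))) > 0) + 1L       # local minima
  if (length(cand) < 2L) seg_error("fewer than 2 velocity minima found")

  # prominence: height of the lower of the two flanking maxima above the
  # minimum, within half a period on each side
  half <- as.integer(round(period * fs / 2))
  prom <- vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    min(max(v[lo:i]), max(v[i:hi])) - v[i]
  }, numeric(1))
  thr <- prominence_frac * stats::IQR(v)
  cand <- cand[prom >= thr]
  if (length(cand) < 2L) seg_error("fewer than 2 prominent downward peaks")

  # depth-first pruning to the separation gate: deepest minima claim a
  # blocking window of +/- min_sep around themselves
  min_sep <- as.integer(ceiling(min_sep_frac * period * fs))
  ord <- cand[order(v[cand])]
  blocked <- logical(n)
  kept <- integer(0)
  for (i in ord) {
    if (!blocked[i]) {
      kept <- c(kept, i)
      blocked[max(1L, i - min_sep + 1L):min(n, i + min_sep - 1L)] <- TRUE
    }
  }
  kept <- sort(kept)
  if (length(kept) < 2L) seg_error("fewer than 2 stride events survive gating")
  kept + s - 1L
}

# Stride period (s) from the first dominant autocorrelation peak of the
# demeaned in-run velocity, searched between `lo_s` and `hi_s`.
estimate_stride_period <- function(v, fs, lo_s = 0.4, hi_s = 1.6) {
  v <- v - mean(v)
  if (stats::sd(v) == 0) return(NA_real_)
  max_lag <- min(length(v) - 1L, as.integer(ceiling(hi_s * fs)))
  ac <- stats::acf(v, lag.max = max_lag, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  lags <- seq_along(ac) - 1L
  win <- lags >= lo_s * fs & lags <= hi_s * fs
  if (!any(win)) return(NA_real_)
  best <- lags[win][which.max(ac[win])]
  if (max(ac[win]) <= 0) return(NA_real_)
  best / fs
}

#' Detect left and right initial contacts from the right knee angle
#'
#' For each stride event, the right initial contact is the knee-extension
#' minimum of the right knee angle within +/- `window_frac` of a stride
#' around the event; the left initial contact is the corresponding landmark
#' offset by half a stride. Strides whose window holds no usable landmark
#' (flat signal, or the minimum pinned to the window edge) are flagged
#' unusable rather than failing.
#'
#' @param right_knee_angle Numeric vector, degrees.
#' @param stride_peaks Stride-event indices from [detect_strides()].
#' @param fs Sampling rate, Hz.
#' @param window_frac Search half-window around each event, fraction of the
#'   local stride period.
#' @return data.frame with columns `index`, `side` ("right"/"left"),
#'   `stride` (originating stride event) and `usable`; rows sorted by index
#'   with sides alternating right, left, right, ... among usable strides.
#' @export
detect_initial_contacts <- function(right_knee_angle, stride_peaks, fs,
                                    window_frac = 0.3) {
  if (length(stride_peaks) < 1L)
    stop("stride_peaks is empty", call. = FALSE)
  n <- length(right_knee_angle)
  periods <- diff(stride_peaks)
  med_T <- stats::median(periods)
  loc_T <- c(periods, med_T)

  rows <- lapply(seq_along(stride_peaks), function(k) {
    p <- stride_peaks[k]
    half <- as.integer(round(window_frac * loc_T[k]))
    lo <- max(1L, p - half); hi <- min(n, p + half)
    w <- right_knee_angle[lo:hi]
    usable <- TRUE
    if (diff(range(w)) < 1e-8) usable <- FALSE
    im <- which.min(w)
    if (im == 1L || im == length(w)) usable <- FALSE   # not a local min
    ric <- lo + im - 1L
    lic <- ric + as.integer(round(0.5 * loc_T[k]))
    data.frame(index = c(ric, lic), side = c("right", "left"),
               stride = k, usable = usable & c(TRUE, lic <= n))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$index), ]
  rownames(out) <- NULL
  out
}

#' Cut signals into 150-point normalized gait cycles
#'
#' Cycle `k` of one side spans the half-open interval between that side's
#' consecutive initial contacts. Every curve (6 sagittal joint angles, 8
#' segmental acceleration magnitudes, 8 pitch angular velocities) is
#' linearly resampled to exactly 150 points. Cycles shorter than
#' `min_samples`, or built on an unusable initial contact, are dropped.
#'
#' @param rec A [session_recording()].
#' @param initial_contacts data.frame from [detect_initial_contacts()].
#' @param n_points Number of points per normalized cycle (150).
#' @param min_samples Minimum raw cycle length in samples.
#' @return List of `gait_cycle` objects; each holds `side`, `start`, `end`
#'   (half-open), `stride`, `stride_time` (s) and `curves`, a
#'   `n_points x 22` named matrix.
#' @export
segment_and_normalize <- function(rec, initial_contacts, n_points = 150,
                                  min_samples = 10) {
  fs <- rec$sampling_rate
  curves_src <- c(
    stats::setNames(lapply(joint_names(), function(j) rec$joints[[j]]),
                    paste0(joint_names(), "_angle")),
    stats::setNames(lapply(names(rec$segments), function(loc)
      accel_magnitude(rec$segments[[loc]]$acc[, 1],
                      rec$segments[[loc]]$acc[, 2],
                      rec$segments[[loc]]$acc[, 3])),
      paste0(names(rec$segments), "_acc_mag")),
    stats::setNames(lapply(names(rec$segments), function(loc)
      rec$segments[[loc]]$gyr[, 2]),
      paste0(names(rec$segments), "_gyr_pitch")))

  sig_mat <- do.call(cbind, curves_src)

  out <- list()
  for (sd in c("right", "left")) {
    ics <- initial_contacts[initial_contacts$side == sd, , drop = FALSE]
    if (nrow(ics) < 2L) next
    for (k in seq_len(nrow(ics) - 1L)) {
      if (!ics$usable[k] || !ics$usable[k + 1L]) next
      a <- ics$index[k]; b <- ics$index[k + 1L]
      if (b - a < min_samples) next
      # linear resampling of [a, b) onto n_points; exact on integer grids
      xout <- seq(a, b - 1L, length.out = n_points)
      lo <- pmin(floor(xout), b - 2L)
      frac <- xout - lo
      curves <- sig_mat[lo, , drop = FALSE] +
        frac * (sig_mat[lo + 1L, , drop = FALSE] -
                  sig_mat[lo, , drop = FALSE])
      out[[length(out) + 1L]] <- structure(
        list(side = sd, start = a, end = b, stride = ics$stride[k],
             stride_time = (b - a) / fs, curves = curves),
        class = "gait_cycle")
    }
  }
  out
}
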