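#' Construct a session recording
#'
#' A `session_recording` holds one subject's full instrumented run: 6-axis
#' streams for each of up to eight body segments, sagittal joint angles,
#' the sagittal (forward) pelvis velocity, and the lap table. All streams
#' share one length and one sampling rate. Sample indices are 1-based;
#' lap/cycle spans are half-open `[start, end)`.
#'
#' @param subject_id Character scalar.
#' @param sampling_rate Sampling frequency in Hz (default 240).
#' @param segments Named list (names in L1..L8); each element a list with
#'   `acc` and `gyr`, numeric n x 3 matrices (m/s^2 and deg/s; columns
#'   x, y, z with y the medio-lateral/pitch axis, forward rotation positive).
#' @param joints Named list of numeric vectors: sagittal angles in degrees,
#'   flexion positive, names from [joint_names()].
#' @param pelvis_velocity Numeric vector, sagittal pelvis velocity in m/s.
#' @param laps data.frame with columns `lap` (1..n), `run` (1, 2 or 3),
#'   `lap_in_run`, `start`, `end` (half-open sample spans), delimiting the
#'   400 m laps.
#' @param nominal_speed Nominal running speed in km/h.
#' @param lap_length_m Lap length in metres (default 400).
#'
#' @return Object of class `session_recording`.
#' @export
session_recording <- function(subject_id, sampling_rate = 240,
                              segments, joints, pelvis_velocity,
                              laps, nominal_speed, lap_length_m = 400) {
  rec <- structure(
    list(subject_id = as.character(subject_id),
         sampling_rate = sampling_rate,
         segments = segments,
         joints = joints,
         pelvis_velocity = as.numeric(pelvis_velocity),
         laps = laps,
         nominal_speed = nominal_speed,
         lap_length_m = lap_length_m),
    class = "session_recording")
  validate_session_recording(rec)
}

#' Validate a session recording
#'
#' Checks the container invariants: positive sampling rate, known location
#' codes and joint names, equal stream lengths, 3-column segment matrices,
#' and a strictly increasing lap table within the stream length. Errors name
#' the offending field.
#'
#' @param rec A [session_recording()].
#' @return `rec`, invisibly-validated (returned unchanged).
#' @export
validate_session_recording <- function(rec) {
  stopifnot(inherits(rec, "session_recording"))
  if (!is.numeric(rec$sampling_rate) || rec$sampling_rate <= 0)
    stop("sampling_rate must be > 0", call. = FALSE)
  if (length(rec$pelvis_velocity) == 0L)
    stop("pelvis_velocity: empty stream", call. = FALSE)
  n <- length(rec$pelvis_velocity)

  assert_location_codes(names(rec$segments))
  for (loc in names(rec$segments)) {
    seg <- rec$segments[[loc]]
    for (part in c("acc", "gyr")) {
      m <- seg[[part]]
      if (is.null(m) || !is.matrix(m) || ncol(m) != 3L)
        stop(sprintf("segment %s: %s must be an n x 3 matrix", loc, part),
             call. = FALSE)
      if (nrow(m) != n)
        stop(sprintf("segment %s: %s length %d != stream length %d",
                     loc, part, nrow(m), n), call. = FALSE)
      if (nrow(m) == 0L)
        stop(sprintf("segment %s: empty stream", loc), call. = FALSE)
    }
  }
  bad_joint <- setdiff(names(rec$joints), joint_names())
  if (length(bad_joint) > 0L)
    stop("unknown joint(s): ", paste(bad_joint, collapse = ", "),
         call. = FALSE)
  for (jn in names(rec$joints)) {
    if (length(rec$joints[[jn]]) != n)
      stop(sprintf("joint %s: length %d != stream length %d",
                   jn, length(rec$joints[[jn]]), n), call. = FALSE)
  }

  laps <- rec$laps
  need <- c("lap", "run", "lap_in_run", "start", "end")
  if (!is.data.frame(laps) || !all(need %in% names(laps)))
    stop("laps: must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(laps) > 0L) {
    if (any(laps$start >= laps$end))
      stop("laps: start must be < end", call. = FALSE)
    if (is.unsorted(laps$start, strictly = TRUE))
      stop("laps: lap starts must be strictly increasing", call. = FALSE)
    if (any(laps$start < 1L) || any(laps$end > n + 1L))
      stop("laps: lap boundaries beyond stream length", call. = FALSE)
    if (!all(laps$run %in% 1:3))
      stop("laps: run must be 1, 2 or 3", call. = FALSE)
  }
  if (!is.numeric(rec$nominal_speed) || rec$nominal_speed <= 0)
    stop("nominal_speed must be > 0", call. = FALSE)
  rec
}

#' @export
print.session_recording <- function(x, ...) {
  n <- length(x$pelvis_velocity)
  cat(sprintf(
    "<session_recording> subject %s: %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, n, x$sampling_rate, n / x$sampling_rate))
  cat(sprintf("  segments: %s\n", paste(names(x$segments), collapse = " ")))
  cat(sprintf("  joints:   %s\n", paste(names(x$joints), collapse = " ")))
  cat(sprintf("  laps:     %d (%g m) at %g km/h\n",
              nrow(x$laps), x$lap_length_m, x$nominal_speed))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A [session_recording()].
#' @return Numeric scalar, seconds.
#' @export
session_duration <- function(rec) {
  length(rec$pelvis_velocity) / rec$sampling_rate
}
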