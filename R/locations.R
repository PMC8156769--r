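#' IMU body-location codes
#'
#' The eight instrumented body segments and their location codes:
#' L1 sternum, L2 pelvis, L3 right thigh, L4 left thigh, L5 right tibia,
#' L6 left tibia, L7 right foot, L8 left foot.
#'
#' @return Named character vector mapping code to segment name.
#' @export
#' @examples
#' location_codes()["L6"]
location_codes <- function() {
  c(L1 = "sternum",  L2 = "pelvis",
    L3 = "thigh_right", L4 = "thigh_left",
    L5 = "tibia_right", L6 = "tibia_left",
    L7 = "foot_right",  L8 = "foot_left")
}

#' Sagittal joint names
#'
#' The six lower-limb joints whose sagittal angles enter the feature set.
#'
#' @return Character vector of joint names.
#' @export
joint_names <- function() {
  c("ankle_left", "ankle_right", "knee_left", "knee_right",
    "hip_left", "hip_right")
}

# Sensors needed to compute each joint angle: a joint is available when
# both adjacent segments are instrumented.
joint_requirements <- function() {
  list(
    hip_right   = c("L2", "L3"),
    hip_left    = c("L2", "L4"),
    knee_right  = c("L3", "L5"),
    knee_left   = c("L4", "L6"),
    ankle_right = c("L5", "L7"),
    ankle_left  = c("L6", "L8")
  )
}

assert_location_codes <- function(locations) {
  bad <- setdiff(locations, names(location_codes()))
  if (length(bad) > 0L) {
    stop("unknown location code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(locations)
}

#' Gait-event windows for joint-angle extrema
#'
#' Windows are expressed as fractions of the normalized gait cycle
#' (0 = initial contact of the cycle's own side) and each event is either a
#' maximum (flexion-type) or a minimum (extension-type) of the angle inside
#' its window. `extremum` per joint: the knee uses an extension minimum at
#' IC, toe-off and end swing and flexion maxima at mid stance and mid swing;
#' the hip peaks into flexion at IC and mid swing and into extension at toe
#' off; the ankle peaks at IC and mid stance and plantarflexes at toe off.
#'
#' @return data.frame with columns joint (ankle/knee/hip), event, extremum
#'   ("max"/"min"), lo, hi (cycle fractions).
#' @export
joint_event_windows <- function() {
  if (!is.null(.windows_cache$tbl)) return(.windows_cache$tbl)
  .windows_cache$tbl <- rbind(
    data.frame(joint = "ankle",
               event = c("ic", "midstance", "toeoff"),
               extremum = c("max", "max", "min"),
               lo = c(0.00, 0.05, 0.30), hi = c(0.05, 0.35, 0.45)),
    data.frame(joint = "knee",
               event = c("ic", "midstance", "toeoff", "midswing", "endswing"),
               extremum = c("min", "max", "min", "max", "min"),
               lo = c(0.00, 0.05, 0.30, 0.50, 0.85),
               hi = c(0.05, 0.35, 0.45, 0.75, 1.00)),
    data.frame(joint = "hip",
               event = c("ic", "toeoff", "midswing"),
               extremum = c("max", "min", "max"),
               lo = c(0.00, 0.30, 0.50), hi = c(0.05, 0.45, 0.75))
  )
  .windows_cache$tbl
}

.windows_cache <- new.env(parent = emptyenv())
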