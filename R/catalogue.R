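#' The 157-feature catalogue
#'
#' Canonical, ordered list of all features extracted per gait cycle:
#'
#' * 96 segment features — for each of the 8 locations, peak acceleration
#'   magnitude, peak pitch angular velocity, and mean/STD/IQR/skewness/
#'   kurtosis of both curves (12 per location);
#' * 2 shock-attenuation features (left/right tibia vs pelvis);
#' * 22 joint-angle event extrema (knee 5 per side, ankle 3, hip 3);
#' * 3 left-right symmetry features (one per joint level, from the IC event);
#' * 30 joint-angle statistics (5 per joint);
#' * 4 spatiotemporal features (stride time and stride length, per side).
#'
#' Family counts are 43 biomechanical, 110 statistical, 4 spatiotemporal.
#' The row order defines the canonical feature order used for deterministic
#' tie-breaking in feature selection.
#'
#' @return data.frame with columns `name`, `family` (biomechanical /
#'   statistical / spatiotemporal), `group` (segment / shock / joint_event /
#'   symmetry / joint_stat / spatiotemporal), `location`, `joint`, `stat`,
#'   and `requires` (list column: location codes needed to compute it).
#' @export
#' @examples
#' nrow(feature_catalogue())     # 157
#' table(feature_catalogue()$family)
feature_catalogue <- function() {
  if (!is.null(.catalogue_cache$tbl)) return(.catalogue_cache$tbl)
  locs <- names(location_codes())
  stats5 <- c("mean", "std", "iqr", "skew", "kurt")
  rows <- list()
  add <- function(name, family, group, location = NA_character_,
                  joint = NA_character_, stat = NA_character_, requires) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, family = family, group = group, location = location,
      joint = joint, stat = stat, requires = I(list(requires)))
  }

  for (loc in locs) {
    add(paste0(loc, "_acc_peak"), "biomechanical", "segment", loc,
        stat = "peak", requires = loc)
    add(paste0(loc, "_gyr_peak"), "biomechanical", "segment", loc,
        stat = "peak", requires = loc)
    for (s in stats5) {
      add(paste0(loc, "_acc_", s), "statistical", "segment", loc,
          stat = s, requires = loc)
    }
    for (s in stats5) {
      add(paste0(loc, "_gyr_", s), "statistical", "segment", loc,
          stat = s, requires = loc)
    }
  }

  add("shock_att_left", "biomechanical", "shock",
      requires = c("L6", "L2"))
  add("shock_att_right", "biomechanical", "shock",
      requires = c("L5", "L2"))

  req <- joint_requirements()
  ev <- joint_event_windows()
  for (jn in joint_names()) {
    kind <- sub("_(left|right)$", "", jn)
    for (e in ev$event[ev$joint == kind]) {
      add(paste0(jn, "_", e), "biomechanical", "joint_event",
          joint = jn, stat = e, requires = req[[jn]])
    }
    for (s in stats5) {
      add(paste0(jn, "_", s), "statistical", "joint_stat",
          joint = jn, stat = s, requires = req[[jn]])
    }
  }

  for (kind in c("ankle", "knee", "hip")) {
    both <- paste0(kind, c("_left", "_right"))
    add(paste0(kind, "_sym_ic"), "biomechanical", "symmetry",
        joint = kind, stat = "ic",
        requires = unique(unlist(req[both])))
  }

  # Spatiotemporal features are attributed to the segmentation chain that
  # measures them: stride events come from the pelvis velocity (L2) and
  # initial contacts from the right knee angle (L3 + L5). This keeps every
  # single-IMU configuration at exactly 12 features.
  for (side in c("left", "right")) {
    add(paste0("stride_time_", side), "spatiotemporal", "spatiotemporal",
        stat = "stride_time", requires = c("L2", "L3", "L5"))
    add(paste0("stride_length_", side), "spatiotemporal", "spatiotemporal",
        stat = "stride_length", requires = c("L2", "L3", "L5"))
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  .catalogue_cache$tbl <- out
  out
}

# The catalogue is immutable; build it once per session.
.catalogue_cache <- new.env(parent = emptyenv())

#' Canonical feature names
#'
#' @return Character vector of the 157 feature names in canonical order.
#' @export
feature_names <- function() feature_catalogue()$name
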