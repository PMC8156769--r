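#' Enumerate all non-empty sensor subsets
#'
#' All `2^n - 1` non-empty subsets of the given locations, in a
#' deterministic canonical order: by subset size, then lexicographically by
#' location code.
#'
#' @param locations Character vector of location codes (default all eight).
#' @return List of character vectors.
#' @export
#' @examples
#' length(enumerate_subsets())  # 255
enumerate_subsets <- function(locations = names(location_codes())) {
  assert_location_codes(locations)
  if (length(locations) < 1L) stop("empty location set", call. = FALSE)
  locations <- sort(locations)
  out <- list()
  for (r in seq_along(locations)) {
    combs <- utils::combn(locations, r, simplify = FALSE)
    out <- c(out, combs)
  }
  out
}

#' Joints computable from a sensor configuration
#'
#' A sagittal joint angle is available iff both adjacent segments are
#' instrumented: hip needs pelvis + thigh, knee thigh + tibia, ankle
#' tibia + foot (per side).
#'
#' @param config Character vector of location codes.
#' @return Character vector of available joint names (possibly empty).
#' @export
#' @examples
#' derive_joints(c("L2", "L3"))  # right hip
derive_joints <- function(config) {
  assert_location_codes(config)
  req <- joint_requirements()
  names(req)[vapply(req, function(r) all(r %in% config), logical(1))]
}

#' Feature mask of a sensor configuration
#'
#' The canonical feature names computable from a location subset: the 12
#' segment features per included location, each derived joint's event
#' extrema and 5 statistics, the symmetry feature of a joint level when
#' both sides are derivable, shock attenuation per (tibia, pelvis) pair
#' present, and the spatiotemporal features when the pelvis (the
#' segmentation source) is included.
#'
#' @param config Character vector of location codes.
#' @return Character vector of feature names, in canonical order.
#' @export
#' @examples
#' length(feature_mask("L6"))              # 12
#' length(feature_mask(c("L4", "L6")))     # 34
feature_mask <- function(config) {
  assert_location_codes(config)
  cat <- feature_catalogue()
  ok <- vapply(cat$requires, function(r) all(r %in% config), logical(1))
  cat$name[ok]
}

# The selected sensor combinations compared in the study: all eight single
# locations, nine two-adjacent-IMU pairs, ten 3-4 IMU sets, and the whole
# body.
reference_configurations <- function() {
  quasi <- list(c("L2", "L3"), c("L2", "L4"), c("L3", "L5"), c("L4", "L6"),
                c("L5", "L7"), c("L6", "L8"), c("L3", "L4"), c("L5", "L6"),
                c("L7", "L8"))
  three_plus <- list(c("L2", "L5", "L6"), c("L2", "L3", "L4"),
                     c("L2", "L3", "L5"), c("L2", "L4", "L6"),
                     c("L3", "L5", "L7"), c("L4", "L6", "L8"),
                     c("L3", "L4", "L5", "L6"), c("L5", "L6", "L7", "L8"),
                     c("L2", "L3", "L5", "L7"), c("L2", "L4", "L6", "L8"))
  list(minimally_intrusive = as.list(names(location_codes())),
       quasi_minimally_intrusive = quasi,
       three_plus = three_plus,
       whole_body = list(names(location_codes())))
}

#' Category of a sensor configuration
#'
#' `minimally_intrusive` for single locations, `quasi_minimally_intrusive`
#' for the nine listed two-adjacent-IMU pairs, `three_plus` for the ten
#' listed 3-4 IMU sets, `whole_body` for all eight, and `other` for any
#' subset not in the comparison list.
#'
#' @param config Character vector of location codes.
#' @return Category string.
#' @export
categorize <- function(config) {
  assert_location_codes(config)
  key <- paste(sort(config), collapse = " ")
  refs <- reference_configurations()
  for (cat in names(refs)) {
    keys <- vapply(refs[[cat]], function(x) paste(sort(x), collapse = " "),
                   character(1))
    if (key %in% keys) return(cat)
  }
  "other"
}

#' Build a sensor configuration object
#'
#' Bundles a location subset with its derived joints, feature mask and
#' category.
#'
#' @param locations Character vector of location codes.
#' @return Object of class `sensor_configuration` with elements
#'   `locations`, `derived_joints`, `feature_mask`, `category`.
#' @export
sensor_configuration <- function(locations) {
  assert_location_codes(locations)
  locations <- sort(unique(locations))
  structure(list(locations = locations,
                 derived_joints = derive_joints(locations),
                 feature_mask = feature_mask(locations),
                 category = categorize(locations)),
            class = "sensor_configuration")
}

#' @export
print.sensor_configuration <- function(x, ...) {
  cat(sprintf("<sensor_configuration> %s [%s]: %d joints, %d features\n",
              paste(x$locations, collapse = " "), x$category,
              length(x$derived_joints), length(x$feature_mask)))
  invisible(x)
}

#' Label for a configuration
#' @param config Character vector of location codes.
#' @return Single string like `"L4+L6"`.
#' @export
config_label <- function(config) paste(sort(config), collapse = "+")
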