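#' Write a session recording to disk
#'
#' On-disk layout (frozen): a directory holding one wide CSV
#' (`streams.csv`, one row per sample; columns `pelvis_velocity`,
#' `<loc>_acc_<x|y|z>`, `<loc>_gyr_<x|y|z>`, `<joint>_angle`) plus a JSON
#' sidecar (`meta.json`) with subject id, sampling rate, nominal speed, lap
#' length and the lap table (1-based half-open sample spans).
#'
#' @param rec A validated [session_recording()].
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(rec, path) {
  validate_session_recording(rec)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("unwritable path: ", path, call. = FALSE)

  cols <- list(pelvis_velocity = rec$pelvis_velocity)
  for (loc in names(rec$segments)) {
    for (part in c("acc", "gyr")) {
      m <- rec$segments[[loc]][[part]]
      for (k in 1:3) {
        cols[[paste0(loc, "_", part, "_", c("x", "y", "z")[k])]] <- m[, k]
      }
    }
  }
  for (jn in names(rec$joints)) {
    cols[[paste0(jn, "_angle")]] <- rec$joints[[jn]]
  }
  data.table::fwrite(data.table::as.data.table(cols),
                     file.path(path, "streams.csv"))

  meta <- list(
    subject_id = rec$subject_id,
    sampling_rate = rec$sampling_rate,
    nominal_speed = rec$nominal_speed,
    lap_length_m = rec$lap_length_m,
    locations = names(rec$segments),
    joints = names(rec$joints),
    laps = rec$laps
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session recording from disk
#'
#' Reads the layout written by [write_session()] and returns a fully
#' validated recording. Missing streams, unknown location codes or a
#' malformed sidecar raise errors naming the problem.
#'
#' @param path Directory written by [write_session()].
#' @return A [session_recording()].
#' @export
read_session <- function(path) {
  meta_file <- file.path(path, "meta.json")
  csv_file <- file.path(path, "streams.csv")
  if (!file.exists(meta_file)) stop("missing meta.json in ", path, call. = FALSE)
  if (!file.exists(csv_file)) stop("missing streams.csv in ", path, call. = FALSE)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  assert_location_codes(meta$locations)

  dt <- data.table::fread(csv_file)
  getcol <- function(nm) {
    if (!nm %in% names(dt))
      stop("missing required stream: ", nm, call. = FALSE)
    as.numeric(dt[[nm]])
  }
  segments <- list()
  for (loc in meta$locations) {
    segments[[loc]] <- list(
      acc = cbind(x = getcol(paste0(loc, "_acc_x")),
                  y = getcol(paste0(loc, "_acc_y")),
                  z = getcol(paste0(loc, "_acc_z"))),
      gyr = cbind(x = getcol(paste0(loc, "_gyr_x")),
                  y = getcol(paste0(loc, "_gyr_y")),
                  z = getcol(paste0(loc, "_gyr_z"))))
  }
  joints <- list()
  for (jn in meta$joints) joints[[jn]] <- getcol(paste0(jn, "_angle"))

  laps <- as.data.frame(meta$laps)
  session_recording(
    subject_id = meta$subject_id,
    sampling_rate = as.numeric(meta$sampling_rate),
    segments = segments,
    joints = joints,
    pelvis_velocity = getcol("pelvis_velocity"),
    laps = laps,
    nominal_speed = meta$nominal_speed,
    lap_length_m = meta$lap_length_m)
}

#' Write / read a stride-level feature table
#'
#' Plain CSV with the metadata columns first and one column per canonical
#' feature name.
#'
#' @param tbl data.frame as produced by [session_features()] or
#'   [prepare_feature_table()].
#' @param path CSV file path.
#' @return `path` (write) or the table (read).
#' @export
write_feature_table <- function(tbl, path) {
  data.table::fwrite(tbl, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write an evaluation report bundle
#'
#' Emits `report.json` (full nested report), `confusion.csv` (aggregate
#' 3x3 confusion matrix) and `selected_features.csv` (per-fold ranks) into
#' a directory.
#'
#' @param report An evaluation report from [nested_loso_evaluate()].
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(path, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  cm <- as.data.frame(report$aggregate_confusion)
  data.table::fwrite(cbind(true = rownames(report$aggregate_confusion), cm),
                     file.path(path, "confusion.csv"))
  sel <- do.call(rbind, lapply(report$per_fold, function(f) {
    data.frame(left_out_subject = f$left_out_subject,
               rank = seq_along(f$selected_features),
               feature = f$selected_features)
  }))
  data.table::fwrite(sel, file.path(path, "selected_features.csv"))
  invisible(path)
}
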