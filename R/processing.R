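#' Fatigue-condition label for a lap
#'
#' Laps 2-4 of the first run are the no-fatigue condition, laps 8-10 of the
#' first run mild fatigue, and laps 1-3 of the third run (directly after
#' the fatiguing protocol) heavy fatigue; every other lap — including the
#' whole second (fatiguing) run — is excluded.
#'
#' @param run_id Run index (1, 2 or 3).
#' @param lap_in_run Lap number within that run.
#' @return One of `"no_fatigue"`, `"mild_fatigue"`, `"heavy_fatigue"`,
#'   `"excluded"`.
#' @export
#' @examples
#' assign_label(1, 3)  # no_fatigue
#' assign_label(3, 2)  # heavy_fatigue
assign_label <- function(run_id, lap_in_run) {
  if (!run_id %in% 1:3)
    stop("run_id must be 1, 2 or 3", call. = FALSE)
  if (!is.numeric(lap_in_run) || lap_in_run < 1)
    stop("lap_in_run out of range", call. = FALSE)
  if (run_id == 1 && lap_in_run >= 2 && lap_in_run <= 4) "no_fatigue"
  else if (run_id == 1 && lap_in_run >= 8 && lap_in_run <= 10) "mild_fatigue"
  else if (run_id == 3 && lap_in_run <= 3) "heavy_fatigue"
  else "excluded"
}

#' The three fatigue-condition levels, in order
#' @return Character vector: no_fatigue, mild_fatigue, heavy_fatigue.
#' @export
fatigue_levels <- function() c("no_fatigue", "mild_fatigue", "heavy_fatigue")

#' One-lap moving average over stride features
#'
#' Causal (trailing) distance window: smoothed row `i` is the mean of all
#' rows whose cumulative distance lies in `(d_i - window_m, d_i]`. Rows
#' with less than one full window of history (`d_i < d_1 + window_m`) are
#' dropped, so output rows always average a full lap.
#'
#' @param x Numeric matrix or data.frame of feature columns (rows =
#'   strides, ordered by distance).
#' @param distance_m Non-decreasing numeric vector of cumulative distances.
#' @param window_m Window length in metres (default 400, one lap).
#' @return List with `values` (smoothed matrix) and `keep` (indices of the
#'   surviving input rows). Warns and returns zero rows when the total
#'   distance spans less than one window.
#' @export
lap_moving_average <- function(x, distance_m, window_m = 400) {
  if (window_m <= 0) stop("window_m must be > 0", call. = FALSE)
  if (is.unsorted(distance_m)) stop("distances must be non-decreasing",
                                    call. = FALSE)
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(length(distance_m) == n)
  keep <- which(distance_m >= distance_m[1] + window_m)
  if (length(keep) == 0L) {
    warning("total distance < one window; no smoothed rows", call. = FALSE)
    return(list(values = x[integer(0), , drop = FALSE], keep = integer(0)))
  }
  # window (d_i - w, d_i]: first index j with d_j > d_i - w
  lo <- findInterval(distance_m[keep] - window_m, distance_m) + 1L
  cs <- rbind(0, apply(x, 2, cumsum))
  cnt <- keep - lo + 1L
  vals <- (cs[keep + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / cnt
  colnames(vals) <- colnames(x)
  list(values = vals, keep = keep)
}

#' Per-subject z-score normalization
#'
#' For each subject and feature, `(x - mean) / STD` over that subject's
#' rows; zero-variance features map to 0.
#'
#' @param tbl data.frame with a `subject_id` column and feature columns.
#' @param feature_cols Character vector of feature column names (defaults
#'   to every canonical feature name present).
#' @return `tbl` with the feature columns normalized.
#' @export
zscore_per_subject <- function(tbl, feature_cols = NULL) {
  if (is.null(feature_cols))
    feature_cols <- intersect(feature_names(), names(tbl))
  for (s in unique(tbl$subject_id)) {
    idx <- which(tbl$subject_id == s)
    if (length(idx) < 2L)
      stop("subject ", s, " has fewer than 2 rows", call. = FALSE)
    m <- as.matrix(tbl[idx, feature_cols, drop = FALSE])
    mu <- colMeans(m)
    sdv <- apply(m, 2, stats::sd)
    z <- sweep(m, 2, mu, "-")
    nz <- sdv > 0
    z[, nz] <- sweep(z[, nz, drop = FALSE], 2, sdv[nz], "/")
    z[, !nz] <- 0
    tbl[idx, feature_cols] <- z
  }
  tbl
}

#' Smooth, label and normalize a stride-level feature table
#'
#' The modelling table used for classification: the one-lap moving average
#' is applied per subject and per run (the fatiguing run separates runs 1
#' and 3, so windows never span the gap), rows without a full lap of
#' history are dropped, unlabeled rows are removed, and features are
#' z-scored per subject over the remaining rows. The default order is
#' smooth-then-z-score; `order = "zscore_first"` swaps the two stages.
#'
#' @param stride_tbl Stride-level table from [session_features()] (one or
#'   several subjects row-bound together).
#' @param window_m Moving-average window, metres.
#' @param order `"smooth_first"` (default) or `"zscore_first"`.
#' @return data.frame with metadata columns, `label` as a factor over the
#'   three conditions, and the smoothed, normalized feature columns.
#' @export
prepare_feature_table <- function(stride_tbl, window_m = 400,
                                  order = c("smooth_first", "zscore_first")) {
  order <- match.arg(order)
  fcols <- intersect(feature_names(), names(stride_tbl))

  if (order == "zscore_first")
    stride_tbl <- zscore_per_subject(stride_tbl, fcols)

  groups <- split(seq_len(nrow(stride_tbl)),
                  list(stride_tbl$subject_id, stride_tbl$run), drop = TRUE)
  smoothed <- lapply(groups, function(idx) {
    idx <- idx[order(stride_tbl$distance_m[idx])]
    sm <- lap_moving_average(stride_tbl[idx, fcols, drop = FALSE],
                             stride_tbl$distance_m[idx], window_m)
    if (length(sm$keep) == 0L) return(NULL)
    out <- stride_tbl[idx[sm$keep],
                      setdiff(names(stride_tbl), fcols), drop = FALSE]
    cbind(out, as.data.frame(sm$values))
  })
  out <- do.call(rbind, smoothed)
  rownames(out) <- NULL
  out <- out[out$label %in% fatigue_levels(), , drop = FALSE]
  out$label <- factor(out$label, levels = fatigue_levels())
  if (order == "smooth_first")
    out <- zscore_per_subject(out, fcols)
  out
}

#' Feature tables for a whole synthetic cohort
#'
#' Convenience wrapper: generates each subject's session, extracts its
#' stride-level features, and row-binds the cohort; sessions are processed
#' one at a time so full recordings are never held together in memory.
#'
#' @inheritParams generate_cohort
#' @param prepare If `TRUE` (default) return the smoothed, labeled,
#'   z-scored modelling table; otherwise the raw stride-level table.
#' @param window_m Moving-average window, metres.
#' @return data.frame (see [prepare_feature_table()] / [session_features()]).
#' @export
cohort_features <- function(n_subjects = 8, effects = fatigue_effect_model(),
                            seed = 1, subject_effect_sd = 0.3,
                            prepare = TRUE, window_m = 400, ...) {
  if (!is.numeric(n_subjects) || n_subjects < 2)
    stop("n_subjects must be >= 2", call. = FALSE)
  tabs <- lapply(seq_len(n_subjects), function(i) {
    sim <- generate_cohort_subject(i, n_subjects, effects, seed,
                                   subject_effect_sd, ...)
    session_features(sim$recording)
  })
  tbl <- do.call(rbind, tabs)
  rownames(tbl) <- NULL
  if (prepare) prepare_feature_table(tbl, window_m = window_m) else tbl
}
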