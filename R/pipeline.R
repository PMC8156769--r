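#' Run the full fatigue-detection pipeline
#'
#' End-to-end driver over a synthetic cohort: generate sessions, segment
#' and extract stride features, build the smoothed/labeled/z-scored
#' modelling table, evaluate every requested sensor configuration with
#' nested leave-one-subject-out cross-validation, and (optionally) write a
#' report bundle per configuration plus a cross-configuration summary.
#'
#' @param n_subjects Cohort size.
#' @param effects A [fatigue_effect_model()].
#' @param seed Master seed for the whole pipeline.
#' @param configurations List of location-code vectors to evaluate
#'   (default: the best-performing configuration of each comparison
#'   category in the study design — L6, L4+L6, L3+L4+L5+L6, whole body).
#' @param spec A [training_spec()].
#' @param window_m Moving-average window, metres.
#' @param out_dir Output directory for CSV/JSON reports, or `NULL` to skip
#'   writing.
#' @param table Optionally, a pre-built modelling table (skips simulation).
#' @param verbose Log stage progress with row counts to stderr.
#' @return List with `table` (the modelling table), `reports` (one
#'   `eval_report` per configuration) and `summary` (data.frame sorted by
#'   mean accuracy, descending).
#' @export
run_pipeline <- function(n_subjects = 8, effects = fatigue_effect_model(),
                         seed = 1,
                         configurations = list(
                           "L6", c("L4", "L6"), c("L3", "L4", "L5", "L6"),
                           names(location_codes())),
                         spec = training_spec(seed = seed),
                         window_m = 400, out_dir = NULL, table = NULL,
                         verbose = TRUE) {
  log_msg <- function(...) if (verbose) message(sprintf(...))
  if (is.null(table)) {
    log_msg("simulating %d subjects and extracting features ...", n_subjects)
    table <- cohort_features(n_subjects, effects, seed = seed,
                             window_m = window_m)
  }
  log_msg("modelling table: %d rows x %d features, %d subjects",
          nrow(table), length(intersect(feature_names(), names(table))),
          length(unique(table$subject_id)))

  reports <- lapply(configurations, function(cfg) {
    log_msg("evaluating %s ...", config_label(cfg))
    rep <- nested_loso_evaluate(table, cfg, spec)
    log_msg("  accuracy %.3f +/- %.3f", rep$accuracy_mean, rep$accuracy_sd)
    rep
  })
  names(reports) <- vapply(configurations, config_label, character(1))

  summary <- summarize_reports(reports)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(reports)) {
      write_eval_report(reports[[nm]],
                        file.path(out_dir, gsub("\\+", "_", nm)))
    }
    data.table::fwrite(summary, file.path(out_dir, "summary.csv"))
  }
  list(table = table, reports = reports, summary = summary)
}

#' Summarize evaluation reports across configurations
#'
#' @param reports List of `eval_report` objects.
#' @return data.frame (configuration, category, n_features, accuracy mean
#'   and SD, aggregate accuracy) sorted by mean accuracy, descending.
#' @export
summarize_reports <- function(reports) {
  out <- do.call(rbind, lapply(reports, function(r) {
    data.frame(configuration = r$configuration, category = r$category,
               n_features = r$n_features,
               accuracy_mean = r$accuracy_mean, accuracy_sd = r$accuracy_sd,
               accuracy_aggregate =
                 sum(diag(r$aggregate_confusion)) / sum(r$aggregate_confusion))
  }))
  out <- out[order(-out$accuracy_mean), ]
  rownames(out) <- NULL
  out
}

#' Top-ranked features per configuration
#'
#' Frequency-based ranking across outer folds: features are ordered by how
#' often they were selected and, among equals, by their mean rank within
#' the folds' selections.
#'
#' @param report An `eval_report`.
#' @param n Number of top features to return.
#' @return data.frame with columns `rank`, `feature`, `n_folds_selected`,
#'   `mean_within_fold_rank`.
#' @export
ranked_feature_table <- function(report, n = 5) {
  sel <- lapply(report$per_fold, `[[`, "selected_features")
  feats <- unique(unlist(sel))
  freq <- vapply(feats, function(f)
    sum(vapply(sel, function(s) f %in% s, logical(1))), numeric(1))
  mrank <- vapply(feats, function(f)
    mean(unlist(lapply(sel, function(s) match(f, s))), na.rm = TRUE),
    numeric(1))
  ord <- order(-freq, mrank)
  k <- min(n, length(feats))
  data.frame(rank = seq_len(k), feature = feats[ord][seq_len(k)],
             n_folds_selected = freq[ord][seq_len(k)],
             mean_within_fold_rank = mrank[ord][seq_len(k)])
}
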