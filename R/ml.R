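#' Training specification for the fatigue classifier
#'
#' @param n_trees Number of trees in the random forest (study value 100).
#' @param k_selected Number of features kept by the inner-loop selection
#'   (study value 12).
#' @param seed Master seed; every stochastic step derives its own seed from
#'   it, so individual folds are reproducible in isolation.
#' @return Object of class `training_spec`.
#' @export
training_spec <- function(n_trees = 100, k_selected = 12, seed = 1) {
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  if (k_selected < 1) stop("k_selected must be >= 1", call. = FALSE)
  structure(list(n_trees = n_trees, k_selected = k_selected,
                 seed = as.integer(seed)),
            class = "training_spec")
}

#' Out-of-bag permutation feature importance
#'
#' Importance of each feature as the mean over trees of the out-of-bag
#' accuracy drop after permuting that feature's out-of-bag values
#' (random-forest permutation importance). Deterministic given the seed.
#'
#' @param x data.frame or matrix of features (rows = observations).
#' @param y Factor of class labels (>= 2 classes present).
#' @param spec A [training_spec()].
#' @param seed Seed for this fit (defaults to `spec$seed`).
#' @return Named numeric vector of importances (one per feature).
#' @export
oob_permutation_importance <- function(x, y, spec = training_spec(),
                                       seed = spec$seed) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L)
    stop("need at least 2 classes for importance", call. = FALSE)
  fit <- ranger::ranger(
    x = as.data.frame(x), y = y,
    num.trees = spec$n_trees, importance = "permutation",
    seed = seed, num.threads = 1)
  fit$variable.importance
}

#' Select the top-k features by mean importance
#'
#' Averages importance vectors (e.g. across inner folds), ranks
#' descending, and keeps the top `k`; ties are broken by canonical
#' catalogue order. A mask of at most `k` features (the single-sensor
#' case) is returned whole, unselected.
#'
#' @param importances Numeric vector, or a matrix/list of vectors to be
#'   averaged arithmetically (rows/elements = folds).
#' @param k Number of features to keep.
#' @return Character vector of feature names, ranked best first.
#' @export
select_features <- function(importances, k = 12) {
  if (is.list(importances)) importances <- do.call(rbind, importances)
  if (is.matrix(importances)) importances <- colMeans(importances)
  if (length(importances) < 1L) stop("no features to select", call. = FALSE)
  nm <- names(importances)
  canon <- match(nm, feature_names())
  canon[is.na(canon)] <- length(feature_names()) + seq_len(sum(is.na(canon)))
  ord <- order(-importances, canon)
  ranked <- nm[ord]
  if (length(ranked) <= k) ranked else ranked[seq_len(k)]
}

#' Classification metrics from a 3x3 confusion matrix
#'
#' One-vs-rest per-class sensitivity, specificity, precision and F1
#' (harmonic mean of precision and sensitivity), plus overall accuracy.
#' Rows are true classes, columns predicted. A class with zero predicted
#' positives gets precision 0 with a warning.
#'
#' @param cm Square numeric matrix of non-negative counts.
#' @return List with `per_class` (data.frame: class, sensitivity,
#'   specificity, precision, f1) and `accuracy`.
#' @export
classification_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (any(cm < 0)) stop("confusion matrix has negative counts", call. = FALSE)
  total <- sum(cm)
  if (total == 0) stop("confusion matrix is all zero", call. = FALSE)
  classes <- rownames(cm) %||% paste0("class", seq_len(nrow(cm)))
  per <- lapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    if (tp + fp == 0) {
      warning("class ", classes[i], ": no predicted positives; precision 0",
              call. = FALSE)
      prec <- 0
    } else prec <- tp / (tp + fp)
    f1 <- if (is.na(sens) || prec + sens == 0) 0 else
      2 * prec * sens / (prec + sens)
    data.frame(class = classes[i], sensitivity = sens, specificity = spec,
               precision = prec, f1 = f1)
  })
  list(per_class = do.call(rbind, per),
       accuracy = sum(diag(cm)) / total)
}

#' Nested leave-one-subject-out evaluation of one sensor configuration
#'
#' Outer loop: each subject in turn is the test set. Inner loop: for each
#' remaining (validation) subject, a 100-tree random forest is fitted on
#' the other training subjects and out-of-bag permutation importances are
#' recorded; importances are averaged arithmetically over the inner folds
#' and the top `k_selected` features chosen. The final forest is trained
#' on all training subjects with the selected features and evaluated on
#' the held-out subject. The test subject's rows are never seen by any
#' inner fold.
#'
#' @param tbl Modelling table from [prepare_feature_table()] (columns
#'   `subject_id`, `label`, features).
#' @param config Character vector of location codes, or a
#'   [sensor_configuration()].
#' @param spec A [training_spec()].
#' @return List of class `eval_report`: `configuration`, `category`,
#'   `per_fold` (left_out_subject, train_subjects, confusion,
#'   selected_features, accuracy), `aggregate_confusion`, `metrics`
#'   (per-class mean and SD over folds), `accuracy_mean`, `accuracy_sd`.
#' @export
nested_loso_evaluate <- function(tbl, config, spec = training_spec()) {
  if (inherits(config, "sensor_configuration")) {
    mask <- config$feature_mask
    locs <- config$locations
  } else {
    locs <- config
    mask <- feature_mask(config)
  }
  mask <- intersect(mask, names(tbl))
  if (length(mask) == 0L)
    stop("configuration has an empty feature mask", call. = FALSE)
  subjects <- unique(tbl$subject_id)
  if (length(subjects) < 3L)
    stop("nested LOSO needs >= 3 subjects", call. = FALSE)
  if (nlevels(droplevels(as.factor(tbl$label))) < 3L)
    stop("need all 3 fatigue classes present", call. = FALSE)

  lv <- fatigue_levels()
  agg <- matrix(0L, 3, 3, dimnames = list(true = lv, predicted = lv))
  per_fold <- list()
  for (oi in seq_along(subjects)) {
    test_subj <- subjects[oi]
    train_subjects <- setdiff(subjects, test_subj)
    imps <- list()
    for (vi in seq_along(train_subjects)) {
      val_subj <- train_subjects[vi]
      inner <- tbl[!(tbl$subject_id %in% c(test_subj, val_subj)), ,
                   drop = FALSE]
      imps[[vi]] <- oob_permutation_importance(
        inner[, mask, drop = FALSE], inner$label, spec,
        seed = derive_seed(spec$seed, oi, vi))
    }
    selected <- select_features(imps, spec$k_selected)

    train <- tbl[tbl$subject_id != test_subj, , drop = FALSE]
    test <- tbl[tbl$subject_id == test_subj, , drop = FALSE]
    fit <- ranger::ranger(
      x = train[, selected, drop = FALSE], y = droplevels(train$label),
      num.trees = spec$n_trees,
      seed = derive_seed(spec$seed, oi, 0), num.threads = 1)
    pred <- stats::predict(fit, data = test[, selected, drop = FALSE])
    cm <- table(true = factor(test$label, levels = lv),
                predicted = factor(pred$predictions, levels = lv))
    cm <- unclass(cm)
    agg <- agg + cm
    per_fold[[oi]] <- list(
      left_out_subject = test_subj,
      train_subjects = train_subjects,
      n_test = nrow(test),
      confusion = cm,
      selected_features = selected,
      accuracy = sum(diag(cm)) / sum(cm))
  }

  fold_metrics <- lapply(per_fold, function(f)
    classification_metrics(f$confusion)$per_class)
  metric_names <- c("sensitivity", "specificity", "precision", "f1")
  metrics <- do.call(rbind, lapply(seq_along(lv), function(i) {
    rows <- do.call(rbind, lapply(fold_metrics, function(m) m[i, ]))
    out <- data.frame(class = lv[i])
    for (mn in metric_names) {
      out[[paste0(mn, "_mean")]] <- mean(rows[[mn]], na.rm = TRUE)
      out[[paste0(mn, "_sd")]] <- stats::sd(rows[[mn]], na.rm = TRUE)
    }
    out
  }))
  accs <- vapply(per_fold, `[[`, numeric(1), "accuracy")
  structure(list(configuration = config_label(locs),
                 category = categorize(locs),
                 n_features = length(mask),
                 per_fold = per_fold,
                 aggregate_confusion = agg,
                 metrics = metrics,
                 accuracy_mean = mean(accs),
                 accuracy_sd = stats::sd(accs)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s [%s]: accuracy %.3f +/- %.3f (%d folds)\n",
              x$configuration, x$category, x$accuracy_mean, x$accuracy_sd,
              length(x$per_fold)))
  print(x$aggregate_confusion)
  invisible(x)
}
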