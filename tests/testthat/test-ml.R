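test_that("OOB permutation importance finds signal and is seeded", {
  tbl <- constructed_table(n_subjects = 3, n_per_class = 30)
  feats <- feature_mask(c("L4", "L6"))
  spec <- training_spec(seed = 42)
  imp <- oob_permutation_importance(tbl[, feats], tbl$label, spec)
  expect_length(imp, length(feats))
  expect_equal(names(which.max(imp)), "L6_acc_std")
  expect_identical(imp,
                   oob_permutation_importance(tbl[, feats], tbl$label, spec))

  # pure-noise features: importances centred at 0
  noise <- constructed_table(n_subjects = 3, n_per_class = 30,
                             informative = NULL)
  imp0 <- oob_permutation_importance(noise[, feats], noise$label, spec)
  expect_lt(abs(mean(imp0)), 0.01)

  expect_error(
    oob_permutation_importance(tbl[, feats],
                               rep("no_fatigue", nrow(tbl)), spec),
    "2 classes")
})

test_that("importance agrees with an independent forest implementation", {
  skip_if_not_installed("randomForest")
  # graded signal strengths: both implementations should order them alike
  strengths <- c(L6_acc_std = 1.5, L6_acc_peak = 1.0, L4_gyr_std = 0.7,
                 knee_left_midstance = 0.45, L4_acc_iqr = 0.25)
  tbl <- constructed_table(n_subjects = 3, n_per_class = 40,
                           strengths = strengths)
  feats <- feature_mask(c("L4", "L6"))
  imp <- oob_permutation_importance(tbl[, feats], tbl$label,
                                    training_spec(n_trees = 300, seed = 42))
  withr::with_seed(42,
    rf <- randomForest::randomForest(x = tbl[, feats], y = tbl$label,
                                     ntree = 300, importance = TRUE))
  imp_rf <- rf$importance[, "MeanDecreaseAccuracy"]
  expect_equal(names(which.max(imp_rf)), names(which.max(imp)))
  sig <- names(strengths)
  expect_gt(stats::cor(imp[sig], imp_rf[sig], method = "spearman"), 0.6)
  # both rank every true signal above the noise floor
  expect_true(all(rank(-imp)[sig] <= 10))
  expect_true(all(rank(-imp_rf[names(imp)])[sig] <= 10))
})

test_that("feature selection keeps top-k with canonical tie-breaking", {
  imp <- stats::setNames(seq(34, 1), feature_mask(c("L4", "L6")))
  sel <- select_features(imp, 12)
  expect_length(sel, 12)
  expect_equal(sel[1], names(imp)[1])

  # single-sensor mask of 12 features: returned whole
  imp1 <- stats::setNames(stats::runif(12), feature_mask("L6"))
  expect_length(select_features(imp1, 12), 12)

  # ties resolved by catalogue order
  tied <- stats::setNames(c(1, 1, 0), c("L6_acc_std", "L1_acc_peak", "L2_acc_mean"))
  expect_equal(select_features(tied, 1), "L1_acc_peak")

  # list/matrix input averaged across folds
  two <- list(stats::setNames(c(1, 0), c("a", "b")),
              stats::setNames(c(0, 3), c("a", "b")))
  expect_equal(select_features(two, 1), "b")
})

test_that("classification metrics follow one-vs-rest definitions", {
  d <- diag(c(5, 7, 9))
  rownames(d) <- colnames(d) <- fatigue_levels()
  m <- classification_metrics(d)
  expect_equal(m$accuracy, 1)
  expect_true(all(m$per_class$sensitivity == 1))
  expect_true(all(m$per_class$f1 == 1))

  u <- matrix(4, 3, 3)
  m <- classification_metrics(u)
  expect_equal(m$accuracy, 1 / 3)
  expect_true(all(abs(m$per_class$sensitivity - 1 / 3) < 1e-12))

  cm <- matrix(c(8, 1, 1, 2, 6, 2, 0, 2, 8), 3, 3, byrow = TRUE)
  m <- classification_metrics(cm)
  expect_equal(m$accuracy, 22 / 30)
  expect_equal(m$per_class$precision[1], 8 / 10)
  expect_equal(m$per_class$sensitivity[1], 8 / 10)

  expect_error(classification_metrics(matrix(0, 3, 3)), "all zero")
  # third class never predicted -> zero predicted positives
  never_pred <- matrix(c(2, 1, 0, 1, 2, 0, 1, 1, 0), 3, 3, byrow = TRUE)
  expect_warning(m <- classification_metrics(never_pred),
                 "no predicted positives")
  expect_equal(m$per_class$precision[3], 0)
})

test_that("nested LOSO separates test subjects and aggregates correctly", {
  tbl <- constructed_table(n_subjects = 4, n_per_class = 25)
  spec <- training_spec(seed = 7)
  rep <- nested_loso_evaluate(tbl, c("L4", "L6"), spec)

  subjects <- unique(tbl$subject_id)
  expect_length(rep$per_fold, 4)
  for (f in rep$per_fold) {
    # provenance: the test subject is excluded from every training list
    expect_false(f$left_out_subject %in% f$train_subjects)
    expect_setequal(c(f$left_out_subject, f$train_subjects), subjects)
    expect_equal(f$n_test, sum(tbl$subject_id == f$left_out_subject))
    expect_equal(sum(f$confusion), f$n_test)
    expect_length(f$selected_features, 12)
  }
  # aggregate totals equal total labeled rows
  expect_equal(sum(rep$aggregate_confusion), nrow(tbl))
  # aggregate accuracy = row-weighted mean of fold accuracies
  accs <- vapply(rep$per_fold, `[[`, numeric(1), "accuracy")
  ns <- vapply(rep$per_fold, `[[`, numeric(1), "n_test")
  expect_equal(sum(diag(rep$aggregate_confusion)) / sum(rep$aggregate_confusion),
               sum(accs * ns) / sum(ns))
  # perfectly informative feature -> near-perfect accuracy, selected first
  expect_gt(rep$accuracy_mean, 0.95)
  expect_true(all(vapply(rep$per_fold, function(f)
    f$selected_features[1] == "L6_acc_std", TRUE)))

  expect_error(nested_loso_evaluate(tbl[tbl$subject_id %in% subjects[1:2], ],
                                    c("L4", "L6"), spec), ">= 3 subjects")
  tbl_bad <- tbl; tbl_bad$label <- droplevels(factor("no_fatigue"))
  expect_error(nested_loso_evaluate(tbl_bad, c("L4", "L6"), spec), "classes")
})

test_that("single-sensor configurations skip selection (12 features)", {
  tbl <- constructed_table(n_subjects = 3, n_per_class = 20, config = "L6",
                           informative = "L6_acc_std")
  rep <- nested_loso_evaluate(tbl, "L6", training_spec(seed = 3))
  for (f in rep$per_fold) {
    expect_setequal(f$selected_features, feature_mask("L6"))
  }
})

test_that("reports summarize and rank features across folds", {
  tbl <- constructed_table(n_subjects = 3, n_per_class = 20)
  reports <- list(
    a = nested_loso_evaluate(tbl, c("L4", "L6"), training_spec(seed = 1)),
    b = nested_loso_evaluate(tbl, "L6", training_spec(seed = 1)))
  sm <- summarize_reports(reports)
  expect_equal(nrow(sm), 2)
  expect_true(all(diff(sm$accuracy_mean) <= 0))

  rk <- ranked_feature_table(reports$a, n = 5)
  expect_equal(nrow(rk), 5)
  expect_equal(rk$feature[1], "L6_acc_std")
  expect_true(all(diff(rk$n_folds_selected) <= 0))
})
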