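# Leave-2-male-trials-out cross-validation, the metric suite and
# outlier-trial quality control.

#' Expected call for each class label
#'
#' Male and focal-male tracks are expected to be classified as male;
#' couples and females as non-male. Unknown labels return `NA` and are
#' excluded from evaluation.
#'
#' @param label character vector of labels.
#' @return character vector `"male"` / `"non_male"` / `NA`.
#' @export
expected_call <- function(label) {
  out <- rep(NA_character_, length(label))
  out[label %in% c("male", "focal_male")] <- "male"
  out[label %in% c("couple", "female")] <- "non_male"
  out
}

#' Enumerate leave-2-out folds over the male trials
#'
#' One fold per unordered pair of male trials held out for testing; the
#' remaining male trials train the detector. Enumeration order is
#' deterministic (sorted trial ids).
#'
#' @param male_trials character vector of >= 3 male trial ids.
#' @return list of folds, each `list(fold_id, test_male, train_male)`.
#' @export
make_folds <- function(male_trials) {
  male_trials <- sort(unique(male_trials))
  if (length(male_trials) < 3L)
    stopf("parameter error: need >= 3 male trials, got %d",
          length(male_trials))
  pairs <- utils::combn(male_trials, 2L)
  lapply(seq_len(ncol(pairs)), function(k) {
    list(fold_id = sprintf("fold%02d", k),
         test_male = pairs[, k],
         train_male = setdiff(male_trials, pairs[, k]))
  })
}

#' Run one cross-validation fold
#'
#' Feature selection and detector fitting see only training-split rows:
#' the screen compares male segments of the training trials against
#' non-male segments of the designated validation trials (which are in no
#' fold's test set), and the scaler and SVM are fitted on the training male
#' segments alone. The test set is the two held-out male trials plus every
#' couple, female and focal-male track outside the validation trials.
#'
#' @param fold one element of [make_folds()].
#' @param fm feature matrix of the whole dataset.
#' @param validation_trials trial ids reserved for screening/tuning,
#'   excluded from testing.
#' @param config a [detector_config()].
#' @param alpha,cor_threshold selection parameters.
#' @return `"fold_result"`: the selection, detector, segment predictions
#'   and voted track predictions (with `expected` calls attached).
#' @export
run_fold <- function(fold, fm, validation_trials = character(),
                     config = detector_config(), alpha = 0.01,
                     cor_threshold = 0.85) {
  is_male_lab <- fm$label == "male"
  train_rows <- is_male_lab & fm$trial_id %in% fold$train_male
  screen_nonmale <- fm$label %in% c("couple", "female") &
    fm$trial_id %in% validation_trials
  if (!any(screen_nonmale))
    stopf("no non-male segments available for screening; supply validation_trials containing non-male tracks")
  screen_fm <- fm[train_rows | screen_nonmale, , drop = FALSE]
  sel <- select_features(screen_fm, screen_fm$label == "male",
                         alpha = alpha, cor_threshold = cor_threshold)
  if (!length(sel$selected)) {
    # no feature separates the classes (e.g. a null dataset): fall back to
    # correlation pruning of the full candidate set so a detector can still
    # be fitted; the screen is advisory in that case
    message(fold$fold_id,
            ": no significant features; pruning full candidate set")
    sel$significant <- sel$statistics$feature
    sel <- correlation_prune(screen_fm, sel, cor_threshold)
  }
  det <- fit_detector(fm[train_rows, , drop = FALSE], sel$selected, config)
  test_rows <- (is_male_lab & fm$trial_id %in% fold$test_male) |
    (fm$label %in% c("couple", "female", "focal_male") &
       !(fm$trial_id %in% validation_trials))
  if (!any(test_rows)) stopf("empty test set in %s", fold$fold_id)
  seg_preds <- predict_segments(det, fm[test_rows, , drop = FALSE])
  track_preds <- vote_tracks(seg_preds)
  track_preds$expected <- expected_call(track_preds$label)
  structure(list(fold_id = fold$fold_id, fold = fold, selection = sel,
                 detector = det, segment_preds = seg_preds,
                 track_preds = track_preds),
            class = "fold_result")
}

# average precision (step-wise PR AUC): sum over thresholds of
# (recall gain) * precision
pr_auc <- function(score, positive) {
  o <- order(score, decreasing = TRUE)
  pos <- positive[o]
  if (!any(pos)) return(NA_real_)
  tp <- cumsum(pos)
  prec <- tp / seq_along(pos)
  rec <- tp / sum(pos)
  sum(diff(c(0, rec)) * prec)
}

roc_auc <- function(score, positive) {
  if (!any(positive) || all(positive)) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = positive, predictor = score,
                                 levels = c(FALSE, TRUE), direction = "<",
                                 quiet = TRUE)))
}

fold_track_metrics <- function(tp) {
  tp <- tp[!is.na(tp$expected), , drop = FALSE]
  exp_male <- tp$expected == "male"
  call_male <- tp$call == "male"
  TP <- sum(exp_male & call_male); FN <- sum(exp_male & !call_male)
  FP <- sum(!exp_male & call_male); TN <- sum(!exp_male & !call_male)
  rec_m <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  rec_n <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  prec_m <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  f1 <- if (is.na(prec_m) || is.na(rec_m) || prec_m + rec_m == 0) NA_real_
        else 2 * prec_m * rec_m / (prec_m + rec_m)
  sub_acc <- vapply(KNOWN_LABELS, function(l) {
    i <- tp$label == l
    if (any(i)) mean(tp$call[i] == tp$expected[i]) else NA_real_
  }, numeric(1))
  c(accuracy = mean(call_male == exp_male),
    balanced_accuracy = mean(c(rec_m, rec_n)),
    precision = prec_m, recall = rec_m, f1 = f1,
    roc_auc = roc_auc(tp$decision, exp_male),
    pr_auc_male = pr_auc(tp$decision, exp_male),
    pr_auc_non_male = pr_auc(-tp$decision, !exp_male),
    stats::setNames(sub_acc, paste0("acc_", names(sub_acc))),
    TP = TP, FN = FN, FP = FP, TN = TN)
}

percentile_ci <- function(x, n_boot = 2000L, level = 0.95) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(c(lo = NA_real_, hi = NA_real_))
  bm <- vapply(seq_len(n_boot), function(i) {
    mean(sample(x, replace = TRUE))
  }, numeric(1))
  stats::setNames(stats::quantile(bm, c((1 - level) / 2, (1 + level) / 2),
                                  names = FALSE), c("lo", "hi"))
}

#' Aggregate fold results into a metrics report
#'
#' Track-level accuracy, balanced accuracy, precision, recall, F1, ROC AUC
#' and PR AUC per fold, averaged across folds with percentile-bootstrap 95%
#' confidence intervals, plus per-subclass accuracies and the pooled
#' confusion matrix (summed over folds). Folds where a ranking metric is
#' undefined (a single class present) are excluded from that metric's
#' average with a message. The bootstrap is seeded internally so the report
#' is deterministic.
#'
#' @param fold_results list of `"fold_result"` objects.
#' @param n_boot bootstrap resamples for the CIs.
#' @return a `"metrics_report"`: `$per_fold` (data.frame), `$summary`
#'   (mean and CI per metric), `$confusion` (2x2 pooled counts).
#' @export
compute_metrics <- function(fold_results, n_boot = 2000L) {
  stopifnot(length(fold_results) >= 1L)
  per_fold <- as.data.frame(t(vapply(
    fold_results, function(fr) fold_track_metrics(fr$track_preds),
    fold_track_metrics(fold_results[[1L]]$track_preds))))
  per_fold <- cbind(fold_id = vapply(fold_results, `[[`, character(1),
                                     "fold_id"), per_fold)
  metric_cols <- setdiff(names(per_fold),
                         c("fold_id", "TP", "FN", "FP", "TN"))
  n_undef <- sum(is.na(per_fold$roc_auc))
  if (n_undef > 0)
    message(n_undef, " fold(s) had undefined ranking metrics (single class)")
  summary <- do.call(rbind, lapply(metric_cols, function(m) {
    x <- per_fold[[m]]
    ci <- withr_seed(107L, percentile_ci(x, n_boot))
    data.frame(metric = m, mean = mean(x, na.rm = TRUE),
               lo = ci[["lo"]], hi = ci[["hi"]], n_folds = sum(is.finite(x)),
               stringsAsFactors = FALSE)
  }))
  confusion <- matrix(c(sum(per_fold$TP), sum(per_fold$FN),
                        sum(per_fold$FP), sum(per_fold$TN)),
                      2L, 2L, byrow = TRUE,
                      dimnames = list(expected = c("male", "non_male"),
                                      called = c("male", "non_male")))
  structure(list(per_fold = per_fold, summary = summary,
                 confusion = confusion),
            class = "metrics_report")
}

# evaluate an expression under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics report>\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-18s %.3f (%.3f-%.3f)\n", s$metric[i], s$mean[i],
                s$lo[i], s$hi[i]))
  cat("pooled confusion (rows expected, cols called):\n")
  print(x$confusion)
  invisible(x)
}

#' Run the full cross-validation
#'
#' Enumerates leave-2-out folds over the male trials (validation trials
#' excluded), runs each fold and aggregates the metrics.
#'
#' @param fm feature matrix of the whole dataset.
#' @param validation_trials trial ids held out from training and testing
#'   (used for screening non-males and for tuning).
#' @inheritParams run_fold
#' @return list with `folds` (fold results) and `metrics`
#'   (a `"metrics_report"`).
#' @export
run_crossval <- function(fm, validation_trials = character(),
                         config = detector_config(), alpha = 0.01,
                         cor_threshold = 0.85) {
  male_trials <- setdiff(unique(fm$trial_id[fm$label == "male"]),
                         validation_trials)
  folds <- make_folds(male_trials)
  results <- lapply(folds, run_fold, fm = fm,
                    validation_trials = validation_trials, config = config,
                    alpha = alpha, cor_threshold = cor_threshold)
  list(folds = results, metrics = compute_metrics(results))
}

#' Flag outlier trials by duration and travelled distance
#'
#' Advisory quality control: for every track, the duration and total path
#' length are computed; a trial is flagged when its per-trial centroid lies
#' outside the normal-theory 95% confidence ellipse (chi-squared Mahalanobis
#' bound) of the remaining trials' (duration, distance) track points. The
#' leave-one-trial-out fit keeps a grossly anomalous trial from masking
#' itself by inflating the covariance. Exclusion of a flagged trial is the
#' caller's decision.
#'
#' @param x a `trackset` with >= 3 trials (fewer: nothing is flagged, with
#'   a message).
#' @param level confidence level of the ellipse (default 0.95).
#' @return character vector of flagged trial ids (possibly empty), with the
#'   per-trial statistics in attribute `"stats"`.
#' @export
detect_outlier_trials <- function(x, level = 0.95) {
  stopifnot(inherits(x, "trackset"))
  trial <- vapply(x$tracks, `[[`, character(1), "trial_id")
  if (length(unique(trial)) < 3L) {
    message("fewer than 3 trials; outlier QC skipped")
    return(character(0))
  }
  dur <- vapply(x$tracks, track_duration, numeric(1))
  dist <- vapply(x$tracks, function(tr) {
    sum(sqrt(rowSums(diff(tr$xyz)^2)))
  }, numeric(1))
  pts <- cbind(dur, dist)
  idx <- split(seq_along(dur), trial)
  cent <- do.call(rbind, lapply(idx, function(i) {
    colMeans(pts[i, , drop = FALSE])
  }))
  # each trial is scored against the ellipse of the other trials' tracks,
  # so a grossly anomalous trial cannot mask itself by inflating the fit
  d2 <- vapply(names(idx), function(tr) {
    rest <- pts[-idx[[tr]], , drop = FALSE]
    S <- stats::cov(rest)
    if (!is.finite(det(S)) || det(S) <= 0) return(NA_real_)
    stats::mahalanobis(cent[tr, , drop = FALSE], colMeans(rest), S)
  }, numeric(1))
  flagged <- names(idx)[!is.na(d2) & d2 > stats::qchisq(level, df = 2L)]
  out <- flagged
  attr(out, "stats") <- data.frame(trial_id = rownames(cent),
                                   mean_duration = cent[, 1L],
                                   mean_distance = cent[, 2L],
                                   mahalanobis2 = d2,
                                   row.names = NULL,
                                   stringsAsFactors = FALSE)
  out
}
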