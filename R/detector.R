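# One-class detector: Z-score standardisation fitted on male training data,
# nu-parameterised one-class SVM, per-segment prediction, per-track voting.

#' Detector configuration
#'
#' @param nu upper bound on the fraction of training errors and lower bound
#'   on the fraction of support vectors, in (0, 1]. Default 0.20, the
#'   grid-search optimum on the field data.
#' @param kernel one of `"radial_basis"` (default, the grid-search
#'   optimum), `"linear"`, `"polynomial"`, `"sigmoid"`.
#' @param gamma kernel bandwidth; `NULL` uses
#'   `1 / (n_features * mean feature variance)` of the standardised
#'   training data.
#' @param degree,coef0 polynomial/sigmoid kernel parameters.
#' @return a `"detector_config"` list.
#' @export
detector_config <- function(nu = 0.20, kernel = "radial_basis",
                            gamma = NULL, degree = 3L, coef0 = 0) {
  if (!(nu > 0 && nu <= 1)) stopf("parameter error: nu must be in (0, 1]")
  kernel <- match.arg(kernel,
                      c("radial_basis", "linear", "polynomial", "sigmoid"))
  structure(list(nu = nu, kernel = kernel, gamma = gamma,
                 degree = degree, coef0 = coef0),
            class = "detector_config")
}

e1071_kernel <- c(radial_basis = "radial", linear = "linear",
                  polynomial = "polynomial", sigmoid = "sigmoid")

#' Fit the one-class detector on male training segments
#'
#' Standardisation (Z-score) statistics are computed from the male training
#' rows only and later applied unchanged to all test data; the one-class
#' SVM then learns a decision boundary around the standardised male
#' segments. Rows not labelled `male` violate the contract and raise an
#' error.
#'
#' @param fm feature matrix whose rows are all male training segments.
#' @param selected character vector of feature names to use.
#' @param config a [detector_config()].
#' @return a `"trained_detector"`: scaler means/sds, the fitted SVM, the
#'   config and the feature set.
#' @export
fit_detector <- function(fm, selected, config = detector_config()) {
  stopifnot(inherits(config, "detector_config"))
  if (!all(fm$label == "male"))
    stopf("contract violation: non-male rows in the training matrix")
  if (nrow(fm) < 10L)
    stopf("need >= 10 male training segments")
  missing_f <- setdiff(selected, names(fm))
  if (length(missing_f))
    stopf("schema mismatch: missing feature(s) %s",
          paste(missing_f, collapse = ", "))
  X <- as.matrix(fm[selected])
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0] <- 1      # constant feature: centre only
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, `/`)
  gamma <- config$gamma %||% (1 / (ncol(Xs) * mean(apply(Xs, 2L, stats::var))))
  fit <- e1071::svm(Xs, y = NULL, type = "one-classification",
                    kernel = e1071_kernel[[config$kernel]],
                    nu = config$nu, gamma = gamma, degree = config$degree,
                    coef0 = config$coef0, scale = FALSE)
  structure(list(mean = mu, sd = sdv, fit = fit, config = config,
                 gamma = gamma, features = selected),
            class = "trained_detector")
}

#' @export
print.trained_detector <- function(x, ...) {
  cat(sprintf(
    "<one-class detector> nu = %.2f, kernel = %s, %d features, %d SVs\n",
    x$config$nu, x$config$kernel, length(x$features), x$fit$tot.nSV))
  invisible(x)
}

#' Predict segments with a trained detector
#'
#' Applies the male-training scaler, evaluates the signed distance to the
#' hyperplane (positive inside the boundary: male), and maps it to a
#' pseudo-probability with the logistic function `1 / (1 + exp(-d))` —
#' larger distances mean more certainty.
#'
#' @param det a `"trained_detector"`.
#' @param fm feature matrix to score (must contain the detector's feature
#'   set).
#' @return data.frame with lineage columns plus `decision`, `prob` and the
#'   binary `call` (`"male"` / `"non_male"`).
#' @export
predict_segments <- function(det, fm) {
  stopifnot(inherits(det, "trained_detector"))
  missing_f <- setdiff(det$features, names(fm))
  if (length(missing_f))
    stopf("schema mismatch: missing feature(s) %s",
          paste(missing_f, collapse = ", "))
  X <- as.matrix(fm[det$features])
  Xs <- sweep(sweep(X, 2L, det$mean), 2L, det$sd, `/`)
  dec <- as.numeric(attr(stats::predict(det$fit, Xs, decision.values = TRUE),
                         "decision.values"))
  out <- fm[intersect(LINEAGE_COLUMNS, names(fm))]
  out$decision <- dec
  out$prob <- stats::plogis(dec)
  out$call <- ifelse(dec > 0, "male", "non_male")
  out
}

#' Vote segment predictions into track predictions
#'
#' Each track is called by the mode of its segments' calls; an exact tie is
#' classified as anomalous (non-male). The track-level decision score is
#' the mean of the segment decision values (used for ranking-based
#' metrics), with the matching logistic pseudo-probability.
#'
#' @param preds segment predictions from [predict_segments()].
#' @return data.frame with one row per track: `track_id`, `trial_id`,
#'   `label`, `n_segments`, `n_male_calls`, `decision`, `prob`, `call`.
#' @export
vote_tracks <- function(preds) {
  idx <- split(seq_len(nrow(preds)), preds$track_id)
  rows <- lapply(idx, function(i) {
    male_n <- sum(preds$call[i] == "male")
    non_n <- length(i) - male_n
    data.frame(track_id = preds$track_id[i][1L],
               trial_id = preds$trial_id[i][1L],
               label = preds$label[i][1L],
               n_segments = length(i),
               n_male_calls = male_n,
               decision = mean(preds$decision[i]),
               prob = stats::plogis(mean(preds$decision[i])),
               call = if (male_n > non_n) "male" else "non_male",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
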