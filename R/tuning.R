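# Cross-validated grid search over nu, kernel, window size and overlap.

#' Hyperparameter grid specification
#'
#' Defaults reproduce the full tuning ranges: nu from 0 to 1 in steps of
#' 0.01, the four kernels, window sizes 1-10 s in steps of 0.2 s and
#' overlaps 0.2-5 s in steps of 0.2 s. Infeasible combinations (overlap >=
#' window, or nu = 0, which the nu-formulation does not admit) are skipped
#' at search time with a logged count.
#'
#' @param nu,kernel,window_s,overlap_s candidate values.
#' @return a `"grid_spec"` list.
#' @export
grid_spec <- function(nu = seq(0, 1, by = 0.01),
                      kernel = c("linear", "radial_basis", "polynomial",
                                 "sigmoid"),
                      window_s = seq(1, 10, by = 0.2),
                      overlap_s = seq(0.2, 5, by = 0.2)) {
  structure(list(nu = nu, kernel = kernel, window_s = window_s,
                 overlap_s = overlap_s),
            class = "grid_spec")
}

#' Enumerate the feasible grid
#'
#' @param grid a [grid_spec()].
#' @return data.frame of feasible combinations, with the number skipped in
#'   attribute `"n_skipped"`.
#' @export
feasible_grid <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  full <- expand.grid(nu = grid$nu, kernel = grid$kernel,
                      window_s = grid$window_s, overlap_s = grid$overlap_s,
                      stringsAsFactors = FALSE)
  ok <- full$overlap_s < full$window_s & full$nu > 0 & full$nu <= 1
  out <- full[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Grid search maximising validation balanced accuracy
#'
#' Every feasible combination is evaluated end to end: tracks are
#' re-filtered and re-segmented for each (window, overlap) pair, features
#' re-extracted, features selected (training males of the non-validation
#' trials vs the validation non-males), the detector fitted on the training
#' males, and the validation tracks voted and scored by balanced accuracy.
#' Feature extraction and selection are cached per (window, overlap) since
#' nu and kernel do not affect them. The search is exhaustive over the
#' feasible grid and deterministic; results are ranked by balanced accuracy
#' with ties broken by smaller nu, then smaller window.
#'
#' @param x a `trackset`.
#' @param validation_trials trial ids (male and non-male) scored by the
#'   search; disjoint from the training trials by construction.
#' @param grid a [grid_spec()].
#' @param alpha,cor_threshold selection parameters.
#' @return data.frame of configurations sorted best-first, with columns
#'   `window_s, overlap_s, nu, kernel, balanced_accuracy, n_selected`.
#' @export
grid_search <- function(x, validation_trials, grid = grid_spec(),
                        alpha = 0.01, cor_threshold = 0.85) {
  stopifnot(inherits(x, "trackset"))
  fg <- feasible_grid(grid)
  if (!nrow(fg)) stopf("empty feasible grid")
  if (attr(fg, "n_skipped") > 0)
    message("skipped ", attr(fg, "n_skipped"), " infeasible combinations")
  windows <- unique(fg[c("window_s", "overlap_s")])
  rows <- list()
  for (w in seq_len(nrow(windows))) {
    ws <- windows$window_s[w]; os <- windows$overlap_s[w]
    fx <- filter_short_tracks(x, ws, quiet = TRUE)
    fm <- feature_matrix(segment_dataset(fx, ws, os))
    train_rows <- fm$label == "male" &
      !(fm$trial_id %in% validation_trials)
    val_rows <- fm$trial_id %in% validation_trials
    screen_fm <- fm[(train_rows | (val_rows & fm$label != "male")), ,
                    drop = FALSE]
    sel <- tryCatch(
      select_features(screen_fm, screen_fm$label == "male", alpha,
                      cor_threshold),
      error = function(e) NULL)
    if (is.null(sel) || !length(sel$selected)) next
    sub <- fg[fg$window_s == ws & fg$overlap_s == os, , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      cfg <- detector_config(nu = sub$nu[k], kernel = sub$kernel[k])
      ba <- tryCatch({
        det <- fit_detector(fm[train_rows, , drop = FALSE], sel$selected,
                            cfg)
        tp <- vote_tracks(predict_segments(det, fm[val_rows, , drop = FALSE]))
        tp$expected <- expected_call(tp$label)
        tp <- tp[!is.na(tp$expected), , drop = FALSE]
        rec_m <- mean(tp$call[tp$expected == "male"] == "male")
        rec_n <- mean(tp$call[tp$expected == "non_male"] == "non_male")
        mean(c(rec_m, rec_n))
      }, error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        window_s = ws, overlap_s = os, nu = sub$nu[k],
        kernel = sub$kernel[k], balanced_accuracy = ba,
        n_selected = length(sel$selected), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$balanced_accuracy, out$nu, out$window_s), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
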