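fake_fold <- function(tp, id = "fold01") {
  structure(list(fold_id = id, fold = NULL, selection = NULL,
                 detector = NULL, segment_preds = NULL, track_preds = tp),
            class = "fold_result")
}

mk_tp <- function(expected, call, decision = NULL) {
  n <- length(expected)
  lab <- ifelse(expected == "male", "male", "couple")
  data.frame(track_id = sprintf("t%03d", seq_len(n)), trial_id = "T1",
             label = lab, n_segments = 2, n_male_calls = 1,
             decision = decision %||% ifelse(call == "male", 1, -1),
             prob = 0.5, call = call, expected = expected,
             stringsAsFactors = FALSE)
}

test_that("fold enumeration is all unordered pairs of male trials", {
  expect_length(make_folds(sprintf("M%02d", 1:8)), 28L)
  expect_length(make_folds(c("a", "b", "c")), 3L)
  folds <- make_folds(sprintf("M%d", 1:5))
  pairs <- t(vapply(folds, `[[`, character(2), "test_male"))
  manual <- t(combn(sort(sprintf("M%d", 1:5)), 2))
  expect_equal(pairs, manual)
  # train/test disjoint in every fold
  for (f in folds)
    expect_length(intersect(f$test_male, f$train_male), 0L)
  expect_error(make_folds(c("a", "b")), "parameter error")
})

test_that("expected calls map focal males to male and couples/females to non-male", {
  expect_equal(expected_call(c("male", "focal_male", "couple", "female",
                               "unknown")),
               c("male", "male", "non_male", "non_male", NA))
})

test_that("metrics match hand computation on a constructed confusion", {
  # TP=6 FN=4 TN=7 FP=3 with male positive
  expected <- c(rep("male", 10), rep("non_male", 10))
  call <- c(rep("male", 6), rep("non_male", 4),
            rep("non_male", 7), rep("male", 3))
  m <- swarmtrack:::fold_track_metrics(mk_tp(expected, call))
  expect_equal(m[["recall"]], 0.6)
  expect_equal(m[["precision"]], 6 / 9, tolerance = 1e-12)
  expect_equal(m[["balanced_accuracy"]], 0.65)
  expect_equal(m[["accuracy"]], 13 / 20)
  expect_equal(m[["f1"]], 2 * (6 / 9) * 0.6 / ((6 / 9) + 0.6))
  expect_equal(unname(m[c("TP", "FN", "FP", "TN")]), c(6, 4, 3, 7))
})

test_that("perfect predictions score 1 on every metric", {
  expected <- rep(c("male", "non_male"), each = 8)
  tp <- mk_tp(expected, expected,
              decision = ifelse(expected == "male", 2, -2) + rnorm(16, 0, 0.1))
  rep <- compute_metrics(list(fake_fold(tp)), n_boot = 50)
  s <- rep$summary
  for (m in c("accuracy", "balanced_accuracy", "precision", "recall", "f1",
              "roc_auc", "pr_auc_male"))
    expect_equal(s$mean[s$metric == m], 1)
})

test_that("random scores give chance-level ROC AUC", {
  set.seed(77)
  expected <- rep(c("male", "non_male"), each = 1000)
  dec <- rnorm(2000)
  auc <- swarmtrack:::roc_auc(dec, expected == "male")
  expect_equal(auc, 0.5, tolerance = 0.04)
})

test_that("PR AUC equals the average-precision step sum", {
  score <- c(0.9, 0.8, 0.7, 0.6)
  pos <- c(TRUE, FALSE, TRUE, FALSE)
  # by hand: recall steps at ranks 1 (P=1) and 3 (P=2/3)
  expect_equal(swarmtrack:::pr_auc(score, pos), 0.5 * 1 + 0.5 * 2 / 3)
  expect_equal(swarmtrack:::pr_auc(c(2, 1), c(TRUE, FALSE)), 1)
})

test_that("pooled confusion counts are the sum over folds", {
  tp1 <- mk_tp(c("male", "male", "non_male"), c("male", "non_male", "male"))
  tp2 <- mk_tp(c("male", "non_male", "non_male"),
               c("male", "non_male", "non_male"))
  rep <- compute_metrics(list(fake_fold(tp1, "f1"), fake_fold(tp2, "f2")),
                         n_boot = 50)
  expect_equal(sum(rep$confusion), 6)
  expect_equal(rep$confusion["male", "male"], 2)
  expect_equal(rep$confusion["non_male", "non_male"], 2)
  expect_equal(rep$confusion["male", "non_male"], 1)
  expect_equal(rep$confusion["non_male", "male"], 1)
})

test_that("fold runs are complete, deterministic, and leak-free by interface", {
  fm <- small_fm()
  val <- c("C01")
  folds <- make_folds(setdiff(unique(fm$trial_id[fm$label == "male"]), val))
  fr <- run_fold(folds[[1]], fm, validation_trials = val)
  # every test track got a call
  test_ids <- unique(fm$track_id[
    (fm$label == "male" & fm$trial_id %in% folds[[1]]$test_male) |
      (fm$label %in% c("couple", "female", "focal_male") &
         !(fm$trial_id %in% val))])
  expect_setequal(fr$track_preds$track_id, test_ids)
  fr2 <- run_fold(folds[[1]], fm, validation_trials = val)
  expect_equal(fr$track_preds, fr2$track_preds)
  expect_identical(fr$selection$selected, fr2$selection$selected)
})

test_that("outlier-trial QC flags an injected high-velocity trial and only that", {
  ds <- simulate_swarm(sim_config(
    seed = 19L, n_male_trials = 5L, male_tracks_per_trial = 4L,
    male_duration = c(8, 12), n_couple_trials = 0L,
    couple_tracks_per_trial = 0L, n_female = 0L, n_focal = 0L,
    n_anomalous_trials = 1L))
  flagged <- detect_outlier_trials(ds)
  expect_true("M01" %in% flagged)
})

test_that("outlier-trial QC stays quiet under the null and on tiny datasets", {
  set.seed(23)
  rates <- replicate(20, {
    ds <- simulate_swarm(sim_config(
      seed = sample.int(1e6, 1), n_male_trials = 5L,
      male_tracks_per_trial = 4L, male_duration = c(8, 12),
      n_couple_trials = 0L, couple_tracks_per_trial = 0L,
      n_female = 0L, n_focal = 0L))
    length(detect_outlier_trials(ds)) / 5
  })
  expect_lte(mean(rates), 0.10)  # ~5% nominal plus Monte-Carlo slack
  one <- simulate_swarm(sim_config(seed = 2L, n_male_trials = 1L,
                                   male_tracks_per_trial = 3L,
                                   male_duration = c(8, 10),
                                   n_couple_trials = 0L,
                                   couple_tracks_per_trial = 0L,
                                   n_female = 0L, n_focal = 0L))
  expect_message(flags <- detect_outlier_trials(one), "fewer than 3")
  expect_length(flags, 0L)
})
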