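# gaussian male training matrix with lineage
gauss_fm <- function(n = 200, d = 4, label = "male", shift = 0,
                     trial = "T1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n * d, shift), n, d,
              dimnames = list(NULL, paste0("f", seq_len(d))))
  cbind(data.frame(segment_id = sprintf("%s_s%04d", trial, seq_len(n)),
                   track_id = sprintf("%s_t%03d", trial,
                                      rep(seq_len(ceiling(n / 4)),
                                          each = 4L)[seq_len(n)]),
                   trial_id = trial, label = label,
                   stringsAsFactors = FALSE),
        as.data.frame(X))
}

test_that("the scaler is fitted on male training rows and standardises them", {
  fm <- gauss_fm(seed = 1)
  det <- fit_detector(fm, paste0("f", 1:4))
  X <- as.matrix(fm[paste0("f", 1:4)])
  Xs <- sweep(sweep(X, 2, det$mean), 2, det$sd, `/`)
  expect_equal(unname(colMeans(Xs)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(Xs, 2, sd)), rep(1, 4), tolerance = 1e-12)
})

test_that("non-male rows in training violate the contract", {
  fm <- gauss_fm(seed = 2)
  fm$label[5] <- "couple"
  expect_error(fit_detector(fm, paste0("f", 1:4)), "contract violation")
})

test_that("nu bounds the training-error fraction", {
  fm <- gauss_fm(n = 1000, seed = 3)
  det <- fit_detector(fm, paste0("f", 1:4), detector_config(nu = 0.20))
  preds <- predict_segments(det, fm)
  outlier_frac <- mean(preds$call != "male")
  expect_lte(outlier_frac, 0.20 + 0.05)     # upper bound plus slack
  expect_gte(outlier_frac, 0.20 - 0.10)     # and not vacuously tiny
})

test_that("a far-away point is classified as an outlier", {
  fm <- gauss_fm(n = 300, seed = 4)
  det <- fit_detector(fm, paste0("f", 1:4))
  far <- gauss_fm(n = 5, shift = 25)
  preds <- predict_segments(det, far)
  expect_true(all(preds$call == "non_male"))
  expect_true(all(preds$decision < 0))
})

test_that("pseudo-probability is the logistic of the decision value", {
  fm <- gauss_fm(n = 100, seed = 5)
  det <- fit_detector(fm, paste0("f", 1:4))
  preds <- predict_segments(det, fm)
  expect_equal(preds$prob, plogis(preds$decision))
  expect_true(all(diff(preds$prob[order(preds$decision)]) >= 0))
  expect_equal(plogis(0), 0.5)   # a decision of 0 maps to probability 0.5
})

test_that("schema mismatch is rejected", {
  fm <- gauss_fm(seed = 6)
  det <- fit_detector(fm, paste0("f", 1:4))
  expect_error(predict_segments(det, fm[-(5:8)]), "schema mismatch")
  expect_error(fit_detector(fm, c("f1", "nope")), "schema mismatch")
})

test_that("voting follows the mode with ties resolved to non-male", {
  mk_preds <- function(calls, track = "t1") {
    data.frame(segment_id = paste0(track, "_", seq_along(calls)),
               track_id = track, trial_id = "T1", label = "male",
               decision = ifelse(calls == "male", 1, -1),
               prob = 0.5, call = calls, stringsAsFactors = FALSE)
  }
  expect_equal(vote_tracks(mk_preds(c("male", "male", "non_male")))$call,
               "male")
  expect_equal(vote_tracks(mk_preds(c("male", "non_male")))$call,
               "non_male")
  # permutation invariance
  p <- mk_preds(c("male", "non_male", "male", "non_male", "male"))
  expect_equal(vote_tracks(p)$call, vote_tracks(p[5:1, ])$call)
})

test_that("track votes equal the brute-force majority over 100 synthetic tracks", {
  set.seed(11)
  rows <- list()
  for (k in 1:100) {
    n <- sample(2:7, 1)
    calls <- sample(c("male", "non_male"), n, replace = TRUE)
    rows[[k]] <- data.frame(
      segment_id = sprintf("t%03d_%d", k, seq_len(n)),
      track_id = sprintf("t%03d", k), trial_id = "T1", label = "male",
      decision = rnorm(n), prob = 0.5, call = calls,
      stringsAsFactors = FALSE)
  }
  preds <- do.call(rbind, rows)
  tp <- vote_tracks(preds)
  for (k in seq_len(nrow(tp))) {
    calls <- preds$call[preds$track_id == tp$track_id[k]]
    manual <- if (sum(calls == "male") > length(calls) / 2) "male"
              else "non_male"
    expect_equal(tp$call[k], manual)
    expect_equal(tp$decision[k],
                 mean(preds$decision[preds$track_id == tp$track_id[k]]))
  }
})

test_that("duplicating every training row leaves predictions unchanged", {
  fm <- gauss_fm(n = 150, seed = 7)
  sel <- paste0("f", 1:4)
  det1 <- fit_detector(fm, sel, detector_config(kernel = "radial_basis"))
  det2 <- fit_detector(rbind(fm, fm), sel,
                       detector_config(kernel = "radial_basis"))
  test <- gauss_fm(n = 40, seed = 8)
  p1 <- predict_segments(det1, test)
  p2 <- predict_segments(det2, test)
  # the boundary is identical (calls agree everywhere); decision values are
  # defined up to the dual normalisation, which doubles with the row count
  expect_identical(p1$call, p2$call)
  expect_gt(cor(p1$decision, p2$decision), 0.999)
})
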