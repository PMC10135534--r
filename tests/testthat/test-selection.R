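# tiny feature-matrix builder: lineage + given feature columns
mini_fm <- function(..., label) {
  feats <- list(...)
  n <- length(feats[[1]])
  cbind(data.frame(segment_id = sprintf("s%03d", seq_len(n)),
                   track_id = sprintf("t%03d", seq_len(n)),
                   trial_id = "T1", label = label,
                   stringsAsFactors = FALSE),
        as.data.frame(feats))
}

test_that("the U test matches wilcox.test's normal approximation, ties included", {
  set.seed(4)
  for (i in 1:20) {
    x <- round(rnorm(30), i %% 3)    # rounding induces ties
    y <- round(rnorm(25, 0.3), i %% 3)
    got <- swarmtrack:::mann_whitney_u(x, y)
    ref <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(got[["U"]], unname(ref$statistic))
    expect_equal(got[["p"]], ref$p.value, tolerance = 1e-12)
  }
})

test_that("a feature identical in both classes is never selected", {
  lab <- rep(c("male", "couple"), each = 50)
  fm <- mini_fm(f_same = rep(1:50, 2), f_shift = c(rnorm(50), rnorm(50, 20)),
                label = lab)
  sel <- mann_whitney_screen(fm, fm$label == "male")
  p <- sel$statistics$p[sel$statistics$feature == "f_same"]
  expect_gt(p, 0.5)
  expect_false("f_same" %in% sel$selected)
  expect_true("f_shift" %in% sel$selected)
})

test_that("a 10-SD shift with 200 segments per class is always detected", {
  set.seed(10)
  lab <- rep(c("male", "couple"), each = 200)
  fm <- mini_fm(f = c(rnorm(200), rnorm(200, 10)), label = lab)
  sel <- mann_whitney_screen(fm, fm$label == "male")
  expect_identical(sel$selected, "f")
})

test_that("constant features get p = 1", {
  lab <- rep(c("male", "couple"), each = 10)
  fm <- mini_fm(f = rep(3, 20), label = lab)
  sel <- mann_whitney_screen(fm, fm$label == "male")
  expect_equal(sel$statistics$p, 1)
})

test_that("perfectly correlated features collapse to one representative", {
  set.seed(2)
  lab <- rep(c("male", "couple"), each = 100)
  base <- c(rnorm(100), rnorm(100, 5))
  fm <- mini_fm(a = base, b = 2 * base + 1, label = lab)
  sel <- select_features(fm, fm$label == "male")
  expect_length(sel$selected, 1L)
  expect_length(sel$groups, 1L)
})

test_that("uncorrelated significant features all survive pruning", {
  set.seed(6)
  lab <- rep(c("male", "couple"), each = 150)
  fm <- mini_fm(a = c(rnorm(150), rnorm(150, 4)),
                b = c(rnorm(150), rnorm(150, -4)),
                c = c(rnorm(150), rnorm(150, 4)) + rep(c(0, 0), 150),
                label = lab)
  # decorrelate c from a by fresh noise
  fm$c <- c(rnorm(150), rnorm(150, 4))
  sel <- select_features(fm, fm$label == "male")
  expect_setequal(sel$selected, c("a", "b", "c"))
})

test_that("correlation groups use transitive closure, checked by brute force", {
  set.seed(8)
  n <- 400
  lab <- rep(c("male", "couple"), each = n / 2)
  shift <- rep(c(0, 6), each = n / 2)
  a <- rnorm(n) + shift
  b <- 0.95 * a + sqrt(1 - 0.95^2) * rnorm(n)    # r(a,b) ~ 0.95
  cc <- 0.95 * b + sqrt(1 - 0.95^2) * rnorm(n)   # r(b,c) ~ 0.95, r(a,c) ~ 0.9
  d <- rnorm(n) + shift                          # independent of a,b,c
  fm <- mini_fm(a = a, b = b, c = cc, d = d, label = lab)
  sel <- select_features(fm, fm$label == "male", cor_threshold = 0.92)
  # brute-force oracle: flood-fill the thresholded correlation graph of the
  # significant set and keep one representative per component
  sig <- sel$significant
  cm <- abs(cor(fm[sig])) >= 0.92
  comp <- seq_along(sig)
  repeat {
    changed <- FALSE
    for (i in seq_along(sig)) for (j in seq_along(sig)) {
      if (cm[i, j] && comp[j] != comp[i]) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  n_groups <- length(unique(comp))
  expect_length(sel$selected, n_groups)
  expect_length(sel$groups, n_groups)
  # exactly one representative per brute-force component
  for (g in unique(comp)) {
    expect_length(intersect(sel$selected, sig[comp == g]), 1L)
  }
})

test_that("selection is deterministic and train-rows-only by interface", {
  fm <- small_fm()
  is_male <- fm$label == "male"
  s1 <- select_features(fm, is_male)
  s2 <- select_features(fm, is_male)
  expect_identical(s1$selected, s2$selected)
  expect_true(all(s1$selected %in% s1$significant))
  expect_true(all(s1$significant %in% s1$statistics$feature))
})

test_that("selection results serialise to JSON and back", {
  fm <- small_fm()
  sel <- select_features(fm, fm$label == "male")
  path <- withr::local_tempfile(fileext = ".json")
  write_selection(sel, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$selected, sel$selected)
  expect_equal(parsed$threshold, sel$threshold)
})
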