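# Sampling-based Shapley attribution of segment decision values.

#' Per-feature Shapley attributions of decision values
#'
#' Permutation-sampling Shapley estimation: for each Monte-Carlo sample a
#' random feature ordering and a random background row are drawn; walking
#' through the ordering, each feature's marginal effect on the model output
#' (switching that feature from the background value to the explained
#' row's value) is credited to it. Because the per-sample credits telescope
#' to `f(x) - f(b)`, local accuracy is exact for every row: baseline +
#' row attributions = that row's decision value to machine precision.
#' Attributions explain the signed decision value, so positive values
#' contribute towards the male (inlier) class.
#'
#' @param model a `"trained_detector"` or a function mapping a numeric
#'   matrix (columns = features) to a numeric vector of outputs.
#' @param X data.frame or matrix of rows to explain (feature columns only,
#'   original feature scale for a detector).
#' @param background matrix/data.frame of background rows (training
#'   segments for a detector).
#' @param n_samples Monte-Carlo samples; at least `2 * n_features`.
#' @param seed integer; fixes the sampled permutations and background rows
#'   (bit-identical attributions for a fixed seed).
#' @return an `"attribution_matrix"`: `$phi` (rows x features), `$baseline`
#'   (mean model output over the sampled background rows) and `$fx` (model
#'   outputs of the explained rows).
#' @export
attribute <- function(model, X, background, n_samples = NULL, seed = 1L) {
  f <- if (inherits(model, "trained_detector")) {
    feats <- model$features
    function(M) {
      Xs <- sweep(sweep(M, 2L, model$mean), 2L, model$sd, `/`)
      as.numeric(attr(stats::predict(model$fit, Xs,
                                     decision.values = TRUE),
                      "decision.values"))
    }
  } else {
    stopifnot(is.function(model))
    model
  }
  if (inherits(model, "trained_detector")) {
    X <- as.matrix(as.data.frame(X)[model$features])
    background <- as.matrix(as.data.frame(background)[model$features])
  } else {
    X <- as.matrix(X)
    background <- as.matrix(background)
  }
  if (!nrow(background)) stopf("empty background")
  d <- ncol(X)
  n <- nrow(X)
  n_samples <- n_samples %||% max(50L, 2L * d)
  if (n_samples < 2L * d)
    stopf("n_samples must be >= 2 * n_features (%d)", 2L * d)
  phi <- matrix(0, n, d, dimnames = list(NULL, colnames(X)))
  fb <- numeric(n_samples)
  withr_seed(seed, {
    for (s in seq_len(n_samples)) {
      perm <- sample.int(d)
      b <- background[sample.int(nrow(background), 1L), ]
      # hybrids: row r of M starts as b; features are switched to X[r, ]
      # in permutation order, evaluating after each switch
      M <- matrix(b, n, d, byrow = TRUE, dimnames = list(NULL, colnames(X)))
      prev <- f(M)
      fb[s] <- prev[1L]
      for (j in perm) {
        M[, j] <- X[, j]
        cur <- f(M)
        phi[, j] <- phi[, j] + (cur - prev)
        prev <- cur
      }
    }
  })
  structure(list(phi = phi / n_samples, baseline = mean(fb),
                 fx = f(X),
                 n_samples = n_samples, seed = seed),
            class = "attribution_matrix")
}

#' @export
print.attribution_matrix <- function(x, ...) {
  cat(sprintf("<attributions> %d rows x %d features, baseline %.4f\n",
              nrow(x$phi), ncol(x$phi), x$baseline))
  invisible(x)
}

#' Rank features by mean absolute attribution
#'
#' @param attr an `"attribution_matrix"`.
#' @return data.frame `feature, mean_abs_attribution, rank`, ordered by
#'   decreasing mean absolute attribution; ties keep a stable order by
#'   feature name.
#' @export
summarise_attributions <- function(attr) {
  stopifnot(inherits(attr, "attribution_matrix"))
  ma <- colMeans(abs(attr$phi))
  o <- order(-ma, colnames(attr$phi))
  data.frame(feature = colnames(attr$phi)[o],
             mean_abs_attribution = ma[o],
             rank = seq_along(o), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Feature value / attribution pairs for scatter plots
#'
#' @param attr an `"attribution_matrix"`.
#' @param X the rows that were explained (feature columns only, same order).
#' @return long data.frame `feature, value, attribution`.
#' @export
attribution_scatter <- function(attr, X) {
  stopifnot(inherits(attr, "attribution_matrix"))
  X <- as.matrix(as.data.frame(X)[colnames(attr$phi)])
  stopifnot(nrow(X) == nrow(attr$phi))
  data.frame(
    feature = rep(colnames(attr$phi), each = nrow(X)),
    value = as.vector(X),
    attribution = as.vector(attr$phi),
    stringsAsFactors = FALSE)
}
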