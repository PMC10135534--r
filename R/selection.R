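# Feature selection: Mann-Whitney U screen with Bonferroni correction,
# then correlation pruning of the surviving set.

# vectorised two-sided Mann-Whitney U with normal approximation, tie and
# continuity correction (matches stats::wilcox.test(exact = FALSE))
mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  sigma <- sqrt((n1 * n2 / 12) *
                  ((n1 + n2 + 1) - sum(ties^3 - ties) /
                     ((n1 + n2) * (n1 + n2 - 1))))
  if (!is.finite(sigma) || sigma == 0) return(c(U = U, p = 1))
  z <- U - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sigma
  c(U = U, p = 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE), 0.5))
}

#' Mann-Whitney screening of features
#'
#' Each feature is compared between the reference (male) and anomalous
#' (non-male) segments with a two-sided Mann-Whitney U test — chosen as a
#' non-parametric test with no distributional assumption — using the normal
#' approximation with tie correction (segment counts run to thousands).
#' Features rejecting the null at the Bonferroni-corrected level
#' `alpha / n` (family-wise error rate `alpha` over `n` candidate features)
#' are selected. Screening must only ever see training-split rows; the
#' function takes the rows it is given and nothing else.
#'
#' @param fm feature matrix (training rows only).
#' @param is_male logical vector per row: TRUE for the reference class.
#' @param alpha family-wise error rate (default 0.01).
#' @return object of class `"selection_result"` with per-feature `U` and
#'   `p`, the threshold `alpha/n`, and the significant set. Constant
#'   features get p = 1 and are never selected.
#' @export
mann_whitney_screen <- function(fm, is_male, alpha = 0.01) {
  stopifnot(length(is_male) == nrow(fm), any(is_male), any(!is_male))
  feats <- feature_names(fm)
  res <- vapply(feats, function(f) {
    mann_whitney_u(fm[[f]][is_male], fm[[f]][!is_male])
  }, numeric(2))
  threshold <- alpha / length(feats)
  stats_df <- data.frame(feature = feats, U = res["U", ], p = res["p", ],
                         row.names = NULL, stringsAsFactors = FALSE)
  structure(list(statistics = stats_df, alpha = alpha,
                 threshold = threshold,
                 significant = feats[stats_df$p < threshold],
                 groups = NULL, selected = feats[stats_df$p < threshold]),
            class = "selection_result")
}

#' Prune correlated features
#'
#' Among the significant features, groups are formed by the transitive
#' closure of absolute Pearson correlation at or above the threshold, and
#' one representative is kept per group: the member with the smallest
#' screening p-value, ties broken by schema order.
#'
#' @param fm feature matrix (training rows only; same rows as the screen).
#' @param sel a `"selection_result"` from [mann_whitney_screen()].
#' @param threshold absolute-correlation grouping threshold (default 0.85).
#' @return the `"selection_result"` with `groups` and final `selected` set
#'   filled in.
#' @export
correlation_prune <- function(fm, sel, threshold = 0.85) {
  stopifnot(inherits(sel, "selection_result"))
  feats <- sel$significant
  if (length(feats) <= 1L) {
    sel$groups <- as.list(feats)
    sel$selected <- feats
    return(sel)
  }
  cm <- suppressWarnings(stats::cor(as.matrix(fm[feats])))
  cm[is.na(cm)] <- 0
  adj <- abs(cm) >= threshold
  # union-find transitive closure
  parent <- seq_along(feats)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(feats)) for (j in seq_len(i - 1L)) {
    if (adj[i, j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_along(feats), find, integer(1))
  pvals <- sel$statistics$p[match(feats, sel$statistics$feature)]
  groups <- split(seq_along(feats), roots)
  keep <- vapply(groups, function(idx) {
    idx[order(pvals[idx], idx)][1L]   # min p, then schema order
  }, integer(1))
  sel$groups <- lapply(groups, function(idx) feats[idx])
  names(sel$groups) <- NULL
  sel$selected <- feats[sort(keep)]
  sel
}

#' Full selection stage
#'
#' Screen then prune; see [mann_whitney_screen()] and
#' [correlation_prune()]. Deterministic given the matrix.
#'
#' @inheritParams mann_whitney_screen
#' @param cor_threshold passed to [correlation_prune()].
#' @return a `"selection_result"`.
#' @export
select_features <- function(fm, is_male, alpha = 0.01, cor_threshold = 0.85) {
  correlation_prune(fm, mann_whitney_screen(fm, is_male, alpha),
                    cor_threshold)
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection> %d candidates, %d significant at p < %.2g, %d after pruning\n",
    nrow(x$statistics), length(x$significant), x$threshold,
    length(x$selected)))
  invisible(x)
}

#' Serialise a selection result to JSON
#'
#' @param sel a `"selection_result"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path) {
  jsonlite::write_json(
    list(alpha = sel$alpha, threshold = sel$threshold,
         statistics = sel$statistics, significant = sel$significant,
         groups = sel$groups, selected = sel$selected),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
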