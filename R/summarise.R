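SERIES_STATS <- c("mean", "median", "sd", "q1", "q3", "kurt", "skew",
                  "n_ext", "n_zc")

#' Nine-statistic summary of a feature series
#'
#' Reduces a per-timestep series to mean, median, standard deviation
#' (n-1 denominator), 1st and 3rd quartiles (linear-interpolation
#' convention), kurtosis and skewness (moment estimators; excess kurtosis),
#' the number of local extrema (strict sign changes of the first
#' difference, minima and maxima combined) and the number of zero crossings
#' (strict sign changes of the raw series, exact zeros skipped). A constant
#' series has undefined kurtosis and skewness; both are set to 0 by
#' convention.
#'
#' @param x numeric series.
#' @return named numeric vector of the nine statistics; all-`NA` when the
#'   series has fewer than 3 values (sentinel resolved by imputation at
#'   matrix assembly).
#' @export
summarise_series <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L)
    return(stats::setNames(rep(NA_real_, 9L), SERIES_STATS))
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7L)
  const <- stats::sd(x) == 0
  c(mean = mean(x), median = stats::median(x), sd = stats::sd(x),
    q1 = q[1L], q3 = q[2L],
    kurt = if (const) 0 else e1071::kurtosis(x, type = 1L),
    skew = if (const) 0 else e1071::skewness(x, type = 1L),
    n_ext = count_sign_changes(diff(x)),
    n_zc = count_sign_changes(x))
}

# strict sign changes with exact zeros skipped
count_sign_changes <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0)
  sum(s[-length(s)] != s[-1L])
}
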