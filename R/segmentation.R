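#' Split a track into equal-duration overlapping segments
#'
#' A window of fixed duration advances from the first timestamp in steps of
#' `window_s - overlap_s`; each snapshot becomes one segment, so consecutive
#' segments share exactly `overlap_s` seconds. A trailing remainder shorter
#' than the window is discarded — all segments must be equally sized in
#' duration. Sample boundaries: a segment starting at `t_start` takes every
#' sample with `t_start <= t_i <= t_start + window_s` (at exactly 25 Hz a
#' 1.6 s window yields 41 samples, i.e. 40 inter-frame intervals).
#'
#' @param tr a [track()].
#' @param window_s window length in seconds (> 0).
#' @param overlap_s overlap between consecutive windows in seconds,
#'   `0 <= overlap_s < window_s`.
#' @return list of `"segment"` objects, each carrying the parent lineage
#'   (`segment_id`, `track_id`, `trial_id`, `label`) plus the `t`/`xyz`
#'   slice.
#' @export
window_track <- function(tr, window_s, overlap_s) {
  stopifnot(inherits(tr, "track"))
  if (!(window_s > 0))
    stopf("parameter error: window_s must be > 0")
  if (overlap_s < 0 || overlap_s >= window_s)
    stopf("parameter error: need 0 <= overlap_s < window_s")
  step <- window_s - overlap_s
  t0 <- tr$t[1L]
  dur <- track_duration(tr)
  if (dur < window_s) return(list())
  n_seg <- floor((dur - window_s) / step + 1e-9) + 1
  # guard against floating-point shortfall at the last window
  eps <- 1e-9 * max(1, window_s)
  starts <- t0 + step * (seq_len(n_seg) - 1L)
  segs <- vector("list", n_seg)
  for (k in seq_len(n_seg)) {
    lo <- starts[k] - eps
    hi <- starts[k] + window_s + eps
    idx <- which(tr$t >= lo & tr$t <= hi)
    segs[[k]] <- structure(
      list(segment_id = sprintf("%s#%03d", tr$track_id, k),
           track_id = tr$track_id, trial_id = tr$trial_id,
           label = tr$label,
           t = tr$t[idx], xyz = tr$xyz[idx, , drop = FALSE],
           window_s = window_s, overlap_s = overlap_s),
      class = "segment")
  }
  segs
}

#' @export
print.segment <- function(x, ...) {
  cat(sprintf("<segment %s> label %s, %d samples, %.2f s window\n",
              x$segment_id, x$label, length(x$t), x$window_s))
  invisible(x)
}

#' Segment every track of a dataset
#'
#' Applies [window_track()] to each track. Tracks shorter than the window
#' produce no segments; run [filter_short_tracks()] first so every track
#' contributes at least two segments to the vote.
#'
#' @param x a `trackset`.
#' @inheritParams window_track
#' @return flat list of segments.
#' @export
segment_dataset <- function(x, window_s = 1.6, overlap_s = 0.8) {
  stopifnot(inherits(x, "trackset"))
  segs <- lapply(x$tracks, window_track, window_s = window_s,
                 overlap_s = overlap_s)
  unlist(segs, recursive = FALSE, use.names = FALSE)
}
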