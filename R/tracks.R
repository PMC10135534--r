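#' Construct a single flight track
#'
#' A track is an ordered sequence of 3D positions with timestamps,
#' \eqn{T = \{(x_i, y_i, z_i, t_i)\}}, belonging to one tracked individual
#' (or one mating couple tracked as a single entity). Positions are in
#' metres, times in seconds; field recordings are nominally sampled at
#' 25 Hz but no fixed rate is assumed.
#'
#' @param track_id character scalar, unique within the dataset.
#' @param trial_id character scalar identifying the recording session.
#' @param label class label; one of `male`, `female`, `focal_male`,
#'   `couple`, anything else becomes `"unknown"`.
#' @param t numeric vector of strictly increasing times (s).
#' @param xyz numeric matrix with `length(t)` rows and columns x, y, z (m).
#' @return an object of class `"track"`.
#' @export
track <- function(track_id, trial_id, label, t, xyz) {
  xyz <- as.matrix(xyz)
  if (!is_finite_num(t) || !is_finite_num(xyz))
    stopf("track '%s': non-finite coordinates or times", track_id)
  if (ncol(xyz) != 3L)
    stopf("track '%s': xyz must have 3 columns", track_id)
  if (length(t) != nrow(xyz))
    stopf("track '%s': %d times but %d positions", track_id, length(t), nrow(xyz))
  if (length(t) < 2L)
    stopf("track '%s': needs at least 2 samples", track_id)
  if (any(diff(t) <= 0))
    stopf("track '%s': times not strictly increasing", track_id)
  colnames(xyz) <- c("x", "y", "z")
  structure(
    list(track_id = as.character(track_id), trial_id = as.character(trial_id),
         label = normalise_label(label), t = as.numeric(t),
         xyz = unname(xyz)),
    class = "track")
}

#' Duration of a track in seconds
#'
#' Defined as \eqn{t_N - t_0}, not the sample count, because windows are
#' specified in seconds.
#'
#' @param x a `track`.
#' @return numeric scalar (s).
#' @export
track_duration <- function(x) {
  stopifnot(inherits(x, "track"))
  x$t[length(x$t)] - x$t[1L]
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track %s> trial %s, label %s, %d samples, %.2f s\n",
              x$track_id, x$trial_id, x$label, length(x$t), track_duration(x)))
  invisible(x)
}

#' Construct a dataset of tracks
#'
#' A `trackset` bundles the tracks of one or more trials (recording
#' sessions). Track ids must be unique across the whole dataset.
#'
#' @param tracks list of [track()] objects.
#' @return an object of class `"trackset"`.
#' @export
trackset <- function(tracks = list()) {
  if (!all(vapply(tracks, inherits, logical(1), "track")))
    stopf("all elements must be track objects")
  ids <- vapply(tracks, `[[`, character(1), "track_id")
  if (anyDuplicated(ids))
    stopf("duplicate track_id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(tracks) <- ids
  # canonical order: sorted by track id, so round-trips are identity
  structure(list(tracks = tracks[order(ids)]), class = "trackset")
}

#' @export
print.trackset <- function(x, ...) {
  lab <- track_labels(x)
  cat(sprintf("<trackset> %d tracks, %d trials\n",
              length(x$tracks), length(trial_ids(x))))
  if (length(lab)) print(table(label = lab))
  invisible(x)
}

#' @export
length.trackset <- function(x) length(x$tracks)

#' Track labels, track ids and trial ids of a dataset
#'
#' @param x a `trackset`.
#' @return character vector.
#' @export
track_labels <- function(x) {
  unname(vapply(x$tracks, `[[`, character(1), "label"))
}

#' @rdname track_labels
#' @export
track_ids <- function(x) {
  unname(vapply(x$tracks, `[[`, character(1), "track_id"))
}

#' @rdname track_labels
#' @export
trial_ids <- function(x) {
  sort(unique(vapply(x$tracks, `[[`, character(1), "trial_id")))
}

#' Subset a dataset by predicate on its tracks
#'
#' @param x a `trackset`.
#' @param trials,labels optional character vectors to keep.
#' @return a `trackset`.
#' @export
subset_tracks <- function(x, trials = NULL, labels = NULL) {
  keep <- rep(TRUE, length(x$tracks))
  if (!is.null(trials))
    keep <- keep & vapply(x$tracks, `[[`, character(1), "trial_id") %in% trials
  if (!is.null(labels))
    keep <- keep & track_labels(x) %in% labels
  trackset(x$tracks[keep])
}

#' Convert a dataset to the canonical long format
#'
#' One row per sample, columns `track_id, trial_id, label, t, x, y, z`.
#'
#' @param x a `trackset`.
#' @return data.frame.
#' @export
as_track_frame <- function(x) {
  stopifnot(inherits(x, "trackset"))
  if (!length(x$tracks)) {
    return(data.frame(track_id = character(), trial_id = character(),
                      label = character(), t = numeric(), x = numeric(),
                      y = numeric(), z = numeric(),
                      stringsAsFactors = FALSE))
  }
  parts <- lapply(x$tracks, function(tr) {
    data.frame(track_id = tr$track_id, trial_id = tr$trial_id,
               label = tr$label, t = tr$t,
               x = tr$xyz[, 1L], y = tr$xyz[, 2L], z = tr$xyz[, 3L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

TRACK_COLUMNS <- c("track_id", "trial_id", "label", "t", "x", "y", "z")

#' Build a dataset from a long-format data frame
#'
#' @param df data.frame with columns `track_id, trial_id, label, t, x, y, z`.
#' @return a `trackset`.
#' @export
as_trackset <- function(df) {
  missing_cols <- setdiff(TRACK_COLUMNS, names(df))
  if (length(missing_cols))
    stopf("format error: missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  df <- df[order(df$track_id, df$t), , drop = FALSE]
  idx <- split(seq_len(nrow(df)), df$track_id)
  tracks <- lapply(idx, function(i) {
    sub <- df[i, , drop = FALSE]
    if (any(diff(sub$t) <= 0))
      stopf("validation error: track '%s' has non-increasing times",
            sub$track_id[1L])
    if (length(unique(sub$trial_id)) != 1L)
      stopf("validation error: track '%s' spans multiple trials",
            sub$track_id[1L])
    track(sub$track_id[1L], sub$trial_id[1L], sub$label[1L],
          sub$t, cbind(sub$x, sub$y, sub$z))
  })
  trackset(unname(tracks))
}

#' Read tracks from a long-format CSV file
#'
#' The canonical on-disk format: UTF-8 CSV, '.' decimal separator, one row
#' per sample with columns `track_id, trial_id, label, t, x, y, z`.
#'
#' @param path file path.
#' @return a `trackset`.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(track_id = "character",
                                       trial_id = "character"))
  as_trackset(df)
}

#' Write tracks to a long-format CSV file
#'
#' Inverse of [read_tracks()]: reading the file back yields an identical
#' dataset up to float formatting (full precision is written).
#'
#' @param x a `trackset`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(x, path) {
  df <- as_track_frame(x)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop tracks too short to yield at least two segments
#'
#' Tracks shorter (in duration) than twice the segment window are removed,
#' so every retained track yields at least two segments for voting.
#'
#' @param x a `trackset`.
#' @param window_s segment window length (s), > 0.
#' @param quiet suppress the per-class removal message.
#' @return filtered `trackset`.
#' @export
filter_short_tracks <- function(x, window_s, quiet = FALSE) {
  stopifnot(inherits(x, "trackset"), window_s > 0)
  dur <- vapply(x$tracks, track_duration, numeric(1))
  keep <- dur >= 2 * window_s
  if (!quiet && any(!keep)) {
    removed <- table(track_labels(x)[!keep])
    message("filter_short_tracks removed ",
            paste(sprintf("%s=%d", names(removed), removed), collapse = ", "))
  }
  trackset(x$tracks[keep])
}
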