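# Per-segment feature assembly: the full battery, expanded through the
# nine-statistic summary into one flat named vector per segment.

SERIES_FAMILIES <- c("speed", "raccel", "rjerk", "vx", "vy", "vz",
                     "ax", "ay", "az", "jx", "jy", "jz",
                     "alpha",
                     "angvel_XY", "angacc_XY", "angvel_YZ", "angacc_YZ",
                     "angvel_XZ", "angacc_XZ", "angvel_3D", "angacc_3D",
                     "pvel", "tvel", "ivel", "cdist")

SCALAR_FEATURES <- c("straightness", "hull_volume", "hull_area",
                     "curv_XY_mean", "curv_XY_sd", "curv_YZ_mean",
                     "curv_YZ_sd", "curv_XZ_mean", "curv_XZ_sd",
                     "css_mean", "css_sd", "fractal_dim")

#' Feature schema
#'
#' The fixed, ordered set of feature names produced by
#' [extract_features()]: 25 per-timestep series (kinematics, angle of
#' flight, angular rates over four projections, orthogonal velocity
#' components, centroid distance) each expanded through the nine summary
#' statistics, plus 12 whole-segment scalars — 237 features, named
#' `family_plane_statistic` (e.g. `angvel_XY_q3`).
#'
#' @return character vector of feature names.
#' @export
feature_schema <- function() {
  c(as.vector(t(outer(SERIES_FAMILIES, SERIES_STATS, paste, sep = "_"))),
    SCALAR_FEATURES)
}

#' Extract the full feature vector of one segment
#'
#' Applies the whole battery — kinematic series, angle of flight, angular
#' velocity/acceleration per projection, orthogonal velocity components,
#' centroid distance, straightness, convex hull volume and area, planar
#' curvature summaries, curvature scale space and fractal dimension — and
#' expands every series through [summarise_series()]. Extraction is fully
#' deterministic. Degenerate sub-features yield `NA` sentinels resolved by
#' median imputation when a feature matrix is assembled.
#'
#' @param seg a `segment` with >= 8 samples.
#' @param css_sigma sigma grid for [curvature_scale_space()].
#' @param css_bins arc-length bins for [curvature_scale_space()].
#' @return named numeric vector following [feature_schema()].
#' @export
extract_features <- function(seg, css_sigma = css_default_sigma(),
                             css_bins = 64L) {
  series <- c(kinematics(seg),
              list(alpha = angle_of_flight(seg)$alpha),
              angular_rates(seg),
              orthogonal_velocities(seg)[c("pvel", "tvel", "ivel")],
              list(cdist = centroid_distance(seg)))
  out <- unlist(lapply(SERIES_FAMILIES, function(f) {
    stats::setNames(summarise_series(series[[f]]),
                    paste(f, SERIES_STATS, sep = "_"))
  }))
  hull <- convex_hull_metrics(seg)
  scalars <- c(straightness = straightness(seg),
               hull_volume = hull$hull_volume, hull_area = hull$hull_area,
               unlist(curvature(seg)),
               unlist(curvature_scale_space(seg, css_sigma, css_bins)),
               fractal_dim = fractal_dimension(seg))
  c(out, scalars[SCALAR_FEATURES])
}

#' Assemble the feature matrix of a set of segments
#'
#' One row per segment: four lineage columns (`segment_id`, `track_id`,
#' `trial_id`, `label`) followed by the full feature schema. Segments that
#' fail extraction (too few samples) are skipped with a message, never an
#' error. Remaining `NA` sentinels are imputed with the column median
#' (0 when a column is entirely `NA`); the number of imputed cells is
#' recorded in the `"n_imputed"` attribute.
#'
#' @param segments list of `segment` objects.
#' @param css_sigma,css_bins passed to [extract_features()].
#' @param impute impute `NA` sentinels with column medians (default TRUE).
#' @return data.frame feature matrix.
#' @export
feature_matrix <- function(segments, css_sigma = css_default_sigma(),
                           css_bins = 64L, impute = TRUE) {
  rows <- vector("list", length(segments))
  kept <- logical(length(segments))
  for (i in seq_along(segments)) {
    fv <- tryCatch(extract_features(segments[[i]], css_sigma, css_bins),
                   error = function(e) NULL)
    if (is.null(fv)) {
      message("skipping degenerate segment ", segments[[i]]$segment_id)
      next
    }
    rows[[i]] <- fv
    kept[i] <- TRUE
  }
  segments <- segments[kept]
  mat <- do.call(rbind, rows[kept])
  lineage <- data.frame(
    segment_id = vapply(segments, `[[`, character(1), "segment_id"),
    track_id = vapply(segments, `[[`, character(1), "track_id"),
    trial_id = vapply(segments, `[[`, character(1), "trial_id"),
    label = vapply(segments, `[[`, character(1), "label"),
    stringsAsFactors = FALSE)
  n_imp <- 0L
  if (impute && anyNA(mat)) {
    for (j in seq_len(ncol(mat))) {
      nas <- is.na(mat[, j])
      if (any(nas)) {
        med <- stats::median(mat[!nas, j])
        mat[nas, j] <- if (is.finite(med)) med else 0
        n_imp <- n_imp + sum(nas)
      }
    }
  }
  out <- cbind(lineage, as.data.frame(mat))
  rownames(out) <- NULL
  attr(out, "n_imputed") <- n_imp
  out
}

LINEAGE_COLUMNS <- c("segment_id", "track_id", "trial_id", "label")

#' Feature columns of a feature matrix
#'
#' @param fm feature matrix from [feature_matrix()].
#' @return character vector of feature column names (lineage excluded).
#' @export
feature_names <- function(fm) setdiff(names(fm), LINEAGE_COLUMNS)
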