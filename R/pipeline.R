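# End-to-end orchestration: simulate/ingest -> QC -> filter -> segment ->
# extract -> cross-validated folds -> metrics -> attribution, with a run
# manifest for reproducibility.

#' Run configuration
#'
#' @param input path to a long-format track CSV, or `NULL` to simulate a
#'   synthetic dataset with `sim`.
#' @param sim a [sim_config()] used when `input` is `NULL`.
#' @param window_s,overlap_s segmentation parameters (s); defaults 1.6 and
#'   0.8, the grid-search optimum.
#' @param alpha,cor_threshold selection parameters (defaults 0.01, 0.85).
#' @param detector a [detector_config()].
#' @param validation_trials trial ids held out for screening/tuning; `NULL`
#'   picks the first two trials containing couple tracks.
#' @param qc if TRUE, trials flagged by [detect_outlier_trials()] are
#'   excluded (flags are always recorded in the manifest).
#' @param attribution if TRUE, Shapley attributions are computed for the
#'   best and worst folds by balanced accuracy.
#' @param attribution_rows,attribution_samples caps for the attribution
#'   stage.
#' @param seed integer driving the attribution sampling.
#' @param out_dir run directory to write outputs into, or `NULL` to skip
#'   writing.
#' @return a `"run_config"` list.
#' @export
run_config <- function(input = NULL, sim = sim_config(),
                       window_s = 1.6, overlap_s = 0.8,
                       alpha = 0.01, cor_threshold = 0.85,
                       detector = detector_config(),
                       validation_trials = NULL,
                       qc = TRUE, attribution = TRUE,
                       attribution_rows = 100L,
                       attribution_samples = NULL,
                       seed = 1L, out_dir = NULL) {
  stopifnot(window_s > 0, overlap_s >= 0, overlap_s < window_s,
            alpha > 0, alpha <= 1, cor_threshold > 0, cor_threshold <= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Execute the full pipeline
#'
#' Stages: load or simulate the dataset; advisory outlier-trial QC
#' (optionally excluding flagged trials); removal of tracks shorter than
#' two windows; segmentation; feature extraction; leave-2-male-trials-out
#' cross-validation (selection, scaling and fitting inside each fold's
#' training split); metric aggregation; Shapley attribution of the best-
#' and worst-performing folds. A manifest recording the configuration,
#' seeds and stage outcomes is returned (and written to `out_dir` when
#' given), enabling reproducible reruns.
#'
#' @param config a [run_config()].
#' @return list with `dataset`, `features`, `cv` (folds + metrics),
#'   `attribution` (best/worst fold attributions or `NULL`) and `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dataset <- if (is.null(config$input)) {
    simulate_swarm(config$sim)
  } else {
    read_tracks(config$input)
  }
  flagged <- detect_outlier_trials(dataset)
  if (config$qc && length(flagged)) {
    message("QC excluding trial(s): ", paste(flagged, collapse = ", "))
    dataset <- subset_tracks(dataset,
                             trials = setdiff(trial_ids(dataset), flagged))
  }
  filtered <- filter_short_tracks(dataset, config$window_s)
  segs <- segment_dataset(filtered, config$window_s, config$overlap_s)
  fm <- feature_matrix(segs)
  validation_trials <- config$validation_trials %||% {
    ct <- sort(unique(fm$trial_id[fm$label == "couple"]))
    utils::head(ct, 2L)
  }
  cv <- run_crossval(fm, validation_trials, config$detector,
                     config$alpha, config$cor_threshold)
  attr_out <- NULL
  if (isTRUE(config$attribution)) {
    ba <- cv$metrics$per_fold$balanced_accuracy
    picks <- unique(c(which.max(ba), which.min(ba)))
    attr_out <- lapply(cv$folds[picks], function(fr) {
      det <- fr$detector
      train_fm <- fm[fm$label == "male" &
                       fm$trial_id %in% fr$fold$train_male, , drop = FALSE]
      test_fm <- fm[match(fr$segment_preds$segment_id, fm$segment_id), ,
                    drop = FALSE]
      test_fm <- utils::head(test_fm, config$attribution_rows)
      bg <- utils::head(train_fm, config$attribution_rows)
      am <- attribute(det, test_fm, bg,
                      n_samples = config$attribution_samples,
                      seed = config$seed)
      list(fold_id = fr$fold_id, attributions = am,
           ranking = summarise_attributions(am),
           scatter = attribution_scatter(am, test_fm))
    })
    names(attr_out) <- vapply(cv$folds[picks], `[[`, character(1),
                              "fold_id")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("swarmtrack")),
    seed = config$seed,
    window_s = config$window_s, overlap_s = config$overlap_s,
    alpha = config$alpha, cor_threshold = config$cor_threshold,
    nu = config$detector$nu, kernel = config$detector$kernel,
    simulated = is.null(config$input),
    sim_seed = if (is.null(config$input)) config$sim$seed,
    n_tracks = length(dataset), n_tracks_filtered = length(filtered),
    n_segments = length(segs), n_features = length(feature_names(fm)),
    flagged_trials = as.character(flagged), qc_excluded = isTRUE(config$qc),
    validation_trials = validation_trials,
    n_folds = length(cv$folds))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(summary = cv$metrics$summary,
           confusion = as.data.frame(as.table(cv$metrics$confusion))),
      file.path(config$out_dir, "metrics.json"),
      auto_unbox = TRUE, digits = NA)
    utils::write.csv(cv$metrics$per_fold,
                     file.path(config$out_dir, "per_fold.csv"),
                     row.names = FALSE)
    if (!is.null(attr_out)) {
      for (nm in names(attr_out)) {
        utils::write.csv(attr_out[[nm]]$ranking,
                         file.path(config$out_dir,
                                   paste0("attribution_", nm, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  list(dataset = dataset, features = fm, cv = cv, attribution = attr_out,
       manifest = manifest)
}
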