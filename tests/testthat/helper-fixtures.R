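# Fixture builders used across the suite. Everything is generated in code;
# no stored data.

# bare segment from coordinates (bypasses windowing)
make_segment <- function(xyz, t = NULL, fs = 25, label = "male",
                         id = "seg1", track_id = "trk1", trial_id = "T1") {
  xyz <- as.matrix(xyz)
  if (is.null(t)) t <- (seq_len(nrow(xyz)) - 1L) / fs
  structure(list(segment_id = id, track_id = track_id, trial_id = trial_id,
                 label = label, t = t, xyz = xyz,
                 window_s = diff(range(t)), overlap_s = 0),
            class = "segment")
}

# straight line along a direction, constant speed
line_segment <- function(n = 50, speed = 1, dir = c(1, 0, 0), fs = 25,
                         origin = c(0, 0, 0)) {
  t <- (seq_len(n) - 1L) / fs
  dir <- dir / sqrt(sum(dir^2))
  make_segment(outer(speed * t, dir) +
                 matrix(origin, n, 3L, byrow = TRUE), t)
}

# circle of radius r in the XY plane at angular rate omega
circle_segment <- function(r = 0.5, omega = 2.5, fs = 25, duration = 2,
                           z = 1) {
  t <- seq(0, duration, by = 1 / fs)
  make_segment(cbind(r * cos(omega * t), r * sin(omega * t), z), t)
}

# 3D random-walk segment
rw_segment <- function(n = 40, sd = 0.05, fs = 25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  make_segment(apply(matrix(rnorm(3L * n, 0, sd), n, 3L), 2L, cumsum))
}

# small simulated dataset for integration tests (fast: ~40 tracks)
small_sim <- function(seed = 11L, ...) {
  simulate_swarm(sim_config(
    seed = seed, n_male_trials = 4L, male_tracks_per_trial = 3L,
    male_duration = c(8, 12), n_couple_trials = 3L,
    couple_tracks_per_trial = 4L, couple_duration = c(4, 6),
    n_female = 2L, n_focal = 2L, ...))
}

# feature matrix of a small simulated dataset, cached per session
small_fm <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 11L) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      ds <- filter_short_tracks(small_sim(seed), 1.6, quiet = TRUE)
      cache[[key]] <- feature_matrix(segment_dataset(ds, 1.6, 0.8))
    }
    cache[[key]]
  }
})
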