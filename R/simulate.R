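# Synthetic swarm simulator: labelled multi-trial datasets emulating the
# structure of field recordings, so the whole pipeline is testable without
# the original data.

#' Simulation configuration
#'
#' Defaults emulate the field data's structure: 8 male trials of long
#' (15-40 s) smooth quasi-circular orbit tracks above a fixed point
#' (yielding roughly 3000 male segments at the default 1.6 s / 0.8 s
#' windowing) and 4 couple trials of short (4-10 s) erratic tracks, plus a
#' handful of female and focal-male tracks hosted in the couple trials
#' (roughly 1000 non-male segments in total). Males orbit with small
#' vertical variance; non-males follow the same orbital baseline plus an
#' Ornstein-Uhlenbeck-style correlated acceleration process with
#' heavy-tailed kicks, scaled by `erraticity` — at `erraticity = 0` the
#' classes are behaviourally identical, so class separability degrades
#' towards chance.
#'
#' @param seed integer; fixes the entire dataset.
#' @param fs sampling rate (Hz), default 25.
#' @param n_male_trials,male_tracks_per_trial,male_duration number of male
#'   trials, tracks per trial and duration range (s).
#' @param n_couple_trials,couple_tracks_per_trial,couple_duration same for
#'   couple trials.
#' @param n_female,female_duration,n_focal,focal_duration female and
#'   focal-male track counts (spread over the couple trials) and duration
#'   ranges.
#' @param orbit_radius radius range of the male orbit (m).
#' @param orbit_omega angular-rate range (rad/s).
#' @param vertical_sd SD of the male vertical jitter process (m).
#' @param erraticity scale in \[0, 1\] of the non-male erratic perturbation.
#' @param accel_sd acceleration-noise SD of the erratic process (m/s^2).
#' @param kick_rate expected heavy-tailed direction-change kicks per second.
#' @param n_anomalous_trials male trials whose velocities are multiplied by
#'   `velocity_multiplier` (wind scenario; for QC testing).
#' @param velocity_multiplier see above, default 5.
#' @return a `"sim_config"` list.
#' @export
sim_config <- function(seed = 1L, fs = 25,
                       n_male_trials = 8L, male_tracks_per_trial = 12L,
                       male_duration = c(15, 40),
                       n_couple_trials = 4L, couple_tracks_per_trial = 30L,
                       couple_duration = c(4, 10),
                       n_female = 5L, female_duration = c(4, 8),
                       n_focal = 6L, focal_duration = c(8, 12),
                       orbit_radius = c(0.3, 0.6),
                       orbit_omega = c(1.5, 3),
                       vertical_sd = 0.04,
                       erraticity = 1,
                       accel_sd = 6,
                       kick_rate = 1.5,
                       n_anomalous_trials = 0L,
                       velocity_multiplier = 5) {
  stopifnot(fs > 0, vertical_sd >= 0, accel_sd >= 0, kick_rate >= 0,
            erraticity >= 0, all(male_duration > 0),
            all(couple_duration > 0))
  structure(as.list(environment()), class = "sim_config")
}

# smooth quasi-circular orbit above a fixed point
sim_orbit <- function(duration, fs, radius, omega, vertical_sd, z0 = 2.5) {
  t <- seq(0, duration, by = 1 / fs)
  n <- length(t)
  dt <- 1 / fs
  phase <- cumsum(c(stats::runif(1, 0, 2 * pi),
                    omega * dt + stats::rnorm(n - 1L, 0, 0.04 * sqrt(dt))))
  # slowly wandering radius and height (AR(1) with long memory)
  r <- radius * (1 + as.numeric(stats::filter(stats::rnorm(n, 0, 0.03),
                                              0.98, "recursive")))
  z <- z0 + as.numeric(stats::filter(stats::rnorm(n, 0, vertical_sd * 0.2),
                                     0.98, "recursive"))
  xyz <- cbind(r * cos(phase), r * sin(phase), z)
  # small measurement noise (~2 mm)
  xyz <- xyz + matrix(stats::rnorm(3 * n, 0, 0.002), n, 3L)
  list(t = t, xyz = xyz)
}

# correlated-acceleration erratic displacement added to a baseline path
sim_erratic_offset <- function(n, dt, accel_sd, kick_rate) {
  v <- matrix(0, n, 3L)
  a <- c(0, 0, 0)
  theta <- 2.5           # mean reversion of the acceleration process
  out <- matrix(0, n, 3L)
  for (k in 2:n) {
    # heavy-tailed innovations (t with 3 df) and occasional large kicks
    eps <- stats::rt(3L, df = 3)
    a <- a - theta * a * dt + accel_sd * sqrt(dt) * eps
    if (stats::runif(1) < kick_rate * dt)
      a <- a + accel_sd * stats::rt(3L, df = 3)
    v[k, ] <- v[k - 1L, ] * (1 - 1.5 * dt) + a * dt
    out[k, ] <- out[k - 1L, ] + v[k, ] * dt
  }
  out
}

#' Simulate a labelled multi-trial swarm dataset
#'
#' See [sim_config()] for the generative model. Deterministic given the
#' config's seed.
#'
#' @param config a [sim_config()].
#' @return a `trackset`.
#' @export
simulate_swarm <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  tracks <- list()
  withr_seed(cfg$seed, {
    dt <- 1 / cfg$fs
    runifr <- function(r) stats::runif(1, r[1L], r[2L])
    mk_orbit_track <- function(id, trial, label, durange) {
      o <- sim_orbit(runifr(durange), cfg$fs, runifr(cfg$orbit_radius),
                     runifr(cfg$orbit_omega) * sample(c(-1, 1), 1L),
                     cfg$vertical_sd)
      track(id, trial, label, o$t, o$xyz)
    }
    mk_erratic_track <- function(id, trial, label, durange) {
      o <- sim_orbit(runifr(durange), cfg$fs, runifr(cfg$orbit_radius),
                     runifr(cfg$orbit_omega) * sample(c(-1, 1), 1L),
                     cfg$vertical_sd)
      n <- length(o$t)
      off <- sim_erratic_offset(n, dt, cfg$accel_sd, cfg$kick_rate)
      track(id, trial, label, o$t, o$xyz + cfg$erraticity * off)
    }
    anomalous <- if (cfg$n_anomalous_trials > 0) {
      seq_len(min(cfg$n_anomalous_trials, cfg$n_male_trials))
    } else integer(0)
    for (tr in seq_len(cfg$n_male_trials)) {
      trial <- sprintf("M%02d", tr)
      for (k in seq_len(cfg$male_tracks_per_trial)) {
        tk <- mk_orbit_track(sprintf("%s_t%03d", trial, k), trial, "male",
                             cfg$male_duration)
        if (tr %in% anomalous) {
          ctr <- colMeans(tk$xyz)
          tk$xyz <- sweep(sweep(tk$xyz, 2L, ctr), 2L,
                          rep(cfg$velocity_multiplier, 3L), `*`)
          tk$xyz <- sweep(tk$xyz, 2L, ctr, `+`)
        }
        tracks[[length(tracks) + 1L]] <- tk
      }
    }
    extra_female <- rep(seq_len(cfg$n_couple_trials),
                        length.out = cfg$n_female)
    extra_focal <- rep(seq_len(cfg$n_couple_trials),
                       length.out = cfg$n_focal)
    for (tr in seq_len(cfg$n_couple_trials)) {
      trial <- sprintf("C%02d", tr)
      for (k in seq_len(cfg$couple_tracks_per_trial)) {
        tracks[[length(tracks) + 1L]] <-
          mk_erratic_track(sprintf("%s_t%03d", trial, k), trial, "couple",
                           cfg$couple_duration)
      }
      for (k in which(extra_female == tr)) {
        tracks[[length(tracks) + 1L]] <-
          mk_erratic_track(sprintf("%s_f%03d", trial, k), trial, "female",
                           cfg$female_duration)
      }
      for (k in which(extra_focal == tr)) {
        tracks[[length(tracks) + 1L]] <-
          mk_orbit_track(sprintf("%s_fm%03d", trial, k), trial,
                         "focal_male", cfg$focal_duration)
      }
    }
  })
  trackset(tracks)
}

#' Shuffle track labels of a feature matrix
#'
#' Control experiment: permutes the label assignment across tracks (each
#' track keeps one label, segment lineage intact), destroying any
#' label/behaviour association while preserving the feature distribution.
#'
#' @param fm feature matrix.
#' @param seed integer.
#' @return the feature matrix with permuted labels.
#' @export
shuffle_track_labels <- function(fm, seed = 1L) {
  tr <- unique(fm$track_id)
  lab <- fm$label[match(tr, fm$track_id)]
  new_lab <- withr_seed(seed, sample(lab))
  fm$label <- new_lab[match(fm$track_id, tr)]
  fm
}
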