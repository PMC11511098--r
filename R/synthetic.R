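# Seeded synthetic two-group sEMG cohort generator.
#
# Signal model: a smooth per-task activation envelope multiplying zero-mean
# band-limited Gaussian noise (the standard surrogate for an sEMG interference
# signal), plus a small broadband baseline. Group effects enter only through
# three latent parameters, so a neutral effect makes the two groups
# exchangeable by construction:
#   * mvc_amplitude_scale  — multiplies patients' maximal-effort amplitude
#     (< 1 models pain-limited effort; drives the MVC/GRASP denominators),
#   * envelope_complexity_shift — adds to patients' envelope modulation depth
#     (deeper modulation lowers mean rectified amplitude, lowering raw EWL),
#   * spectral_shift_hz — shifts patients' noise band (drives zero crossings).

.SEED_MOD <- 2147483629 # large prime < 2^31

# band-limited Gaussian noise: white noise spectrally shaped by the
# Butterworth magnitude response (circular FFT on a 5-smooth length, cropped
# to n — stationary, so cropping is exact)
.band_noise <- function(n, filt) {
  N <- stats::nextn(n, c(2L, 3L, 5L))
  w <- stats::rnorm(N)
  g <- sqrt(.filter_gain(filt$b, filt$a, N)) # |H|, single-pass magnitude
  x <- Re(stats::fft(stats::fft(w) * g, inverse = TRUE)) / N
  x[seq_len(n)]
}

# carrier band-pass designs are reused across a participant's tasks
.butter_cache <- new.env(parent = emptyenv())
.butter_cached <- function(lo, hi, nyq) {
  key <- paste(signif(c(lo, hi, nyq), 12), collapse = "|")
  f <- .butter_cache[[key]]
  if (is.null(f)) {
    f <- signal::butter(4, c(lo, hi) / nyq, type = "pass")
    .butter_cache[[key]] <- f
  }
  f
}

# deterministic substream seed from a few small integers (double-safe)
.derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 11
  for (p in parts) s <- (s * 48271 + (as.numeric(p) %% .SEED_MOD)) %% .SEED_MOD
  as.integer(s)
}

#' Group-effect settings for the synthetic cohort
#'
#' @param mvc_amplitude_scale Multiplicative factor (> 0) on patients'
#'   maximal-effort (MVC/GRASP task) amplitude on the affected sensors; values
#'   below 1 model pain-limited maximal effort.
#' @param envelope_complexity_shift Additive change to patients' envelope
#'   modulation depth on affected sensors (positive = deeper, busier
#'   envelopes, lowering mean rectified amplitude and raw enhanced wavelength).
#' @param spectral_shift_hz Shift of patients' interference-noise band centre
#'   in Hz on affected sensors (positive = higher frequencies, more zero
#'   crossings).
#' @param affected_sensors Integer sensor indices the effect applies to;
#'   `NULL` (default) means every sensor of the cohort.
#' @return A `group_effect` list.
#' @export
group_effect <- function(mvc_amplitude_scale = 1,
                         envelope_complexity_shift = 0,
                         spectral_shift_hz = 0,
                         affected_sensors = NULL) {
  if (!is.numeric(mvc_amplitude_scale) || mvc_amplitude_scale <= 0) {
    stop("invalid `mvc_amplitude_scale`: must be > 0")
  }
  structure(list(mvc_amplitude_scale = mvc_amplitude_scale,
                 envelope_complexity_shift = envelope_complexity_shift,
                 spectral_shift_hz = spectral_shift_hz,
                 affected_sensors =
                   if (is.null(affected_sensors)) NULL
                   else as.integer(affected_sensors)),
            class = "group_effect")
}

#' Is a group effect neutral (null)?
#' @param effect A [group_effect()].
#' @return Logical.
#' @export
is_null_effect <- function(effect) {
  effect$mvc_amplitude_scale == 1 &&
    effect$envelope_complexity_shift == 0 &&
    effect$spectral_shift_hz == 0
}

#' Configuration of a synthetic two-group sEMG cohort
#'
#' Defaults mirror the study design the generator emulates: 21 healthy and 20
#' patient participants, 7 forearm sensors sampled at 1000 Hz, 20 functional
#' (Sollerman) tasks plus 7 maximal-voluntary-contraction movements and 6
#' maximal-effort grasps, with ~4 s tasks whose functional-task durations are
#' jittered by +/-25% so signal lengths differ.
#'
#' @param n_healthy,n_patients Group sizes.
#' @param n_sensors Number of sensors.
#' @param n_shft_tasks,n_mvc_tasks,n_grasp_tasks Tasks per family.
#' @param fs Sampling rate in Hz.
#' @param task_duration_s Nominal task duration in seconds.
#' @param seed Integer seed; the whole cohort is a deterministic function of it.
#' @param effect A [group_effect()].
#' @param amp_meanlog,amp_sdlog Log-normal parameters of the per-sensor
#'   maximal envelope amplitude (mV).
#' @param band_low,band_high Interference-noise band edges in Hz (inside the
#'   25--500 Hz analysis band).
#' @param baseline_mV Standard deviation of the additive broadband baseline
#'   noise (mV).
#' @param age_confounder Simulate the groups' age difference as a mild
#'   age-related decline of maximal amplitude (off by default).
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_healthy = 21, n_patients = 20, n_sensors = 7,
                          n_shft_tasks = 20, n_mvc_tasks = 7,
                          n_grasp_tasks = 6, fs = 1000,
                          task_duration_s = 4, seed = 1,
                          effect = group_effect(),
                          amp_meanlog = log(0.8), amp_sdlog = 0.35,
                          band_low = 60, band_high = 350,
                          baseline_mV = 0.005,
                          age_confounder = FALSE) {
  cfg <- list(n_healthy = as.integer(n_healthy),
              n_patients = as.integer(n_patients),
              n_sensors = as.integer(n_sensors),
              n_shft_tasks = as.integer(n_shft_tasks),
              n_mvc_tasks = as.integer(n_mvc_tasks),
              n_grasp_tasks = as.integer(n_grasp_tasks),
              fs = fs, task_duration_s = task_duration_s,
              seed = as.integer(seed), effect = effect,
              amp_meanlog = amp_meanlog, amp_sdlog = amp_sdlog,
              band_low = band_low, band_high = band_high,
              baseline_mV = baseline_mV,
              age_confounder = isTRUE(age_confounder))
  for (f in c("n_healthy", "n_patients", "n_sensors", "n_shft_tasks",
              "n_mvc_tasks", "n_grasp_tasks")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      stop("invalid cohort configuration: `", f, "` must be a count >= 1")
    }
  }
  if (!is.numeric(cfg$fs) || cfg$fs <= 2 * cfg$band_high) {
    stop("invalid cohort configuration: `fs` must exceed twice `band_high`")
  }
  if (!is.numeric(cfg$task_duration_s) || cfg$task_duration_s <= 0) {
    stop("invalid cohort configuration: `task_duration_s` must be > 0")
  }
  if (!inherits(cfg$effect, "group_effect")) {
    stop("invalid cohort configuration: `effect` must be a group_effect()")
  }
  if (is.null(cfg$effect$affected_sensors)) {
    cfg$effect$affected_sensors <- seq_len(cfg$n_sensors)
  }
  if (any(cfg$effect$affected_sensors < 1L |
          cfg$effect$affected_sensors > cfg$n_sensors)) {
    stop("invalid cohort configuration: `affected_sensors` outside 1..n_sensors")
  }
  structure(cfg, class = "cohort_config")
}

#' Read a cohort configuration from a YAML file
#'
#' Top-level keys use the [cohort_config()] argument names; group-effect keys
#' may be nested under `effect`.
#'
#' @param path Path to a YAML file.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$effect)) y$effect <- do.call(group_effect, y$effect)
  do.call(cohort_config, y)
}

# one participant x sensor latent profile row
.draw_profiles <- function(cfg) {
  eff <- cfg$effect
  ids <- c(sprintf("H%02d", seq_len(cfg$n_healthy)),
           sprintf("P%02d", seq_len(cfg$n_patients)))
  grp <- rep(c("healthy", "patient"), c(cfg$n_healthy, cfg$n_patients))
  n_p <- length(ids)
  age <- round(c(stats::rnorm(cfg$n_healthy, 47, 11),
                 stats::rnorm(cfg$n_patients, 71, 9)))
  ns <- cfg$n_sensors
  n_rows <- n_p * ns
  amp <- stats::rlnorm(n_rows, cfg$amp_meanlog, cfg$amp_sdlog)
  depth <- stats::runif(n_rows, 0.35, 0.65)
  band_shift <- round(stats::rnorm(n_rows, 0, 8)) # whole-Hz jitter
  out <- tibble::tibble(
    participant_id = rep(ids, each = ns),
    group = rep(grp, each = ns),
    age = rep(age, each = ns),
    sensor = rep(seq_len(ns), n_p),
    amp_mV = amp, mod_depth = depth,
    band_low = cfg$band_low + band_shift,
    band_high = cfg$band_high + band_shift,
    mvc_scale = rep(1, n_rows))
  if (cfg$age_confounder) out$amp_mV <- out$amp_mV * exp(-0.008 * (out$age - 59))
  hit <- out$group == "patient" & out$sensor %in% eff$affected_sensors
  out$mvc_scale[hit] <- eff$mvc_amplitude_scale
  out$mod_depth[hit] <- pmin(pmax(out$mod_depth[hit] +
                                    eff$envelope_complexity_shift, 0.05), 0.95)
  out$band_low[hit] <- out$band_low[hit] + eff$spectral_shift_hz
  out$band_high[hit] <- out$band_high[hit] + eff$spectral_shift_hz
  out
}

#' Generate one synthetic sEMG recording
#'
#' Draws one recording from its own random substream: a smooth activation
#' envelope (1--4 Gaussian bumps with random timing and width, modulation
#' depth `profile$mod_depth`) multiplying unit-RMS band-limited Gaussian
#' noise, plus a broadband baseline. Maximal-effort task families (`mvc`,
#' `grasp`) are performed at near-maximal effort scaled by
#' `profile$mvc_scale`; functional tasks (`shft`) at a submaximal fraction
#' drawn uniformly from 0.35--0.85.
#'
#' @param profile A one-row latent profile (fields `amp_mV`, `mod_depth`,
#'   `band_low`, `band_high`, `mvc_scale`).
#' @param task_spec List with `family` ("shft", "mvc" or "grasp"), `task_id`,
#'   `duration_s`, `fs`, and `baseline_mV`.
#' @param seed Integer seed of this recording's independent substream.
#' @return Numeric vector of samples in mV (zero mean up to the baseline).
#' @export
generate_recording <- function(profile, task_spec, seed) {
  set.seed(seed)
  fs <- task_spec$fs
  n <- max(2L, round(fs * task_spec$duration_s))
  maximal <- task_spec$family %in% c("mvc", "grasp")
  effort <- if (maximal) {
    profile$mvc_scale * stats::rlnorm(1, 0, 0.05)
  } else {
    stats::runif(1, 0.35, 0.85)
  }
  k <- sample(1:4, 1)
  centres <- stats::runif(k, 0.1, 0.9)
  widths <- stats::runif(k, 0.08, 0.25)
  t01 <- seq(0, 1, length.out = n)
  env0 <- rep(0, n)
  for (j in seq_len(k)) env0 <- env0 + exp(-0.5 * ((t01 - centres[j]) / widths[j])^2)
  m <- max(env0)
  if (m > 0) env0 <- env0 / m
  d <- profile$mod_depth
  env <- profile$amp_mV * effort * ((1 - d) + d * env0)

  nyq <- fs / 2
  lo <- min(max(profile$band_low, 1), nyq - 2)
  hi <- min(max(profile$band_high, lo + 1), nyq - 1)
  carrier <- .band_noise(n, .butter_cached(lo, hi, nyq))
  carrier <- carrier / stats::sd(carrier)
  env * carrier + stats::rnorm(n, 0, task_spec$baseline_mV)
}

#' Generate a seeded synthetic two-group sEMG cohort
#'
#' Deterministic for a fixed configuration seed: latent per-participant
#' parameters are drawn first, then every (participant, task, sensor)
#' recording is generated from its own derived substream, so recordings can be
#' re-drawn in isolation for paired comparisons.
#'
#' @param config A [cohort_config()].
#' @return A `semg_cohort` list with `recordings` (tibble; one row per
#'   participant x task x sensor, samples in a list-column), `ground_truth`
#'   (latent per-participant x sensor parameters), `task_durations`, and the
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  profiles <- .draw_profiles(config)
  # functional-task durations jittered +/-25% once per task id, so task
  # lengths differ while equal-length batches remain possible
  durations <- tibble::tibble(
    task_family = rep(c("shft", "mvc", "grasp"),
                      c(config$n_shft_tasks, config$n_mvc_tasks,
                        config$n_grasp_tasks)),
    task_id = c(seq_len(config$n_shft_tasks), seq_len(config$n_mvc_tasks),
                seq_len(config$n_grasp_tasks)),
    duration_s = c(config$task_duration_s *
                     stats::runif(config$n_shft_tasks, 0.75, 1.25),
                   rep(config$task_duration_s,
                       config$n_mvc_tasks + config$n_grasp_tasks)))

  ids <- unique(profiles$participant_id)
  fam_code <- c(shft = 1L, mvc = 2L, grasp = 3L)
  grid <- tidyr::expand_grid(pid_idx = seq_along(ids),
                             durations,
                             sensor = seq_len(config$n_sensors))
  n_rec <- nrow(grid)
  samples <- vector("list", n_rec)
  prof_key <- paste(profiles$participant_id, profiles$sensor)
  prof_idx <- match(paste(ids[grid$pid_idx], grid$sensor), prof_key)
  # plain vectors: avoids per-recording tibble row extraction in the hot loop
  p_amp <- profiles$amp_mV; p_depth <- profiles$mod_depth
  p_lo <- profiles$band_low; p_hi <- profiles$band_high
  p_scale <- profiles$mvc_scale
  g_fam <- grid$task_family; g_task <- grid$task_id
  g_dur <- grid$duration_s; g_sensor <- grid$sensor; g_pid <- grid$pid_idx
  for (r in seq_len(n_rec)) {
    k <- prof_idx[r]
    prof <- list(amp_mV = p_amp[k], mod_depth = p_depth[k],
                 band_low = p_lo[k], band_high = p_hi[k],
                 mvc_scale = p_scale[k])
    spec <- list(family = g_fam[r], task_id = g_task[r],
                 duration_s = g_dur[r], fs = config$fs,
                 baseline_mV = config$baseline_mV)
    s <- .derive_seed(config$seed, g_pid[r], fam_code[[g_fam[r]]], g_task[r],
                      g_sensor[r])
    samples[[r]] <- generate_recording(prof, spec, s)
  }
  recordings <- tibble::tibble(
    participant_id = ids[grid$pid_idx],
    group = profiles$group[prof_idx],
    task_family = grid$task_family,
    task_id = grid$task_id,
    sensor = grid$sensor,
    fs = config$fs,
    samples = samples)
  structure(list(recordings = recordings, ground_truth = profiles,
                 task_durations = durations, config = config),
            class = "semg_cohort")
}

#' @export
print.semg_cohort <- function(x, ...) {
  cfg <- x$config
  cat("<semg_cohort> ", cfg$n_healthy, " healthy + ", cfg$n_patients,
      " patients, ", cfg$n_sensors, " sensors, ",
      cfg$n_shft_tasks, "/", cfg$n_mvc_tasks, "/", cfg$n_grasp_tasks,
      " shft/mvc/grasp tasks, fs = ", cfg$fs, " Hz, seed = ", cfg$seed,
      "\n  ", nrow(x$recordings), " recordings\n", sep = "")
  invisible(x)
}

#' Write a cohort to long-format CSV
#'
#' One row per sample with header
#' `participant_id,group,task_family,task_id,sensor,t_ms,amplitude_mV`; the
#' latent ground truth goes to a second CSV keyed by participant.
#'
#' @param cohort A `semg_cohort`.
#' @param path Output CSV path for the recordings.
#' @param ground_truth_path Optional output CSV path for the latent
#'   parameters.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, ground_truth_path = NULL) {
  rec <- cohort$recordings
  fs <- rec$fs[1L]
  long <- tibble::tibble(
    participant_id = rep(rec$participant_id, lengths(rec$samples)),
    group = rep(rec$group, lengths(rec$samples)),
    task_family = rep(rec$task_family, lengths(rec$samples)),
    task_id = rep(rec$task_id, lengths(rec$samples)),
    sensor = rep(rec$sensor, lengths(rec$samples)),
    t_ms = unlist(lapply(lengths(rec$samples),
                         function(L) (seq_len(L) - 1) * 1000 / fs),
                  use.names = FALSE),
    amplitude_mV = unlist(rec$samples, use.names = FALSE))
  readr::write_csv(long, path)
  if (!is.null(ground_truth_path)) {
    readr::write_csv(cohort$ground_truth, ground_truth_path)
  }
  invisible(path)
}

#' Read a long-format cohort CSV back into a recordings tibble
#'
#' @param path CSV written by [write_cohort_csv()].
#' @return A recordings tibble (one row per participant x task x sensor with a
#'   `samples` list-column), suitable for [preprocess_cohort()].
#' @export
read_cohort_csv <- function(path) {
  # base strtod parsing is correctly rounded, so the shortest-representation
  # doubles written by write_cohort_csv() round-trip bit-identically
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "group", "task_family", "task_id", "sensor",
            "t_ms", "amplitude_mV")
  if (!all(need %in% names(long))) {
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "))
  }
  key <- paste(long$participant_id, long$task_family, long$task_id, long$sensor,
               sep = "\r")
  first <- !duplicated(key)
  fs <- if (sum(long$t_ms > 0) > 0) {
    round(1000 / min(long$t_ms[long$t_ms > 0]))
  } else NA_real_
  tibble::tibble(
    participant_id = long$participant_id[first],
    group = long$group[first],
    task_family = long$task_family[first],
    task_id = long$task_id[first],
    sensor = long$sensor[first],
    fs = fs,
    samples = unname(split(long$amplitude_mV, factor(key, levels = key[first]))))
}
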