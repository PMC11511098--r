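# Shared fixtures: reduced cohort configurations and naive reference
# implementations used as oracles.

# reduced two-group cohort for pipeline-level tests: participants, functional
# tasks and durations are cut down (10+10, 5 functional tasks, 0.5 s), while
# the maximal-effort batteries keep the study's 7 MVC + 6 GRASP tasks so the
# normalization denominators keep their statistical character
tiny_config <- function(seed, effect = group_effect(), n_healthy = 10,
                        n_patients = 10, n_shft = 5, n_mvc = 7, n_grasp = 6,
                        n_sensors = 7, duration = 0.5) {
  cohort_config(n_healthy = n_healthy, n_patients = n_patients,
                n_sensors = n_sensors, n_shft_tasks = n_shft,
                n_mvc_tasks = n_mvc, n_grasp_tasks = n_grasp,
                task_duration_s = duration, seed = seed, effect = effect)
}

# generate -> preprocess -> features -> overall group comparisons
run_reduced_comparisons <- function(seed, effect = group_effect(), ...) {
  co <- generate_cohort(tiny_config(seed, effect, ...))
  pr <- preprocess_cohort(co)
  no <- normalization_table(pr)
  am <- amplitude_feature_table(pr, no)
  wa <- waveform_feature_table(pr)
  su <- participant_summary(am, wa)
  list(summary = su, comparisons = compare_all_variables(su),
       norms = no, processed = pr, amp = am, wave = wa)
}

# naive per-sample loops, the independent oracles for the waveform features
naive_nzc <- function(x) {
  count <- 0L
  for (i in seq_len(length(x) - 1L)) {
    if ((x[i] > 0 && x[i + 1L] < 0) || (x[i] < 0 && x[i + 1L] > 0)) {
      count <- count + 1L
    }
  }
  count * 1000 / length(x)
}

naive_ewl <- function(x) {
  L <- length(x)
  total <- 0
  for (i in 2:L) {
    p <- if (i >= 0.2 * L && i <= 0.8 * L) 0.75 else 0.5
    total <- total + abs(x[i] - x[i - 1L])^p
  }
  total * 1000 / L
}

# default latent profile for single-recording tests
test_profile <- function(amp_mV = 1, mod_depth = 0.5, band_low = 60,
                         band_high = 350, mvc_scale = 1) {
  list(amp_mV = amp_mV, mod_depth = mod_depth, band_low = band_low,
       band_high = band_high, mvc_scale = mvc_scale)
}

test_task <- function(family = "shft", duration_s = 1, fs = 1000,
                      baseline_mV = 0.005) {
  list(family = family, task_id = 1L, duration_s = duration_s, fs = fs,
       baseline_mV = baseline_mV)
}
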