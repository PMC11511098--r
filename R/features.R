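# Amplitude features (median, range of the normalized 1000-frame envelope)
# and waveform features (zero-crossing rate NZC and enhanced wavelength EWL of
# the band-passed raw signal), with per-participant min-max rescaling and
# task averaging.

#' Median and range of a normalized 1000-frame envelope
#'
#' @param envelope Dimensionless numeric envelope of length `n_frames`.
#' @param n_frames Required envelope length.
#' @return Named numeric vector `c(median = , range = )`. The median of an
#'   even-length signal is the mean of the two middle order statistics; range
#'   is max minus min.
#' @export
amplitude_params <- function(envelope, n_frames = 1000L) {
  envelope <- as.numeric(envelope)
  if (length(envelope) != n_frames) {
    stop("envelope has ", length(envelope), " frames, expected ", n_frames)
  }
  c(median = stats::median(envelope),
    range = max(envelope) - min(envelope))
}

#' Zero-crossing rate (NZC) of a waveform-path signal
#'
#' Counts strict sign changes between consecutive samples (a sample exactly
#' equal to zero breaks the change: `x[i] > 0 & x[i+1] < 0` or vice versa),
#' then scales by `1000 / L` — a mean count per 1000 frames, i.e. per second
#' at a 1 kHz sampling rate, so signals of different lengths are comparable.
#'
#' @param samples Numeric vector, length >= 2.
#' @return Crossing rate per 1000 frames.
#' @export
compute_nzc <- function(samples) {
  x <- as.numeric(samples)
  L <- length(x)
  if (L < 2L) stop("NZC needs at least 2 samples, got ", L)
  a <- x[-L]
  b <- x[-1L]
  count <- sum((a > 0 & b < 0) | (a < 0 & b > 0))
  count * 1000 / L
}

#' Enhanced wavelength (EWL) of a waveform-path signal
#'
#' Sum over i = 2..L of `|x[i] - x[i-1]|^p`, with the exponent p = 0.75 when
#' the index i lies in the central window (`i >= 0.2 L` and `i <= 0.8 L`,
#' real-valued bounds, no rounding) and p = 0.50 otherwise; the sum is scaled
#' by `1000 / L` like the zero-crossing rate. The sub-unit exponent compresses
#' large excursions; the central window weights the mid-task portion where the
#' grasp is established.
#'
#' @param samples Numeric vector, length >= 2.
#' @return Enhanced wavelength per 1000 frames.
#' @export
compute_ewl <- function(samples) {
  x <- as.numeric(samples)
  L <- length(x)
  if (L < 2L) stop("EWL needs at least 2 samples, got ", L)
  i <- 2:L
  p <- ifelse(i >= 0.2 * L & i <= 0.8 * L, 0.75, 0.5)
  sum(abs(diff(x))^p) * 1000 / L
}

#' Min-max rescale per-task rates for one participant x sensor
#'
#' Affine map sending the minimum over the participant's tasks to 0 and the
#' maximum to 1. When all values are tied (degenerate spread) every task maps
#' to 0 and a warning is raised; continuous signals cannot produce this.
#'
#' @param values Numeric vector of per-task raw rates (>= 2 tasks).
#' @param context Optional string for the degenerate-case warning.
#' @return Numeric vector in `[0, 1]`, same length.
#' @export
rescale_minmax <- function(values, context = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("min-max rescaling needs >= 2 tasks")
  lo <- min(values)
  hi <- max(values)
  if (hi == lo) {
    warning("degenerate min-max rescale (all values equal",
            if (!is.null(context)) paste0("; ", context), "); returning zeros")
    return(rep(0, length(values)))
  }
  (values - lo) / (hi - lo)
}

#' Average per-task feature rows into one value per participant x sensor
#'
#' Arithmetic mean over the functional tasks. Every expected task must be
#' present; missing tasks raise an error naming them (no silent imputation).
#'
#' @param rows Tibble with `participant_id`, `sensor`, `task_id`, and feature
#'   columns.
#' @param feature_cols Character vector of columns to average.
#' @param expected_tasks Integer vector of task ids that must be present for
#'   every participant x sensor.
#' @return Tibble keyed by `participant_id` (+ `group` if present) and
#'   `sensor` with task-averaged feature columns.
#' @export
average_over_tasks <- function(rows, feature_cols,
                               expected_tasks = sort(unique(rows$task_id))) {
  stopifnot(is.data.frame(rows), all(feature_cols %in% names(rows)))
  chk <- dplyr::summarise(
    dplyr::group_by(rows, .data$participant_id, .data$sensor),
    missing = paste(setdiff(expected_tasks, .data$task_id), collapse = ","),
    .groups = "drop")
  bad <- chk[nzchar(chk$missing), ]
  if (nrow(bad) > 0L) {
    stop("missing tasks: ",
         paste(sprintf("%s sensor %d (tasks %s)", bad$participant_id,
                       bad$sensor, bad$missing), collapse = "; "))
  }
  keys <- intersect(c("participant_id", "group", "sensor"), names(rows))
  dplyr::summarise(dplyr::group_by(rows, dplyr::across(dplyr::all_of(keys))),
                   dplyr::across(dplyr::all_of(feature_cols), mean),
                   .groups = "drop")
}

#' Per-task amplitude feature table for a processed cohort
#'
#' Normalizes each functional-task 1000-frame envelope by the participant's
#' MAX, MVC, and GRASP denominators and extracts the median and range.
#'
#' @param processed Output of [preprocess_cohort()].
#' @param norms Output of [normalization_table()].
#' @return Tibble `participant_id, group, sensor, task_id, method, median,
#'   range` with `method` one of `"MAX"`, `"MVC"`, `"GRASP"`.
#' @export
amplitude_feature_table <- function(processed, norms) {
  shft <- processed[processed$task_family == "shft", ]
  nf <- length(shft$envelope[[1L]])
  key <- paste(norms$participant_id, norms$sensor)
  ridx <- match(paste(shft$participant_id, shft$sensor), key)
  out <- vector("list", 3L)
  methods <- c(MAX = "max_mV", MVC = "mvc_mV", GRASP = "grasp_mV")
  for (m in seq_along(methods)) {
    denom <- norms[[methods[[m]]]][ridx]
    pars <- vapply(seq_len(nrow(shft)), function(r) {
      env <- normalize_envelope(shft$envelope[[r]], denom[r],
                                context = paste0(shft$participant_id[r],
                                                 " sensor ", shft$sensor[r]))
      amplitude_params(env, nf)
    }, numeric(2L))
    out[[m]] <- tibble::tibble(
      participant_id = shft$participant_id, group = shft$group,
      sensor = shft$sensor, task_id = shft$task_id,
      method = names(methods)[m],
      median = pars[1L, ], range = pars[2L, ])
  }
  dplyr::bind_rows(out)
}

#' Per-task waveform feature table for a processed cohort
#'
#' Computes raw NZC and EWL rates for every functional-task recording, then
#' min-max rescales each rate across the participant's tasks separately per
#' sensor and parameter.
#'
#' @param processed Output of [preprocess_cohort()].
#' @return Tibble `participant_id, group, sensor, task_id, nzc_rate, ewl_rate,
#'   nzc_rescaled, ewl_rescaled`.
#' @export
waveform_feature_table <- function(processed) {
  shft <- processed[processed$task_family == "shft", ]
  out <- tibble::tibble(
    participant_id = shft$participant_id, group = shft$group,
    sensor = shft$sensor, task_id = shft$task_id,
    nzc_rate = vapply(shft$waveform, compute_nzc, numeric(1L)),
    ewl_rate = vapply(shft$waveform, compute_ewl, numeric(1L)))
  out <- dplyr::group_by(out, .data$participant_id, .data$sensor)
  out <- dplyr::mutate(
    out,
    nzc_rescaled = rescale_minmax(.data$nzc_rate,
                                  context = paste0(.data$participant_id[1L],
                                                   " sensor ", .data$sensor[1L],
                                                   " NZC")),
    ewl_rescaled = rescale_minmax(.data$ewl_rate,
                                  context = paste0(.data$participant_id[1L],
                                                   " sensor ", .data$sensor[1L],
                                                   " EWL")))
  dplyr::ungroup(out)
}

#' Task-averaged participant summary in wide variable form
#'
#' Averages the per-task features over the functional tasks and spreads them
#' into one column per variable using the field's naming convention:
#' `M_<METHOD><sensor>` and `R_<METHOD><sensor>` for the amplitude median and
#' range under each normalization method, and `NZC<sensor>` / `EWL<sensor>`
#' for the task-averaged rescaled waveform parameters.
#'
#' @param amp Output of [amplitude_feature_table()].
#' @param wave Output of [waveform_feature_table()].
#' @return Wide tibble, one row per participant with a `group` column.
#' @export
participant_summary <- function(amp, wave) {
  amp_avg <- dplyr::bind_rows(lapply(split(amp, amp$method), function(d) {
    a <- average_over_tasks(d, c("median", "range"))
    a$method <- d$method[1L]
    a
  }))
  amp_long <- tidyr::pivot_longer(amp_avg, c("median", "range"),
                                  names_to = "stat", values_to = "value")
  amp_long$variable <- paste0(ifelse(amp_long$stat == "median", "M_", "R_"),
                              amp_long$method, amp_long$sensor)
  wave_avg <- average_over_tasks(wave, c("nzc_rescaled", "ewl_rescaled"))
  wave_long <- tidyr::pivot_longer(wave_avg, c("nzc_rescaled", "ewl_rescaled"),
                                   names_to = "stat", values_to = "value")
  wave_long$variable <- paste0(ifelse(wave_long$stat == "nzc_rescaled",
                                      "NZC", "EWL"), wave_long$sensor)
  long <- dplyr::bind_rows(
    amp_long[, c("participant_id", "group", "variable", "value")],
    wave_long[, c("participant_id", "group", "variable", "value")])
  tidyr::pivot_wider(long, names_from = "variable", values_from = "value")
}
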