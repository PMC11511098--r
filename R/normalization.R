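# Per-participant, per-sensor amplitude-normalization values (MAX, MVC,
# GRASP) and their application to amplitude envelopes.
#
# Maxima are taken on the filtered, rectified, smoothed envelope *before*
# 1000-frame resampling (resampling can clip the true peak); division is then
# applied to the resampled envelope.

#' Compute MAX / MVC / GRASP normalization values for one participant
#'
#' The three denominators are per-sensor envelope maxima (mV): `max_mV` over
#' all functional (`shft`) task envelopes, `mvc_mV` over the
#' maximal-voluntary-contraction movements, and `grasp_mV` over the
#' maximal-effort grasps.
#'
#' @param processed Amplitude-path rows of [preprocess_cohort()] for a single
#'   participant (must carry `env_peak_mV`, `task_family`, `sensor`).
#' @return A tibble with one row per sensor:
#'   `participant_id, sensor, max_mV, mvc_mV, grasp_mV`.
#' @export
compute_normalization_values <- function(processed) {
  stopifnot(is.data.frame(processed))
  pid <- unique(processed$participant_id)
  if (length(pid) != 1L) {
    stop("`processed` must contain exactly one participant, got: ",
         paste(pid, collapse = ", "))
  }
  sensors <- sort(unique(processed$sensor))
  sf <- factor(processed$sensor, levels = sensors)
  fam_max <- function(fam) {
    sel <- processed$task_family == fam
    v <- tapply(processed$env_peak_mV[sel], sf[sel], max)
    as.numeric(v)[match(sensors, names(v))]
  }
  out <- tibble::tibble(participant_id = pid, sensor = sensors,
                        max_mV = fam_max("shft"), mvc_mV = fam_max("mvc"),
                        grasp_mV = fam_max("grasp"))
  miss <- out[is.na(out$max_mV) | is.na(out$mvc_mV) | is.na(out$grasp_mV), ]
  if (nrow(miss) > 0L) {
    fams <- c("shft", "mvc", "grasp")[c(anyNA(out$max_mV), anyNA(out$mvc_mV),
                                        anyNA(out$grasp_mV))]
    stop("missing task family for participant ", pid,
         ", sensors ", paste(miss$sensor, collapse = ","),
         ": no recordings in family ", paste(fams, collapse = ","))
  }
  out
}

#' Normalization values for every participant in a processed cohort
#'
#' @param processed Output of [preprocess_cohort()].
#' @return Tibble `participant_id, group, sensor, max_mV, mvc_mV, grasp_mV`.
#' @export
normalization_table <- function(processed) {
  grp <- processed[!duplicated(processed$participant_id),
                   c("participant_id", "group")]
  out <- dplyr::bind_rows(lapply(
    split(processed, processed$participant_id), compute_normalization_values))
  dplyr::left_join(grp, out, by = "participant_id")
}

#' Normalize an amplitude envelope by a denominator
#'
#' Plain division by a positive per-participant, per-sensor maximum (mV). The
#' result is dimensionless; values above 1 are legitimate when the denominator
#' comes from a task family whose maximum was below the functional-task peak
#' (maximal-effort denominators are not guaranteed to dominate).
#'
#' @param envelope Non-negative numeric envelope (mV).
#' @param denom Positive scalar denominator (mV).
#' @param context Optional string identifying participant/sensor for error
#'   messages.
#' @return Dimensionless numeric envelope.
#' @export
normalize_envelope <- function(envelope, denom, context = NULL) {
  if (!is.numeric(denom) || length(denom) != 1L || is.na(denom) || denom <= 0) {
    stop("normalization denominator must be > 0",
         if (!is.null(context)) paste0(" (", context, ")"))
  }
  as.numeric(envelope) / denom
}
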