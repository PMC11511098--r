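# Signal conditioning: zero-phase Butterworth filtering, rectification +
# Gaussian smoothing, and fixed-frame resampling.
#
# Zero-phase filtering is realised by applying the squared magnitude response
# |H(w)|^2 of the designed filter in the frequency domain over a symmetric
# odd-reflection extension of the signal. This is the edge-transient-free limit
# of forward-backward time-domain application: identical magnitude response,
# exactly zero phase, and exactly symmetric under time reversal.

# cache of squared-magnitude gain vectors keyed by (N, coefficients)
.gain_cache <- new.env(parent = emptyenv())

# smallest 5-smooth length >= n0 with the same parity as `parity`
.smooth_len <- function(n0, parity) {
  N <- stats::nextn(n0, c(2L, 3L, 5L))
  while ((N - parity) %% 2L != 0L) N <- stats::nextn(N + 1L, c(2L, 3L, 5L))
  N
}

.unit_circle <- function(N) {
  key <- paste0("z", N)
  z <- .gain_cache[[key]]
  if (is.null(z)) {
    z <- exp(-2i * pi * (seq_len(N) - 1) / N)
    .gain_cache[[key]] <- z
  }
  z
}

.filter_gain <- function(b, a, N) {
  key <- paste(N, paste(signif(c(b, a), 12), collapse = ","), sep = "|")
  g <- .gain_cache[[key]]
  if (is.null(g)) {
    z <- .unit_circle(N)
    horner <- function(coef) { # sum coef[k] * z^(k-1), Horner form
      acc <- rep(coef[length(coef)] + 0i, N)
      for (k in (length(coef) - 1L):1L) acc <- acc * z + coef[k]
      acc
    }
    g <- Mod(horner(b) / horner(a))^2
    .gain_cache[[key]] <- g
  }
  g
}

# odd-reflection (whole-point antisymmetric) extension by p samples each side;
# x may be a matrix (signals in columns)
.odd_extend <- function(x, p) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- min(p, n - 1L)
  top <- 2 * x[rep(1L, m), , drop = FALSE] - x[(1L + m):2L, , drop = FALSE]
  bot <- 2 * x[rep(n, m), , drop = FALSE] - x[(n - 1L):(n - m), , drop = FALSE]
  if (p > m) {
    top <- rbind(top[rep(1L, p - m), , drop = FALSE], top)
    bot <- rbind(bot, bot[rep(m, p - m), , drop = FALSE])
  }
  rbind(top, x, bot)
}

# apply one or more (b, a) filters as a single zero-phase pass;
# filters: list of list(b=, a=). Vector in -> vector out; matrix -> matrix.
.zero_phase <- function(x, filters) {
  was_vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("signal too short for zero-phase filtering (length ", n, ")")
  N <- .smooth_len(3L * n - 2L, n %% 2L)
  p <- (N - n) %/% 2L
  xp <- .odd_extend(x, p)
  g <- rep(1, N)
  for (f in filters) g <- g * .filter_gain(f$b, f$a, N)
  Y <- Re(stats::mvfft(stats::mvfft(xp) * g, inverse = TRUE)) / N
  out <- Y[(p + 1L):(p + n), , drop = FALSE]
  if (was_vec) drop(out) else out
}

.design_bandpass <- function(fs, low, high, order) {
  nyq <- fs / 2
  if (low <= 0 || low >= nyq) {
    stop("band-pass lower cutoff ", low, " Hz must lie in (0, ", nyq, ") Hz")
  }
  if (high >= nyq) {
    # upper edge at/above Nyquist is unrealizable; the pass-band reduces to a
    # high-pass at `low`
    signal::butter(order, low / nyq, type = "high")
  } else {
    signal::butter(order, c(low, high) / nyq, type = "pass")
  }
}

.design_bandstop <- function(fs, low, high, order) {
  nyq <- fs / 2
  if (low <= 0 || high >= nyq || low >= high) {
    stop("band-stop edges (", low, ", ", high, ") Hz invalid for fs = ", fs, " Hz")
  }
  signal::butter(order, c(low, high) / nyq, type = "stop")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters a raw sEMG trace with a Butterworth band-pass applied with zero
#' phase, so that the output has the filter's squared magnitude response and no
#' phase distortion. When `high` is at or above the Nyquist frequency the
#' upper edge is unrealizable and the filter degenerates to a high-pass at
#' `low` (the effective pass-band is unchanged).
#'
#' @param samples Numeric vector, signal in mV.
#' @param fs Sampling rate in Hz.
#' @param low,high Pass-band edges in Hz.
#' @param order Butterworth design order.
#' @return Filtered numeric vector, same length as `samples`.
#' @export
#' @examples
#' x <- sin(2 * pi * 100 * (0:999) / 1000)
#' y <- bandpass_filter(x, fs = 1000)
#' max(abs(y[400:600])) # ~ amplitude preserved at 100 Hz
bandpass_filter <- function(samples, fs, low = 25, high = 500, order = 4) {
  f <- .design_bandpass(fs, low, high, order)
  .zero_phase(as.numeric(samples), list(f))
}

#' Zero-phase Butterworth band-stop (notch) filter
#'
#' Removes a narrow band (by default the 50 Hz power-line component) with zero
#' phase.
#'
#' @inheritParams bandpass_filter
#' @param low,high Stop-band edges in Hz.
#' @return Filtered numeric vector, same length as `samples`.
#' @export
bandstop_filter <- function(samples, fs, low = 49.5, high = 50.5, order = 4) {
  f <- .design_bandstop(fs, low, high, order)
  .zero_phase(as.numeric(samples), list(f))
}

# Gaussian kernel with sd `sigma` samples, truncated at +/- 4 sigma, unit sum
.gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# even ("reflect") extension by p samples each side, matrix columns = signals
.reflect_extend <- function(x, p) {
  x <- as.matrix(x)
  n <- nrow(x)
  idx <- function(i) {
    # reflect indices into 1..n (half-sample symmetric would repeat the edge;
    # whole-sample reflection is used: 2,3,... mirrored)
    i <- abs(i - 1L) %% (2L * (n - 1L))
    ifelse(i >= n, 2L * (n - 1L) - i, i) + 1L
  }
  x[idx((1L - p):(n + p)), , drop = FALSE]
}

# Gaussian smoothing by FFT convolution; x vector or matrix (columns)
.gauss_smooth <- function(x, sigma) {
  was_vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 1L) return(if (was_vec) drop(x) else x)
  k <- .gauss_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  xp <- .reflect_extend(x, r)
  np <- nrow(xp)
  N <- stats::nextn(np + length(k), c(2L, 3L, 5L))
  kw <- numeric(N)
  kw[1L:(r + 1L)] <- k[(r + 1L):length(k)]
  kw[(N - r + 1L):N] <- k[1L:r]
  Xp <- rbind(xp, matrix(0, N - np, ncol(xp)))
  Y <- Re(stats::mvfft(stats::mvfft(Xp) * stats::fft(kw), inverse = TRUE)) / N
  out <- Y[(r + 1L):(r + n), , drop = FALSE]
  if (was_vec) drop(out) else out
}

#' Rectify and smooth a signal into an amplitude envelope
#'
#' Takes the absolute value of the signal and convolves it with a unit-sum
#' Gaussian kernel (sd `sigma_ms` milliseconds, truncated at four standard
#' deviations, reflective edge handling), producing a non-negative activation
#' envelope of the same length.
#'
#' @param samples Numeric vector, signal in mV.
#' @param fs Sampling rate in Hz.
#' @param sigma_ms Gaussian kernel standard deviation in milliseconds.
#' @return Non-negative numeric vector (envelope, mV), same length as input.
#' @export
rectify_smooth <- function(samples, fs, sigma_ms = 50) {
  if (!is.numeric(sigma_ms) || length(sigma_ms) != 1L || sigma_ms <= 0) {
    stop("`sigma_ms` must be a single positive number")
  }
  env <- .gauss_smooth(abs(as.numeric(samples)), sigma_ms * fs / 1000)
  pmax(env, 0) # clip tiny negative FFT round-off
}

#' Resample a signal to a fixed number of frames
#'
#' Linear interpolation on a uniform grid that includes both endpoints, so the
#' first and last samples are preserved exactly and monotone inputs stay
#' monotone.
#'
#' @param samples Numeric vector of length >= 2.
#' @param n Target number of frames.
#' @return Numeric vector of length `n`.
#' @export
resample_frames <- function(samples, n = 1000L) {
  samples <- as.numeric(samples)
  L <- length(samples)
  if (L < 2L) stop("cannot resample a signal of length ", L, " (need >= 2)")
  if (L == n) return(samples)
  stats::approx(seq(0, 1, length.out = L), samples,
                xout = seq(0, 1, length.out = n))$y
}

#' Amplitude-path preprocessing of one recording
#'
#' Chains the amplitude-path conditioning steps: zero-phase Butterworth
#' band-pass (25--500 Hz), 50 Hz band-stop, rectification with Gaussian
#' smoothing, and resampling to a fixed 1000-frame envelope.
#'
#' @param recording A recording as produced by [generate_cohort()] (a list or
#'   one-row tibble with `samples` and `fs`), or a plain numeric vector if
#'   `fs` is supplied.
#' @param fs Sampling rate in Hz (ignored when `recording` carries its own).
#' @param sigma_ms Gaussian smoothing sd in milliseconds.
#' @param n_frames Envelope length after resampling.
#' @param band_low,band_high,notch_low,notch_high,order Filter settings in Hz.
#' @return A `processed_signal` list with elements `samples` (the 1000-frame
#'   envelope), `n_frames`, `path = "amplitude"`, `env_peak` (envelope maximum
#'   before resampling, the value used for normalization), and `steps`.
#' @export
preprocess_amplitude <- function(recording, fs = NULL, sigma_ms = 50,
                                 n_frames = 1000L,
                                 band_low = 25, band_high = 500,
                                 notch_low = 49.5, notch_high = 50.5,
                                 order = 4) {
  xf <- .recording_samples(recording, fs)
  filters <- list(.design_bandpass(xf$fs, band_low, band_high, order),
                  .design_bandstop(xf$fs, notch_low, notch_high, order))
  y <- .zero_phase(xf$x, filters)
  env <- rectify_smooth(y, xf$fs, sigma_ms)
  out <- resample_frames(env, n_frames)
  structure(list(samples = out, n_frames = length(out), path = "amplitude",
                 env_peak = max(env), fs = xf$fs,
                 steps = c("bandpass", "bandstop", "rectify_smooth",
                           "resample_frames")),
            class = "processed_signal")
}

#' Waveform-path preprocessing of one recording
#'
#' Applies only the zero-phase Butterworth band-pass (25--500 Hz); the signal
#' keeps its original length, sign, and amplitude scale. Optionally the 50 Hz
#' band-stop can be added (`notch = TRUE`).
#'
#' @inheritParams preprocess_amplitude
#' @param notch Apply the band-stop filter as well (off by default on this
#'   path).
#' @return A `processed_signal` list with `path = "waveform"` and the filtered
#'   samples at original length.
#' @export
preprocess_waveform <- function(recording, fs = NULL,
                                band_low = 25, band_high = 500,
                                notch = FALSE,
                                notch_low = 49.5, notch_high = 50.5,
                                order = 4) {
  xf <- .recording_samples(recording, fs)
  filters <- list(.design_bandpass(xf$fs, band_low, band_high, order))
  steps <- "bandpass"
  if (notch) {
    filters <- c(filters, list(.design_bandstop(xf$fs, notch_low, notch_high, order)))
    steps <- c(steps, "bandstop")
  }
  y <- .zero_phase(xf$x, filters)
  structure(list(samples = y, n_frames = length(y), path = "waveform",
                 fs = xf$fs, steps = steps),
            class = "processed_signal")
}

.recording_samples <- function(recording, fs) {
  if (is.numeric(recording)) {
    if (is.null(fs)) stop("`fs` is required when `recording` is a bare vector")
    return(list(x = as.numeric(recording), fs = fs))
  }
  x <- recording$samples
  if (is.list(x)) x <- x[[1L]]
  f <- recording$fs
  if (is.null(f)) f <- fs
  if (is.null(f)) stop("recording carries no sampling rate and `fs` not given")
  list(x = as.numeric(x), fs = f[1L])
}

#' @export
print.processed_signal <- function(x, ...) {
  cat("<processed_signal> path=", x$path, ", n_frames=", x$n_frames,
      ", steps: ", paste(x$steps, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Preprocess a whole cohort on both paths
#'
#' Runs every recording through the amplitude path and, for functional-task
#' (`shft`) recordings, also through the waveform path. Recordings of equal
#' length are batched through one multivariate FFT, so a full cohort is
#' processed in a few passes. Maximal-effort recordings (`mvc`, `grasp`) only
#' contribute their pre-resampling envelope peak (the normalization
#' denominator), so their envelopes and waveforms are not retained.
#'
#' @param cohort A `semg_cohort` from [generate_cohort()], or its `recordings`
#'   tibble.
#' @param sigma_ms Gaussian smoothing sd in milliseconds.
#' @param n_frames Amplitude-path envelope length.
#' @param notch_waveform Apply the 50 Hz band-stop on the waveform path too.
#' @param band_low,band_high,notch_low,notch_high,order Filter settings in Hz.
#' @return A tibble with one row per recording: identifiers, `env_peak_mV`,
#'   and list-columns `envelope` (1000-frame amplitude envelope; `shft` rows
#'   only) and `waveform` (band-passed raw signal; `shft` rows only).
#' @export
preprocess_cohort <- function(cohort, sigma_ms = 50, n_frames = 1000L,
                              notch_waveform = FALSE,
                              band_low = 25, band_high = 500,
                              notch_low = 49.5, notch_high = 50.5, order = 4) {
  rec <- if (inherits(cohort, "semg_cohort")) cohort$recordings else cohort
  stopifnot(is.data.frame(rec))
  fs <- rec$fs[1L]
  amp_filters <- list(.design_bandpass(fs, band_low, band_high, order),
                      .design_bandstop(fs, notch_low, notch_high, order))
  wav_filters <- list(.design_bandpass(fs, band_low, band_high, order))
  if (notch_waveform) {
    wav_filters <- c(wav_filters,
                     list(.design_bandstop(fs, notch_low, notch_high, order)))
  }
  sigma <- sigma_ms * fs / 1000

  n <- nrow(rec)
  env_peak <- numeric(n)
  envelope <- vector("list", n)
  waveform <- vector("list", n)
  lens <- vapply(rec$samples, length, integer(1L))
  for (L in unique(lens)) {
    idx <- which(lens == L)
    X <- matrix(unlist(rec$samples[idx], use.names = FALSE), nrow = L)
    A <- .gauss_smooth(abs(.zero_phase(X, amp_filters)), sigma)
    A <- pmax(A, 0)
    env_peak[idx] <- apply(A, 2L, max)
    is_shft <- rec$task_family[idx] == "shft"
    if (any(is_shft)) {
      W <- .zero_phase(X[, is_shft, drop = FALSE], wav_filters)
      for (j in seq_along(idx)[is_shft]) {
        e <- resample_frames(A[, j], n_frames)
        envelope[[idx[j]]] <- e
        # functional-task normalization peaks are taken on the resampled
        # envelope, so the MAX-normalized unit bound is exact by construction
        env_peak[idx[j]] <- max(e)
      }
      kk <- which(is_shft)
      for (j in seq_along(kk)) waveform[[idx[kk[j]]]] <- W[, j]
    }
  }
  out <- rec[, c("participant_id", "group", "task_family", "task_id", "sensor", "fs")]
  out$env_peak_mV <- env_peak
  out$envelope <- envelope
  out$waveform <- waveform
  tibble::as_tibble(out)
}

#' Write retained processed signals to long-format CSV
#'
#' One row per frame with the cohort schema plus `path` (`"amplitude"` or
#' `"waveform"`) and `frame` columns. Only functional-task rows retain their
#' signals after [preprocess_cohort()], so only those are written.
#'
#' @param processed Output of [preprocess_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_processed_csv <- function(processed, path) {
  shft <- processed[processed$task_family == "shft", ]
  one <- function(col, label) {
    lens <- lengths(shft[[col]])
    tibble::tibble(
      participant_id = rep(shft$participant_id, lens),
      group = rep(shft$group, lens),
      task_family = rep(shft$task_family, lens),
      task_id = rep(shft$task_id, lens),
      sensor = rep(shft$sensor, lens),
      path = label,
      frame = unlist(lapply(lens, seq_len), use.names = FALSE),
      value = unlist(shft[[col]], use.names = FALSE))
  }
  readr::write_csv(rbind(one("envelope", "amplitude"),
                         one("waveform", "waveform")), path)
  invisible(path)
}
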