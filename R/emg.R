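#' Construct an EMG recording
#'
#' An `emg_recording` holds a multi-channel surface-EMG stream sampled at a
#' fixed rate. The reference hardware is an 8-electrode forearm band sampling
#' at 200 Hz, but both the channel count and the rate are configurable.
#'
#' @param samples numeric matrix, one column per channel, amplitudes in mV.
#' @param fs sampling rate in Hz.
#' @param t0 start time in seconds.
#' @return an object of class `emg_recording` with elements `samples`
#'   (matrix), `n_channels`, `fs`, `t0`.
#' @export
emg_recording <- function(samples, fs = 200, t0 = 0) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || nrow(samples) == 0L)
    stop("`samples` must be a non-empty numeric matrix")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar")
  structure(
    list(samples = unname(samples), n_channels = ncol(samples),
         fs = fs, t0 = t0),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels, %d samples @ %g Hz (%.2f s)\n",
              x$n_channels, nrow(x$samples), x$fs, nrow(x$samples) / x$fs))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `emg_recording`.
#' @export
emg_duration <- function(rec) nrow(rec$samples) / rec$fs

#' Construct a calibration profile
#'
#' Per-channel envelope levels measured in a relaxed state (`rest`) and while
#' squeezing a disc vigorously with the fingers (`max`, the maximum voluntary
#' contraction). Both are on the post-amplification envelope scale in mV.
#'
#' @param rest numeric vector of per-channel rest envelope means.
#' @param max numeric vector of per-channel maximum-contraction envelopes.
#' @return an object of class `calibration_profile`.
#' @export
calibration_profile <- function(rest, max) {
  rest <- as.numeric(rest); max <- as.numeric(max)
  if (length(rest) != length(max))
    stop("`rest` and `max` must have the same length")
  if (any(rest < 0)) stop("rest envelope must be non-negative")
  if (any(max <= rest)) stop("max envelope must exceed rest on every channel")
  structure(list(rest = rest, max = max), class = "calibration_profile")
}

#' Preprocess one raw EMG channel into an amplitude envelope
#'
#' Applies the standard envelope chain: amplification (default 20 dB on the
#' amplitude convention, i.e. x10), full-wave rectification, and a causal
#' 2nd-order low-pass Butterworth filter (default corner 3 Hz) with unit DC
#' gain. Filter ringing can undershoot zero slightly; the output is clipped
#' at 0 because an envelope is a magnitude.
#'
#' @param raw numeric vector, raw channel amplitudes in mV.
#' @param fs sampling rate in Hz.
#' @param gain_db amplifier gain in dB (amplitude convention).
#' @param fc low-pass corner frequency in Hz; must satisfy `fc < fs / 2`.
#' @param order filter order.
#' @return numeric envelope vector, same length as `raw`, non-negative.
#' @export
preprocess_channel <- function(raw, fs = 200, gain_db = 20, fc = 3, order = 2) {
  if (length(raw) == 0L) stop("empty series")
  if (fc >= fs / 2) stop("`fc` must be below the Nyquist frequency fs/2")
  rectified <- abs(raw * 10^(gain_db / 20))
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  env <- as.numeric(signal::filter(bf, rectified))
  pmax(env, 0)
}

#' DC gain of the designed envelope low-pass filter
#'
#' Exposed so the unit-gain property of the Butterworth design can be
#' checked directly: H(0) = sum(b) / sum(a).
#'
#' @inheritParams preprocess_channel
#' @return scalar gain at 0 Hz.
#' @export
envelope_filter_dc_gain <- function(fs = 200, fc = 3, order = 2) {
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  sum(bf$b) / sum(bf$a)
}

#' Envelope of every channel of a recording
#'
#' @param rec an `emg_recording` of raw signals.
#' @inheritParams preprocess_channel
#' @return matrix of envelopes, one column per channel.
#' @export
emg_envelope <- function(rec, gain_db = 20, fc = 3, order = 2) {
  apply(rec$samples, 2L, preprocess_channel,
        fs = rec$fs, gain_db = gain_db, fc = fc, order = order)
}

#' Rest-subtracted channel normalization
#'
#' Normalizes an instantaneous envelope vector so the rest-subtracted channel
#' activations sum to 1: `out[i] = (emg[i] - rest[i]) / sum_j(emg[j] - rest[j])`.
#' This is the input representation used by the motion classifier.
#'
#' @param emg numeric vector of per-channel envelope values.
#' @param rest per-channel rest envelope (same length).
#' @return numeric vector summing to 1.
#' @export
normalize_vector <- function(emg, rest) {
  if (length(emg) != length(rest)) stop("`emg` and `rest` lengths differ")
  d <- emg - rest
  s <- sum(d)
  if (s == 0) stop("zero total activation: signals at rest")
  d / s
}

#' Muscle contraction level (MCL)
#'
#' Mean over channels of the envelope position between the rest and
#' maximum-contraction calibration levels:
#' `MCL = mean_n (emg[n] - rest[n]) / (max[n] - rest[n])`.
#' Approximately in \[0, 1\] for valid inputs; supra-calibration contractions
#' can exceed 1, so the value is clamped to `clamp` (set `clamp = NULL` to
#' disable).
#'
#' @param emg per-channel envelope vector.
#' @param cal a [calibration_profile()].
#' @param clamp two-element numeric range or NULL.
#' @return scalar contraction level.
#' @export
muscle_contraction_level <- function(emg, cal, clamp = c(0, 1.5)) {
  if (length(emg) != length(cal$rest)) stop("channel count mismatch")
  mcl <- mean((emg - cal$rest) / (cal$max - cal$rest))
  if (!is.null(clamp)) mcl <- min(max(mcl, clamp[1]), clamp[2])
  mcl
}

#' Time-domain window features
#'
#' MAV (mean absolute value), IEMG (integrated EMG, the sum of absolute
#' values) and RMS over one analysis window.
#'
#' @param window numeric vector of amplitudes.
#' @return list with elements `mav`, `iemg`, `rms`.
#' @export
window_features <- function(window) {
  if (length(window) == 0L) stop("empty window")
  list(mav = mean(abs(window)),
       iemg = sum(abs(window)),
       rms = sqrt(mean(window^2)))
}

#' Extract training samples from a gesture recording
#'
#' A training recording lasts 8 s with the gesture performed between the
#' second and sixth seconds; feature vectors are drawn from that \[2 s, 6 s)
#' active window only. Each sample is the normalized envelope vector at the
#' selected instant. Selection is evenly spaced by default; a seeded random
#' subsample is available.
#'
#' @param rec an `emg_recording` of raw signals, at least 6 s long.
#' @param label class label attached to every sample ("hold" or "release").
#' @param cal a [calibration_profile()] used for normalization.
#' @param n_samples number of samples to draw.
#' @param method "even" (deterministic) or "random" (seeded subsample).
#' @param seed RNG seed for `method = "random"`.
#' @return list with `x` (n_samples x n_channels matrix of normalized
#'   vectors), `y` (labels), `indices` (1-based sample indices used).
#' @export
build_training_samples <- function(rec, label, cal, n_samples = 20,
                                   method = c("even", "random"), seed = 1L) {
  method <- match.arg(method)
  if (emg_duration(rec) < 6) stop("active window incomplete: recording shorter than 6 s")
  idx <- active_window_indices(rec$fs, n_samples, method, seed)
  env <- emg_envelope(rec)
  x <- t(apply(env[idx, , drop = FALSE], 1L, normalize_vector, rest = cal$rest))
  list(x = x, y = rep(label, n_samples), indices = idx)
}

# 1-based indices into the [2 s, 6 s) active window; 0-based positions are
# evenly spaced from 2*fs with step (4*fs)/n so that n=4 at fs=200 gives
# 400, 600, 800, 1000.
active_window_indices <- function(fs, n_samples, method = "even", seed = 1L) {
  lo <- 2 * fs          # 0-based start of active window
  hi <- 6 * fs          # 0-based exclusive end
  if (method == "even") {
    pos <- lo + floor((hi - lo) * (seq_len(n_samples) - 1L) / n_samples)
  } else {
    pos <- withr_seed(seed, sort(sample(seq.int(lo, hi - 1L), n_samples)))
  }
  as.integer(pos) + 1L
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write / read EMG recordings as CSV
#'
#' Tabular interchange format: columns `t, ch1..chK`, header required, units
#' mV. On read the sampling rate is inferred from the timestamps and, when
#' `fs` is given, validated against it.
#'
#' @param rec an `emg_recording`.
#' @param path file path.
#' @export
write_emg_csv <- function(rec, path) {
  t <- rec$t0 + (seq_len(nrow(rec$samples)) - 1L) / rec$fs
  df <- data.frame(t = t, rec$samples)
  names(df) <- c("t", paste0("ch", seq_len(rec$n_channels)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_emg_csv
#' @param fs expected sampling rate in Hz, or NULL to accept the inferred one.
#' @param tol relative tolerance for the fs check.
#' @export
read_emg_csv <- function(path, fs = NULL, tol = 0.01) {
  df <- utils::read.csv(path)
  if (names(df)[1] != "t" || ncol(df) < 2L)
    stop("EMG CSV must have columns t, ch1..chK")
  dt <- diff(df$t)
  fs_inf <- 1 / stats::median(dt)
  if (!is.null(fs) && abs(fs_inf - fs) / fs > tol)
    stop(sprintf("sampling rate %.2f Hz inferred from timestamps differs from configured %g Hz",
                 fs_inf, fs))
  emg_recording(as.matrix(df[, -1, drop = FALSE]),
                fs = if (is.null(fs)) fs_inf else fs, t0 = df$t[1])
}
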