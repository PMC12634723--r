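#' Classify hold/release motion over a recording
#'
#' Runs the full per-sample chain: channel envelopes, muscle contraction
#' level (MCL) gating, rest-subtracted normalization and the LLGMN posterior.
#' Samples whose MCL falls below `mcl_gate` are labelled `rest`; otherwise
#' the label is the posterior argmax with ties broken toward `release`
#' (hold time is never accrued on ambiguity). A running-mode label smoother
#' of odd width `smooth` suppresses single-sample flicker; set `smooth = 0`
#' to disable.
#'
#' @param rec an [emg_recording()] of raw signals.
#' @param cal a [calibration_profile()].
#' @param model a trained [llgmn_model()].
#' @param mcl_gate rest gate on the MCL scale.
#' @param smooth odd smoothing window in samples (0 = off).
#' @param latency label timestamp correction in samples: the causal envelope
#'   filter delays the signal by its low-frequency group delay, so decisions
#'   are shifted earlier by this amount. `NULL` (default) uses the designed
#'   filter's group delay at DC (about 15 samples at 200 Hz with a 3 Hz
#'   corner); 0 disables.
#' @return a `motion_labels` object: `labels` (character vector over
#'   `{hold, release, rest}`), `dt` (step in s), `t0`, `mcl` (per-sample MCL).
#' @export
classify_motion <- function(rec, cal, model, mcl_gate = 0.05, smooth = 5L,
                            latency = NULL) {
  env <- emg_envelope(rec)
  n <- nrow(env)
  mcl <- numeric(n)
  labels <- character(n)
  for (i in seq_len(n)) {
    mcl[i] <- muscle_contraction_level(env[i, ], cal)
    if (mcl[i] < mcl_gate) {
      labels[i] <- "rest"
    } else {
      xn <- normalize_vector(env[i, ], cal$rest)
      p <- llgmn_forward(model, xn)
      top <- which(p == max(p))
      labels[i] <- if (length(top) > 1L && "release" %in% names(p)[top])
        "release" else names(p)[top[1L]]
    }
  }
  if (smooth > 0L) labels <- smooth_labels(labels, smooth)
  if (is.null(latency)) latency <- envelope_group_delay(rec$fs)
  latency <- min(as.integer(latency), n - 1L)
  if (latency > 0L)
    labels <- c(labels[(latency + 1L):n], rep(labels[n], latency))
  motion_labels(labels, dt = 1 / rec$fs, t0 = rec$t0, mcl = mcl)
}

#' Group delay of the envelope filter at DC, in samples
#'
#' A 2nd-order low-pass Butterworth delays slow envelope modulations by
#' `sqrt(2) / (2 pi fc)` seconds (the sum of its pole time constants), which
#' the bilinear-transform digital design inherits at low frequency.
#'
#' @inheritParams preprocess_channel
#' @export
envelope_group_delay <- function(fs = 200, fc = 3) {
  round(fs * sqrt(2) / (2 * pi * fc))
}

#' Construct a motion label series
#'
#' @param labels character vector with values in `{hold, release, rest}`.
#' @param dt time step in seconds.
#' @param t0 start time in seconds.
#' @param mcl optional per-sample MCL trace.
#' @export
motion_labels <- function(labels, dt, t0 = 0, mcl = NULL) {
  ok <- labels %in% c("hold", "release", "rest")
  if (!all(ok)) stop("labels must be hold/release/rest")
  structure(list(labels = labels, dt = dt, t0 = t0, mcl = mcl),
            class = "motion_labels")
}

#' Running-mode smoother for categorical label series
#'
#' Each position is replaced by the most frequent label in the centred
#' window of odd width `width`; ties keep the original centre label. The
#' ends use the truncated window.
#'
#' @param labels character vector.
#' @param width odd window width in samples.
#' @return smoothed character vector, same length.
#' @export
smooth_labels <- function(labels, width = 5L) {
  if (width %% 2L != 1L) stop("`width` must be odd")
  n <- length(labels)
  half <- width %/% 2L
  out <- labels
  for (i in seq_len(n)) {
    win <- labels[max(1L, i - half):min(n, i + half)]
    tab <- table(win)
    top <- names(tab)[tab == max(tab)]
    if (!(labels[i] %in% top)) out[i] <- top[1L]
  }
  out
}

#' Total hold time of a label series
#'
#' `(number of samples labelled hold) * dt`, in seconds. Additive over
#' concatenated series by construction.
#'
#' @param ml a `motion_labels` object.
#' @return seconds labelled hold.
#' @export
total_hold_time <- function(ml) sum(ml$labels == "hold") * ml$dt

#' Contiguous hold intervals of a label series
#'
#' @param ml a `motion_labels` object.
#' @return data.frame with columns `start`, `end` in seconds (end exclusive).
#' @export
hold_intervals <- function(ml) {
  is_hold <- ml$labels == "hold"
  if (!any(is_hold)) return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(is_hold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = ml$t0 + (starts[keep] - 1L) * ml$dt,
             end = ml$t0 + ends[keep] * ml$dt)
}

#' Write / read motion label series as CSV (`t,label`)
#'
#' @param ml a `motion_labels` object.
#' @param path file path.
#' @export
write_labels_csv <- function(ml, path) {
  t <- ml$t0 + (seq_along(ml$labels) - 1L) * ml$dt
  utils::write.csv(data.frame(t = t, label = ml$labels), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path)
  dt <- stats::median(diff(df$t))
  motion_labels(df$label, dt = dt, t0 = df$t[1])
}
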