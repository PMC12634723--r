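#' Generate a ground-truth session schedule
#'
#' A schedule emulates one phase of the 60-disc test: strictly increasing
#' per-disc event times (placement or turn), a hand hold window preceding
#' each event, an arm-movement burst at each event, and optional quiet
#' ("thinking") intervals with no arm motion. Defaults reflect a healthy
#' participant: about 1 s per disc (placing totals near 62 s), hold
#' occupying about 45% of each inter-event gap, and amplitude levels drawn
#' near the healthy-cohort reference means (roll-dominant rotation bursts of
#' order 130 deg/s in placing, X-axis accelerations of order 2 m/s^2).
#'
#' @param phase `"placing"` or `"turning"`.
#' @param n_discs number of discs.
#' @param seed RNG seed; every generated stream is deterministic given it.
#' @param lighting `"normal"`, `"shadow"`, `"flash"` or `"dim"`.
#' @param fps synthetic camera frame rate, Hz.
#' @param gap_mean,gap_sd inter-event gap distribution, s.
#' @param hold_frac fraction of each gap spent holding the disc.
#' @param initial_delay time before the first event, s.
#' @param quiet data.frame (`start`, `end`) of no-motion intervals, s; NULL
#'   for the default single 1 s pause inside the initial delay.
#' @param upside_down_holes hole ids placed black-side-up (placing phase).
#' @param perturbed_holes hole ids affected by shadow/flash lighting;
#'   default the bottom-right hole.
#' @return a `session_schedule` object.
#' @export
make_session_schedule <- function(phase = c("placing", "turning"), n_discs = 60L,
                                  seed = 1L, lighting = "normal", fps = 10,
                                  gap_mean = 1.0, gap_sd = 0.15,
                                  hold_frac = 0.45, initial_delay = 2,
                                  quiet = NULL, upside_down_holes = integer(0),
                                  perturbed_holes = NULL) {
  phase <- match.arg(phase)
  if (!lighting %in% c("normal", "shadow", "flash", "dim"))
    stop(sprintf("unknown lighting mode '%s'", lighting))
  withr_seed(seed, {
    gaps <- pmin(pmax(stats::rnorm(n_discs, gap_mean, gap_sd), 0.5), 2)
    times <- initial_delay + cumsum(gaps)
    holds <- data.frame(start = times - hold_frac * gaps, end = times)
    # rotation burst amplitudes near the healthy reference levels, deg/s
    rot_mu <- if (phase == "placing") c(130, 140, 190) else c(110, 90, 63)
    acc_mu <- if (phase == "placing") c(2.1, 2.7, 1.3) else c(0.9, 1.2, 0.8)
    axis <- rep_len(1:3, n_discs)
    bursts <- data.frame(
      t = times - 0.5 * gaps,
      axis = axis,
      gyro_amp = pmax(stats::rnorm(n_discs, rot_mu[axis], 15), 30),
      acc_amp = pmax(stats::rnorm(n_discs, acc_mu[axis], 0.15), 0.4)
    )
    if (is.null(quiet)) quiet <- data.frame(start = 0.4, end = 1.4)
    if (is.null(perturbed_holes)) perturbed_holes <- n_discs
    structure(
      list(phase = phase, n_discs = as.integer(n_discs), seed = seed,
           lighting = lighting, fps = fps,
           events = data.frame(hole_id = seq_len(n_discs), t = times),
           hold_windows = holds, bursts = bursts, quiet = quiet,
           upside_down_holes = as.integer(upside_down_holes),
           perturbed_holes = as.integer(perturbed_holes),
           duration = max(times) + 1),
      class = "session_schedule"
    )
  })
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(sprintf("<session_schedule> %s phase, %d discs, %.1f s, lighting %s, seed %d\n",
              x$phase, x$n_discs, x$duration, x$lighting, x$seed))
  invisible(x)
}

# ground-truth color of each of n_holes at time t; holes beyond the schedule
# are empty in placing and hold an unturned (red) disc in turning
schedule_disc_state <- function(schedule, t, n_holes = schedule$n_discs) {
  col <- rep(if (schedule$phase == "placing") "white" else "red", n_holes)
  done <- schedule$events$hole_id[schedule$events$t <= t]
  if (schedule$phase == "placing") {
    col[done] <- "red"
    col[intersect(done, schedule$upside_down_holes)] <- "black"
  } else {
    col[done] <- "black"
  }
  col
}

synth_palette <- function() {
  list(white = c(255, 255, 255), red = c(200, 30, 30), black = c(25, 25, 25))
}

# lighting transform for an RGB block (n x 3); `perturbed` marks pixels under
# the local shadow/flash patch
apply_lighting <- function(rgb, lighting, perturbed, shadow_factor = 0.1) {
  if (lighting == "dim") rgb <- rgb * 0.5
  if (lighting == "shadow" && any(perturbed))
    rgb[perturbed, ] <- rgb[perturbed, , drop = FALSE] * shadow_factor
  if (lighting == "flash" && any(perturbed))
    rgb[perturbed, ] <- 255
  rgb
}

#' Render the synthetic board at one instant
#'
#' `mode = "holes"` produces a compact `hole_patches` frame holding only the
#' sampled neighbourhood of each hole centre (what [observe_board()] reads);
#' `mode = "full"` renders the complete 640 x 480 image with discs of
#' `disc_radius` px. Both modes draw the same colors, lighting transform
#' (shadow: RGB x `shadow_factor` at perturbed holes; flash: saturation to
#' white; dim: global value x 0.5) and +/- `noise` counts of uniform pixel
#' noise.
#'
#' @param schedule a [make_session_schedule()].
#' @param layout a [board_layout()].
#' @param t frame time in s.
#' @param mode `"holes"` or `"full"`.
#' @param noise noise half-range in counts (0 disables).
#' @param shadow_factor RGB multiplier inside the shadow patch.
#' @return a `hole_patches` object or an image array, values 0-255.
#' @export
render_frame <- function(schedule, layout, t, mode = c("holes", "full"),
                         noise = 3, shadow_factor = 0.1) {
  mode <- match.arg(mode)
  pal <- synth_palette()
  cols <- schedule_disc_state(schedule, t, nrow(layout$holes))
  pert <- layout$holes$id %in% schedule$perturbed_holes
  r <- layout$sample_radius
  side <- 2L * r + 1L
  if (mode == "holes") {
    n <- nrow(layout$holes)
    side2 <- side * side
    base <- t(vapply(cols, function(cc) pal[[cc]], numeric(3)))
    pix <- base[rep(seq_len(n), each = side2), , drop = FALSE]
    pix <- apply_lighting(pix, schedule$lighting, rep(pert, each = side2),
                          shadow_factor)
    if (noise > 0)
      pix <- pix + (sample.int(2L * noise + 1L, length(pix), replace = TRUE) -
                      noise - 1L)
    pix <- pmin(pmax(pix, 0), 255)
    structure(list(pix = array(pix, dim = c(side2, n, 3)), side = side,
                   t = t, radius = r),
              class = "hole_patches")
  } else {
    w <- layout$image_size[1]; h <- layout$image_size[2]
    img <- array(255, dim = c(h, w, 3))
    disc_r <- 12L
    off <- sample_offsets(disc_r)
    for (i in seq_len(nrow(layout$holes))) {
      if (cols[i] == "white") next
      rows <- layout$holes$y[i] + off$dy + 1L
      colx <- layout$holes$x[i] + off$dx + 1L
      ok <- rows >= 1 & rows <= h & colx >= 1 & colx <= w
      for (ch in 1:3)
        img[cbind(rows[ok], colx[ok], ch)] <- pal[[cols[i]]][ch]
    }
    if (schedule$lighting == "dim") img <- img * 0.5
    if (schedule$lighting %in% c("shadow", "flash")) {
      for (i in which(pert)) {
        ys <- max(1L, layout$holes$y[i] - 19L):min(h, layout$holes$y[i] + 20L)
        xs <- max(1L, layout$holes$x[i] - 19L):min(w, layout$holes$x[i] + 20L)
        if (schedule$lighting == "shadow")
          img[ys, xs, ] <- img[ys, xs, ] * shadow_factor
        else img[ys, xs, ] <- 255
      }
    }
    if (noise > 0)
      img <- img + array(sample.int(2L * noise + 1L, length(img), replace = TRUE) -
                           noise - 1L, dim = dim(img))
    pmin(pmax(img, 0), 255)
  }
}

#' Generate the timed frame sequence of a session
#'
#' Frames run from t = 0 to the schedule duration at the schedule's frame
#' rate. Deterministic given `seed`.
#'
#' @inheritParams render_frame
#' @param seed RNG seed for pixel noise; defaults to the schedule seed.
#' @return list with `frames` (list) and `times` (numeric, s).
#' @export
gen_board_frames <- function(schedule, layout, mode = c("holes", "full"),
                             noise = 3, seed = NULL, shadow_factor = 0.1) {
  mode <- match.arg(mode)
  if (is.null(seed)) seed <- schedule$seed
  times <- seq(0, schedule$duration, by = 1 / schedule$fps)
  frames <- withr_seed(seed, lapply(times, function(t)
    render_frame(schedule, layout, t, mode, noise, shadow_factor)))
  list(frames = frames, times = times)
}

#' Write a frame sequence as PNG files plus a manifest
#'
#' Files are named `frame_<index>_<t_ms>.png`; `manifest.csv` lists
#' `t,filename`. Requires full-image frames.
#'
#' @param frames list of image arrays (0-255).
#' @param times frame times in s.
#' @param dir output directory (created).
#' @export
write_frames_png <- function(frames, times, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fn <- sprintf("frame_%04d_%d.png", seq_along(frames) - 1L,
                round(times * 1000))
  for (i in seq_along(frames))
    png::writePNG(frames[[i]] / 255, file.path(dir, fn[i]))
  utils::write.csv(data.frame(t = times, filename = fn),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a PNG frame directory written by [write_frames_png()]
#'
#' Unreadable frames are skipped with a warning; analysis continues on the
#' remaining frames.
#'
#' @param dir frame directory containing `manifest.csv`.
#' @return list with `frames` and `times`.
#' @export
read_frames_png <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  frames <- list(); times <- numeric(0)
  for (i in seq_len(nrow(man))) {
    img <- tryCatch(png::readPNG(file.path(dir, man$filename[i])) * 255,
                    error = function(e) {
                      warning(sprintf("skipping unreadable frame %s: %s",
                                      man$filename[i], conditionMessage(e)))
                      NULL
                    })
    if (!is.null(img)) {
      frames[[length(frames) + 1L]] <- img
      times <- c(times, man$t[i])
    }
  }
  list(frames = frames, times = times)
}

# per-channel target envelope trajectories over the session
emg_target_envelope <- function(schedule, cal, fs, pattern_hold, ramp = 0.15) {
  n <- ceiling(schedule$duration * fs)
  t <- (seq_len(n) - 1L) / fs
  span <- cal$max - cal$rest
  act <- numeric(n)  # 0..1 activation profile of the hold gesture
  for (k in seq_len(nrow(schedule$hold_windows))) {
    s <- schedule$hold_windows$start[k]; e <- schedule$hold_windows$end[k]
    act <- pmax(act, pmin(pmin((t - s) / ramp, (e - t) / ramp), 1))
  }
  act <- pmax(act, 0)
  env <- outer(act, pattern_hold) * rep(span, each = n) +
    rep(cal$rest, each = n)
  list(env = env, act = act, t = t)
}

#' Generate a synthetic raw EMG recording for a session
#'
#' Inside each scheduled hold window, channels 4 and 5 rise toward the
#' maximum-contraction calibration level (trapezoid with 0.15 s ramps)
#' while the other channels mildly co-activate; outside the windows all
#' channels sit at the rest level. The target envelope (plus Gaussian noise
#' of sd 2% of the calibration span, clipped at 0) is converted to a raw
#' signed signal whose rectified, amplified, low-passed envelope reproduces
#' it: `raw = env / gain * z / E|z|` with `z` standard normal.
#'
#' @param schedule a [make_session_schedule()].
#' @param cal a [calibration_profile()] (8 channels).
#' @param fs sampling rate, Hz.
#' @param seed RNG seed; defaults to the schedule seed.
#' @param pattern activation pattern of the hold gesture per channel,
#'   as a fraction of the rest-to-max span.
#' @return an [emg_recording()] of raw mV signals.
#' @export
gen_emg <- function(schedule, cal, fs = 200, seed = NULL,
                    pattern = c(0.25, 0.25, 0.25, 0.9, 0.9, 0.25, 0.25, 0.25)) {
  if (is.null(seed)) seed <- schedule$seed
  if (length(cal$rest) != length(pattern)) stop("pattern/calibration mismatch")
  if (any(schedule$hold_windows$end > schedule$duration))
    stop("hold window outside session duration")
  tgt <- emg_target_envelope(schedule, cal, fs, pattern)
  withr_seed(seed + 1L, {
    span <- cal$max - cal$rest
    env <- tgt$env + matrix(stats::rnorm(length(tgt$env), 0,
                                         rep(0.02 * span, each = nrow(tgt$env))),
                            nrow = nrow(tgt$env))
    env <- pmax(env, 0)
    z <- matrix(stats::rnorm(length(env)), nrow = nrow(env))
    raw <- env / 10 * z / sqrt(2 / pi)
    emg_recording(raw, fs = fs)
  })
}

#' Generate one 8-s gesture training recording
#'
#' The gesture (hold or release) is performed between seconds 2 and 6 of an
#' 8-s recording, the window [build_training_samples()] draws from. The two
#' gestures differ in their channel signature: hold is dominated by
#' channels 4-5; release adds wrist-extensor co-activation on channels 3
#' and 6 with channels 4-5 at half drive.
#'
#' @param gesture `"hold"` or `"release"`.
#' @param cal a [calibration_profile()].
#' @param fs sampling rate, Hz.
#' @param seed RNG seed.
#' @return an [emg_recording()] of raw mV signals, 8 s long.
#' @export
gen_training_recording <- function(gesture = c("hold", "release"), cal,
                                   fs = 200, seed = 1L) {
  gesture <- match.arg(gesture)
  pattern <- if (gesture == "hold")
    c(0.25, 0.25, 0.25, 0.9, 0.9, 0.25, 0.25, 0.25)
  else c(0.15, 0.15, 0.55, 0.45, 0.45, 0.55, 0.15, 0.15)
  sched <- structure(
    list(duration = 8, seed = seed,
         hold_windows = data.frame(start = 2, end = 6)),
    class = "session_schedule")
  gen_emg(sched, cal, fs = fs, seed = seed, pattern = pattern)
}

#' Generate a synthetic IMU trace for a session
#'
#' Baseline: continuous arm motion modelled as a constant-magnitude forearm
#' rotation (quadrature sinusoids of `base_gyro` deg/s on roll/pitch) that
#' switches off inside the schedule's quiet intervals; gravity (1 g on Z);
#' sensor noise (0.06 deg/s gyro, 4 mg accel RMS). Each scheduled burst
#' adds a half-sine pulse of its stated gyroscope amplitude on its axis and
#' of its acceleration amplitude (m/s^2) on the matching accelerometer
#' axis. Amplitudes beyond the sensor ranges are an error.
#'
#' @param schedule a [make_session_schedule()].
#' @param fs sampling rate, Hz.
#' @param seed RNG seed; defaults to the schedule seed.
#' @param base_gyro baseline rotation amplitude, deg/s.
#' @param burst_width pulse width, s.
#' @return an [imu_trace()].
#' @export
gen_imu <- function(schedule, fs = 50, seed = NULL, base_gyro = 40,
                    burst_width = 0.3) {
  if (is.null(seed)) seed <- schedule$seed
  if (any(schedule$bursts$t > schedule$duration)) stop("burst outside duration")
  if (any(schedule$bursts$gyro_amp > 2000)) stop("gyro amplitude beyond sensor range")
  if (any(schedule$bursts$acc_amp / 9.81 + 1 > 16))
    stop("acceleration amplitude beyond sensor range")
  n <- ceiling(schedule$duration * fs)
  t <- (seq_len(n) - 1L) / fs
  active <- rep(TRUE, n)
  for (k in seq_len(nrow(schedule$quiet)))
    active <- active & !(t >= schedule$quiet$start[k] & t < schedule$quiet$end[k])
  gyro <- cbind(base_gyro * sinpi(2 * 1.2 * t),
                base_gyro * cospi(2 * 1.2 * t),
                0.5 * base_gyro * sinpi(2 * 0.7 * t)) * active
  accel_ms2 <- matrix(0, n, 3)
  for (k in seq_len(nrow(schedule$bursts))) {
    b <- schedule$bursts[k, ]
    sel <- t >= b$t - burst_width / 2 & t <= b$t + burst_width / 2
    pulse <- sinpi((t[sel] - (b$t - burst_width / 2)) / burst_width)
    gyro[sel, b$axis] <- gyro[sel, b$axis] + b$gyro_amp * pulse
    accel_ms2[sel, b$axis] <- accel_ms2[sel, b$axis] + b$acc_amp * pulse
  }
  withr_seed(seed + 2L, {
    gyro <- gyro + matrix(stats::rnorm(3 * n, 0, 0.06), n, 3)
    accel_g <- ms2_to_accel_g(accel_ms2) +
      matrix(stats::rnorm(3 * n, 0, 0.004), n, 3)
  })
  imu_trace(t, pmin(pmax(gyro, -2000), 2000), pmin(pmax(accel_g, -16), 16), fs = fs)
}
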