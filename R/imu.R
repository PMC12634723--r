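#' Construct an IMU trace
#'
#' Forearm inertial trace: 3-axis gyroscope in deg/s (roll, pitch, yaw) and
#' 3-axis accelerometer in g, sampled at `fs`. Sensor ranges are validated
#' (gyro +/- 2000 deg/s, accel +/- 16 g).
#'
#' @param t numeric timestamps in seconds (monotone increasing).
#' @param gyro n x 3 matrix, deg/s.
#' @param accel n x 3 matrix, g.
#' @param fs sampling rate in Hz.
#' @return an `imu_trace` object.
#' @export
imu_trace <- function(t, gyro, accel, fs = 50) {
  gyro <- as.matrix(gyro); accel <- as.matrix(accel)
  if (length(t) == 0L) stop("empty trace")
  if (is.unsorted(t, strictly = TRUE)) stop("timestamps must be strictly increasing")
  if (nrow(gyro) != length(t) || nrow(accel) != length(t))
    stop("gyro/accel length mismatch")
  if (any(abs(gyro) > 2000)) stop("gyro value outside +/- 2000 deg/s sensor range")
  if (any(abs(accel) > 16)) stop("accel value outside +/- 16 g sensor range")
  structure(list(t = t, gyro = unname(gyro), accel = unname(accel), fs = fs),
            class = "imu_trace")
}

#' Convert accelerometer samples from g to m/s^2 with gravity compensation
#'
#' Multiplies by 9.81 and subtracts gravitational acceleration (9.81 m/s^2)
#' from the Z axis, which is assumed to stay near world-vertical (no
#' orientation fusion is applied).
#'
#' @param accel_g 3-vector or n x 3 matrix in g, axis order (x, y, z).
#' @return same shape, in m/s^2.
#' @export
accel_to_ms2 <- function(accel_g) {
  m <- if (is.matrix(accel_g)) accel_g else matrix(accel_g, ncol = 3)
  if (any(!is.finite(m))) stop("non-finite accelerometer input")
  out <- m * 9.81
  out[, 3] <- out[, 3] - 9.81
  if (is.matrix(accel_g)) out else drop(out)
}

#' Inverse of [accel_to_ms2()]
#' @param accel_ms2 3-vector or n x 3 matrix in m/s^2 (gravity-compensated).
#' @export
ms2_to_accel_g <- function(accel_ms2) {
  m <- if (is.matrix(accel_ms2)) accel_ms2 else matrix(accel_ms2, ncol = 3)
  m[, 3] <- m[, 3] + 9.81
  out <- m / 9.81
  if (is.matrix(accel_ms2)) out else drop(out)
}

#' Local maxima of |x| with a minimum prominence
#'
#' A sample is a peak when it strictly exceeds its immediate neighbours on
#' the magnitude scale and its prominence (height above the higher of the
#' two deepest valleys separating it from larger peaks or the series ends)
#' is at least `prominence`.
#'
#' @param x numeric series.
#' @param prominence minimum prominence on the |x| scale.
#' @return integer indices of accepted peaks.
#' @export
find_abs_peaks <- function(x, prominence = 0.3) {
  a <- abs(x)
  n <- length(a)
  if (n < 3L) return(integer(0))
  cand <- which(a[2:(n - 1)] > a[1:(n - 2)] & a[2:(n - 1)] >= a[3:n]) + 1L
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    # walk left/right until a higher sample or the end; valley floor each side
    left_min <- min(a[1:i])
    j <- i
    while (j > 1L && a[j - 1L] <= a[i]) j <- j - 1L
    if (j > 1L) left_min <- min(a[j:i])
    right_min <- min(a[i:n])
    j <- i
    while (j < n && a[j + 1L] <= a[i]) j <- j + 1L
    if (j < n) right_min <- min(a[i:j])
    keep[k] <- (a[i] - max(left_min, right_min)) >= prominence
  }
  cand[keep]
}

#' Summarize one test phase of an IMU trace
#'
#' Angular velocity: per-axis maximum magnitude (deg/s) plus mean/min/max of
#' the signed signal. Linear acceleration (gravity-compensated m/s^2):
#' per-axis mean of detected peak magnitudes (prominence-gated; 0 when no
#' peak is found) plus mean/min/max.
#'
#' @param trace an [imu_trace()].
#' @param peak_prominence minimum peak prominence in m/s^2.
#' @return a `kin_summary` list with `gyro_max_abs`, `gyro_stats`,
#'   `accel_peak_mean`, `accel_stats` (axes roll/pitch/yaw and x/y/z).
#' @export
summarize_phase <- function(trace, peak_prominence = 0.3) {
  acc <- accel_to_ms2(trace$accel)
  gyro_axes <- c("roll", "pitch", "yaw")
  acc_axes <- c("x", "y", "z")
  stats3 <- function(m, axes) {
    s <- data.frame(axis = axes,
                    mean = colMeans(m),
                    min = apply(m, 2, min),
                    max = apply(m, 2, max))
    rownames(s) <- NULL
    s
  }
  peak_mean <- vapply(seq_len(3), function(j) {
    idx <- find_abs_peaks(acc[, j], peak_prominence)
    if (length(idx) == 0L) 0 else mean(abs(acc[idx, j]))
  }, numeric(1))
  structure(
    list(gyro_max_abs = stats::setNames(apply(abs(trace$gyro), 2, max), gyro_axes),
         gyro_stats = stats3(trace$gyro, gyro_axes),
         accel_peak_mean = stats::setNames(peak_mean, acc_axes),
         accel_stats = stats3(acc, acc_axes)),
    class = "kin_summary"
  )
}

#' Total inactivity ("thinking") time of a trace
#'
#' Sum of the durations of maximal intervals in which every gyro axis stays
#' below `gyro_thresh` deg/s in magnitude and every gravity-compensated
#' acceleration axis stays below `accel_thresh` m/s^2. Each quiet sample
#' contributes one sample period.
#'
#' @param trace an [imu_trace()].
#' @param gyro_thresh threshold in deg/s.
#' @param accel_thresh threshold in m/s^2.
#' @return seconds of inactivity.
#' @export
inactivity_time <- function(trace, gyro_thresh = 10, accel_thresh = 0.3) {
  if (gyro_thresh <= 0 || accel_thresh <= 0) stop("thresholds must be positive")
  acc <- accel_to_ms2(trace$accel)
  quiet <- apply(abs(trace$gyro) < gyro_thresh, 1, all) &
    apply(abs(acc) < accel_thresh, 1, all)
  sum(quiet) / trace$fs
}

#' Write / read IMU traces as CSV (`t,gx,gy,gz,ax,ay,az`; gyro deg/s, accel g)
#' @param trace an `imu_trace`.
#' @param path file path.
#' @export
write_imu_csv <- function(trace, path) {
  df <- data.frame(t = trace$t, trace$gyro, trace$accel)
  names(df) <- c("t", "gx", "gy", "gz", "ax", "ay", "az")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_imu_csv
#' @param fs sampling rate; NULL to infer from timestamps.
#' @export
read_imu_csv <- function(path, fs = NULL) {
  df <- utils::read.csv(path)
  if (is.null(fs)) fs <- 1 / stats::median(diff(df$t))
  imu_trace(df$t, as.matrix(df[, c("gx", "gy", "gz")]),
            as.matrix(df[, c("ax", "ay", "az")]), fs = fs)
}

#' Export a kinematic summary as JSON
#' @param summary a `kin_summary`.
#' @param path file path.
#' @export
write_kin_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
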