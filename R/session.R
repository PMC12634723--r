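#' Default session configuration
#'
#' Central knob bundle for the pipeline: sensor rates, calibration profile
#' (post-amplification envelope mV), the MCL rest gate, the vision debounce
#' and the rule thresholds. All values can be overridden via `...`.
#'
#' @param ... named overrides of the defaults.
#' @return named list.
#' @export
default_session_config <- function(...) {
  cfg <- list(
    schema_version = 1L,
    phase = "placing",
    seed = 1L,
    lighting = "normal",
    n_discs = 60L,
    fs_emg = 200,
    fs_imu = 50,
    fps = 10,
    calibration = list(rest = rep(2, 8), max = rep(50, 8)),
    mcl_gate = 0.05,
    smooth = 5L,
    debounce = 2L,
    thresholds = default_thresholds()
  )
  utils::modifyList(cfg, list(...))
}

#' Simulate a complete session directory
#'
#' Generates one phase of a synthetic test session and writes every stream
#' the analyzer consumes: `frames/` (PNG sequence plus manifest),
#' `emg.csv`, `imu.csv`, `train_hold.csv` / `train_release.csv` (8-s
#' gesture recordings for per-session classifier training), `layout.json`,
#' `schedule.json` (ground truth) and `config.json`. Byte-identical for a
#' given config and seed.
#'
#' @param dir output directory (created).
#' @param config a [default_session_config()] list.
#' @return `dir`, invisibly.
#' @export
simulate_session <- function(dir, config = default_session_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cal <- calibration_profile(config$calibration$rest, config$calibration$max)
  layout <- board_layout()
  sched <- make_session_schedule(config$phase, n_discs = config$n_discs,
                                 seed = config$seed, lighting = config$lighting,
                                 fps = config$fps)
  fr <- gen_board_frames(sched, layout, mode = "full")
  write_frames_png(fr$frames, fr$times, file.path(dir, "frames"))
  write_emg_csv(gen_emg(sched, cal, fs = config$fs_emg), file.path(dir, "emg.csv"))
  write_imu_csv(gen_imu(sched, fs = config$fs_imu), file.path(dir, "imu.csv"))
  write_emg_csv(gen_training_recording("hold", cal, config$fs_emg,
                                       seed = config$seed + 10L),
                file.path(dir, "train_hold.csv"))
  write_emg_csv(gen_training_recording("release", cal, config$fs_emg,
                                       seed = config$seed + 11L),
                file.path(dir, "train_release.csv"))
  write_layout_json(layout, file.path(dir, "layout.json"))
  jsonlite::write_json(list(
    phase = sched$phase, seed = sched$seed, lighting = sched$lighting,
    fps = sched$fps, duration = sched$duration, events = sched$events,
    hold_windows = sched$hold_windows, bursts = sched$bursts,
    quiet = sched$quiet), file.path(dir, "schedule.json"),
    auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Train the per-session hold/release classifier
#'
#' Builds 20 normalized feature vectors per gesture from the two 8-s
#' training recordings and fits the LLGMN.
#'
#' @param rec_hold,rec_release [emg_recording()]s of the two gestures.
#' @param cal a [calibration_profile()].
#' @param n_samples samples per gesture.
#' @return a trained `llgmn`.
#' @export
train_session_model <- function(rec_hold, rec_release, cal, n_samples = 20) {
  sh <- build_training_samples(rec_hold, "hold", cal, n_samples)
  sr <- build_training_samples(rec_release, "release", cal, n_samples)
  llgmn_train(rbind(sh$x, sr$x), c(sh$y, sr$y),
              classes = c("hold", "release"))
}

#' Analyze a session directory into a report
#'
#' Runs the full pipeline: board tracking (per-disc placing/turning times),
#' EMG motion classification (total hold time), IMU summaries and
#' inactivity, and the expert rulebase. Missing streams produce explicit
#' NULL fields, `complete = FALSE`, and findings restricted to the
#' available measurements.
#'
#' @param dir session directory (see [simulate_session()]).
#' @param rulebase rulebase to evaluate; default the shipped one.
#' @return a `session_report` list; see Details.
#' @export
analyze_session <- function(dir, rulebase = default_rulebase()) {
  config <- jsonlite::read_json(file.path(dir, "config.json"),
                                simplifyVector = TRUE)
  thresholds <- if (!is.null(config$thresholds)) as.list(config$thresholds)
    else default_thresholds()
  phase <- config$phase
  suf <- if (phase == "placing") "p" else "t"
  report <- list(schema_version = 1L, phase = phase, complete = TRUE,
                 timing = NULL, emg = NULL, imu = NULL, findings = NULL)

  layout <- read_layout_json(file.path(dir, "layout.json"))
  frames_dir <- file.path(dir, "frames")
  if (dir.exists(frames_dir)) {
    fr <- read_frames_png(frames_dir)
    state <- track_board(fr$frames, fr$times, layout, phase,
                         debounce = config$debounce %||% 2L)
    tm <- disc_timings(state$events, phase_start = 0)
    report$timing <- list(events = state$events, durations = tm$durations,
                          total = tm$total, placed = state$placed,
                          empty = state$empty)
  } else report$complete <- FALSE

  emg_path <- file.path(dir, "emg.csv")
  if (file.exists(emg_path) && file.exists(file.path(dir, "train_hold.csv"))) {
    cal <- calibration_profile(config$calibration$rest, config$calibration$max)
    rec <- read_emg_csv(emg_path, fs = config$fs_emg)
    model <- train_session_model(
      read_emg_csv(file.path(dir, "train_hold.csv"), fs = config$fs_emg),
      read_emg_csv(file.path(dir, "train_release.csv"), fs = config$fs_emg),
      cal)
    labels <- classify_motion(rec, cal, model,
                              mcl_gate = config$mcl_gate %||% 0.05,
                              smooth = config$smooth %||% 5L)
    report$emg <- list(total_hold_time = total_hold_time(labels),
                       hold_intervals = hold_intervals(labels))
  } else report$complete <- FALSE

  imu_path <- file.path(dir, "imu.csv")
  if (file.exists(imu_path)) {
    trace <- read_imu_csv(imu_path, fs = config$fs_imu)
    report$imu <- list(summary = summarize_phase(trace),
                       inactivity = inactivity_time(trace))
  } else report$complete <- FALSE

  phase_ctx <- list(
    total = report$timing$total,
    durations = report$timing$durations,
    kin = report$imu$summary,
    inactivity = report$imu$inactivity)
  ctx <- if (phase == "placing") rule_context(placing = phase_ctx)
    else rule_context(turning = phase_ctx)
  report$findings <- evaluate_rules(ctx, thresholds, rulebase)
  class(report) <- "session_report"
  report
}

#' Write a session report as JSON and a plain-text summary
#'
#' @param report a `session_report`.
#' @param path output JSON path; a `.txt` summary is written alongside.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$imu$summary <- if (!is.null(out$imu$summary)) unclass(out$imu$summary)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  txt <- c(sprintf("Phase: %s", report$phase),
           sprintf("Total phase time: %s s",
                   fmt_or_na(report$timing$total)),
           sprintf("Discs placed: %s", fmt_or_na(report$timing$placed)),
           sprintf("Total hold time: %s s",
                   fmt_or_na(report$emg$total_hold_time)),
           sprintf("Inactivity: %s s", fmt_or_na(report$imu$inactivity)),
           "Findings:",
           if (is.null(report$findings) || nrow(report$findings) == 0L) "  (none)"
           else paste0("  - ", report$findings$text))
  writeLines(txt, sub("\\.json$", ".txt", path))
  invisible(path)
}

fmt_or_na <- function(x) if (is.null(x)) "NA" else format(round(x, 3))

#' Recompute the packaged reference-table aggregates and compare
#'
#' Recomputes the hold-time agreement summary (from the classifier and
#' test-rig columns of the packaged comparison table) and the footer
#' means of the hold-time, angular-velocity and acceleration tables, and
#' compares each against its published footer value.
#'
#' @return data.frame with columns `check`, `expected`, `actual`, `pass`.
#' @export
validate_tables <- function() {
  t1 <- load_fixture("table1")
  t4 <- load_fixture("table4")
  t5 <- load_fixture("table5")
  t6 <- load_fixture("table6")
  acc <- accuracy_summary(t1$hold_time_classifier_s, t1$hold_time_test_setup_s)
  m <- function(v) column_stats(v)$mean
  checks <- data.frame(
    check = c("holdtime_accuracy_mean", "holdtime_accuracy_min",
              "holdtime_accuracy_max",
              "placing_total_mean", "placing_hold_mean", "placing_hold_pct_mean",
              "turning_hold_mean", "turning_hold_pct_mean",
              "roll_placing_mean", "acc_x_placing_mean"),
    expected = c(96.2, 92.9, 99.5, 61.7, 27.5, 44.6, 29.1, 43.4, 128.6, 2.1),
    actual = c(acc$mean, acc$min, acc$max,
               m(t4$placing_total_s), m(t4$placing_hold_s),
               m(t4$placing_hold_pct), m(t4$turning_hold_s),
               m(t4$turning_hold_pct),
               m(t5$roll_placing_dps), m(t6$x_placing_ms2))
  )
  checks$pass <- checks$expected == checks$actual
  checks
}
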