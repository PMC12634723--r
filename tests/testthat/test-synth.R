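test_that("schedules are valid and deterministic under a seed", {
  for (sd in 1:5) {
    s <- make_session_schedule("placing", n_discs = 60, seed = sd)
    expect_true(all(diff(s$events$t) > 0))
    hw <- s$hold_windows
    expect_true(all(hw$end > hw$start))
    expect_true(all(hw$start[-1] >= hw$end[-nrow(hw)] - 1e-9))
  }
  a <- make_session_schedule("turning", seed = 3)
  b <- make_session_schedule("turning", seed = 3)
  expect_identical(a$events, b$events)
  expect_identical(a$bursts, b$bursts)
  expect_error(make_session_schedule("placing", lighting = "disco"), "lighting")
})

test_that("hole-patch and full-image renderers classify identically", {
  layout <- board_layout()
  sched <- make_session_schedule("placing", n_discs = 60, seed = 2)
  for (t in c(0, 15, 40, sched$duration)) {
    fh <- render_frame(sched, layout, t, "holes", noise = 0)
    ff <- render_frame(sched, layout, t, "full", noise = 0)
    expect_identical(observe_board(fh, layout), observe_board(ff, layout))
  }
  # pixel noise of +/- 3 counts never flips a class under normal light
  fh2 <- render_frame(sched, layout, 40, "holes", noise = 3)
  expect_identical(observe_board(fh2, layout),
                   observe_board(render_frame(sched, layout, 40, "holes",
                                              noise = 0), layout))
})

test_that("lighting perturbations affect only the perturbed holes", {
  layout <- board_layout()
  sh <- make_session_schedule("placing", n_discs = 60, seed = 4,
                              lighting = "shadow", perturbed_holes = 42L)
  obs <- observe_board(render_frame(sh, layout, sh$duration, "holes"), layout)
  expect_true(obs[42] %in% c("black", "unknown"))  # occupied hole under shadow
  expect_equal(obs[-42], rep("red", 59))

  fl <- make_session_schedule("turning", n_discs = 60, seed = 4,
                              lighting = "flash", perturbed_holes = c(15L, 30L))
  obs2 <- observe_board(render_frame(fl, layout, fl$duration, "holes"), layout)
  expect_true(all(obs2[c(15, 30)] == "white"))
  expect_equal(obs2[-c(15, 30)], rep("black", 58))

  # dim: discs remain classifiable, the white board floor becomes unknown
  dm <- make_session_schedule("placing", n_discs = 10, seed = 4, lighting = "dim")
  obs3 <- observe_board(render_frame(dm, layout, dm$duration, "holes"), layout)
  expect_equal(obs3[1:10], rep("red", 10))
  expect_equal(obs3[11:60], rep("unknown", 50))
})

test_that("synthetic EMG realizes the scheduled activation profile", {
  cal <- test_cal()
  quiet <- structure(list(duration = 5, seed = 2,
                          hold_windows = data.frame(start = numeric(0),
                                                    end = numeric(0))),
                     class = "session_schedule")
  rec <- gen_emg(quiet, cal)
  env <- emg_envelope(rec)
  mcl <- apply(env, 1, muscle_contraction_level, cal = cal)
  expect_true(all(mcl[-(1:100)] < 0.05))  # after filter warm-up

  one <- structure(list(duration = 6, seed = 3,
                        hold_windows = data.frame(start = 2, end = 4)),
                   class = "session_schedule")
  rec2 <- gen_emg(one, cal)
  env2 <- emg_envelope(rec2)
  mid <- env2[(2.5 * 200):(3.5 * 200), ]
  mcl_mid <- mean(apply(mid, 1, muscle_contraction_level, cal = cal))
  expect_gt(mcl_mid, 0.3)
  # channels 4 and 5 dominate during the hold
  expect_true(all(rank(-colMeans(mid))[4:5] <= 2))

  expect_identical(gen_emg(one, cal)$samples, gen_emg(one, cal)$samples)
})

test_that("synthetic IMU realizes bursts, quiet intervals and range checks", {
  sched <- make_session_schedule("placing", n_discs = 10, seed = 5)
  tr <- gen_imu(sched)
  expect_equal(inactivity_time(tr),
               sum(sched$quiet$end - sched$quiet$start),
               tolerance = 1 / 50 + 1e-9)

  # with baseline motion and bursts removed the whole trace is quiet
  sched0 <- sched
  sched0$bursts <- sched$bursts[0, ]
  expect_equal(inactivity_time(gen_imu(sched0, base_gyro = 0)),
               sched0$duration, tolerance = 0.1)

  bad <- sched
  bad$bursts$acc_amp[1] <- 20 * 9.81
  expect_error(gen_imu(bad), "sensor range")

  expect_identical(gen_imu(sched)$gyro, gen_imu(sched)$gyro)
})

test_that("frame sequences round-trip through PNG files", {
  layout <- board_layout()
  sched <- make_session_schedule("placing", n_discs = 2, seed = 6,
                                 gap_mean = 0.6)
  fr <- gen_board_frames(sched, layout, mode = "full")
  d <- withr::local_tempdir()
  write_frames_png(fr$frames, fr$times, d)
  back <- read_frames_png(d)
  expect_equal(length(back$frames), length(fr$frames))
  expect_equal(back$times, fr$times)
  expect_identical(observe_board(back$frames[[5]], layout),
                   observe_board(fr$frames[[5]], layout))

  # a corrupt frame is skipped with a warning and analysis continues
  writeLines("not a png", file.path(d, utils::read.csv(
    file.path(d, "manifest.csv"))$filename[1]))
  expect_warning(back2 <- read_frames_png(d), "skipping unreadable")
  expect_equal(length(back2$frames), length(fr$frames) - 1)
})
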