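test_that("RGB to HSV uses the half-degree scale and matches base R", {
  expect_equal(unname(rgb_to_hsv(c(255, 0, 0))), c(0, 255, 255))
  expect_equal(unname(rgb_to_hsv(c(255, 255, 255))), c(0, 0, 255))
  expect_equal(unname(rgb_to_hsv(c(0, 0, 0))), c(0, 0, 0))
  expect_error(rgb_to_hsv(c(300, 0, 0)), "\\[0, 255\\]")

  set.seed(17)
  px <- matrix(sample(0:255, 3000, replace = TRUE), ncol = 3)
  ours <- rgb_to_hsv(px)
  ref <- t(grDevices::rgb2hsv(t(px), maxColorValue = 255)) *
    rep(c(180, 255, 255), each = nrow(px))
  expect_lt(max(abs(ours - ref)), 1)  # within one count of the reference
})

test_that("hole color classification follows the threshold ranges", {
  expect_equal(classify_hole_color(c(5, 200, 200)), "red")
  expect_equal(classify_hole_color(c(90, 10, 240)), "white")
  expect_equal(classify_hole_color(c(50, 128, 15)), "black")
  expect_equal(classify_hole_color(c(50, 60, 150)), "unknown")
  # overlap at low V: darkness dominates (precedence black > red)
  expect_equal(classify_hole_color(c(5, 200, 20)), "black")
  # wrap-around red hue
  expect_equal(classify_hole_color(c(175, 200, 120)), "red")
})

test_that("board observation takes a majority vote per hole", {
  layout <- board_layout()
  empty <- make_session_schedule("placing", n_discs = 15, seed = 1)
  f0 <- render_frame(empty, layout, t = 0, mode = "full", noise = 0)
  expect_equal(observe_board(f0, layout), rep("white", 60))

  f1 <- render_frame(empty, layout, t = 100, mode = "full", noise = 0)
  obs <- observe_board(f1, layout)
  expect_equal(obs[1:15], rep("red", 15))
  expect_equal(obs[16:60], rep("white", 45))

  gray <- array(128, dim = c(480, 640, 3))
  expect_equal(observe_board(gray, layout), rep("unknown", 60))
})

test_that("state machine commits debounced transitions with correct kinds", {
  layout <- board_layout()
  st <- board_state_new(layout, "placing", debounce = 2)
  obs <- rep("white", 60); obs[5] <- "red"
  r1 <- advance_state(st, obs, 1.0)
  expect_equal(nrow(r1$events), 0)          # one frame is not enough
  r2 <- advance_state(r1$state, obs, 1.1)
  expect_equal(r2$events$kind, "placed_correct")
  expect_equal(r2$events$t, 1.0)            # stamped with the first frame
  expect_equal(r2$events$hole_id, 5L)
  expect_equal(r2$state$placed, 1L)
  expect_equal(r2$state$empty, 59L)

  # upside-down disc in placing
  st2 <- board_state_new(layout, "placing", debounce = 1)
  obs2 <- rep("white", 60); obs2[7] <- "black"
  expect_equal(advance_state(st2, obs2, 2)$events$kind, "placed_upside_down")

  # turning-phase semantics
  st3 <- board_state_new(layout, "turning", debounce = 1)
  obs3 <- rep("red", 60); obs3[1] <- "black"; obs3[2] <- "white"
  ev <- advance_state(st3, obs3, 3)$events
  expect_setequal(ev$kind, c("turned_correct", "removed_incorrect"))

  # identical observation: no events; unknown leaves holes unchanged
  st4 <- board_state_new(layout, "placing")
  expect_equal(nrow(advance_state(st4, st4$colors, 0)$events), 0)
  expect_equal(nrow(advance_state(st4, rep("unknown", 60), 0)$events), 0)
})

test_that("placed + empty = 60 after every state advance", {
  layout <- board_layout()
  sched <- make_session_schedule("placing", n_discs = 60, seed = 13,
                                 gap_mean = 0.6, gap_sd = 0.05)
  st <- board_state_new(layout, "placing")
  for (t in seq(0, sched$duration, by = 0.5)) {
    obs <- observe_board(render_frame(sched, layout, t, "holes"), layout)
    st <- advance_state(st, obs, t)$state
    expect_equal(st$placed + st$empty, 60L)
  }
  expect_equal(st$placed, 60L)
})

test_that("disc timings partition the phase duration", {
  ev <- data.frame(t = c(2.0, 3.2))
  tm <- disc_timings(ev, phase_start = 0.9)
  expect_equal(tm$durations, c(1.1, 1.2))
  expect_equal(tm$total, 2.3)
  expect_equal(sum(tm$durations), tm$total)
  expect_equal(disc_timings(data.frame(t = numeric(0)))$total, 0)
  expect_error(disc_timings(data.frame(t = c(3, 2))), "time-ordered")
})

test_that("layout and event-log files round-trip", {
  layout <- board_layout()
  p <- withr::local_tempfile(fileext = ".json")
  write_layout_json(layout, p)
  back <- read_layout_json(p)
  expect_equal(back$holes, layout$holes)
  expect_equal(back$image_size, layout$image_size)

  ev <- data.frame(t = c(1, 2), hole_id = c(3L, 4L),
                   kind = c("placed_correct", "placed_correct"),
                   phase = c("placing", "placing"))
  pe <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(ev, pe)
  expect_equal(read_events_csv(pe), ev)
})
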