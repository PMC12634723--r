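#' Board layout: hole centres on the camera image
#'
#' The dexterity board has 60 holes, by default a 4 x 15 grid imaged at
#' 640 x 480 px. Centres are pixel coordinates (0-based, x rightward,
#' y downward, pixel-centre convention). Colors are sampled over a disc of
#' `sample_radius` px around each centre.
#'
#' @param image_size `c(width, height)` in px.
#' @param rows,cols grid shape; `rows * cols` must be 60 unless `n_holes`
#'   is changed.
#' @param sample_radius sampling radius in px.
#' @return a `board_layout` object with a `holes` data.frame
#'   (`id, row, col, x, y`).
#' @export
board_layout <- function(image_size = c(640L, 480L), rows = 4L, cols = 15L,
                         sample_radius = 5L) {
  w <- image_size[1]; h <- image_size[2]
  grid <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  holes <- data.frame(
    id = seq_len(rows * cols),
    row = grid$row, col = grid$col,
    x = round((grid$col - 0.5) * w / cols),
    y = round((grid$row - 0.5) * h / rows)
  )
  if (any(holes$x < 0 | holes$x >= w | holes$y < 0 | holes$y >= h))
    stop("hole centres outside image bounds")
  if (anyDuplicated(holes[, c("x", "y")])) stop("duplicate hole centres")
  structure(list(image_size = c(w, h), sample_radius = sample_radius,
                 holes = holes),
            class = "board_layout")
}

#' Write / read a board layout as JSON
#' @param layout a `board_layout`.
#' @param path file path.
#' @export
write_layout_json <- function(layout, path) {
  jsonlite::write_json(
    list(image_size = layout$image_size, sample_radius = layout$sample_radius,
         holes = layout$holes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout_json
#' @export
read_layout_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(image_size = as.integer(doc$image_size),
                 sample_radius = doc$sample_radius,
                 holes = as.data.frame(doc$holes)),
            class = "board_layout")
}

#' RGB to HSV on the half-degree scale
#'
#' Standard piecewise hue formula with outputs matched to the thresholding
#' convention: H in \[0, 180\] (degrees / 2), S and V in \[0, 255\].
#' Achromatic pixels (max = min) have hue 0; V = max(R,G,B);
#' S = 255 (V - min) / V, 0 when V = 0.
#'
#' @param rgb numeric vector `c(r, g, b)` in \[0, 255\], or an n x 3 matrix.
#' @return vector `c(h, s, v)`, or an n x 3 matrix for matrix input.
#' @export
rgb_to_hsv <- function(rgb) {
  m <- if (is.matrix(rgb)) rgb else matrix(rgb, ncol = 3)
  if (any(m < 0 | m > 255)) stop("RGB channels must be in [0, 255]")
  r <- m[, 1]; g <- m[, 2]; b <- m[, 3]
  v <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  delta <- v - mn
  s <- ifelse(v == 0, 0, 255 * delta / v)
  h <- numeric(length(r))
  chrom <- delta > 0
  hr <- chrom & v == r
  hg <- chrom & !hr & v == g
  hb <- chrom & !hr & !hg
  h[hr] <- 60 * ((g[hr] - b[hr]) / delta[hr])
  h[hg] <- 60 * (2 + (b[hg] - r[hg]) / delta[hg])
  h[hb] <- 60 * (4 + (r[hb] - g[hb]) / delta[hb])
  h <- ifelse(h < 0, h + 360, h) / 2
  out <- cbind(h = h, s = s, v = v)
  if (is.matrix(rgb)) out else drop(out)
}

#' Default HSV thresholds for disc colors
#'
#' Half-degree-scale ranges separating the white board surface from the red
#' and black disc faces. The black and red ranges overlap at low V; the
#' classifier resolves this with precedence black > red > white (darkness
#' dominates).
#'
#' @return nested list of `c(lo, hi)` ranges per channel per color.
#' @export
default_color_thresholds <- function() {
  list(
    white = list(h = c(0, 180), s = c(0, 30), v = c(220, 255)),
    red = list(h = list(c(0, 10), c(160, 180)), s = c(100, 255), v = c(30, 255)),
    black = list(h = c(0, 180), s = c(0, 255), v = c(0, 30))
  )
}

in_range <- function(x, rng) {
  if (is.list(rng)) {
    hit <- rep(FALSE, length(x))
    for (r in rng) hit <- hit | (x >= r[1] & x <= r[2])
    hit
  } else x >= rng[1] & x <= rng[2]
}

#' Classify HSV pixels into disc color classes
#'
#' Membership test against the thresholds in precedence order
#' black, red, white; `unknown` when no range matches.
#'
#' @param hsv vector `c(h, s, v)` or n x 3 matrix on the 0-180/0-255 scale.
#' @param thresholds see [default_color_thresholds()].
#' @return character class(es) in `{white, red, black, unknown}`.
#' @export
classify_hole_color <- function(hsv, thresholds = default_color_thresholds()) {
  m <- if (is.matrix(hsv)) hsv else matrix(hsv, ncol = 3)
  out <- rep("unknown", nrow(m))
  for (cls in c("black", "red", "white")) {
    th <- thresholds[[cls]]
    hit <- out == "unknown" &
      in_range(m[, 1], th$h) & in_range(m[, 2], th$s) & in_range(m[, 3], th$v)
    out[hit] <- cls
  }
  if (is.matrix(hsv)) out else out[1]
}

# 0-based (dx, dy) offsets of the sampling disc
sample_offsets <- function(radius) {
  d <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  d[d$dx^2 + d$dy^2 <= radius^2, ]
}

#' Observe per-hole disc colors in one frame
#'
#' For each hole, every pixel within `sample_radius` of the centre is
#' classified and the majority class wins; ties give `unknown`. The frame
#' may be a full image array (`height x width x 3`, values 0-255) or a
#' `hole_patches` object produced by the synthetic renderer, which stores
#' only the sampled neighbourhoods.
#'
#' @param frame image array or `hole_patches` object.
#' @param layout a [board_layout()].
#' @param thresholds color thresholds.
#' @return character vector of 60 color classes in hole-id order.
#' @export
observe_board <- function(frame, layout, thresholds = default_color_thresholds()) {
  r <- layout$sample_radius
  off <- sample_offsets(r)
  npx <- nrow(off)
  if (inherits(frame, "hole_patches")) {
    side <- frame$side
    rr <- frame$radius
    if (rr < r) stop("patch radius smaller than layout sample radius")
    # linear indices of the sampling disc inside a (side x side) patch
    mask <- (off$dx + rr) * side + off$dy + rr + 1L
    pix <- matrix(frame$pix[mask, , ], ncol = 3L)
    n_holes <- dim(frame$pix)[2]
  } else {
    h <- dim(frame)[1]; w <- dim(frame)[2]
    if (w != layout$image_size[1] || h != layout$image_size[2])
      stop("frame size does not match layout")
    holes <- layout$holes
    if (any(holes$x - r < 0 | holes$x + r >= w | holes$y - r < 0 | holes$y + r >= h))
      stop("sampling disc outside image for some hole")
    rows <- rep(holes$y + 1L, each = npx) + off$dy        # 0-based -> 1-based
    cols <- rep(holes$x + 1L, each = npx) + off$dx
    pix <- cbind(frame[cbind(rows, cols, 1L)],
                 frame[cbind(rows, cols, 2L)],
                 frame[cbind(rows, cols, 3L)])
    n_holes <- nrow(holes)
  }
  classes <- c("white", "red", "black", "unknown")
  code <- match(classify_hole_color(rgb_to_hsv(pix), thresholds), classes)
  hole_of <- rep(seq_len(n_holes), each = npx)
  counts <- matrix(tabulate((hole_of - 1L) * 4L + code, nbins = n_holes * 4L),
                   ncol = 4L, byrow = TRUE)
  top <- pmax(counts[, 1], counts[, 2], counts[, 3], counts[, 4])
  winner <- classes[max.col(counts, ties.method = "first")]
  tie <- rowSums(counts == top) > 1L
  winner[tie] <- "unknown"
  winner
}

#' Initialize the board state machine
#'
#' In the placing phase holes start empty (white); in the turning phase all
#' 60 discs start placed red-side up. `placed + empty = 60` holds at all
#' times.
#'
#' @param layout a [board_layout()].
#' @param phase `"placing"` or `"turning"`.
#' @param debounce consecutive frames a transition must persist before its
#'   event is committed.
#' @return a `board_state` object.
#' @export
board_state_new <- function(layout, phase = c("placing", "turning"), debounce = 2L) {
  phase <- match.arg(phase)
  n <- nrow(layout$holes)
  colors <- rep(if (phase == "placing") "white" else "red", n)
  structure(
    list(phase = phase, colors = colors,
         pend_color = rep(NA_character_, n), pend_count = integer(n),
         pend_t = rep(NA_real_, n),
         debounce = as.integer(debounce),
         events = empty_events(),
         placed = sum(colors != "white"), empty = sum(colors == "white")),
    class = "board_state"
  )
}

empty_events <- function() {
  data.frame(t = numeric(0), hole_id = integer(0),
             kind = character(0), phase = character(0))
}

# event kind for a committed transition, or NA for silent transitions
event_kind <- function(phase, from, to) {
  if (phase == "placing") {
    if (from == "white" && to == "red") return("placed_correct")
    if (from == "white" && to == "black") return("placed_upside_down")
  } else {
    if (from == "red" && to == "black") return("turned_correct")
    if (from == "red" && to == "white") return("removed_incorrect")
  }
  NA_character_
}

#' Advance the board state machine with one observation
#'
#' A hole's color change must persist for `debounce` consecutive frames
#' before it is committed; the committed event is stamped with the time of
#' the first frame of the transition. `unknown` observations leave the hole
#' unchanged (fail-safe under shadows and flash) and interrupt any pending
#' transition.
#'
#' @param state a `board_state`.
#' @param observation character vector of per-hole color classes.
#' @param timestamp frame time in seconds.
#' @return list `(state, events)` where `events` holds the rows committed
#'   by this call.
#' @export
advance_state <- function(state, observation, timestamp) {
  n <- length(state$colors)
  if (length(observation) != n) stop("observation length mismatch")
  changed <- which(observation != state$colors & observation != "unknown")
  stable <- setdiff(which(state$pend_count > 0L), changed)
  if (length(stable)) {
    state$pend_color[stable] <- NA_character_
    state$pend_count[stable] <- 0L
  }
  new_events <- empty_events()
  for (i in changed) {
    obs <- observation[i]
    if (!is.na(state$pend_color[i]) && state$pend_color[i] == obs) {
      state$pend_count[i] <- state$pend_count[i] + 1L
    } else {
      state$pend_color[i] <- obs
      state$pend_count[i] <- 1L
      state$pend_t[i] <- timestamp
    }
    if (state$pend_count[i] >= state$debounce) {
      kind <- event_kind(state$phase, state$colors[i], obs)
      if (!is.na(kind)) {
        new_events <- rbind(new_events, data.frame(
          t = state$pend_t[i], hole_id = i, kind = kind, phase = state$phase))
      }
      state$colors[i] <- obs
      state$pend_color[i] <- NA_character_
      state$pend_count[i] <- 0L
    }
  }
  if (nrow(new_events)) {
    state$events <- rbind(state$events, new_events)
    state$placed <- sum(state$colors != "white")
    state$empty <- sum(state$colors == "white")
  }
  list(state = state, events = new_events)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-disc durations from an ordered event log
#'
#' Disc k's duration is the gap to the previous event (the first relative to
#' `phase_start`); the total phase time is the last event time minus
#' `phase_start`. The per-disc durations sum to the total exactly.
#'
#' @param events data.frame with a time-ordered `t` column.
#' @param phase_start phase start time in seconds.
#' @return list `durations` (numeric) and `total` (scalar seconds).
#' @export
disc_timings <- function(events, phase_start = 0) {
  if (nrow(events) == 0L) return(list(durations = numeric(0), total = 0))
  if (is.unsorted(events$t)) stop("events must be time-ordered")
  d <- diff(c(phase_start, events$t))
  if (any(d < 0)) stop("event before phase start")
  list(durations = d, total = events$t[nrow(events)] - phase_start)
}

#' Write / read a disc event log as CSV (`t,hole_id,kind,phase`)
#' @param events event data.frame.
#' @param path file path.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) utils::read.csv(path)

#' Run the state machine over a frame sequence
#'
#' @param frames list of frames (arrays or `hole_patches`).
#' @param times numeric frame timestamps in seconds.
#' @param layout a [board_layout()].
#' @param phase `"placing"` or `"turning"`.
#' @param thresholds color thresholds.
#' @param debounce see [board_state_new()].
#' @return final `board_state` (with accumulated `events`).
#' @export
track_board <- function(frames, times, layout, phase = "placing",
                        thresholds = default_color_thresholds(), debounce = 2L) {
  state <- board_state_new(layout, phase, debounce)
  for (i in seq_along(frames)) {
    obs <- observe_board(frames[[i]], layout, thresholds)
    state <- advance_state(state, obs, times[i])$state
  }
  state
}
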