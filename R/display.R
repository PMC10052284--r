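# The ecological head-up display: future-touchdown-velocity frames.

#' Colour ramp of the display
#'
#' Linear green-to-red ramp over the safe range of the normalised
#' touchdown velocity: pure green `(0, 255, 0)` at `pi = 0`, red
#' `(255, 0, 0)` at `pi = 1`, with `red = floor(255 * pi)` and
#' `green = 255 - red` in between. Values above 1 (unsafe) carry no colour.
#'
#' @param p Numeric vector of pi values.
#' @return An integer matrix with columns `r`, `g`, `b`; rows are NA where
#'   `p > 1` or not finite.
#' @export
ramp_color <- function(p) {
  r <- ifelse(is.finite(p) & p <= 1, as.integer(floor(255 * pmin(pmax(p, 0), 1))),
              NA_integer_)
  cbind(r = r, g = 255L - r, b = ifelse(is.na(r), NA_integer_, 0L))
}

#' Compute one display frame
#'
#' A frame of the augmentation at observation time `t_now`: the future
#' (and recent past) touchdown-velocity curve in units of `V_crt`, its
#' green-to-red colouring where safe, the unsafe (black-hatched) mask, and
#' the end-of-trial boundary (the no-response contact time). The curve
#' value at `t_now` is the `V_td/V_crt` that would result from triggering
#' the attempt lift immediately.
#'
#' @param slice A [pi_timeline()].
#' @param t_now Current time (s from descent onset), within the trial.
#' @param past_span_s Seconds of past curve kept visible.
#' @return A list of class `display_frame`: `t_now`, `axis_times`,
#'   `normalized_curve`, `color_per_point` (rgb matrix, NA above the
#'   critical line), `unsafe_mask`, `end_of_trial_time`, `current_pi`.
#' @examples
#' sl <- pi_timeline(9, 0, "LL", dt = 0.05)
#' fr <- compute_frame(sl, t_now = 8)
#' fr$current_pi
#' @export
compute_frame <- function(slice, t_now, past_span_s = 5) {
  stopifnot(inherits(slice, "pi_timeline"))
  t_end <- attr(slice, "t_end")
  if (t_now > t_end + 1e-9) stop("t_now is beyond the end of the trial")
  if (t_now < min(slice$time) - 1e-9) stop("t_now is before the slice span")
  keep <- slice$time >= t_now - past_span_s
  times <- slice$time[keep]
  curve <- slice$pi[keep]
  i <- which.min(abs(times - t_now))
  structure(list(
    t_now = t_now,
    axis_times = times,
    normalized_curve = curve,
    color_per_point = ramp_color(curve),
    unsafe_mask = !is.finite(curve) | curve > 1,
    end_of_trial_time = t_end,
    current_pi = curve[i]
  ), class = "display_frame")
}

#' Animate the display over a trial
#'
#' Successive frames advance `t_now` from the start of the slice to the
#' end-of-trial boundary; the gap between the boundary (the left edge of
#' the black area) and the current-time marker closes monotonically, the
#' display-space image of the helicopter closing on the deck.
#'
#' @param slice A [pi_timeline()].
#' @param frame_rate Frames per second.
#' @param past_span_s Seconds of past curve kept visible.
#' @return A list of `display_frame`s; the final frame has
#'   `t_now == end_of_trial_time`.
#' @export
animate <- function(slice, frame_rate = 10, past_span_s = 5) {
  stopifnot(frame_rate > 0)
  t_end <- attr(slice, "t_end")
  t0 <- min(slice$time)
  ts <- unique(c(seq(t0, t_end, by = 1 / frame_rate), t_end))
  lapply(ts, function(t) compute_frame(slice, t, past_span_s = past_span_s))
}

#' Rasterise a display frame to PNG
#'
#' Deterministic pixel rendering of a frame: columns are axis times, the
#' area under the curve is filled with the green-to-red ramp, unsafe
#' columns are hatched dark gray above the critical line, the critical
#' line is black, the current-time marker is a dotted white-on-dark
#' column, and everything past the end of trial is black.
#'
#' @param frame A [compute_frame()] result.
#' @param path Output PNG path.
#' @param height Pixel rows of the raster.
#' @param pi_max Top of the vertical axis in pi units.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(frame, path, height = 120, pi_max = 2) {
  stopifnot(inherits(frame, "display_frame"))
  w <- length(frame$axis_times)
  img <- array(1, dim = c(height, w, 3)) # white background
  rowof <- function(p) {
    # pi = 0 at the bottom row, pi_max at the top
    pmin(height, pmax(1, height - round(p / pi_max * (height - 1))))
  }
  crit_row <- rowof(1)
  for (j in seq_len(w)) {
    p <- frame$normalized_curve[j]
    if (frame$unsafe_mask[j]) {
      # hatched black area above the critical line
      rows <- seq_len(crit_row)
      shade <- ifelse((rows + j) %% 4 < 2, 0.15, 0.45)
      img[rows, j, ] <- shade
    } else {
      col <- frame$color_per_point[j, ] / 255
      rows <- seq(rowof(p), height)
      img[rows, j, 1] <- col[1]
      img[rows, j, 2] <- col[2]
      img[rows, j, 3] <- col[3]
    }
  }
  img[crit_row, , ] <- 0 # critical velocity line
  j_now <- which.min(abs(frame$axis_times - frame$t_now))
  img[seq(1, height, by = 3), j_now, ] <- 0 # dotted current-time marker
  past_end <- frame$axis_times > frame$end_of_trial_time + 1e-9
  if (any(past_end)) img[, past_end, ] <- 0
  png::writePNG(img, path)
  invisible(path)
}

#' Serialise a display frame to JSON
#'
#' @param frame A [compute_frame()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_frame_json <- function(frame, path) {
  stopifnot(inherits(frame, "display_frame"))
  obj <- list(
    t_now = frame$t_now,
    end_of_trial_time = frame$end_of_trial_time,
    current_pi = frame$current_pi,
    axis_times = frame$axis_times,
    normalized_curve = frame$normalized_curve,
    unsafe_mask = frame$unsafe_mask,
    color_per_point = frame$color_per_point
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
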