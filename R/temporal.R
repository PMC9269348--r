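#' Frame observation series
#'
#' Container for an ordered stream of per-frame observations at a fixed
#' frame interval, the input to the temporal feature extractors.
#'
#' @param obs Data frame with columns `frame_index` (strictly increasing
#'   integers), `eye_closed`, `mouth_open` (logical), and optionally
#'   `timestamp`, `ear`, `mar`, `valid`.
#' @param t0 Frame interval in seconds (> 0), i.e. `1 / fps`.
#' @return An object of class `"frame_series"`: list with `obs` and `t0`.
#' @export
frame_series <- function(obs, t0) {
  stopifnot(is.data.frame(obs), nrow(obs) > 0,
            is.numeric(t0), length(t0) == 1L, is.finite(t0), t0 > 0)
  need <- c("frame_index", "eye_closed", "mouth_open")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop("observation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(diff(obs$frame_index) <= 0))
    stop("frame indices must be strictly increasing", call. = FALSE)
  if (!"valid" %in% names(obs)) obs$valid <- TRUE
  # invalid frames carry the last valid eye/mouth state forward
  if (any(!obs$valid)) {
    obs$eye_closed <- locf(obs$eye_closed, obs$valid, default = FALSE)
    obs$mouth_open <- locf(obs$mouth_open, obs$valid, default = FALSE)
  }
  structure(list(obs = obs, t0 = t0), class = "frame_series")
}

# last-observation-carried-forward over frames flagged invalid
locf <- function(x, valid, default) {
  idx <- ifelse(valid, seq_along(x), NA_integer_)
  idx <- cummax(ifelse(is.na(idx), 0L, idx))
  out <- ifelse(idx > 0L, x[pmax(idx, 1L)], default)
  out
}

subset_series <- function(series, i) {
  structure(list(obs = series$obs[i, , drop = FALSE], t0 = series$t0),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("frame_series: %d frames at %.4g s/frame (%.1f s)\n",
              nrow(x$obs), x$t0, nrow(x$obs) * x$t0))
  invisible(x)
}

# lengths of maximal TRUE runs in a logical vector
run_lengths_true <- function(flag) {
  r <- rle(as.logical(flag))
  r$lengths[r$values]
}

#' Longest continuous eye closure in a window
#'
#' Duration of the longest maximal run of closed-eye frames,
#' `(run length) * t0` seconds; 0 if no frame is closed. Runs truncated by
#' the window edge count with their in-window duration.
#'
#' @param series A [frame_series()].
#' @return Duration in seconds.
#' @export
longest_closure <- function(series) {
  stopifnot(inherits(series, "frame_series"))
  runs <- run_lengths_true(series$obs$eye_closed)
  if (length(runs) == 0L) 0 else max(runs) * series$t0
}

#' Number of yawns in a window
#'
#' A yawn is a maximal mouth-open run lasting at least `min_yawn_seconds`;
#' shorter opens (speech, laughter) are excluded by the duration cut-off.
#'
#' @param series A [frame_series()].
#' @param min_yawn_seconds Positive duration cut-off in seconds (default 4).
#' @return Integer yawn count.
#' @export
count_yawns <- function(series, min_yawn_seconds = 4) {
  stopifnot(inherits(series, "frame_series"),
            is.numeric(min_yawn_seconds), min_yawn_seconds > 0)
  runs <- run_lengths_true(series$obs$mouth_open)
  sum(runs * series$t0 >= min_yawn_seconds)
}

#' Frame-ratio PERCLOS
#'
#' Fraction of frames in the window with eyes closed — the frame-count form
#' of the percentage of eyelid closure over time.
#'
#' @param series A [frame_series()].
#' @return Fraction in `[0, 1]`.
#' @export
perclos_frames <- function(series) {
  stopifnot(inherits(series, "frame_series"))
  mean(series$obs$eye_closed)
}

#' P80 PERCLOS from a continuous closure-percentage signal
#'
#' The droop-based PERCLOS definition: within each close--open cycle, with
#' `t1` the upward 20%-closure crossing, `t2` the upward 80% crossing, `t3`
#' the downward 80% crossing, and `t4` the downward 20% crossing, the cycle's
#' PERCLOS is `(t3 - t2) / (t4 - t1)` — the fraction of the droop spent at
#' least 80% closed. Crossing times are located by linear interpolation
#' between samples; the result is averaged over complete cycles.
#'
#' @param closure Numeric vector of eyelid-closure percentages in `[0, 100]`.
#' @param timestamps Increasing numeric vector of sample times (seconds).
#' @return Mean cycle PERCLOS, a fraction in `[0, 1]`.
#' @export
perclos_p80 <- function(closure, timestamps) {
  stopifnot(length(closure) == length(timestamps), length(closure) >= 2,
            all(diff(timestamps) > 0))
  up20 <- crossing_times(closure, timestamps, 20, "up")
  up80 <- crossing_times(closure, timestamps, 80, "up")
  dn80 <- crossing_times(closure, timestamps, 80, "down")
  dn20 <- crossing_times(closure, timestamps, 20, "down")
  vals <- numeric(0)
  # pair each upward 20% crossing with the next 80% up, 80% down, 20% down
  for (t1 in up20) {
    t2 <- up80[up80 > t1][1]
    if (is.na(t2)) next
    t3 <- dn80[dn80 > t2][1]
    if (is.na(t3)) next
    t4 <- dn20[dn20 > t3][1]
    if (is.na(t4)) next
    vals <- c(vals, (t3 - t2) / (t4 - t1))
  }
  if (length(vals) == 0L)
    stop("no complete close-open cycle crossing 20% and 80% closure",
         call. = FALSE)
  mean(vals)
}

# linearly interpolated times at which the signal crosses 'level'
# in the given direction
crossing_times <- function(y, t, level, direction = c("up", "down")) {
  direction <- match.arg(direction)
  d <- y - level
  i <- seq_len(length(y) - 1L)
  hit <- if (direction == "up") d[i] < 0 & d[i + 1L] >= 0 else
    d[i] > 0 & d[i + 1L] <= 0
  i <- i[hit]
  t[i] + (level - y[i]) * (t[i + 1L] - t[i]) / (y[i + 1L] - y[i])
}

#' Window fatigue features
#'
#' Assembles the three per-window fatigue indicators used by the classifier:
#' longest continuous eye closure (seconds), yawn count, and frame-ratio
#' PERCLOS. A window with more than 50% invalid frames is flagged unusable.
#'
#' @inheritParams count_yawns
#' @return An object of class `"window_features"`: one-row data frame with
#'   columns `longest_closure`, `yawn_count`, `perclos`, `usable`.
#' @export
window_features <- function(series, min_yawn_seconds = 4) {
  stopifnot(inherits(series, "frame_series"))
  out <- data.frame(
    longest_closure = longest_closure(series),
    yawn_count = count_yawns(series, min_yawn_seconds),
    perclos = perclos_frames(series),
    usable = mean(series$obs$valid) >= 0.5
  )
  class(out) <- c("window_features", class(out))
  out
}

#' Per-window feature table for a whole stream
#'
#' Cuts the series into consecutive non-overlapping windows of
#' `window_seconds` (half-open, trailing partial window dropped) and computes
#' [window_features()] for each.
#'
#' @inheritParams run_segmented_detection
#' @return Data frame: `window_id`, `start_s`, `end_s`, `longest_closure`,
#'   `yawn_count`, `perclos`, `usable`.
#' @export
stream_window_features <- function(series, window_seconds = 60,
                                   min_yawn_seconds = 4) {
  stopifnot(inherits(series, "frame_series"))
  fpw <- floor(window_seconds / series$t0)
  n_windows <- nrow(series$obs) %/% fpw
  if (n_windows < 1L) stop("series shorter than one window", call. = FALSE)
  rows <- lapply(seq_len(n_windows), function(w) {
    idx <- ((w - 1L) * fpw + 1L):(w * fpw)
    wf <- window_features(subset_series(series, idx), min_yawn_seconds)
    cbind(data.frame(window_id = w, start_s = (idx[1L] - 1L) * series$t0,
                     end_s = idx[length(idx)] * series$t0), wf)
  })
  out <- do.call(rbind, rows)
  class(out) <- "data.frame"
  out
}
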