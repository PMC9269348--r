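#' Standard logistic function
#'
#' The sigmoid weight used by the time-accumulation model,
#' `1 / (1 + exp(-x))`. Strictly increasing, `logistic(0) = 0.5`,
#' `logistic(1) ~= 0.731`.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length, values in (0, 1).
#' @export
#' @examples
#' logistic(c(0, 1))
logistic <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  stats::plogis(x)
}

check_segments <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n != round(n) || n <= 1)
    stop("number of segments 'n' must be an integer > 1", call. = FALSE)
  as.integer(n)
}

#' Accumulated fatigue value over window segments
#'
#' A detection window is split into `n` contiguous segments, each classified
#' awake (0) or fatigue (1); the accumulated fatigue value is
#' \deqn{a_F = \frac{1}{n}\sum_i [x_i \sigma(x_i) - (1 - x_i)\sigma(x_i)]}
#' with \eqn{\sigma} the logistic function. Awake segments contribute
#' \eqn{-\sigma(0) = -0.5}, fatigue segments \eqn{+\sigma(1) \approx 0.731},
#' so `a_F` depends on `x` only through the fatigue count `k = sum(x)` and is
#' strictly increasing in `k`, bounded in \eqn{[-0.5, \sigma(1)]}.
#'
#' @param x Integer/logical vector of per-segment states (0 = awake,
#'   1 = fatigue), length > 1.
#' @return The scalar accumulated fatigue value.
#' @seealso [cumulative_levels()], [decide_window()]
#' @export
#' @examples
#' fatigue_accumulation(c(1, 0, 0))  # -0.089: one noisy segment is filtered
#' fatigue_accumulation(c(1, 1, 1))  #  0.731
fatigue_accumulation <- function(x) {
  if (is.logical(x)) x <- as.integer(x)
  if (!is.numeric(x) || !all(x %in% c(0, 1)))
    stop("segment states 'x' must be 0/1", call. = FALSE)
  n <- check_segments(length(x))
  k <- sum(x)
  (k * logistic(1) - (n - k) * logistic(0)) / n
}

#' Attainable accumulated fatigue levels
#'
#' For a window split into `n` segments the accumulated fatigue value takes
#' exactly `n + 1` values, one per possible fatigue-segment count
#' `k = 0, ..., n`:
#' \deqn{a_F^{(k)} = \frac{1}{n}[k\,\sigma(1) - (n-k)\,\sigma(0)]}
#' The levels form an arithmetic progression from \eqn{-0.5} (all awake) to
#' \eqn{\sigma(1) \approx 0.731} (all fatigue) with gap
#' \eqn{(\sigma(1)+\sigma(0))/n}. For `n = 3` the levels are
#' \eqn{-0.5, -0.089, 0.321, 0.731}.
#'
#' @param n Integer number of segments, > 1.
#' @return Numeric vector of `n + 1` strictly increasing levels, named by `k`.
#' @export
#' @examples
#' round(cumulative_levels(3), 3)
cumulative_levels <- function(n) {
  n <- check_segments(n)
  k <- 0:n
  out <- (k * logistic(1) - (n - k) * logistic(0)) / n
  names(out) <- as.character(k)
  out
}

#' Candidate decision thresholds for the accumulation model
#'
#' Midpoints of adjacent accumulated-fatigue levels: `n` candidates for `n`
#' segments. Thresholding `a_F` at the `j`-th candidate is equivalent to the
#' counting rule "fatigue iff at least `j` segments are fatigued", so the
#' candidates enumerate every achievable operating point of the model. For
#' `n = 3` the candidates are \eqn{-0.295, 0.116, 0.526}.
#'
#' @inheritParams cumulative_levels
#' @return Numeric vector of `n` strictly increasing thresholds.
#' @seealso [select_threshold()]
#' @export
#' @examples
#' round(candidate_thresholds(3), 3)
candidate_thresholds <- function(n) {
  n <- check_segments(n)
  lev <- cumulative_levels(n)
  unname((lev[-1] + lev[-length(lev)]) / 2)
}

#' Window decision from accumulated fatigue evidence
#'
#' Computes the accumulated fatigue value for the per-segment states and
#' compares it with the operating threshold: fatigue iff `a_F >= theta`.
#' Equality counts as fatigue; with midpoint thresholds and exact levels the
#' boundary is unreachable, so the rule only matters under floating point.
#'
#' @param x Per-segment 0/1 states (length > 1).
#' @param theta Finite scalar operating threshold on `a_F`.
#' @return An object of class `"cumulative_result"`: a list with elements
#'   `a_f`, `theta`, `k` (fatigue-segment count), `n`, and `decision`
#'   (`"awake"` or `"fatigue"`).
#' @export
#' @examples
#' decide_window(c(1, 0, 0), theta = 0.116)  # filtered: awake
#' decide_window(c(1, 1, 0), theta = 0.116)  # fatigue
decide_window <- function(x, theta) {
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta))
  a_f <- fatigue_accumulation(x)
  out <- list(
    a_f = a_f, theta = theta,
    k = as.integer(sum(x)), n = length(x),
    decision = if (a_f >= theta) "fatigue" else "awake"
  )
  class(out) <- "cumulative_result"
  out
}

#' @export
print.cumulative_result <- function(x, ...) {
  cat(sprintf("Cumulative fatigue decision: %s\n", x$decision))
  cat(sprintf("  a_F = %.3f (k = %d of n = %d segments fatigued), theta = %.3f\n",
              x$a_f, x$k, x$n, x$theta))
  invisible(x)
}

#' Calibrate the accumulation threshold on labelled windows
#'
#' Evaluates every candidate threshold ([candidate_thresholds()]) on a
#' collection of labelled windows, each described by its fatigue-segment
#' count, and returns the candidate with the highest detection accuracy
#' (smallest candidate on ties, favouring sensitivity) together with the full
#' accuracy table.
#'
#' @param k Integer vector, fatigue-segment count of each window (0..n).
#' @param labels Logical/0-1 vector, `TRUE`/1 = window truly fatigued.
#' @param n Integer number of segments per window, > 1.
#' @return A list with `theta` (selected threshold) and `table`, a data frame
#'   with columns `theta`, `correct`, `accuracy` (one row per candidate).
#' @export
#' @examples
#' # awake windows with k <= 1, fatigue windows with k >= 2 (n = 3):
#' sel <- select_threshold(k = c(0, 1, 1, 2, 3), labels = c(0, 0, 0, 1, 1), n = 3)
#' round(sel$theta, 3)  # 0.116
select_threshold <- function(k, labels, n) {
  n <- check_segments(n)
  labels <- as.logical(labels)
  if (length(k) == 0L || length(k) != length(labels))
    stop("'k' and 'labels' must be non-empty and of equal length", call. = FALSE)
  if (!all(k %in% 0:n))
    stop("segment counts 'k' must lie in 0..n", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("threshold calibration needs both awake and fatigue windows", call. = FALSE)
  a_f <- cumulative_levels(n)[as.character(k)]
  cand <- candidate_thresholds(n)
  correct <- vapply(cand, function(th) sum((a_f >= th) == labels), numeric(1))
  acc <- correct / length(k)
  best <- which.max(acc)  # first max = smallest candidate on ties
  list(
    theta = cand[best],
    table = data.frame(theta = cand, correct = as.integer(correct), accuracy = acc)
  )
}

#' Overall accuracy from per-class confusion counts
#'
#' @param n_per_class Integer vector of sample counts per true class.
#' @param correct_per_class Integer vector of correctly detected counts.
#' @return List with per-class accuracies and the overall accuracy
#'   (total correct / total samples).
#' @export
#' @examples
#' accuracy_from_counts(c(awake = 45, fatigue = 15), c(40, 14))$overall  # 0.9
accuracy_from_counts <- function(n_per_class, correct_per_class) {
  stopifnot(length(n_per_class) == length(correct_per_class),
            all(correct_per_class <= n_per_class), all(n_per_class > 0))
  list(per_class = correct_per_class / n_per_class,
       overall = sum(correct_per_class) / sum(n_per_class))
}

#' Segmented fatigue detection over a frame series
#'
#' The noise-filtering detection loop: cut the observation stream into
#' windows of `window_seconds`, split each window into `n` equal contiguous
#' segments (the first `count %% n` segments absorb the extra frames),
#' compute the three fatigue features per segment, classify each segment with
#' the window classifier, and combine the `n` segment states with
#' [decide_window()].
#'
#' @param series A `frame_series` (see [frame_series()]).
#' @param model A fitted [fatigue_net()] classifier.
#' @param window_seconds Window length in seconds (default 60).
#' @param n Number of segments per window, > 1 (default 3).
#' @param theta Operating threshold on `a_F` (default 0.116).
#' @param min_yawn_seconds Minimum mouth-open run counted as a yawn
#'   (default 4).
#' @return Data frame with one row per window: `window_id`, `start_s`,
#'   `end_s`, `k`, `a_f`, `theta`, `state` (0 awake / 1 fatigue), and the
#'   per-segment state string `segment_states`.
#' @export
run_segmented_detection <- function(series, model, window_seconds = 60,
                                    n = 3, theta = 0.116,
                                    min_yawn_seconds = 4) {
  n <- check_segments(n)
  stopifnot(inherits(series, "frame_series"))
  frames_per_window <- floor(window_seconds / series$t0)
  if (frames_per_window < n)
    stop("segments would be shorter than one frame", call. = FALSE)
  if (window_seconds / n < min_yawn_seconds)
    warning("segment length below the yawn duration cut-off; ",
            "yawns cannot be detected within a segment", call. = FALSE)
  nf <- nrow(series$obs)
  n_windows <- nf %/% frames_per_window
  if (n_windows < 1L)
    stop("series shorter than one window", call. = FALSE)
  rows <- vector("list", n_windows)
  for (w in seq_len(n_windows)) {
    idx <- ((w - 1L) * frames_per_window + 1L):(w * frames_per_window)
    segs <- split_indices(length(idx), n)
    states <- integer(n)
    for (s in seq_len(n)) {
      sub <- subset_series(series, idx[segs[[s]]])
      wf <- window_features(sub, min_yawn_seconds = min_yawn_seconds)
      states[s] <- predict(model, wf)$state
    }
    dec <- decide_window(states, theta)
    rows[[w]] <- data.frame(
      window_id = w,
      start_s = (idx[1L] - 1L) * series$t0,
      end_s = idx[length(idx)] * series$t0,
      k = dec$k, a_f = dec$a_f, theta = theta,
      state = as.integer(dec$decision == "fatigue"),
      segment_states = paste(states, collapse = "")
    )
  }
  do.call(rbind, rows)
}

# partition 'len' items into n contiguous groups; first len %% n groups get
# one extra item
split_indices <- function(len, n) {
  base <- len %/% n
  extra <- len %% n
  sizes <- rep(base, n) + c(rep(1L, extra), rep(0L, n - extra))
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-n] + 1L)
  Map(function(s, e) s:e, starts, ends)
}
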