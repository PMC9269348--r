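## Face bounding-box tracking with a constant-velocity Kalman filter.
##
## State: the four corner coordinates (x1, y1, x2, y2) of the box and their
## per-frame velocities (8 dimensions). The filter predicts the box through
## frames where detection fails (occlusion, head turn) or the detector
## confidence falls below a threshold. Pixel units, origin top-left, x right,
## y down.

box_vec <- function(box) c(box$x1, box$y1, box$x2, box$y2)

validate_box <- function(box) {
  stopifnot(is.list(box), all(c("x1", "y1", "x2", "y2") %in% names(box)))
  v <- box_vec(box)
  if (!all(is.finite(v))) stop("non-finite box coordinates", call. = FALSE)
  if (box$x1 >= box$x2 || box$y1 >= box$y2)
    stop("degenerate face box: need x1 < x2 and y1 < y2", call. = FALSE)
  invisible(box)
}

#' Face bounding box
#'
#' @param x1,y1 Top-left corner (pixels).
#' @param x2,y2 Bottom-right corner (pixels); must exceed the top-left.
#' @param confidence Optional detector confidence in `[0, 1]`.
#' @param frame_index Optional non-negative frame index.
#' @return List of class `"face_box"`.
#' @export
face_box <- function(x1, y1, x2, y2, confidence = NA_real_,
                     frame_index = NA_integer_) {
  box <- structure(list(x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                        confidence = confidence, frame_index = frame_index),
                   class = "face_box")
  validate_box(box)
  box
}

#' Initialize the box tracker state
#'
#' Positions are set to the box corners, velocities to zero. The position
#' prior variance equals the measurement noise; the velocity prior is
#' diffuse (scaled by 100) since no motion has been observed yet.
#'
#' @param box A [face_box()].
#' @param process_noise Per-step process noise variance (px^2), applied to
#'   positions and velocities (default 1).
#' @param measurement_noise Measurement noise variance (px^2) of the corner
#'   coordinates (default 1).
#' @return List of class `"kalman_box_state"` with elements `x` (8-vector:
#'   4 positions then 4 velocities), `p` (8 x 8 covariance), `q`, `r`,
#'   `initialized`.
#' @export
kalman_init <- function(box, process_noise = 1, measurement_noise = 1) {
  validate_box(box)
  stopifnot(process_noise >= 0, measurement_noise >= 0)
  x <- c(box_vec(box), rep(0, 4))
  p <- diag(c(rep(max(measurement_noise, 1e-9), 4), rep(100, 4)))
  structure(list(x = x, p = p, q = process_noise, r = measurement_noise,
                 initialized = TRUE),
            class = "kalman_box_state")
}

kf_mats <- function() {
  f <- diag(8)
  f[cbind(1:4, 5:8)] <- 1  # corner += velocity each frame
  h <- cbind(diag(4), matrix(0, 4, 4))
  list(f = f, h = h)
}

#' One Kalman predict/update step
#'
#' Advances the constant-velocity model one frame; if a measurement box is
#' supplied, fuses it with the prediction, otherwise returns the pure
#' prediction (the degraded path used through occlusions). With measurement
#' noise approaching zero the filtered box converges to the measurement.
#'
#' @param state A `"kalman_box_state"` from [kalman_init()] or a previous
#'   step.
#' @param measurement A [face_box()], or `NULL` for predict-only.
#' @return List with `state` (updated) and `box` (the filtered or predicted
#'   [face_box()]; corner ordering is enforced by a 1-px floor on width and
#'   height).
#' @export
kalman_step <- function(state, measurement = NULL) {
  stopifnot(inherits(state, "kalman_box_state"), isTRUE(state$initialized))
  m <- kf_mats()
  x <- drop(m$f %*% state$x)
  p <- m$f %*% state$p %*% t(m$f) + diag(8) * state$q
  if (!is.null(measurement)) {
    validate_box(measurement)
    z <- box_vec(measurement)
    s <- m$h %*% p %*% t(m$h) + diag(4) * state$r
    kg <- p %*% t(m$h) %*% solve(s + diag(4) * 1e-12)
    x <- x + drop(kg %*% (z - drop(m$h %*% x)))
    p <- (diag(8) - kg %*% m$h) %*% p
    p <- (p + t(p)) / 2  # keep symmetric
  }
  state$x <- x
  state$p <- p
  # enforce corner ordering on the emitted box
  x2 <- max(x[3], x[1] + 1)
  y2 <- max(x[4], x[2] + 1)
  list(state = state,
       box = face_box(x[1], x[2], x2, y2))
}

#' Track a face box through a detection sequence
#'
#' Runs the Kalman filter over per-frame detections. Detections that are
#' absent or fall below `conf_threshold` are replaced by the filter's
#' prediction; if the gap exceeds `max_gap` consecutive frames the track is
#' declared lost and an error is raised.
#'
#' @param detections Data frame with columns `frame`, `x1`, `y1`, `x2`,
#'   `y2`, `confidence`; `NA` coordinates mean no detection in that frame.
#' @param conf_threshold Minimum detector confidence for a measurement to be
#'   used (default 0.5); `NA` confidence counts as trustworthy.
#' @param process_noise,measurement_noise Filter noise variances (px^2).
#' @param max_gap Maximum consecutive predict-only frames before the track
#'   is lost (default 30).
#' @return Data frame `frame`, `x1`, `y1`, `x2`, `y2`, `source`
#'   (`"measured"` or `"predicted"`), one row per input frame. Frames before
#'   the first usable detection are back-filled with it and marked
#'   `"predicted"`.
#' @export
track_faces <- function(detections, conf_threshold = 0.5,
                        process_noise = 1, measurement_noise = 1,
                        max_gap = 30) {
  stopifnot(is.data.frame(detections), nrow(detections) > 0)
  need <- c("frame", "x1", "y1", "x2", "y2")
  if (!all(need %in% names(detections)))
    stop("detections need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  conf <- if ("confidence" %in% names(detections)) detections$confidence
          else rep(NA_real_, nrow(detections))
  usable <- stats::complete.cases(detections[, c("x1", "y1", "x2", "y2")]) &
    (is.na(conf) | conf >= conf_threshold)
  if (!any(usable))
    stop("no usable detection in the sequence: cannot initialize track",
         call. = FALSE)
  first <- which(usable)[1L]
  st <- kalman_init(with(detections[first, ],
                         face_box(x1, y1, x2, y2)),
                    process_noise, measurement_noise)
  nfr <- nrow(detections)
  out <- data.frame(frame = detections$frame,
                    x1 = NA_real_, y1 = NA_real_,
                    x2 = NA_real_, y2 = NA_real_,
                    source = NA_character_)
  # frames before the first usable detection: hold the first box
  for (i in seq_len(first)) {
    out[i, 2:5] <- unlist(detections[first, c("x1", "y1", "x2", "y2")])
    out$source[i] <- if (i == first) "measured" else "predicted"
  }
  gap <- 0L
  if (first < nfr) for (i in (first + 1L):nfr) {
    meas <- if (usable[i])
      with(detections[i, ], face_box(x1, y1, x2, y2)) else NULL
    if (is.null(meas)) {
      gap <- gap + 1L
      if (gap > max_gap)
        stop(sprintf("track lost: %d consecutive frames without detection",
                     gap), call. = FALSE)
    } else gap <- 0L
    stp <- kalman_step(st, meas)
    st <- stp$state
    out[i, 2:5] <- box_vec(stp$box)
    out$source[i] <- if (usable[i]) "measured" else "predicted"
  }
  out
}
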