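## Synthetic fixtures: rendered eye images with known geometry, 68-point
## landmark streams with blink/closure/yawn/expression-noise structure, and
## labelled window feature tables. Everything is seeded and reproducible.

#' Render a synthetic eye image with known geometry
#'
#' Draws a bright ellipse (the eye region) on a black background, optionally
#' tilted, and places the six eye landmarks at the ellipse extremes: corners
#' P1/P4 at the horizontal extremes, lid points P2/P3 (upper) and P6/P5
#' (lower) at `x = -a/2, +a/2` on the ellipse boundary. The geometric
#' openness ratio is `b / a`, which the image-based EAR should recover.
#'
#' @param a Horizontal semi-axis (pixels), > 0.
#' @param b Vertical semi-axis (pixels), `0 <= b <= a`; 0 renders a closed
#'   eye (no bright region).
#' @param tilt Eye tilt in degrees (rotation in image coordinates, positive
#'   turns the P1-P4 line downward toward +y).
#' @param image_size Optional `c(height, width)`; default a square that fits
#'   the tilted ellipse with margin.
#' @param noise_level Standard deviation of additive Gaussian pixel noise
#'   (gray levels, default 0); uses the current RNG state.
#' @return List with `image` (matrix, rows = y, 0..255), `eye` (6 x 2
#'   landmark matrix P1..P6), `true_ear` (`b / a`).
#' @export
render_eye_image <- function(a, b, tilt = 0, image_size = NULL,
                             noise_level = 0) {
  stopifnot(a > 0, b >= 0, b <= a)
  if (is.null(image_size)) {
    # the 50%-extended lid crop of a tilted wide-open eye can span up to
    # about 2a vertically; size the square canvas to hold it with margin
    s <- 2L * ceiling(2 * a + 8) + 1L
    image_size <- c(s, s)
  }
  h <- image_size[1]; w <- image_size[2]
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  th <- tilt * pi / 180
  # pixel centers, un-rotate into ellipse frame
  xg <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  yg <- matrix(seq_len(h), h, w) - cy
  u <- xg * cos(th) + yg * sin(th)
  v <- -xg * sin(th) + yg * cos(th)
  img <- matrix(0, h, w)
  if (b > 0) img[(u / a)^2 + (v / b)^2 <= 1] <- 255
  if (noise_level > 0) {
    img <- img + matrix(stats::rnorm(h * w, sd = noise_level), h, w)
    img <- pmin(pmax(img, 0), 255)
  }
  rot <- function(dx, dy) c(cx + dx * cos(th) - dy * sin(th),
                            cy + dx * sin(th) + dy * cos(th))
  yb <- b * sqrt(3) / 2  # ellipse height at x = +/- a/2
  eye <- rbind(P1 = rot(-a, 0), P2 = rot(-a / 2, -yb), P3 = rot(a / 2, -yb),
               P4 = rot(a, 0), P5 = rot(a / 2, yb), P6 = rot(-a / 2, yb))
  colnames(eye) <- c("x", "y")
  if (any(eye[, 1] < 1 | eye[, 1] > w | eye[, 2] < 1 | eye[, 2] > h))
    stop("ellipse does not fit in the image", call. = FALSE)
  list(image = img, eye = eye, true_ear = b / a)
}

#' Scenario specification for synthetic landmark streams
#'
#' Describes a simulated driving recording: a state schedule (awake/fatigue
#' spans), per-state eye-closure and yawn event processes, and transient
#' expression-noise events (smiles/speech) that depress the EAR below the
#' openness threshold for a few seconds — the failure mode that causes false
#' fatigue alarms in whole-window classification.
#'
#' Defaults describe the emulated study conditions: 30 frames/s, awake
#' blinks of 0.1-0.4 s at 15/min, fatigue closures lognormal with median
#' 2.5 s at 6/min, yawns averaging 6 s at 1.2/min during fatigue only, and
#' (when enabled) expression-noise events of 2-5 s.
#'
#' @param duration Recording length in seconds.
#' @param fps Frames per second.
#' @param schedule Data frame `start_s`, `end_s`, `state` covering
#'   `[0, duration]` without gaps or overlap; `state` is `"awake"` or
#'   `"fatigue"`.
#' @param blink_rate_awake,blink_rate_fatigue Short-blink events per minute.
#' @param blink_range Awake blink duration range (seconds).
#' @param closure_rate_fatigue Long-closure events per minute in fatigue.
#' @param closure_meanlog,closure_sdlog Lognormal parameters of fatigue
#'   closure durations (seconds); defaults give median 2.5 s.
#' @param yawn_rate_awake,yawn_rate_fatigue Yawns per minute.
#' @param yawn_mean,yawn_sd Yawn duration distribution (seconds), truncated
#'   below at 4.5 s.
#' @param noise_rate Expression-noise events per minute in awake spans
#'   (0 disables; "scenario 2" uses 2).
#' @param noise_range Noise event duration range (seconds).
#' @param jitter_sd Landmark jitter standard deviation (pixels).
#' @param ear_open,ear_closed,ear_noise Target EAR during open eyes, closed
#'   eyes, and expression-noise events.
#' @param mar_closed,mar_open Target MAR with mouth closed / open.
#' @param seed Integer RNG seed.
#' @return List of class `"scenario_spec"`.
#' @export
scenario_spec <- function(duration = 300, fps = 30,
                          schedule = data.frame(start_s = 0,
                                                end_s = duration,
                                                state = "awake"),
                          blink_rate_awake = 15, blink_rate_fatigue = 8,
                          blink_range = c(0.1, 0.4),
                          closure_rate_fatigue = 6,
                          closure_meanlog = log(2.5), closure_sdlog = 0.3,
                          yawn_rate_awake = 0, yawn_rate_fatigue = 1.2,
                          yawn_mean = 6, yawn_sd = 1,
                          noise_rate = 0, noise_range = c(2, 5),
                          jitter_sd = 0.5,
                          ear_open = 0.30, ear_closed = 0.08,
                          ear_noise = 0.12,
                          mar_closed = 0.2, mar_open = 0.6,
                          seed = 1) {
  stopifnot(duration > 0, fps > 0, nrow(schedule) >= 1,
            all(schedule$state %in% c("awake", "fatigue")))
  sch <- schedule[order(schedule$start_s), , drop = FALSE]
  if (abs(sch$start_s[1]) > 1e-9 ||
      abs(sch$end_s[nrow(sch)] - duration) > 1e-9 ||
      (nrow(sch) > 1 && any(abs(sch$start_s[-1] - sch$end_s[-nrow(sch)]) > 1e-9)))
    stop("schedule must cover [0, duration] without gaps or overlap",
         call. = FALSE)
  spec <- as.list(environment())
  spec$sch <- NULL
  spec$schedule <- sch
  class(spec) <- "scenario_spec"
  spec
}

# Poisson-process event starts within [t0, t1) at 'rate' per minute,
# each with a duration drawn by 'rdur'
draw_events <- function(t0, t1, rate, rdur) {
  if (rate <= 0 || t1 <= t0) return(data.frame(start = numeric(0),
                                               end = numeric(0)))
  n <- stats::rpois(1, rate / 60 * (t1 - t0))
  if (n == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  start <- sort(stats::runif(n, t0, t1))
  data.frame(start = start, end = pmin(start + rdur(n), t1))
}

# a frame is marked when its centre time falls inside the event, so marked
# durations are unbiased under frame quantization
mark_frames <- function(flag, events, fps) {
  centres <- (seq_along(flag) - 0.5) / fps
  for (i in seq_len(nrow(events)))
    flag <- flag | (centres >= events$start[i] & centres < events$end[i])
  flag
}

#' Generate a synthetic landmark stream
#'
#' Simulates a recording described by a [scenario_spec()]: draws eye-closure,
#' yawn, and expression-noise events per schedule span, converts them into
#' per-frame target EAR/MAR values, and synthesizes a jittered 68-point
#' landmark stream whose computed aspect ratios reproduce those targets.
#' Expression-noise events (awake spans only) depress the EAR below the
#' openness threshold and open the mouth briefly, mimicking smiles and
#' speech.
#'
#' @param spec A [scenario_spec()].
#' @param window_seconds Window length used for the emitted ground-truth
#'   window labels (default 60). A window is labelled fatigue when the
#'   majority of its frames fall in fatigue spans.
#' @return List with `landmarks` (CSV-schema data frame: `frame_index`,
#'   `timestamp`, `x0`..`y67`, `valid`), `truth` (per-frame `frame_index`,
#'   `state`, `eye_closed`, `mouth_open`, `noise`), and `window_labels`
#'   (`window_id`, `label`, 1 = fatigue).
#' @export
generate_stream <- function(spec, window_seconds = 60) {
  stopifnot(inherits(spec, "scenario_spec"))
  with_seed(spec$seed, {
    nf <- floor(spec$duration * spec$fps)
    fps <- spec$fps
    eye_closed <- mouth_open <- noise_on <- rep(FALSE, nf)
    state <- character(nf)
    tmid <- (seq_len(nf) - 0.5) / fps
    for (r in seq_len(nrow(spec$schedule))) {
      sp <- spec$schedule[r, ]
      in_span <- tmid >= sp$start_s & tmid < sp$end_s
      state[in_span] <- sp$state
      if (sp$state == "awake") {
        blinks <- draw_events(sp$start_s, sp$end_s, spec$blink_rate_awake,
                              function(n) stats::runif(n, spec$blink_range[1],
                                                       spec$blink_range[2]))
        eye_closed <- mark_frames(eye_closed, blinks, fps)
        yawns <- draw_events(sp$start_s, sp$end_s, spec$yawn_rate_awake,
                             function(n) pmax(stats::rnorm(n, spec$yawn_mean,
                                                           spec$yawn_sd), 4.5))
        mouth_open <- mark_frames(mouth_open, yawns, fps)
        nse <- draw_events(sp$start_s, sp$end_s, spec$noise_rate,
                           function(n) stats::runif(n, spec$noise_range[1],
                                                    spec$noise_range[2]))
        noise_on <- mark_frames(noise_on, nse, fps)
      } else {
        blinks <- draw_events(sp$start_s, sp$end_s, spec$blink_rate_fatigue,
                              function(n) stats::runif(n, spec$blink_range[1],
                                                       spec$blink_range[2]))
        closures <- draw_events(sp$start_s, sp$end_s,
                                spec$closure_rate_fatigue,
                                function(n) stats::rlnorm(n,
                                                          spec$closure_meanlog,
                                                          spec$closure_sdlog))
        eye_closed <- mark_frames(mark_frames(eye_closed, blinks, fps),
                                  closures, fps)
        yawns <- draw_events(sp$start_s, sp$end_s, spec$yawn_rate_fatigue,
                             function(n) pmax(stats::rnorm(n, spec$yawn_mean,
                                                           spec$yawn_sd), 4.5))
        mouth_open <- mark_frames(mouth_open, yawns, fps)
      }
    }
    ear_target <- ifelse(eye_closed, spec$ear_closed,
                         ifelse(noise_on, spec$ear_noise, spec$ear_open))
    # speech/laughter opens the mouth in short bursts (~0.5 s on/off),
    # well below the yawn duration cut-off
    speech_open <- noise_on & (floor(tmid / 0.5) %% 2 == 0)
    mar_target <- ifelse(mouth_open | speech_open, spec$mar_open,
                         spec$mar_closed)
    lm <- synth_landmarks(ear_target, mar_target, spec$jitter_sd)
    lm <- cbind(data.frame(frame_index = seq_len(nf) - 1L,
                           timestamp = (seq_len(nf) - 1L) / fps),
                lm, data.frame(valid = TRUE))
    truth <- data.frame(frame_index = seq_len(nf) - 1L, state = state,
                        eye_closed = eye_closed | noise_on,
                        mouth_open = mouth_open,
                        noise = noise_on)
    fpw <- floor(window_seconds * fps)
    nw <- nf %/% fpw
    labels <- if (nw >= 1) {
      vapply(seq_len(nw), function(w) {
        idx <- ((w - 1L) * fpw + 1L):(w * fpw)
        as.integer(mean(state[idx] == "fatigue") > 0.5)
      }, integer(1))
    } else integer(0)
    list(landmarks = lm, truth = truth,
         window_labels = data.frame(window_id = seq_len(nw), label = labels))
  })
}

# Build the 68-point frame table from per-frame target EAR/MAR.
# Template geometry: eyes of half-width 20 px centred at (200,180) and
# (280,180); mouth corners 70 px apart. Lid/lip vertical offsets are chosen
# so the computed ratios equal the targets before jitter.
synth_landmarks <- function(ear_target, mar_target, jitter_sd) {
  nf <- length(ear_target)
  base <- template_face()
  a_eye <- 20; half_mouth <- 35
  out <- matrix(rep(t(base), nf), nrow = nf, byrow = TRUE)
  colnames(out) <- paste0(rep(c("x", "y"), times = 68), rep(0:67, each = 2))
  # EAR = h / a for lid offset +/- h at the two lid columns
  h_eye <- ear_target * a_eye
  g_mouth <- mar_target * half_mouth
  for (side in c(0, 6)) {  # right eye rows 37..42, left eye 43..48 (1-based)
    rows <- 37:42 + side
    ycols <- paste0("y", rows - 1)
    out[, ycols[2]] <- 180 - h_eye
    out[, ycols[3]] <- 180 - h_eye
    out[, ycols[5]] <- 180 + h_eye
    out[, ycols[6]] <- 180 + h_eye
  }
  out[, "y50"] <- 260 - g_mouth  # M2 (point 50)
  out[, "y52"] <- 260 - g_mouth  # M3 (point 52)
  out[, "y56"] <- 260 + g_mouth  # M5 (point 56)
  out[, "y58"] <- 260 + g_mouth  # M6 (point 58)
  if (jitter_sd > 0)
    out <- out + matrix(stats::rnorm(length(out), sd = jitter_sd),
                        nrow = nf)
  as.data.frame(out)
}

# Static 68-point template (x, y), 0-based point i in row i+1. Only the eye
# and mouth points matter for the feature path; the rest are plausible
# placeholders (jaw arc, brows, nose).
template_face <- function() {
  pts <- matrix(NA_real_, 68, 2)
  pts[1:17, ] <- cbind(seq(150, 330, length.out = 17),
                       160 + 80 * sin(seq(0, pi, length.out = 17)))
  pts[18:22, ] <- cbind(seq(180, 220, length.out = 5), 150)   # right brow
  pts[23:27, ] <- cbind(seq(260, 300, length.out = 5), 150)   # left brow
  pts[28:31, ] <- cbind(240, seq(170, 215, length.out = 4))   # nose bridge
  pts[32:36, ] <- cbind(seq(225, 255, length.out = 5), 225)   # nose base
  # right eye 37..42: P1..P6
  pts[37:42, ] <- rbind(c(180, 180), c(192, 174), c(208, 174),
                        c(220, 180), c(208, 186), c(192, 186))
  # left eye 43..48
  pts[43:48, ] <- rbind(c(260, 180), c(272, 174), c(288, 174),
                        c(300, 180), c(288, 186), c(272, 186))
  # outer mouth 49..60 (points 48..59)
  pts[49:60, ] <- rbind(c(205, 260), c(215, 253), c(225, 250), c(240, 249),
                        c(255, 250), c(265, 253), c(275, 260), c(265, 267),
                        c(255, 270), c(240, 271), c(225, 270), c(215, 267))
  # inner mouth 61..68 (points 60..67)
  pts[61:68, ] <- rbind(c(215, 260), c(228, 257), c(240, 256), c(252, 257),
                        c(265, 260), c(252, 263), c(240, 264), c(228, 263))
  pts
}

#' Generate a labelled window feature table
#'
#' Draws per-window fatigue features directly from per-class distributions
#' consistent with [generate_stream()] statistics: awake windows have short
#' blinks only (longest closure < 1 s, no yawns, PERCLOS < 0.1), fatigue
#' windows have sustained closures, at least one yawn and elevated PERCLOS.
#' Class counts are exact.
#'
#' @param n_windows Number of windows (>= 10).
#' @param fatigue_fraction Fraction of fatigue windows, in (0, 1)
#'   (default 0.7, emulating a 350/150 fatigue/awake composition at n = 500).
#' @param awake_closure,awake_perclos Ranges for awake windows.
#' @param fatigue_closure,fatigue_perclos Ranges for fatigue windows.
#' @param fatigue_extra_yawns Poisson mean of yawns beyond the first in
#'   fatigue windows.
#' @param seed Integer RNG seed.
#' @return Data frame `longest_closure`, `yawn_count`, `perclos`, `label`
#'   (1 = fatigue).
#' @export
generate_training_set <- function(n_windows = 500, fatigue_fraction = 0.7,
                                  awake_closure = c(0.1, 0.9),
                                  awake_perclos = c(0.005, 0.09),
                                  fatigue_closure = c(2.6, 6),
                                  fatigue_perclos = c(0.31, 0.55),
                                  fatigue_extra_yawns = 0.5,
                                  seed = 1) {
  stopifnot(n_windows >= 10)
  if (fatigue_fraction <= 0 || fatigue_fraction >= 1)
    stop("fatigue_fraction must be in (0, 1)", call. = FALSE)
  with_seed(seed, {
    n_fat <- round(n_windows * fatigue_fraction)
    n_awk <- n_windows - n_fat
    awake <- data.frame(
      longest_closure = stats::runif(n_awk, awake_closure[1],
                                     awake_closure[2]),
      yawn_count = 0L,
      perclos = stats::runif(n_awk, awake_perclos[1], awake_perclos[2]),
      label = 0L)
    fatigue <- data.frame(
      longest_closure = stats::runif(n_fat, fatigue_closure[1],
                                     fatigue_closure[2]),
      yawn_count = 1L + stats::rpois(n_fat, fatigue_extra_yawns),
      perclos = stats::runif(n_fat, fatigue_perclos[1], fatigue_perclos[2]),
      label = 1L)
    out <- rbind(awake, fatigue)
    out[sample.int(nrow(out)), , drop = FALSE]
  })
}
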