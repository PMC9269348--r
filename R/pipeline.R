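## End-to-end detection pipelines: landmarks -> per-frame observations ->
## window features -> classifier, either on whole windows (the plain
## network route) or with per-window segmentation and time-accumulation
## filtering.

#' Pipeline configuration
#'
#' Bundles the operating parameters of the detection pipelines with their
#' calibrated defaults: EAR openness threshold 0.21, MAR threshold 0.4,
#' yawn duration cut-off 4 s, 60-s windows, 3 segments per window, and the
#' accumulation threshold 0.116 (the calibrated midpoint between the one-
#' and two-fatigue-segment evidence levels for n = 3).
#'
#' @param ear_threshold Eyes closed iff EAR <= this (default 0.21).
#' @param mar_threshold Mouth open iff MAR > this (default 0.4).
#' @param min_yawn_seconds Yawn duration cut-off, seconds (default 4).
#' @param window_seconds Detection window, seconds (default 60).
#' @param segments Segments per window for the accumulation model, > 1
#'   (default 3).
#' @param theta Accumulated-fatigue decision threshold (default 0.116).
#' @param fps Frame rate of the landmark stream (default 30).
#' @param seed Integer seed recorded for reproducibility (default 0).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(ear_threshold = 0.21, mar_threshold = 0.4,
                            min_yawn_seconds = 4, window_seconds = 60,
                            segments = 3, theta = 0.116, fps = 30,
                            seed = 0) {
  stopifnot(ear_threshold > 0, mar_threshold > 0, min_yawn_seconds > 0,
            window_seconds > 0, fps > 0)
  check_segments(segments)
  if (floor(window_seconds * fps) < segments)
    stop("window shorter than one frame per segment", call. = FALSE)
  structure(list(ear_threshold = ear_threshold,
                 mar_threshold = mar_threshold,
                 min_yawn_seconds = min_yawn_seconds,
                 window_seconds = window_seconds, segments = segments,
                 theta = theta, fps = fps, seed = seed),
            class = "pipeline_config")
}

series_from_landmarks <- function(landmarks, config) {
  if (is.character(landmarks)) landmarks <- read_landmarks(landmarks)
  if (nrow(landmarks) == 0L) stop("empty landmark stream", call. = FALSE)
  obs <- extract_observations(landmarks, config$ear_threshold,
                              config$mar_threshold)
  frame_series(obs, t0 = 1 / config$fps)
}

#' Whole-window fatigue detection (plain network route)
#'
#' Landmarks -> per-frame openness observations -> one feature vector per
#' window -> network classification, with no segmentation. Sensitive to
#' transient expression noise; compare [run_cumulative_pipeline()].
#'
#' @param landmarks Landmark data frame (see [read_landmarks()]) or a CSV
#'   path.
#' @param model A fitted [fatigue_net()].
#' @param config A [pipeline_config()].
#' @return Data frame with one row per window: `window_id`, `start_s`,
#'   `end_s`, the three features, `probability`, `state` (1 = fatigue).
#' @export
run_bp_pipeline <- function(landmarks, model, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(model, "fatigue_net"))
  series <- series_from_landmarks(landmarks, config)
  feats <- stream_window_features(series, config$window_seconds,
                                  config$min_yawn_seconds)
  pred <- predict(model, feats[, FEATURE_COLS])
  if (is.list(pred) && !is.data.frame(pred))
    pred <- data.frame(probability = pred$probability, state = pred$state)
  cbind(feats, pred)
}

#' Segmented fatigue detection with time-accumulation filtering
#'
#' Like [run_bp_pipeline()] but each window is split into `config$segments`
#' equal segments that are classified individually; the per-segment 0/1
#' states are combined by the accumulated fatigue value and thresholded at
#' `config$theta`. Transient expression noise confined to a minority of
#' segments is filtered out.
#'
#' @inheritParams run_bp_pipeline
#' @return Data frame per window: `window_id`, `start_s`, `end_s`, `k`,
#'   `a_f`, `theta`, `state`, `segment_states`.
#' @export
run_cumulative_pipeline <- function(landmarks, model,
                                    config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(model, "fatigue_net"))
  series <- series_from_landmarks(landmarks, config)
  run_segmented_detection(series, model,
                          window_seconds = config$window_seconds,
                          n = config$segments, theta = config$theta,
                          min_yawn_seconds = config$min_yawn_seconds)
}
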