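## CSV readers/writers for the pipeline's tabular schemas. All round-trip
## losslessly at full double precision.

check_columns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s table is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

LANDMARK_COLS <- c("frame_index", "timestamp",
                   paste0(rep(c("x", "y"), times = 68), rep(0:67, each = 2)),
                   "valid")

#' Read / write a landmark stream CSV
#'
#' One row per frame: `frame_index`, `timestamp`, the 136 coordinate columns
#' `x0, y0, ..., x67, y67`, and a `valid` flag.
#'
#' @param path CSV file path.
#' @param landmarks Landmark data frame (the schema above).
#' @return `read_landmarks()` returns the validated data frame.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, LANDMARK_COLS, "landmark")
  if (any(diff(df$frame_index) <= 0))
    stop("non-monotone frame indices in landmark table", call. = FALSE)
  df$valid <- as.logical(df$valid)
  df
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  check_columns(landmarks, LANDMARK_COLS, "landmark")
  utils::write.csv(landmarks, path, row.names = FALSE)
  invisible(path)
}

OBS_COLS <- c("frame_index", "timestamp", "ear", "mar", "eye_closed",
              "mouth_open", "valid")

#' Read / write a per-frame observation CSV
#'
#' Columns: `frame_index`, `timestamp`, `ear`, `mar`, `eye_closed`,
#' `mouth_open`, `valid`.
#'
#' @param path CSV file path.
#' @param obs Observation data frame.
#' @return `read_observations()` returns the validated data frame.
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, OBS_COLS, "observation")
  if (any(diff(df$frame_index) <= 0))
    stop("non-monotone frame indices in observation table", call. = FALSE)
  for (cc in c("eye_closed", "mouth_open", "valid")) df[[cc]] <- as.logical(df[[cc]])
  df
}

#' @rdname read_observations
#' @export
write_observations <- function(obs, path) {
  check_columns(obs, OBS_COLS, "observation")
  utils::write.csv(obs, path, row.names = FALSE)
  invisible(path)
}

FEATURE_TABLE_COLS <- c("window_id", "start_s", "longest_closure",
                        "yawn_count", "perclos")

#' Read / write a window feature CSV
#'
#' Columns: `window_id`, `start_s`, `longest_closure` (s), `yawn_count`,
#' `perclos`, optional `label`.
#'
#' @param path CSV file path.
#' @param features Feature data frame.
#' @return `read_window_features()` returns the validated data frame.
#' @export
read_window_features <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, FEATURE_TABLE_COLS, "window feature")
  df
}

#' @rdname read_window_features
#' @export
write_window_features <- function(features, path) {
  check_columns(features, FEATURE_TABLE_COLS, "window feature")
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read a face-detection CSV
#'
#' Columns `frame`, `x1`, `y1`, `x2`, `y2`, `confidence`; empty coordinate
#' fields mean no detection in that frame.
#'
#' @param path CSV file path.
#' @return Data frame suitable for [track_faces()].
#' @export
read_detections <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, c("frame", "x1", "y1", "x2", "y2"), "detection")
  df
}

#' Write a reproducibility manifest
#'
#' Records the configuration, seed, package version and input file digests
#' of a pipeline run as JSON.
#'
#' @param path Output JSON path.
#' @param config A [pipeline_config()] (or any list of settings).
#' @param inputs Named character vector of input file paths to digest.
#' @export
write_manifest <- function(path, config, inputs = character(0)) {
  digests <- vapply(inputs, function(f)
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_,
    character(1))
  jsonlite::write_json(
    list(package = "perclos",
         version = as.character(utils::packageVersion("perclos")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = unclass(config),
         input_md5 = as.list(digests)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
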