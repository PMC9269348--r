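## Per-frame eye/mouth openness from 68-point facial landmarks.
##
## Landmark index convention (iBUG 68, 0-based): right eye 36-41, left eye
## 42-47, outer mouth 48-59. Eye points map to P1..P6 as outer corner, two
## upper-lid points, inner corner, two lower-lid points; mouth M1..M6 are the
## corners (48/54), upper lip (50/52) and lower lip (58/56).

RIGHT_EYE_IDX <- 36:41  # P1..P6 in order
LEFT_EYE_IDX <- 42:47
MOUTH_IDX <- c(48, 50, 52, 54, 56, 58)  # M1, M2, M3, M4, M5, M6

dist2 <- function(p, q) sqrt(sum((p - q)^2))

#' Extract the six eye landmarks from a 68-point set
#'
#' @param points 68 x 2 numeric matrix of (x, y) pixel coordinates, ordered
#'   by the standard 68-point convention (0-based indices 0..67 in rows
#'   1..68).
#' @param side `"right"` (indices 36-41) or `"left"` (42-47).
#' @return 6 x 2 matrix with rows P1..P6.
#' @export
eye_points <- function(points, side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(is.matrix(points), nrow(points) == 68L, ncol(points) == 2L)
  idx <- if (side == "right") RIGHT_EYE_IDX else LEFT_EYE_IDX
  m <- points[idx + 1L, , drop = FALSE]
  rownames(m) <- paste0("P", 1:6)
  m
}

#' Extract the six mouth landmarks from a 68-point set
#'
#' @inheritParams eye_points
#' @return 6 x 2 matrix with rows M1..M6 (corners, upper lip, lower lip).
#' @export
mouth_points <- function(points) {
  stopifnot(is.matrix(points), nrow(points) == 68L, ncol(points) == 2L)
  m <- points[MOUTH_IDX + 1L, , drop = FALSE]
  rownames(m) <- paste0("M", 1:6)
  m
}

aspect_ratio_6pt <- function(p, what) {
  stopifnot(is.matrix(p), nrow(p) == 6L, ncol(p) == 2L, all(is.finite(p)))
  width <- dist2(p[1, ], p[4, ])
  if (width <= 0)
    stop(sprintf("coincident %s corners: zero width", what), call. = FALSE)
  (dist2(p[2, ], p[6, ]) + dist2(p[3, ], p[5, ])) / (2 * width)
}

#' Eye aspect ratio from the six eye landmarks
#'
#' `EAR = (|P2-P6| + |P3-P5|) / (2 |P1-P4|)`: mean vertical lid distance over
#' twice the horizontal eye width. Invariant under translation, rotation and
#' uniform scaling of the point set; near zero when the eye is closed.
#'
#' @param eye 6 x 2 matrix with rows P1..P6 (see [eye_points()]).
#' @return Non-negative scalar ratio.
#' @export
#' @examples
#' eye <- rbind(c(0, 0), c(1, 1), c(3, 1), c(4, 0), c(3, -1), c(1, -1))
#' landmark_ear(eye)  # 0.5
landmark_ear <- function(eye) aspect_ratio_6pt(eye, "eye")

#' Mouth aspect ratio from the six mouth landmarks
#'
#' `MAR = (|M2-M6| + |M3-M5|) / (2 |M1-M4|)`; same functional form and
#' invariances as [landmark_ear()]. High during yawns.
#'
#' @param mouth 6 x 2 matrix with rows M1..M6 (see [mouth_points()]).
#' @return Non-negative scalar ratio.
#' @export
landmark_mar <- function(mouth) aspect_ratio_6pt(mouth, "mouth")

#' Image-based eye aspect ratio (improved EAR)
#'
#' Combines the eye landmarks with image processing to measure eye openness
#' robustly when landmark placement is unreliable (dim light, deep eye
#' sockets). Steps: (1) crop the bounding rectangle of the four lid points
#' P2, P3, P5, P6, extended 50% in height both up and down; (2) Gaussian
#' denoising and Otsu binarization of the grayscale crop, mapping the
#' eye-region class to 255; (3) horizontal tilt correction by rotating the
#' crop by minus the P1-P4 line angle (bilinear interpolation); (4) the eye
#' height is `H = M / 255` with `M` the maximum per-column sum of gray
#' values; (5) the eye width is `W = |P1 - P4|`; (6) `EAR = H / W`.
#'
#' @param eye 6 x 2 matrix of eye landmarks P1..P6 in frame coordinates.
#' @param frame_image Numeric matrix, grayscale frame, rows = y (down),
#'   columns = x (right), intensities in 0..255.
#' @param sigma Standard deviation (pixels) of the Gaussian denoising filter
#'   (default 1, a 5x5-scale kernel).
#' @param polarity Which binarized class is the eye region: `"auto"`
#'   (default; the class found at the lid-landmark centroid), `"dark"` (the
#'   darker class, appropriate for real eye crops where iris and lashes are
#'   dark on skin), or `"bright"`.
#' @return List with `ear` and `crop` (class `"eye_crop"`: the binarized
#'   image, crop rectangle, tilt angle in degrees, `m`, `h`, `w`).
#' @export
improved_ear <- function(eye, frame_image, sigma = 1,
                         polarity = c("auto", "dark", "bright")) {
  polarity <- match.arg(polarity)
  stopifnot(is.matrix(eye), nrow(eye) == 6L, is.matrix(frame_image))
  w <- dist2(eye[1, ], eye[4, ])
  if (w <= 0) stop("zero eye width |P1-P4|", call. = FALSE)
  lids <- eye[c(2, 3, 5, 6), , drop = FALSE]
  xr <- range(lids[, 1]); yr <- range(lids[, 2])
  h_ext <- 0.5 * diff(yr)
  x0 <- floor(xr[1]); x1 <- ceiling(xr[2])
  y0 <- floor(yr[1] - h_ext); y1 <- ceiling(yr[2] + h_ext)
  if (x0 < 1 || y0 < 1 || x1 > ncol(frame_image) || y1 > nrow(frame_image))
    stop("eye crop rectangle falls outside the frame image", call. = FALSE)
  crop <- frame_image[y0:y1, x0:x1, drop = FALSE] / 255
  tilt_deg <- atan2(eye[4, 2] - eye[1, 2], eye[4, 1] - eye[1, 1]) * 180 / pi

  if (stats::sd(crop) < 1e-8) {
    # featureless crop (e.g. fully closed eye): no measurable eye region
    return(ear_crop_result(crop * 0, c(x0, y0, x1, y1), tilt_deg, 0, w))
  }
  img <- EBImage::Image(t(crop))
  if (sigma > 0) img <- EBImage::gblur(img, sigma = sigma)
  thr <- EBImage::otsu(img, range = c(0, 1))
  bin <- img > thr
  if (polarity == "dark") {
    eye_is_bright <- FALSE
  } else if (polarity == "bright") {
    eye_is_bright <- TRUE
  } else {
    # class at the lid-landmark centroid = eye region
    cx <- round(mean(lids[, 1])) - x0 + 1L
    cy <- round(mean(lids[, 2])) - y0 + 1L
    cx <- min(max(cx, 1L), ncol(crop)); cy <- min(max(cy, 1L), nrow(crop))
    eye_is_bright <- as.logical(bin[cx, cy])
  }
  bin <- if (eye_is_bright) bin + 0 else 1 - (bin + 0)
  rot <- EBImage::rotate(bin, -tilt_deg, filter = "bilinear", bg.col = 0)
  colsum_max <- max(apply(EBImage::imageData(rot), 1L, sum))  # dim 1 = x
  ear_crop_result(t(EBImage::imageData(bin)) * 255, c(x0, y0, x1, y1),
                  tilt_deg, colsum_max, w)
}

ear_crop_result <- function(bin255, rect, tilt_deg, h, w) {
  crop <- structure(
    list(image = bin255, rect = rect, tilt = tilt_deg,
         m = 255 * h, h = h, w = w),
    class = "eye_crop")
  list(ear = h / w, crop = crop)
}

#' Per-frame open/closed classification from EAR and MAR
#'
#' Eyes count as closed when `ear <= ear_threshold` (equality closed, per
#' the "otherwise closed" rule); mouth counts as open when
#' `mar > mar_threshold`.
#'
#' @param ear,mar Non-negative numeric vectors of equal length.
#' @param ear_threshold Eye openness threshold (default 0.21).
#' @param mar_threshold Mouth openness threshold (default 0.4).
#' @return Data frame with columns `ear`, `mar`, `eye_closed`, `mouth_open`.
#' @export
#' @examples
#' classify_frame(ear = c(0.25, 0.21), mar = c(0.45, 0.1))
classify_frame <- function(ear, mar, ear_threshold = 0.21,
                           mar_threshold = 0.4) {
  stopifnot(length(ear) == length(mar),
            ear_threshold > 0, mar_threshold > 0)
  if (any(ear < 0, na.rm = TRUE) || any(mar < 0, na.rm = TRUE))
    stop("aspect ratios must be non-negative", call. = FALSE)
  data.frame(ear = ear, mar = mar,
             eye_closed = ear <= ear_threshold,
             mouth_open = mar > mar_threshold)
}

#' Openness threshold calibration by accuracy sweep
#'
#' For each candidate threshold `t`, classification accuracy is the fraction
#' of samples whose predicted state (`value > t` = open) matches the label.
#' Returns the grid point with maximum accuracy (smallest on ties) and the
#' full accuracy curve.
#'
#' @param values Numeric vector of per-sample openness ratios.
#' @param labels Logical vector, `TRUE` = open.
#' @param grid Numeric vector of candidate thresholds.
#' @return List with `threshold`, `accuracy`, and `curve` (data frame
#'   `threshold`, `accuracy`).
#' @export
sweep_threshold <- function(values, labels, grid) {
  stopifnot(length(values) >= 1, length(values) == length(labels),
            length(grid) >= 1)
  labels <- as.logical(labels)
  acc <- vapply(grid, function(t) mean((values > t) == labels), numeric(1))
  best <- which.max(acc)  # first = smallest grid point on ties
  list(threshold = grid[best], accuracy = acc[best],
       curve = data.frame(threshold = grid, accuracy = acc))
}

#' Per-frame observations from a landmark stream
#'
#' Computes EAR (mean of left and right eyes), MAR, and the open/closed flags
#' for every frame of a landmark table. Frames flagged invalid get `NA`
#' ratios and `valid = FALSE`; their states are carried forward from the last
#' valid frame when the table enters a [frame_series()].
#'
#' @param landmarks Landmark table as read by [read_landmarks()]: columns
#'   `frame_index`, `timestamp`, `x0`..`x67`, `y0`..`y67`, `valid`.
#' @inheritParams classify_frame
#' @return Data frame: `frame_index`, `timestamp`, `ear`, `mar`,
#'   `eye_closed`, `mouth_open`, `valid`.
#' @export
extract_observations <- function(landmarks, ear_threshold = 0.21,
                                 mar_threshold = 0.4) {
  pts <- landmark_matrix(landmarks)
  nfr <- nrow(landmarks)
  ear <- mar <- rep(NA_real_, nfr)
  valid <- if ("valid" %in% names(landmarks)) as.logical(landmarks$valid)
           else rep(TRUE, nfr)
  for (i in seq_len(nfr)) {
    if (!valid[i]) next
    p <- matrix(pts[i, ], ncol = 2L, byrow = TRUE)
    ear[i] <- (landmark_ear(eye_points(p, "right")) +
               landmark_ear(eye_points(p, "left"))) / 2
    mar[i] <- landmark_mar(mouth_points(p))
  }
  cls <- classify_frame(ifelse(valid, ear, 0), ifelse(valid, mar, 0),
                        ear_threshold, mar_threshold)
  data.frame(frame_index = landmarks$frame_index,
             timestamp = landmarks$timestamp,
             ear = ear, mar = mar,
             eye_closed = cls$eye_closed, mouth_open = cls$mouth_open,
             valid = valid)
}

# 68-point coordinate block as an n_frames x 136 matrix (x0..x67, y0..y67
# interleaved as x_i, y_i pairs in column order x0,y0,x1,y1,...)
landmark_matrix <- function(landmarks) {
  cols <- paste0(rep(c("x", "y"), times = 68), rep(0:67, each = 2))
  miss <- setdiff(cols, names(landmarks))
  if (length(miss))
    stop("landmark table lacks coordinate column(s), e.g. ", miss[1],
         call. = FALSE)
  as.matrix(landmarks[, cols])
}
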