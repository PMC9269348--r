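# Per-frame openness: EAR, MAR, the image-based EAR, state thresholds,
# and threshold calibration.

similarity_transform <- function(p, angle, scale, shift) {
  r <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(scale * p %*% t(r), 2, shift, "+")
}

test_that("landmark EAR matches hand geometry and rejects degenerate eyes", {
  eye <- rbind(c(0, 0), c(1, 1), c(3, 1), c(4, 0), c(3, -1), c(1, -1))
  expect_equal(landmark_ear(eye), 0.5)
  closed <- rbind(c(0, 0), c(1, 0), c(3, 0), c(4, 0), c(3, 0), c(1, 0))
  expect_equal(landmark_ear(closed), 0)
  degen <- eye; degen[4, ] <- degen[1, ]
  expect_error(landmark_ear(degen), "coincident")
})

test_that("EAR and MAR are invariant under similarity transforms", {
  set.seed(31)
  for (i in 1:25) {
    p <- cbind(sort(runif(6, 0, 10)), runif(6, -3, 3))[c(1, 2, 4, 6, 5, 3), ]
    q <- similarity_transform(p, angle = runif(1, -pi, pi),
                              scale = runif(1, 0.2, 5),
                              shift = runif(2, -50, 50))
    expect_equal(landmark_ear(q), landmark_ear(p), tolerance = 1e-9)
    expect_equal(landmark_mar(q), landmark_mar(p), tolerance = 1e-9)
  }
})

test_that("MAR has the same functional form on mouth landmarks", {
  mouth <- rbind(c(0, 0), c(2, 2), c(6, 2), c(8, 0), c(6, -2), c(2, -2))
  expect_equal(landmark_mar(mouth), 0.5)
  closed <- mouth; closed[c(5, 6), ] <- mouth[c(3, 2), ]
  expect_equal(landmark_mar(closed), 0)
})

test_that("frame classification applies the boundary rules", {
  cls <- classify_frame(ear = c(0.25, 0.21, 0.15), mar = c(0.45, 0.4, 0.1))
  expect_identical(cls$eye_closed, c(FALSE, TRUE, TRUE))   # 0.21 counts closed
  expect_identical(cls$mouth_open, c(TRUE, FALSE, FALSE))  # 0.4 counts closed
  expect_error(classify_frame(-0.1, 0.2), "non-negative")
})

test_that("threshold sweep returns the exhaustive-accuracy argmax", {
  values <- c(0.3, 0.4, 0.1, 0.15)
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  grid <- seq(0.05, 0.45, by = 0.05)
  # exhaustive oracle over the grid
  acc <- vapply(grid, function(t) mean((values > t) == labels), numeric(1))
  sw <- sweep_threshold(values, labels, grid)
  expect_equal(sw$curve$accuracy, acc)
  expect_equal(sw$accuracy, 1)
  # under the "value > t = open" rule, t = 0.15 already classifies the
  # closed 0.15 sample correctly, so it is the smallest perfect grid point
  expect_equal(sw$threshold, 0.15)
  # degenerate: identical labels saturate at a grid end
  all_open <- sweep_threshold(c(0.3, 0.4), c(TRUE, TRUE), grid)
  expect_equal(all_open$accuracy, 1)
  expect_equal(all_open$threshold, grid[1])
})

test_that("image-based EAR recovers known column geometry", {
  # 12-px white column in a black crop, eye width 40 -> H = 12, EAR = 0.3
  img <- matrix(0, 60, 50)
  img[20:31, 25] <- 255
  eye <- rbind(c(5, 25), c(15, 18), c(35, 18), c(45, 25), c(35, 32),
               c(15, 32))
  r <- improved_ear(eye, img, sigma = 0)
  expect_equal(r$crop$h, 12)
  expect_equal(r$crop$m, 255 * 12)
  expect_equal(r$ear, 12 / 40)
  # all-background crop: EAR 0, not an error
  expect_equal(improved_ear(eye, matrix(0, 60, 50))$ear, 0)
  # crop outside the frame
  expect_error(improved_ear(eye, matrix(0, 60, 20)), "outside")
})

test_that("image-based EAR recovers ellipse openness within 0.03 across tilts", {
  for (ba in seq(0.05, 0.5, by = 0.05)) {
    for (tilt in c(-25, 0, 25)) {
      r <- render_eye_image(a = 40, b = 40 * ba, tilt = tilt)
      got <- improved_ear(r$eye, r$image)$ear
      expect_lt(abs(got - ba), 0.03)
    }
  }
})

test_that("tilt correction makes the image-based EAR tilt-invariant", {
  base <- improved_ear(render_eye_image(40, 12, 0)$eye,
                       render_eye_image(40, 12, 0)$image)$ear
  for (tilt in c(-20, -10, 10, 20)) {
    r <- render_eye_image(40, 12, tilt)
    expect_lt(abs(improved_ear(r$eye, r$image)$ear - base), 0.02)
  }
})

test_that("image-based EAR beats noisy landmarks on the same instances", {
  # landmark EAR from jittered points vs image EAR from the rendered frame
  set.seed(77)
  err_lm <- err_img <- c()
  for (i in 1:30) {
    ba <- runif(1, 0.1, 0.5)
    r <- render_eye_image(a = 40, b = 40 * ba)
    noisy_eye <- r$eye + matrix(rnorm(12, sd = 1.5), 6, 2)
    # landmark EAR measures lid distance at the +/- a/2 columns, whose
    # geometric value is sqrt(3)/2 * b/a on the ellipse
    err_lm <- c(err_lm, abs(landmark_ear(noisy_eye) / (sqrt(3) / 2) - ba))
    err_img <- c(err_img, abs(improved_ear(r$eye, r$image)$ear - ba))
  }
  expect_lt(mean(err_img), mean(err_lm))
})

test_that("dark-polarity mode measures dark eyes on bright skin", {
  r <- render_eye_image(a = 40, b = 12)
  inverted <- 255 - r$image
  expect_equal(improved_ear(r$eye, inverted, polarity = "dark")$ear,
               improved_ear(r$eye, r$image, polarity = "bright")$ear)
  # auto agrees with the correct explicit polarity on both renderings
  expect_equal(improved_ear(r$eye, inverted)$ear,
               improved_ear(r$eye, r$image)$ear)
})

test_that("observation extraction averages both eyes and honours validity", {
  spec <- scenario_spec(duration = 4, fps = 10, jitter_sd = 0, seed = 3)
  stream <- generate_stream(spec, window_seconds = 2)
  obs <- extract_observations(stream$landmarks)
  expect_equal(nrow(obs), 40)
  open_frames <- !stream$truth$eye_closed
  expect_equal(obs$ear[open_frames], rep(0.30, sum(open_frames)),
               tolerance = 1e-6)
  expect_identical(obs$eye_closed, stream$truth$eye_closed)
  # invalid frames get NA ratios
  lm <- stream$landmarks
  lm$valid[3] <- FALSE
  obs2 <- extract_observations(lm)
  expect_true(is.na(obs2$ear[3]))
  expect_false(obs2$valid[3])
})
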