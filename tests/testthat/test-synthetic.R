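# Synthetic fixtures: rendered eyes, landmark streams, training tables.

test_that("rendered eye images carry consistent geometry and landmarks", {
  r <- render_eye_image(a = 30, b = 9, tilt = 0)
  expect_equal(r$true_ear, 0.3)
  expect_equal(sqrt(sum((r$eye[4, ] - r$eye[1, ])^2)), 60)  # |P1-P4| = 2a
  expect_true(all(r$image %in% c(0, 255)))
  # closed eye renders no bright region
  r0 <- render_eye_image(a = 30, b = 0)
  expect_equal(r0$true_ear, 0)
  expect_true(all(r0$image == 0))
  expect_error(render_eye_image(a = 0, b = 0), "a > 0")
  expect_error(render_eye_image(a = 30, b = 9, image_size = c(10, 10)),
               "fit")
})

test_that("tilted renders preserve the landmark-extreme placement", {
  r <- render_eye_image(a = 30, b = 9, tilt = 20)
  # corners stay 2a apart and the P1->P4 angle equals the tilt
  d <- r$eye[4, ] - r$eye[1, ]
  expect_equal(sqrt(sum(d^2)), 60)
  expect_equal(atan2(d[2], d[1]) * 180 / pi, 20, ignore_attr = TRUE)
})

test_that("streams are reproducible and schedule-consistent", {
  spec <- scenario_spec(duration = 120, fps = 10, seed = 8,
                        schedule = data.frame(start_s = c(0, 60),
                                              end_s = c(60, 120),
                                              state = c("awake", "fatigue")))
  s1 <- generate_stream(spec, window_seconds = 60)
  s2 <- generate_stream(spec, window_seconds = 60)
  expect_identical(s1, s2)
  # window labels recomputed from per-frame truth match the emitted labels
  fpw <- 600
  relab <- vapply(seq_len(2), function(w) {
    idx <- ((w - 1) * fpw + 1):(w * fpw)
    as.integer(mean(s1$truth$state[idx] == "fatigue") > 0.5)
  }, integer(1))
  expect_identical(relab, s1$window_labels$label)
  expect_identical(s1$window_labels$label, c(0L, 1L))
})

test_that("schedule gaps and overlaps are rejected", {
  expect_error(scenario_spec(duration = 100,
                             schedule = data.frame(start_s = c(0, 60),
                                                   end_s = c(50, 100),
                                                   state = c("awake", "fatigue"))),
               "gaps")
  expect_error(scenario_spec(duration = 100,
                             schedule = data.frame(start_s = 0, end_s = 90,
                                                   state = "awake")),
               "cover")
})

test_that("awake scenario-1 windows show only short blinks", {
  spec <- scenario_spec(duration = 600, fps = 10, noise_rate = 0, seed = 31)
  stream <- generate_stream(spec, window_seconds = 60)
  obs <- extract_observations(stream$landmarks)
  feats <- stream_window_features(frame_series(obs, 0.1), 60)
  expect_identical(stream$window_labels$label, rep(0L, 10))
  expect_true(all(feats$yawn_count == 0))
  expect_true(all(feats$perclos < 0.1))
  expect_true(all(feats$longest_closure < 1))
})

test_that("fatigue spans produce sustained closures and yawns", {
  spec <- scenario_spec(duration = 600, fps = 10, seed = 13,
                        schedule = data.frame(start_s = 0, end_s = 600,
                                              state = "fatigue"))
  stream <- generate_stream(spec, window_seconds = 60)
  feats <- stream_window_features(
    frame_series(extract_observations(stream$landmarks), 0.1), 60)
  expect_gt(mean(feats$longest_closure), 2)
  expect_gt(sum(feats$yawn_count), 0)
  expect_gt(mean(feats$perclos), 0.15)
})

test_that("expression noise depresses EAR in awake spans only", {
  spec <- scenario_spec(duration = 300, fps = 10, noise_rate = 2, seed = 17)
  stream <- generate_stream(spec, window_seconds = 60)
  expect_gt(sum(stream$truth$noise), 0)
  obs <- extract_observations(stream$landmarks)
  noisy <- stream$truth$noise & !is.na(obs$ear)
  expect_true(all(obs$ear[noisy] < 0.21))
  # the noise-free generator never sets the flag
  clean <- generate_stream(scenario_spec(duration = 120, fps = 10,
                                         noise_rate = 0, seed = 17), 60)
  expect_identical(sum(clean$truth$noise), 0L)
})

test_that("training tables have exact class counts and stated ranges", {
  ts <- generate_training_set(500, fatigue_fraction = 0.7, seed = 4)
  expect_identical(sum(ts$label == 1), 350L)
  expect_identical(sum(ts$label == 0), 150L)
  small <- generate_training_set(10, fatigue_fraction = 0.5, seed = 4)
  expect_identical(unname(table(small$label)), c(5L, 5L),
                   ignore_attr = TRUE)
  awake <- ts[ts$label == 0, ]
  fatigue <- ts[ts$label == 1, ]
  expect_true(all(awake$longest_closure < 1 & awake$yawn_count == 0 &
                    awake$perclos < 0.1))
  expect_true(all(fatigue$longest_closure > 2.5 & fatigue$yawn_count >= 1 &
                    fatigue$perclos > 0.3))
  expect_error(generate_training_set(100, fatigue_fraction = 1.2),
               "fatigue_fraction")
  expect_identical(generate_training_set(100, seed = 3),
                   generate_training_set(100, seed = 3))
})

test_that("training-table marginals match their sampling distributions", {
  ts <- generate_training_set(2000, fatigue_fraction = 0.5, seed = 10)
  awake <- ts[ts$label == 0, ]
  fatigue <- ts[ts$label == 1, ]
  expect_gt(stats::ks.test(awake$longest_closure,
                           "punif", 0.1, 0.9)$p.value, 0.01)
  expect_gt(stats::ks.test(fatigue$perclos,
                           "punif", 0.31, 0.55)$p.value, 0.01)
})
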