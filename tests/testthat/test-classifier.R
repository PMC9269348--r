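# The per-window fatigue classifier: hidden-layer sizing, training,
# prediction, comparison harness, serialization.

train_fixture <- function(n = 400, seed = 2)
  generate_training_set(n, fatigue_fraction = 0.5, seed = seed)

test_that("hidden-node sizing rule gives the expected candidate sets", {
  # i = 3, j = 1: sqrt(4) + 1..10 = 3..12, containing the usual 3..8 range
  expect_identical(hidden_node_candidates(3, 1), 3:12)
  expect_true(all(3:8 %in% hidden_node_candidates(3, 1)))
  expect_identical(hidden_node_candidates(8, 8), 5:14)
  expect_identical(hidden_node_candidates(3, 1, form = "linear"), 5:14)
  expect_error(hidden_node_candidates(0, 1), "positive")
})

test_that("training on separable windows reaches high held-out accuracy", {
  ts <- train_fixture()
  fit <- fatigue_net(ts[, 1:3], ts$label, epochs = 300, seed = 0)
  held_out <- train_fixture(200, seed = 99)
  acc <- mean(predict(fit, held_out[, 1:3])$state == held_out$label)
  expect_gte(acc, 0.95)
  # history exposes per-epoch train/validation loss and accuracy
  expect_identical(nrow(fit$history), 300L)
  expect_true(all(c("train_loss", "val_loss", "train_acc", "val_acc") %in%
                    names(fit$history)))
})

test_that("permuted labels collapse validation accuracy to chance", {
  ts <- train_fixture()
  set.seed(5)
  fitp <- fatigue_net(ts[, 1:3], sample(ts$label), epochs = 300, seed = 0)
  val_acc <- fitp$history$val_acc[300]
  expect_lt(abs(val_acc - 0.5), 0.1)
})

test_that("training is deterministic given the seed", {
  ts <- train_fixture(100)
  f1 <- fatigue_net(ts[, 1:3], ts$label, epochs = 40, seed = 0)
  f2 <- fatigue_net(ts[, 1:3], ts$label, epochs = 40, seed = 0)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$history, f2$history)
})

test_that("degenerate training inputs are rejected", {
  ts <- train_fixture(50)
  expect_error(fatigue_net(ts[, 1:3], rep(1, 50)), "single class")
  bad <- ts
  bad$perclos[1] <- NaN
  expect_error(fatigue_net(bad[, 1:3], bad$label), "non-finite")
})

test_that("prediction recovers cluster membership and applies the tie rule", {
  ts <- train_fixture()
  fit <- fatigue_net(ts[, 1:3], ts$label, epochs = 300, seed = 0)
  deep_fatigue <- data.frame(longest_closure = 5, yawn_count = 2,
                             perclos = 0.5)
  deep_awake <- data.frame(longest_closure = 0.2, yawn_count = 0,
                           perclos = 0.02)
  expect_identical(predict(fit, deep_fatigue)$state, 1L)
  expect_identical(predict(fit, deep_awake)$state, 0L)
  expect_error(predict(fit, data.frame(longest_closure = NA_real_,
                                       yawn_count = 0, perclos = 0)),
               "non-finite")
  # probability exactly 0.5 (all-zero network) counts awake
  null_net <- fit
  null_net$w1[] <- 0; null_net$b1[] <- 0; null_net$w2[] <- 0; null_net$b2 <- 0
  p <- predict(null_net, deep_fatigue)
  expect_equal(p$probability, 0.5)
  expect_identical(p$state, 0L)
})

test_that("prediction is invariant to consistent affine feature re-encoding", {
  ts <- train_fixture(200)
  fit_s <- fatigue_net(ts[, 1:3], ts$label, epochs = 100, seed = 0)
  rescaled <- ts
  rescaled$longest_closure <- rescaled$longest_closure * 1000 + 7  # ms + offset
  fit_ms <- fatigue_net(rescaled[, 1:3], rescaled$label, epochs = 100,
                        seed = 0)
  probe <- train_fixture(50, seed = 123)
  probe_ms <- probe
  probe_ms$longest_closure <- probe_ms$longest_closure * 1000 + 7
  expect_equal(predict(fit_s, probe[, 1:3])$probability,
               predict(fit_ms, probe_ms[, 1:3])$probability,
               tolerance = 1e-10)
})

test_that("hidden-node comparison tabulates one seeded run per size", {
  ts <- train_fixture(120)
  tab <- compare_hidden_nodes(ts[, 1:3], ts$label, node_list = 3:8,
                              epochs = 60, seed = 0)
  expect_identical(nrow(tab), 6L)
  expect_identical(tab$hidden, 3:8)
  expect_true(all(is.finite(tab$train_acc)))
  # single-size call agrees with a direct fit under the same seed
  one <- compare_hidden_nodes(ts[, 1:3], ts$label, node_list = 4,
                              epochs = 60, seed = 0)
  direct <- fatigue_net(ts[, 1:3], ts$label, hidden = 4, epochs = 60,
                        seed = 0)
  expect_equal(one$train_acc, direct$history$train_acc[60])
  # on separable data, capacity never hurts training accuracy (within 0.02)
  expect_true(all(tab$train_acc >= max(tab$train_acc) - 0.02))
})

test_that("JSON round-trip preserves predictions bit for bit", {
  ts <- train_fixture(150)
  fit <- fatigue_net(ts[, 1:3], ts$label, epochs = 80, seed = 0)
  path <- withr::local_tempfile(fileext = ".json")
  write_fatigue_net(fit, path)
  back <- read_fatigue_net(path)
  probes <- train_fixture(100, seed = 321)
  expect_identical(predict(fit, probes[, 1:3])$probability,
                   predict(back, probes[, 1:3])$probability)
  other <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), other)
  expect_error(read_fatigue_net(other), "not a serialized")
})

test_that("an independent single-hidden-layer fit agrees on the fixture", {
  skip_if_not_installed("nnet")
  ts <- train_fixture()
  fit <- fatigue_net(ts[, 1:3], ts$label, epochs = 300, seed = 0)
  held_out <- train_fixture(200, seed = 99)
  set.seed(0)
  ref <- nnet::nnet(as.matrix(scale(ts[, 1:3])), ts$label, size = 4,
                    entropy = TRUE, maxit = 500, trace = FALSE)
  ref_pred <- as.integer(predict(ref, scale(held_out[, 1:3],
    center = attr(scale(ts[, 1:3]), "scaled:center"),
    scale = attr(scale(ts[, 1:3]), "scaled:scale"))) > 0.5)
  own_pred <- predict(fit, held_out[, 1:3])$state
  expect_gte(mean(ref_pred == held_out$label), 0.95)
  expect_gte(mean(ref_pred == own_pred), 0.95)
})
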