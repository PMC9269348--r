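# Independent brute-force oracles used across the suite.

# longest run of TRUE, by explicit scan
oracle_longest_run <- function(flag) {
  best <- cur <- 0L
  for (v in flag) {
    cur <- if (isTRUE(v)) cur + 1L else 0L
    best <- max(best, cur)
  }
  best
}

# number of maximal TRUE runs of length >= min_len, by explicit scan
oracle_count_runs <- function(flag, min_len) {
  n_runs <- 0L
  cur <- 0L
  for (v in c(flag, FALSE)) {
    if (isTRUE(v)) cur <- cur + 1L
    else {
      if (cur >= min_len) n_runs <- n_runs + 1L
      cur <- 0L
    }
  }
  n_runs
}

# literal term-by-term evaluation of the accumulation sum
oracle_accumulation <- function(x) {
  sig <- function(z) 1 / (1 + exp(-z))
  terms <- vapply(x, function(xi) xi * sig(xi) - (1 - xi) * sig(xi),
                  numeric(1))
  sum(terms) / length(x)
}

# all 0/1 vectors of length n as rows
all_binary_vectors <- function(n) {
  as.matrix(expand.grid(rep(list(0:1), n)))
}

# observation table for a frame series fixture
obs_table <- function(eye_closed, mouth_open = rep(FALSE, length(eye_closed)),
                      valid = rep(TRUE, length(eye_closed))) {
  data.frame(frame_index = seq_along(eye_closed),
             eye_closed = eye_closed, mouth_open = mouth_open, valid = valid)
}

# classifier trained on stream-derived window features (scenario 1,
# alternating awake/fatigue spans), cached per session
stream_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sched <- data.frame(start_s = seq(0, 1680, by = 240),
                          end_s = seq(240, 1920, by = 240),
                          state = rep(c("awake", "fatigue"), 4))
      tr <- generate_stream(scenario_spec(duration = 1920, fps = 10,
                                          schedule = sched, seed = 21),
                            window_seconds = 60)
      feats <- stream_window_features(
        frame_series(extract_observations(tr$landmarks), 0.1), 60)
      cache <<- fatigue_net(feats[, c("longest_closure", "yawn_count",
                                      "perclos")],
                            tr$window_labels$label, epochs = 300, seed = 0)
    }
    cache
  }
})

# small fitted classifier on the separable fixture, cached per session
separable_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ts <- generate_training_set(n_windows = 300, fatigue_fraction = 0.5,
                                  seed = 11)
      cache <<- fatigue_net(ts[, c("longest_closure", "yawn_count", "perclos")],
                            ts$label, hidden = 4, epochs = 300, seed = 0)
    }
    cache
  }
})
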