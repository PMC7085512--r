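# a synthetic trial plus its per-sensor force matrix and full-set events
placement_fixture <- function(n_strides = 6, seed = 41, layout = default_layout(),
                              noise_sd = 0, lag_tau = 0) {
  cfg <- gait_sim_config(n_strides = n_strides, seed = seed,
                         noise_sd = noise_sd, lag_tau = lag_tau)
  trial <- simulate_trial(cfg, layout = layout)
  sig <- process_stream(trial$insole, trial$cal, trial$layout)
  forces <- matrix(force_from_voltage(trial$cal, as.numeric(trial$insole$frames)),
                   nrow = nrow(trial$insole$frames))
  list(trial = trial, sig = sig, forces = forces,
       events = detect_events(sig))
}

test_that("heel sensors top the HS ranking; inactive sensors rank last", {
  fx <- placement_fixture()
  lay <- fx$trial$layout
  rk <- rank_sensors(fx$forces, fx$trial$insole$timestamps, fx$events,
                     sensor_ids = lay$positions$id)
  heel_ids <- lay$positions$id[lay$positions$ap < 5]
  toe_ids <- lay$positions$id[lay$positions$ap > 20]
  expect_true(rk$hs$id[1] %in% heel_ids)
  expect_true(rk$to$id[1] %in% toe_ids)
  expect_true(all(rk$hs$latency >= 0 | !is.finite(rk$hs$latency)))
  # a sensor that never fires gets sentinel latency and the last rank
  forces2 <- cbind(fx$forces, 0)
  rk2 <- rank_sensors(forces2, fx$trial$insole$timestamps, fx$events,
                      sensor_ids = c(lay$positions$id, 99L))
  expect_equal(rk2$hs$id[nrow(rk2$hs)], 99L)
  expect_true(is.infinite(rk2$hs$latency[nrow(rk2$hs)]))
})

test_that("a constructed fast sensor outranks a slow one", {
  fx <- placement_fixture()
  ts <- fx$trial$insole$timestamps
  fast <- slow <- numeric(length(ts))
  for (s in seq_len(nrow(fx$events))) {
    hs <- fx$events$hs_time[s]
    fast[ts >= hs & ts <= hs + 0.5] <- 20
    slow[ts >= hs + 0.06 & ts <= hs + 0.5] <- 20
  }
  rk <- rank_sensors(cbind(fast, slow), ts, fx$events, sensor_ids = 1:2)
  expect_equal(rk$hs$id, c(1L, 2L))
  expect_equal(rk$hs$latency[rk$hs$id == 1], 0)
  expect_gt(rk$hs$latency[rk$hs$id == 2], 0.05)
})

test_that("evaluating the full set against itself is exactly zero", {
  fx <- placement_fixture(noise_sd = 0.005, lag_tau = 0.02)
  lay <- fx$trial$layout
  res <- evaluate_subset(lay$positions$id, fx$trial$insole, fx$trial$cal, lay)
  expect_equal(res$n_pairs, res$n_full)
  expect_true(all(res$diffs$hs_diff == 0))
  expect_true(all(res$diffs$to_diff == 0))
  expect_equal(res$frac_hs, 1)
  expect_equal(res$frac_to, 1)
})

test_that("removing all heel sensors delays heel-strike detection", {
  fx <- placement_fixture()
  lay <- fx$trial$layout
  no_heel <- lay$positions$id[lay$positions$ap >= 5]
  res <- evaluate_subset(no_heel, fx$trial$insole, fx$trial$cal, lay)
  expect_gt(stats::median(res$diffs$hs_diff), 0)
})

test_that("subset validation errors are raised", {
  fx <- placement_fixture(n_strides = 2)
  lay <- fx$trial$layout
  expect_error(evaluate_subset(integer(0), fx$trial$insole, fx$trial$cal, lay),
               "non-empty")
  expect_error(evaluate_subset(c(1L, 999L), fx$trial$insole, fx$trial$cal, lay),
               "contained")
  # a stream where the chosen sensor never activates
  quiet <- voltage_stream(fx$trial$insole$timestamps,
                          matrix(0, nrow(fx$trial$insole$frames), 16), 100)
  expect_error(evaluate_subset(1L, quiet, fx$trial$cal, lay), "active")
})

test_that("adding sensors never worsens HS latency on noiseless input", {
  fx <- placement_fixture()
  lay <- fx$trial$layout
  ord <- order(lay$positions$ap)  # grow the subset from the heel forward
  med_lag <- vapply(c(4, 8, 12, 16), function(k) {
    res <- evaluate_subset(lay$positions$id[ord[seq_len(k)]],
                           fx$trial$insole, fx$trial$cal, lay)
    stats::median(res$diffs$hs_diff)
  }, numeric(1))
  expect_true(all(diff(med_lag) <= 1e-9))
})

test_that("a 16-sensor subset of a dense grid stays synchronous", {
  # 64-sensor grid: 16 AP stations x 4 medio-lateral columns
  grid <- expand.grid(ap = seq(1.5, 24.5, length.out = 16),
                      ml = c(-3, -1, 1, 3))
  lay64 <- insole_layout(data.frame(id = seq_len(64), ap = grid$ap,
                                    ml = grid$ml), 26)
  fx <- placement_fixture(n_strides = 8, layout = lay64,
                          noise_sd = 0.005, lag_tau = 0)
  rk <- rank_sensors(fx$forces, fx$trial$insole$timestamps, fx$events,
                     sensor_ids = lay64$positions$id)
  subset16 <- unique(c(rk$hs$id[1:8], rk$to$id[1:8]))
  res <- evaluate_subset(subset16, fx$trial$insole, fx$trial$cal, lay64)
  expect_gte(res$frac_hs, 0.9)
  expect_gte(res$frac_to, 0.9)
})
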