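cfg <- gait_sim_config()

test_that("vGRF template has contact zeros, stated peaks and an M shape", {
  expect_equal(vgrf_template(0, cfg), 0)
  expect_equal(vgrf_template(1, cfg), 0)
  tau <- seq(0, 1, length.out = 2001)
  f <- vgrf_template(tau, cfg)
  bw <- cfg$body_mass * 9.81
  expect_lt(abs(max(f) - cfg$peak1 * bw) / (cfg$peak1 * bw), 0.01)
  # mid-stance valley at the configured depth
  expect_equal(vgrf_template(0.5, cfg), cfg$valley * bw, tolerance = 1e-9)
  expect_true(all(f >= 0))
  expect_equal(vgrf_template(c(-0.1, 1.1), cfg), c(0, 0))
})

test_that("CoP template is a monotone ramp with exact endpoints", {
  L <- cfg$foot_length
  expect_equal(cop_template(0, cfg), cfg$cop_start * L)
  expect_equal(cop_template(1, cfg), cfg$cop_end * L)
  expect_equal(cop_template(0.5, cfg), (cfg$cop_start + cfg$cop_end) / 2 * L)
  tau <- seq(0, 1, length.out = 500)
  expect_true(all(diff(cop_template(tau, cfg)) > 0))
})

test_that("force allocation conserves, concentrates and is CoP-consistent", {
  lay <- default_layout()
  cal <- tactel_calibration()
  expect_equal(allocate_tactel_forces(0, 10, lay, 3), numeric(16))
  # conservation across random targets
  set.seed(19)
  for (i in 1:20) {
    total <- runif(1, 1, 500)
    cop <- runif(1, 2, 24)
    f <- allocate_tactel_forces(total, cop, lay, 3, f_cap = cal$f_saturation)
    expect_lt(abs(sum(f) - total), 1e-6)
    expect_true(all(f <= cal$f_saturation + 1e-9))
  }
  # tight kernel on an isolated tactel: >= 99% of force lands there
  j <- which(lay$positions$ap == 12)  # isolated midfoot sensor
  f <- allocate_tactel_forces(30, 12, lay, spread = 0.3)
  expect_gt(f[j] / sum(f), 0.99)
  # CoP of allocated forces returns the target within spread/4 (uniform weights)
  ulay <- insole_layout(data.frame(id = 1:13, ap = seq(1, 25, by = 2)), 26)
  for (cop in c(8, 13, 18)) {
    f <- allocate_tactel_forces(100, cop, ulay, spread = 3)
    expect_lt(abs(oracle_cop(f, rep(1, 13), ulay$positions$ap) - cop), 3 / 4)
  }
  # all-saturated case warns and caps
  expect_warning(f <- allocate_tactel_forces(16 * 45 + 10, 13, lay, 3,
                                             f_cap = 45), "capped")
  expect_equal(f, rep(45, 16))
})

test_that("same seed gives bit-identical trials and restores caller RNG", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  t1 <- simulate_trial(gait_sim_config(n_strides = 3, seed = 77))
  after <- runif(1)
  expect_identical(before, after)  # caller RNG untouched
  t2 <- simulate_trial(gait_sim_config(n_strides = 3, seed = 77))
  expect_identical(t1$insole$frames, t2$insole$frames)
  expect_identical(t1$reference$vgrf, t2$reference$vgrf)
  t3 <- simulate_trial(gait_sim_config(n_strides = 3, seed = 78))
  expect_false(identical(t1$insole$frames, t3$insole$frames))
})

test_that("noiseless lag-free processing recovers the true coupled vGRF", {
  cfg1 <- gait_sim_config(n_strides = 5, noise_sd = 0, lag_tau = 0,
                          coupling = 1)
  trial <- simulate_trial(cfg1)
  sig <- process_stream(trial$insole, trial$cal, trial$layout)
  truth <- trial$truth_insole$force
  sel <- truth > 50  # away from threshold crossings and the dead band
  expect_lt(max(abs(sig$vgrf[sel] - truth[sel]) / truth[sel]), 0.01)
})

test_that("ground-truth events agree with reference-side detection", {
  trial <- simulate_trial(gait_sim_config(n_strides = 6, seed = 5))
  ref_sig <- gait_signals(trial$reference$timestamps, trial$reference$vgrf,
                          trial$reference$cop_ap, 200,
                          trial$reference$event_threshold)
  ev <- detect_events(ref_sig)
  expect_equal(nrow(ev), 6L)
  expect_lt(max(abs(ev$hs_time - trial$truth$hs_time)), 1 / 200 + 1e-9)
  expect_lt(max(abs(ev$to_time - trial$truth$to_time)), 1 / 200 + 1e-9)
})

test_that("true CoP is monotone within stance and processing tracks it", {
  cfg0 <- gait_sim_config(n_strides = 5, noise_sd = 0, lag_tau = 0)
  trial <- simulate_trial(cfg0)
  ti <- trial$truth_insole
  for (s in seq_len(nrow(trial$truth))) {
    sel <- ti$timestamps >= trial$truth$hs_time[s] &
      ti$timestamps <= trial$truth$to_time[s]
    expect_true(all(diff(ti$cop[sel]) >= -1e-9))
  }
  sig <- process_stream(trial$insole, trial$cal, trial$layout)
  ok <- is.finite(sig$cop_ap) & is.finite(ti$cop)
  expect_gt(stats::cor(sig$cop_ap[ok], ti$cop[ok]), 0.99)
})

test_that("sensor lag delays heel-strike detection (positive median lag)", {
  trial <- simulate_trial(gait_sim_config(n_strides = 10, seed = 21))
  sig <- process_stream(trial$insole, trial$cal, trial$layout)
  ev <- detect_events(sig)
  expect_equal(nrow(ev), 10L)
  expect_gt(stats::median(ev$hs_time - trial$truth$hs_time), 0)
})

test_that("config invariants are enforced", {
  expect_error(gait_sim_config(stance_fraction = 1.2))
  expect_error(gait_sim_config(noise_sd = -1))
  expect_error(gait_sim_config(valley = 3))  # valley above the peaks
  expect_error(gait_sim_config(coupling = 0))
  expect_error(gait_sim_config(peak_pos = c(0.75, 0.25)))
})
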