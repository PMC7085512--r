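test_that("alignment decimates the reference onto the insole timeline", {
  # coincident grids, zero offset: node lookup is exact
  t100 <- seq(0, 3, by = 0.01)
  t200 <- seq(0, 3, by = 0.005)
  s100 <- sin(2 * pi * 5 * t100)
  s200 <- sin(2 * pi * 5 * t200)
  insole <- gait_signals(t100, abs(s100) * 30 + 25, rep(NaN, length(t100)),
                         100, 3)
  ref <- reference_recording(t200, abs(s200) * 30 + 25, s200 * 5 + 10, 200, 20)
  al <- align_and_resample(insole, ref, trigger_offset = 0)
  expect_equal(al$ref$vgrf, insole$vgrf, tolerance = 1e-12)
  expect_equal(al$ref$cop_ap, s100 * 5 + 10, tolerance = 1e-6)
  expect_error(align_and_resample(insole, ref, trigger_offset = 100),
               "overlap")
})

test_that("a known trigger offset is corrected by alignment", {
  trial <- simulate_trial(gait_sim_config(n_strides = 5, seed = 4))
  sig <- process_stream(trial$insole, trial$cal, trial$layout)
  ref <- trial$reference
  base <- validate_recordings(sig, ref, 66.2, trigger_offset = 0)
  # shift the reference clock by a quarter second, then tell align about it
  ref_shift <- reference_recording(ref$timestamps - 0.25, ref$vgrf,
                                   ref$cop_ap, 200, 20)
  fixed <- validate_recordings(sig, ref_shift, 66.2, trigger_offset = 0.25)
  expect_equal(fixed$events$mae_hs, base$events$mae_hs, tolerance = 1e-9)
  expect_equal(fixed$events$mae_to, base$events$mae_to, tolerance = 1e-9)
})

test_that("event MAE identities and constructed shifts", {
  ref <- stride_table(hs_time = c(0, 1, 2, 3), to_time = c(0.6, 1.6, 2.6, 3.6))
  expect_equal(event_mae(ref, ref)$mae_hs, 0)
  expect_equal(event_mae(ref, ref)$mae_stance, 0)
  # insole HS uniformly 3 samples late at 100 Hz
  late <- stride_table(ref$hs_time + 0.03, ref$to_time)
  m <- event_mae(ref, late)
  expect_equal(m$mae_hs, 0.03)
  expect_equal(m$mae_hs_pct, 0.03 / 0.6 * 100)  # 5% of stance
  expect_equal(m$mae_to, 0)
  expect_equal(m$n_pairs, 4L)
  # symmetric in sign and invariant to stride reordering (median of |x|)
  early <- stride_table(ref$hs_time - 0.03, ref$to_time)
  expect_equal(event_mae(ref, early)$mae_hs, 0.03)
  shuffled <- ref[c(3, 1, 4, 2), ]
  class(shuffled) <- class(ref)
  expect_equal(event_mae(shuffled, late)$mae_hs, 0.03)
  # no pairable strides
  far <- stride_table(ref$hs_time + 10, ref$to_time + 10)
  expect_equal(event_mae(ref, far)$n_pairs, 0L)
  expect_true(is.na(event_mae(ref, far)$mae_hs))
})

test_that("stance profiles are time-normalized faithfully", {
  fs <- 100
  ts <- seq(0, 5, by = 1 / fs)
  # constant signal -> constant profile
  sigc <- gait_signals(ts, rep(50, length(ts)), rep(7, length(ts)), fs, 3)
  tabc <- stride_table(1, 1.6)
  prof <- stance_profiles(sigc, tabc, "cop_ap", lowpass_cutoff = Inf)
  expect_equal(as.numeric(prof), rep(7, 101))
  # two strides of different duration from one template -> same profile
  template <- function(tau) 30 * sin(pi * tau)^2 + 5
  vgrf <- numeric(length(ts))
  s1 <- ts >= 0.5 & ts <= 1.1
  s2 <- ts >= 2.0 & ts <= 3.0
  vgrf[s1] <- template((ts[s1] - 0.5) / 0.6)
  vgrf[s2] <- template((ts[s2] - 2.0) / 1.0)
  sig <- gait_signals(ts, vgrf, rep(NaN, length(ts)), fs, 3)
  tab <- stride_table(c(0.5, 2.0), c(1.1, 3.0))
  p <- stance_profiles(sig, tab, "vgrf", lowpass_cutoff = Inf)
  expect_equal(p[1, ], p[2, ], tolerance = 0.02)
  # identity configuration: no filter, n_points = stance sample count
  seg <- vgrf[s2]
  p_id <- stance_profiles(sig, stride_table(2.0, 3.0), "vgrf",
                          n_points = sum(s2), lowpass_cutoff = Inf)
  expect_equal(as.numeric(p_id), seg, tolerance = 1e-9)
  # too-short stances are skipped with a warning
  expect_warning(
    short <- stance_profiles(sig, stride_table(0.5, 0.51), "vgrf",
                             lowpass_cutoff = Inf),
    "skipped")
  expect_equal(nrow(short), 0L)
})

test_that("zero-phase low-pass keeps slow components and kills fast ones", {
  fs <- 100
  ts <- seq(0, 10, by = 1 / fs)
  slow <- sin(2 * pi * 2 * ts)
  fast <- sin(2 * pi * 45 * ts)
  y <- lowpass_zero_phase(slow + fast, fs, cutoff = 20, order = 4)
  mid <- 101:900  # away from edges
  expect_lt(max(abs(y[mid] - slow[mid])), 0.02)
  # zero phase: cross-correlation peak at zero lag
  cc <- stats::ccf(y[mid], slow[mid], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("profile agreement identities hold", {
  set.seed(8)
  base <- matrix(rep(sin(seq(0, pi, length.out = 101)), 3), 3, byrow = TRUE)
  a <- profile_agreement(base, base)
  expect_equal(a$rho, 1)
  expect_equal(a$rmse, 0)
  expect_equal(profile_agreement(base, -base)$rho, -1)
  # constant 2 cm offset: perfect correlation, RMSE exactly 2
  off <- profile_agreement(base, base + 2)
  expect_equal(off$rho, 1)
  expect_equal(off$rmse, 2)
  # Pearson rho invariant to affine rescaling
  expect_equal(profile_agreement(base, base * 3.7 + 1.2)$rho, 1)
  # zero-variance profile flagged
  flat <- matrix(5, 2, 101)
  zv <- profile_agreement(flat, base)
  expect_true(zv$zero_variance)
  expect_true(is.na(zv$rho))
})

test_that("repeatability RMSE closed forms", {
  prof <- matrix(rep(seq(2, 20, length.out = 101), 4), 4, byrow = TRUE)
  expect_equal(repeatability_rmse(prof, "cop"), 0)
  # two CoP profiles at +/- 1 cm around their mean
  two <- rbind(prof[1, ] + 1, prof[1, ] - 1)
  expect_equal(repeatability_rmse(two, "cop"), 1)
  # vGRF strides scaled +/-10% around a template
  tpl <- 600 * sin(seq(0.1, pi - 0.1, length.out = 101))^2 + 50
  scaled <- rbind(tpl * 1.1, tpl * 0.9)
  r <- repeatability_rmse(scaled, "vgrf", body_mass = 66.2)
  expect_lt(abs(r - 10), 3)  # ~10% of the stride mean
  expect_warning(one <- repeatability_rmse(prof[1, , drop = FALSE], "cop"),
                 "fewer than 2")
  expect_true(is.na(one))
})

test_that("peak body-mass normalization arithmetic", {
  expect_equal(peak_bm_percent(650, 66.2), 650 / (66.2 * 9.81) * 100)
  expect_equal(round(peak_bm_percent(650, 66.2), 1), 100.1)
  expect_equal(peak_bm_percent(66.2 * 9.81, 66.2), 100)
  expect_error(peak_bm_percent(numeric(0), 66.2), "empty")
})

test_that("validating identical recordings gives perfect agreement", {
  trial <- simulate_trial(gait_sim_config(n_strides = 5, seed = 6))
  sig <- process_stream(trial$insole, trial$cal, trial$layout)
  # build a 'reference' that IS the insole signal at its own threshold
  ref <- reference_recording(sig$timestamps, sig$vgrf, sig$cop_ap,
                             sample_rate = 100,
                             event_threshold = sig$vgrf_thresh)
  rep <- validate_recordings(sig, ref, 66.2)
  expect_equal(rep$events$mae_hs, 0)
  expect_equal(rep$events$mae_to, 0)
  expect_equal(rep$agreement$rho_cop, 1, tolerance = 1e-9)
  expect_equal(rep$agreement$rmse_cop, 0, tolerance = 1e-9)
  expect_equal(rep$peaks$vgrf_peak_insole_bm_pct,
               rep$peaks$vgrf_peak_ref_bm_pct)
})
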