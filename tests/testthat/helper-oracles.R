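# Independent oracles, deliberately written differently from the package
# implementation paths they check.

# term-by-term quartic evaluation (package uses Horner form)
oracle_poly <- function(v, p = c(186.1, 224.5, 64.76, -18.59, 0)) {
  vapply(v, function(vi) sum(p * vi^c(4, 3, 2, 1, 0)), numeric(1))
}

# brute-force weighted-centroid CoP
oracle_cop <- function(forces, weights, ap) {
  num <- 0
  den <- 0
  for (i in seq_along(forces)) {
    num <- num + forces[i] * weights[i] * ap[i]
    den <- den + forces[i] * weights[i]
  }
  num / den
}

# synthesize noiseless load-unload curves from a calibration polynomial
make_curves <- function(n_curves, n_points = 60, noise_sd = 0, seed = 42,
                        cal = tactel_calibration()) {
  set.seed(seed)
  lapply(seq_len(n_curves), function(i) {
    v <- seq(-1, -0.02, length.out = n_points)
    v_noisy <- v + stats::rnorm(n_points, 0, noise_sd)
    f <- pmax(oracle_poly(v, c(cal$p)), 0)
    load_unload_curve(c(v_noisy, rev(v_noisy)), c(f, rev(f)),
                      c(rep("loading", n_points), rep("unloading", n_points)))
  })
}

# rectangular vGRF pulse train as gait_signals
pulse_signals <- function(level = 50, stance_s = 0.6, stride_s = 1.0,
                          n = 3, fs = 100, lead_s = 0.5, thresh = 3) {
  total <- lead_s * 2 + n * stride_s
  ts <- seq(0, total - 1 / fs, by = 1 / fs)
  vgrf <- numeric(length(ts))
  for (k in seq_len(n)) {
    hs <- lead_s + (k - 1) * stride_s
    vgrf[ts >= hs & ts < hs + stance_s] <- level
  }
  gait_signals(ts, vgrf, rep(NaN, length(ts)), sample_rate = fs,
               vgrf_thresh = thresh)
}
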