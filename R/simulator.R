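#' Synthetic gait trial configuration
#'
#' Parameters of the synthetic world the simulator generates: a walker of
#' given mass producing a classic double-bump ("M"-shaped) vGRF and a
#' monotone heel-to-toe CoP during each stance, sensed by a 16-tactel insole
#' through inverse transduction with first-order sensor lag and white
#' voltage noise, alongside a noiseless higher-rate reference device.
#'
#' Defaults describe a typical healthy adult of the validation cohort:
#' 66.2 kg body mass, 1.1 s stride time, 60% stance fraction, vGRF peaks of
#' 1.10/1.05 body weight at 25%/75% of stance with a 0.75 body-weight
#' mid-stance valley, CoP travelling from 10% to 85% of a 26 cm foot.
#' Sensor imperfections default to 5 mV voltage noise (consistent with the
#' -0.01 V noise-floor threshold) and a 20 ms lag time-constant standing in
#' for silicone viscoelasticity.
#'
#' The `coupling` parameter is the fraction of the total vGRF actually
#' transmitted to the sensorized area. A sparse 16-tactel insole only
#' samples the plantar regions under its sensors; the remainder of the load
#' passes through unsensorized sole. The default of 0.2 reproduces the
#' roughly 5:1 force-plate-to-insole amplitude ratio seen with this class of
#' device and keeps per-tactel forces inside the sensors' ~45 N range for a
#' typical adult; `coupling = 1` routes the whole load through the tactels
#' (useful for end-to-end identity checks, at the price of heavy sensor
#' saturation at adult body masses).
#'
#' @param body_mass kg.
#' @param stride_time s (HS to next HS).
#' @param stance_fraction stance share of the stride, in (0, 1).
#' @param n_strides number of strides.
#' @param foot_length cm.
#' @param peak1,peak2 vGRF peak heights, body-weight fractions.
#' @param peak_pos positions of the two peaks in normalized stance time.
#' @param valley mid-stance valley depth, body-weight fraction; must be
#'   below `(peak1 + peak2) / 2`.
#' @param ramp contact/release taper width, fraction of stance.
#' @param cop_start,cop_end CoP excursion, fractions of foot length.
#' @param cop_steepness logistic steepness of the CoP ramp.
#' @param spread Gaussian spread of the per-tactel force allocation, cm.
#' @param coupling fraction of the vGRF reaching the tactels, in (0, 1].
#' @param noise_sd white voltage noise, V.
#' @param lag_tau sensor lag time-constant, s (0 disables).
#' @param lag_asym unloading/loading lag ratio (> 1: slower release,
#'   emulating hysteresis asymmetry).
#' @param lead_in unloaded time before the first and after the last stride, s.
#' @param seed integer RNG seed.
#' @return A `gait_sim_config` list.
#' @export
gait_sim_config <- function(body_mass = 66.2, stride_time = 1.1,
                            stance_fraction = 0.60, n_strides = 10L,
                            foot_length = 26, peak1 = 1.10, peak2 = 1.05,
                            peak_pos = c(0.25, 0.75), valley = 0.75,
                            ramp = 0.05, cop_start = 0.10, cop_end = 0.85,
                            cop_steepness = 8, spread = 3, coupling = 0.2,
                            noise_sd = 0.005, lag_tau = 0.02, lag_asym = 1,
                            lead_in = 0.5, seed = 1L) {
  stopifnot(body_mass > 0, stride_time > 0,
            stance_fraction > 0, stance_fraction < 1,
            n_strides >= 0, foot_length > 0,
            peak1 > 0, peak2 > 0, valley > 0,
            valley < (peak1 + peak2) / 2,
            length(peak_pos) == 2L, peak_pos[1] < peak_pos[2],
            peak_pos[1] > 0, peak_pos[2] < 1,
            ramp > 0, ramp < min(peak_pos[1], 1 - peak_pos[2]),
            cop_start < cop_end, spread > 0,
            coupling > 0, coupling <= 1, noise_sd >= 0,
            lag_tau >= 0, lag_asym > 0, lead_in >= 0)
  structure(as.list(environment()), class = "gait_sim_config")
}

# smoothstep taper: 0 at x<=0, 1 at x>=1, C1-continuous
smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

#' Double-bump vGRF stance template
#'
#' Smooth "M"-shaped force profile over normalized stance time `tau` in
#' `[0, 1]`: two raised-cosine bumps at the configured peak positions whose
#' common half-width is solved so that the mid-point between the peaks
#' equals the configured valley depth, multiplied by a smoothstep taper that
#' forces exact zeros at contact and release. Peak heights are attained
#' exactly (the bumps do not overlap the opposite peak).
#'
#' @param tau normalized stance time(s) in `[0, 1]` (values outside return 0).
#' @param cfg a [gait_sim_config()].
#' @return Force, N.
#' @export
vgrf_template <- function(tau, cfg) {
  bw <- cfg$body_mass * 9.81
  c1 <- cfg$peak_pos[1]; c2 <- cfg$peak_pos[2]
  mid <- (c1 + c2) / 2
  # half-width giving the requested valley at the midpoint between peaks
  ratio <- 2 * cfg$valley / (cfg$peak1 + cfg$peak2) - 1
  w <- pi * (mid - c1) / acos(ratio)
  rc <- function(x, c) {
    d <- abs(x - c)
    ifelse(d < w, 0.5 * (1 + cos(pi * d / w)), 0)
  }
  shape <- cfg$peak1 * rc(tau, c1) + cfg$peak2 * rc(tau, c2)
  taper <- smoothstep(tau / cfg$ramp) * smoothstep((1 - tau) / cfg$ramp)
  out <- bw * shape * taper
  out[tau < 0 | tau > 1] <- 0
  out
}

#' Monotone heel-to-toe CoP stance template
#'
#' Normalized logistic ramp from `cop_start` to `cop_end` (fractions of foot
#' length): endpoints are attained exactly and, the logistic being symmetric,
#' the midpoint `tau = 0.5` returns the mean of the two extremes.
#'
#' @param tau normalized stance time(s) in `[0, 1]`.
#' @param cfg a [gait_sim_config()].
#' @return CoP_AP, cm from the heel.
#' @export
cop_template <- function(tau, cfg) {
  k <- cfg$cop_steepness
  s <- stats::plogis(k * (tau - 0.5))
  s0 <- stats::plogis(-k / 2)
  s1 <- stats::plogis(k / 2)
  frac <- cfg$cop_start + (cfg$cop_end - cfg$cop_start) * (s - s0) / (s1 - s0)
  frac * cfg$foot_length
}

#' Allocate a total force over the tactels of a layout
#'
#' Distributes `total` among tactels proportionally to a Gaussian kernel of
#' the given spread centered at the CoP position, then caps each tactel at
#' `f_cap` (sensor saturation), iteratively redistributing the excess over
#' the still-unsaturated tactels. The sum is conserved to within 1e-6 N
#' unless every tactel saturates, in which case a warning is raised and all
#' tactels return the cap.
#'
#' @param total total force, N, >= 0.
#' @param cop center of pressure, cm.
#' @param layout an [insole_layout()].
#' @param spread Gaussian kernel spread, cm.
#' @param f_cap per-tactel saturation force, N (`Inf` disables capping).
#' @return Per-tactel force vector, N.
#' @export
allocate_tactel_forces <- function(total, cop, layout, spread, f_cap = Inf) {
  stopifnot(inherits(layout, "insole_layout"), total >= 0, spread > 0)
  ap <- layout$positions$ap
  n <- length(ap)
  if (total == 0) return(numeric(n))
  kern <- exp(-(ap - cop)^2 / (2 * spread^2))
  if (sum(kern) == 0) kern[which.min(abs(ap - cop))] <- 1
  f <- total * kern / sum(kern)
  if (total > n * f_cap) {
    warning("total force exceeds combined tactel saturation; forces capped")
    return(rep(f_cap, n))
  }
  repeat {
    over <- f > f_cap
    if (!any(over)) break
    excess <- sum(f[over] - f_cap)
    f[over] <- f_cap
    free <- f < f_cap
    if (!any(free)) break
    f[free] <- f[free] + excess * kern[free] / sum(kern[free])
  }
  f
}

# vectorized Newton inversion of the calibration polynomial on
# [v_saturation, 0]; interpolation start + Newton polish to ~1e-12 N
fast_invert <- function(cal, f, grid_n = 2048L) {
  vg <- seq(0, cal$v_saturation, length.out = grid_n)  # force ascending
  fg <- poly_force(cal, vg)
  v <- stats::approx(fg, vg, xout = f, rule = 2, ties = "ordered")$y
  p <- cal$p
  for (iter in 1:4) {
    fv <- poly_force(cal, v)
    dfv <- (4 * p[1] * v + 3 * p[2]) * v^2 + 2 * p[3] * v + p[4]
    v <- pmin(pmax(v - (fv - f) / dfv, cal$v_saturation), 0)
  }
  v
}

# first-order lag with optional loading/unloading asymmetry; voltage goes
# more negative under load, so "loading" means the target is below the state
first_order_lag <- function(v, dt, tau_load, tau_unload = tau_load) {
  if (tau_load <= 0 && tau_unload <= 0) return(v)
  a_load <- if (tau_load > 0) 1 - exp(-dt / tau_load) else 1
  a_unload <- if (tau_unload > 0) 1 - exp(-dt / tau_unload) else 1
  out <- numeric(length(v))
  state <- v[1]
  out[1] <- state
  for (k in seq_along(v)[-1]) {
    a <- if (v[k] < state) a_load else a_unload
    state <- state + a * (v[k] - state)
    out[k] <- state
  }
  out
}

# continuous-time truth: total force and CoP at arbitrary times
truth_at <- function(t, cfg) {
  stance_dur <- cfg$stance_fraction * cfg$stride_time
  tp <- t - cfg$lead_in
  k <- floor(tp / cfg$stride_time)
  phase <- tp - k * cfg$stride_time
  in_walk <- k >= 0 & k < cfg$n_strides
  tau <- ifelse(in_walk & phase < stance_dur, phase / stance_dur, NA_real_)
  force <- numeric(length(t))
  cop <- rep(NaN, length(t))
  on <- !is.na(tau)
  if (any(on)) {
    force[on] <- vgrf_template(tau[on], cfg)
    cop[on] <- cop_template(tau[on], cfg)
  }
  cop[force <= 0] <- NaN
  list(force = force, cop = cop)
}

#' Simulate a complete two-device gait trial
#'
#' Builds the true total force and CoP series stride by stride from the
#' parametric templates, then renders them through both devices:
#' \itemize{
#'   \item \strong{reference}: the noiseless truth sampled at 200 Hz, with
#'     the conventional 20 N event threshold;
#'   \item \strong{insole}: per-sample Gaussian allocation of the coupled
#'     fraction (`cfg$coupling`) of the true force over the layout's tactels
#'     (capped at sensor saturation), numerical
#'     inverse transduction to channel voltages, a per-channel first-order
#'     lag (viscoelasticity surrogate) and additive white voltage noise,
#'     sampled at 100 Hz.
#' }
#' Ground-truth events are the exact threshold crossings of the continuous
#' true force at the reference's 20 N threshold, found by root bisection, so
#' they agree with event detection on the reference recording to within one
#' reference sample. All randomness derives from `cfg$seed`; the caller's
#' RNG state is left untouched.
#'
#' @param cfg a [gait_sim_config()].
#' @param cal a [tactel_calibration()].
#' @param layout an [insole_layout()]; defaults to the shipped 16-tactel
#'   layout scaled to `cfg$foot_length`.
#' @param insole_rate,ref_rate sampling rates, Hz.
#' @return A `synthetic_trial`: list with `insole` ([voltage_stream()]),
#'   `reference` ([reference_recording()]), `truth` ([stride_table()] of
#'   20 N crossings), `truth_insole` (true force/CoP on the insole
#'   timeline), `config`, `cal`, `layout`.
#' @export
simulate_trial <- function(cfg, cal = tactel_calibration(),
                           layout = default_layout(cfg$foot_length),
                           insole_rate = 100, ref_rate = 200) {
  stopifnot(inherits(cfg, "gait_sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)

  duration <- 2 * cfg$lead_in + cfg$n_strides * cfg$stride_time
  stance_dur <- cfg$stance_fraction * cfg$stride_time

  # ground-truth events: exact 20 N crossings of the continuous template
  ref_thresh <- 20
  hs <- to <- numeric(0)
  if (cfg$n_strides > 0 &&
      max(vgrf_template(seq(0, 1, by = 0.001), cfg)) > ref_thresh) {
    f_tau <- function(tau) vgrf_template(tau, cfg) - ref_thresh
    tau_peak1 <- cfg$peak_pos[1]
    tau_hs <- stats::uniroot(f_tau, c(0, tau_peak1), tol = 1e-12)$root
    tau_to <- stats::uniroot(f_tau, c(cfg$peak_pos[2], 1), tol = 1e-12)$root
    starts <- cfg$lead_in + (seq_len(cfg$n_strides) - 1) * cfg$stride_time
    hs <- starts + tau_hs * stance_dur
    to <- starts + tau_to * stance_dur
  }
  truth <- stride_table(hs, to)

  # reference device: noiseless truth @ ref_rate
  t_ref <- seq(0, duration, by = 1 / ref_rate)
  tr <- truth_at(t_ref, cfg)
  reference <- reference_recording(t_ref, tr$force, tr$cop,
                                   sample_rate = ref_rate,
                                   event_threshold = ref_thresh)

  # insole device: allocation -> inverse transduction -> lag -> noise
  t_in <- seq(0, duration, by = 1 / insole_rate)
  ti <- truth_at(t_in, cfg)
  n_tac <- nrow(layout$positions)
  forces <- matrix(0, length(t_in), n_tac)
  loaded <- which(ti$force > 0)
  for (k in loaded) {
    forces[k, ] <- allocate_tactel_forces(cfg$coupling * ti$force[k],
                                          ti$cop[k], layout,
                                          cfg$spread, f_cap = cal$f_saturation)
  }
  volts <- matrix(0, length(t_in), n_tac)
  pos <- forces > 0
  if (any(pos)) volts[pos] <- fast_invert(cal, forces[pos])
  if (cfg$lag_tau > 0) {
    dt <- 1 / insole_rate
    for (j in seq_len(n_tac)) {
      volts[, j] <- first_order_lag(volts[, j], dt, cfg$lag_tau,
                                    cfg$lag_tau * cfg$lag_asym)
    }
  }
  if (cfg$noise_sd > 0) {
    volts <- volts + matrix(stats::rnorm(length(volts), 0, cfg$noise_sd),
                            nrow(volts))
  }
  structure(
    list(insole = voltage_stream(t_in, volts, sample_rate = insole_rate),
         reference = reference,
         truth = truth,
         truth_insole = list(timestamps = t_in, force = ti$force, cop = ti$cop),
         config = cfg, cal = cal, layout = layout),
    class = "synthetic_trial"
  )
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf(
    "Synthetic gait trial: %d strides, %.1f s, seed %d\n  insole %d x %d @ %g Hz; reference @ %g Hz (threshold %g N)\n",
    nrow(x$truth), max(x$insole$timestamps), x$config$seed,
    nrow(x$insole$frames), ncol(x$insole$frames), x$insole$sample_rate,
    x$reference$sample_rate, x$reference$event_threshold))
  invisible(x)
}
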