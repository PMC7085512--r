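#' Reference force-plate recording
#'
#' Container for the gold-standard device: vGRF and CoP_AP sampled at a
#' higher rate (200 Hz by default) with its own, manufacturer-recommended
#' event threshold (20 N by default).
#'
#' @param timestamps sample times, s, uniform.
#' @param vgrf vertical ground reaction force, N.
#' @param cop_ap CoP along the foot AP axis, cm (`NaN` when unloaded).
#' @param sample_rate Hz.
#' @param event_threshold detection threshold, N, > 0.
#' @return A `reference_recording` object.
#' @export
reference_recording <- function(timestamps, vgrf, cop_ap, sample_rate = 200,
                                event_threshold = 20) {
  stopifnot(length(timestamps) == length(vgrf),
            length(vgrf) == length(cop_ap), event_threshold > 0)
  structure(list(timestamps = as.numeric(timestamps), vgrf = as.numeric(vgrf),
                 cop_ap = as.numeric(cop_ap), sample_rate = sample_rate,
                 event_threshold = event_threshold),
            class = "reference_recording")
}

#' Zero-phase low-pass filter
#'
#' Smooths a series with the squared-magnitude response of an n-th order
#' Butterworth filter applied in the frequency domain on an even (reflected)
#' extension of the signal. This matches the passband behaviour of the usual
#' forward-backward (filtfilt) Butterworth filtering — zero phase shift,
#' effective attenuation `1/(1+(f/fc)^(2n))` — without a recursive-filter
#' dependency. Interior `NaN` runs are linearly bridged before filtering and
#' restored to `NaN` afterwards.
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param cutoff -3 dB (single-pass) cutoff, Hz; `Inf` or `NULL` disables
#'   filtering.
#' @param order filter order of the underlying Butterworth design.
#' @return Filtered series, same length.
#' @export
lowpass_zero_phase <- function(x, fs, cutoff = 20, order = 4) {
  if (is.null(cutoff) || !is.finite(cutoff) || cutoff <= 0) return(x)
  n <- length(x)
  if (n < 4L) return(x)
  nan_mask <- !is.finite(x)
  if (all(nan_mask)) return(x)
  if (any(nan_mask)) {
    ok <- which(!nan_mask)
    x <- stats::approx(ok, x[ok], xout = seq_len(n), rule = 2)$y
  }
  ext <- c(x, rev(x))                     # even extension: continuous wrap
  nf <- length(ext)
  k <- 0:(nf - 1)
  f <- pmin(k, nf - k) * fs / nf
  h <- 1 / (1 + (f / cutoff)^(2 * order))
  y <- Re(stats::fft(stats::fft(ext) * h, inverse = TRUE)) / nf
  y <- y[seq_len(n)]
  y[nan_mask] <- NaN
  y
}

#' Align a reference recording onto the insole timeline
#'
#' Shifts the reference clock by the trigger offset, trims both devices to
#' their overlap and linearly interpolates the reference vGRF and CoP onto
#' the insole's (lower-rate) timestamps. The reference CoP is interpolated
#' over its defined samples only and re-masked to `NaN` wherever the
#' interpolated reference vGRF is below the reference event threshold.
#'
#' @param insole a [gait_signals()] object (typically 100 Hz).
#' @param ref a [reference_recording()] (typically 200 Hz).
#' @param trigger_offset seconds to add to the reference timestamps to put
#'   them on the insole clock.
#' @return List with `insole` and `ref`, both [gait_signals()] on the common
#'   insole timeline.
#' @export
align_and_resample <- function(insole, ref, trigger_offset = 0) {
  stopifnot(inherits(ref, "reference_recording"))
  t_ref <- ref$timestamps + trigger_offset
  lo <- max(min(insole$timestamps), min(t_ref))
  hi <- min(max(insole$timestamps), max(t_ref))
  keep <- insole$timestamps >= lo & insole$timestamps <= hi
  if (sum(keep) < 2L) stop("no temporal overlap between devices", call. = FALSE)
  tt <- insole$timestamps[keep]
  vgrf_r <- stats::approx(t_ref, ref$vgrf, xout = tt, rule = 1)$y
  ok <- is.finite(ref$cop_ap)
  cop_r <- if (any(ok)) {
    stats::approx(t_ref[ok], ref$cop_ap[ok], xout = tt, rule = 2)$y
  } else rep(NaN, length(tt))
  cop_r[vgrf_r < ref$event_threshold] <- NaN
  list(
    insole = gait_signals(tt, insole$vgrf[keep], insole$cop_ap[keep],
                          sample_rate = insole$sample_rate,
                          vgrf_thresh = insole$vgrf_thresh),
    ref = gait_signals(tt, vgrf_r, cop_r, sample_rate = insole$sample_rate,
                       vgrf_thresh = ref$event_threshold)
  )
}

# greedy stride pairing by nearest heel-strike within a tolerance
match_strides <- function(ref_table, other_table, tol = NULL) {
  if (nrow(ref_table) == 0L || nrow(other_table) == 0L) {
    return(data.frame(ref = integer(0), other = integer(0)))
  }
  if (is.null(tol)) {
    st <- stats::median(ref_table$stride_time, na.rm = TRUE)
    tol <- if (is.finite(st)) st / 2 else Inf
  }
  used <- rep(FALSE, nrow(other_table))
  pairs <- lapply(seq_len(nrow(ref_table)), function(i) {
    d <- abs(other_table$hs_time - ref_table$hs_time[i])
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tol) {
      used[j] <<- TRUE
      c(i, j)
    } else NULL
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) return(data.frame(ref = integer(0), other = integer(0)))
  data.frame(ref = pairs[, 1], other = pairs[, 2])
}

#' Event-timing median absolute error between two devices
#'
#' Strides are paired across devices by nearest heel-strike within half the
#' reference median stride time; for each paired stride the absolute
#' HS-time, TO-time and stance-duration differences are computed, and their
#' medians reported, both in seconds and as a percentage of that stride's
#' reference stance duration.
#'
#' @param ref_events reference-device [stride_table()].
#' @param insole_events insole [stride_table()].
#' @return List: `mae_hs`, `mae_to`, `mae_stance` (s), `mae_hs_pct`,
#'   `mae_to_pct`, `mae_stance_pct` (% of reference stance), `n_pairs`,
#'   `n_unmatched_ref`, `n_unmatched_insole`. All metrics `NA` when no
#'   strides pair.
#' @export
event_mae <- function(ref_events, insole_events) {
  pairs <- match_strides(ref_events, insole_events)
  n <- nrow(pairs)
  out <- list(mae_hs = NA_real_, mae_to = NA_real_, mae_stance = NA_real_,
              mae_hs_pct = NA_real_, mae_to_pct = NA_real_,
              mae_stance_pct = NA_real_,
              n_pairs = n,
              n_unmatched_ref = nrow(ref_events) - n,
              n_unmatched_insole = nrow(insole_events) - n)
  if (n == 0L) return(out)
  r <- ref_events[pairs$ref, ]
  i <- insole_events[pairs$other, ]
  d_hs <- abs(r$hs_time - i$hs_time)
  d_to <- abs(r$to_time - i$to_time)
  d_st <- abs(r$stance_duration - i$stance_duration)
  out$mae_hs <- stats::median(d_hs)
  out$mae_to <- stats::median(d_to)
  out$mae_stance <- stats::median(d_st)
  out$mae_hs_pct <- stats::median(d_hs / r$stance_duration) * 100
  out$mae_to_pct <- stats::median(d_to / r$stance_duration) * 100
  out$mae_stance_pct <- stats::median(d_st / r$stance_duration) * 100
  out
}

#' Stance-normalized signal profiles
#'
#' Low-pass filters a signal (zero-phase, optional), segments it at each
#' stride's HS/TO, and linearly time-normalizes every stance to `n_points`
#' samples so profiles align across strides and devices. Strides whose
#' stance spans fewer than 3 samples are skipped with a warning.
#'
#' @param signals a [gait_signals()] object.
#' @param table a [stride_table()] detected on (or aligned to) `signals`.
#' @param what `"vgrf"` or `"cop_ap"`.
#' @param n_points points per normalized stance (default 101: 0..100% in 1%
#'   steps).
#' @param lowpass_cutoff low-pass cutoff, Hz; `Inf` disables filtering.
#' @return Matrix, one row per retained stride, `n_points` columns;
#'   attribute `stride_idx` maps rows to table rows.
#' @export
stance_profiles <- function(signals, table, what = c("vgrf", "cop_ap"),
                            n_points = 101L, lowpass_cutoff = 20) {
  what <- match.arg(what)
  stopifnot(n_points >= 2L)
  x <- lowpass_zero_phase(signals[[what]], signals$sample_rate, lowpass_cutoff)
  ts <- signals$timestamps
  tau_out <- seq(0, 1, length.out = n_points)
  rows <- list()
  kept <- integer(0)
  for (s in seq_len(nrow(table))) {
    sel <- which(ts >= table$hs_time[s] & ts <= table$to_time[s])
    seg <- x[sel]
    ok <- is.finite(seg)
    if (length(sel) < 3L || sum(ok) < 3L) {
      warning(sprintf("stride %d: stance shorter than 3 samples, skipped", s))
      next
    }
    tau <- (ts[sel] - table$hs_time[s]) /
      (table$to_time[s] - table$hs_time[s])
    rows[[length(rows) + 1L]] <-
      stats::approx(tau[ok], seg[ok], xout = tau_out, rule = 2)$y
    kept <- c(kept, s)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- matrix(numeric(0), 0L, n_points)
  attr(out, "stride_idx") <- kept
  out
}

#' Agreement between two devices' average stance profiles
#'
#' Averages the per-stride profiles of each device, then computes the
#' Pearson correlation between the averages and, where meaningful
#' (CoP-type signals sharing units and scale), their RMSE. For vGRF the
#' RMSE is conventionally not reported because the two devices measure on
#' very different amplitudes.
#'
#' @param profiles_a,profiles_b stride-by-point matrices from
#'   [stance_profiles()], same number of columns.
#' @return List: `rho`, `rmse`, `mean_a`, `mean_b`, `zero_variance` (TRUE if
#'   either average is constant, in which case `rho` is `NA`).
#' @export
profile_agreement <- function(profiles_a, profiles_b) {
  stopifnot(ncol(profiles_a) == ncol(profiles_b),
            nrow(profiles_a) > 0L, nrow(profiles_b) > 0L)
  ma <- colMeans(profiles_a)
  mb <- colMeans(profiles_b)
  zv <- stats::sd(ma) == 0 || stats::sd(mb) == 0
  list(
    rho = if (zv) NA_real_ else stats::cor(ma, mb),
    rmse = sqrt(mean((ma - mb)^2)),
    mean_a = ma, mean_b = mb, zero_variance = zv
  )
}

#' Within-device repeatability of stance profiles
#'
#' For each stride, the RMSE between its profile and the mean profile of the
#' recording. For vGRF the profiles are first normalized by body weight
#' (mass x g) and each stride's RMSE is then divided by that stride's mean
#' normalized vGRF, giving a percentage; CoP repeatability stays in cm. The
#' recording-level value is the median over strides.
#'
#' @param profiles stride-by-point matrix.
#' @param mode `"cop"` (cm) or `"vgrf"` (% of stride mean, body-weight
#'   normalized).
#' @param body_mass kg, required for `mode = "vgrf"`.
#' @param g gravitational acceleration, m/s^2.
#' @return Median per-stride RMSE (cm or %); `NA` with a warning when fewer
#'   than 2 strides.
#' @export
repeatability_rmse <- function(profiles, mode = c("cop", "vgrf"),
                               body_mass = NULL, g = 9.81) {
  mode <- match.arg(mode)
  if (nrow(profiles) < 2L) {
    warning("repeatability undefined for fewer than 2 strides")
    return(NA_real_)
  }
  if (mode == "vgrf") {
    stopifnot(!is.null(body_mass), body_mass > 0)
    profiles <- profiles / (body_mass * g)
  }
  m <- colMeans(profiles)
  per_stride <- apply(profiles, 1, function(p) sqrt(mean((p - m)^2)))
  if (mode == "vgrf") {
    per_stride <- per_stride / rowMeans(profiles) * 100
  }
  stats::median(per_stride)
}

#' Peak vGRF as percentage of body mass
#'
#' `max(vgrf) / (body_mass * g) * 100`, making peak loads comparable across
#' subjects.
#'
#' @param vgrf_stance vGRF samples or profile, N.
#' @param body_mass kg, > 0.
#' @param g gravitational acceleration, m/s^2.
#' @return Peak in % body mass (BM%).
#' @export
peak_bm_percent <- function(vgrf_stance, body_mass, g = 9.81) {
  if (length(vgrf_stance) == 0L) stop("empty profile", call. = FALSE)
  stopifnot(body_mass > 0)
  max(vgrf_stance) / (body_mass * g) * 100
}

#' Full insole-vs-reference validation battery
#'
#' Runs the complete comparison: temporal alignment, event detection on both
#' devices at their own thresholds, event-timing MAEs, stance-normalized
#' profile extraction, between-device profile agreement (Pearson rho for
#' vGRF and CoP, RMSE for CoP), within-device repeatability, and peak
#' body-mass-normalized vGRF per device.
#'
#' @param insole a [gait_signals()] object from [process_stream()].
#' @param ref a [reference_recording()].
#' @param body_mass subject body mass, kg.
#' @param trigger_offset s, see [align_and_resample()].
#' @param n_points,lowpass_cutoff see [stance_profiles()].
#' @param min_stance,min_swing see [detect_events()].
#' @return A `validation_report`: nested list with `events` (the
#'   [event_mae()] output), `agreement` (`rho_vgrf`, `rho_cop`, `rmse_cop`),
#'   `repeatability` (per device and signal), `peaks` (BM% per device) and
#'   `n_strides` per device. `empty_pairing` is TRUE when no strides paired.
#' @export
validate_recordings <- function(insole, ref, body_mass, trigger_offset = 0,
                                n_points = 101L, lowpass_cutoff = 20,
                                min_stance = 0.1, min_swing = 0.1) {
  al <- align_and_resample(insole, ref, trigger_offset)
  ev_in <- detect_events(al$insole, min_stance = min_stance, min_swing = min_swing)
  ev_fp <- detect_events(al$ref, min_stance = min_stance, min_swing = min_swing)
  maes <- event_mae(ev_fp, ev_in)

  prof <- function(sig, tab, what) {
    stance_profiles(sig, tab, what, n_points = n_points,
                    lowpass_cutoff = lowpass_cutoff)
  }
  vg_in <- prof(al$insole, ev_in, "vgrf")
  vg_fp <- prof(al$ref, ev_fp, "vgrf")
  cp_in <- prof(al$insole, ev_in, "cop_ap")
  cp_fp <- prof(al$ref, ev_fp, "cop_ap")

  agree_v <- if (nrow(vg_in) && nrow(vg_fp)) profile_agreement(vg_fp, vg_in) else NULL
  agree_c <- if (nrow(cp_in) && nrow(cp_fp)) profile_agreement(cp_fp, cp_in) else NULL

  rep_or_na <- function(p, mode) {
    if (nrow(p) >= 2L) repeatability_rmse(p, mode, body_mass = body_mass) else NA_real_
  }
  report <- list(
    events = maes,
    agreement = list(
      rho_vgrf = if (is.null(agree_v)) NA_real_ else agree_v$rho,
      rho_cop = if (is.null(agree_c)) NA_real_ else agree_c$rho,
      rmse_cop = if (is.null(agree_c)) NA_real_ else agree_c$rmse
    ),
    repeatability = list(
      vgrf_insole_pct = rep_or_na(vg_in, "vgrf"),
      vgrf_ref_pct = rep_or_na(vg_fp, "vgrf"),
      cop_insole_cm = rep_or_na(cp_in, "cop"),
      cop_ref_cm = rep_or_na(cp_fp, "cop")
    ),
    peaks = list(
      vgrf_peak_insole_bm_pct = if (nrow(vg_in)) peak_bm_percent(vg_in, body_mass) else NA_real_,
      vgrf_peak_ref_bm_pct = if (nrow(vg_fp)) peak_bm_percent(vg_fp, body_mass) else NA_real_
    ),
    n_strides = list(insole = nrow(ev_in), ref = nrow(ev_fp)),
    empty_pairing = maes$n_pairs == 0L
  )
  class(report) <- "validation_report"
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Insole vs reference validation\n")
  cat(sprintf("  strides: insole %d, reference %d, paired %d\n",
              x$n_strides$insole, x$n_strides$ref, x$events$n_pairs))
  cat(sprintf("  MAE  HS %.3f s (%.2f%%)  TO %.3f s (%.2f%%)  stance %.3f s (%.2f%%)\n",
              x$events$mae_hs, x$events$mae_hs_pct, x$events$mae_to,
              x$events$mae_to_pct, x$events$mae_stance, x$events$mae_stance_pct))
  cat(sprintf("  rho_vGRF %.3f  rho_CoP %.3f  RMSE_CoP %.2f cm\n",
              x$agreement$rho_vgrf, x$agreement$rho_cop, x$agreement$rmse_cop))
  cat(sprintf("  repeatability: vGRF %.2f%% (insole) %.2f%% (ref); CoP %.2f cm (insole) %.2f cm (ref)\n",
              x$repeatability$vgrf_insole_pct, x$repeatability$vgrf_ref_pct,
              x$repeatability$cop_insole_cm, x$repeatability$cop_ref_cm))
  cat(sprintf("  vGRF peak: %.1f BM%% (insole) vs %.1f BM%% (ref)\n",
              x$peaks$vgrf_peak_insole_bm_pct, x$peaks$vgrf_peak_ref_bm_pct))
  invisible(x)
}
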