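#' Multichannel voltage stream
#'
#' Uniformly sampled, timestamped frames of de-offset tactel voltages — the
#' raw input of the processing chain.
#'
#' @param timestamps sample times, s, uniformly spaced.
#' @param frames numeric matrix, one row per sample, one column per tactel.
#' @param sample_rate sampling rate, Hz.
#' @return A `voltage_stream` object.
#' @export
voltage_stream <- function(timestamps, frames, sample_rate = 100) {
  frames <- as.matrix(frames)
  stopifnot(length(timestamps) == nrow(frames))
  if (length(timestamps) > 1L) {
    dt <- diff(timestamps)
    if (max(abs(dt - 1 / sample_rate)) > 1e-6 / sample_rate) {
      stop("timestamps must be uniform at the stated sample rate", call. = FALSE)
    }
  }
  structure(list(timestamps = as.numeric(timestamps), frames = frames,
                 sample_rate = sample_rate),
            class = "voltage_stream")
}

#' @export
print.voltage_stream <- function(x, ...) {
  cat(sprintf("Voltage stream: %d samples x %d channels @ %g Hz (%.2f s)\n",
              nrow(x$frames), ncol(x$frames), x$sample_rate,
              nrow(x$frames) / x$sample_rate))
  invisible(x)
}

#' Derived gait signals: vGRF and CoP_AP time series
#'
#' @param timestamps sample times, s.
#' @param vgrf vertical ground reaction force, N, non-negative.
#' @param cop_ap antero-posterior center of pressure, cm; `NaN` where the
#'   vGRF is below the foot-contact threshold (swing).
#' @param sample_rate Hz.
#' @param vgrf_thresh the threshold used, N (metadata).
#' @return A `gait_signals` object.
#' @export
gait_signals <- function(timestamps, vgrf, cop_ap, sample_rate = 100,
                         vgrf_thresh = NA_real_) {
  stopifnot(length(timestamps) == length(vgrf),
            length(vgrf) == length(cop_ap))
  structure(list(timestamps = as.numeric(timestamps),
                 vgrf = as.numeric(vgrf), cop_ap = as.numeric(cop_ap),
                 sample_rate = sample_rate, vgrf_thresh = vgrf_thresh),
            class = "gait_signals")
}

#' @export
print.gait_signals <- function(x, ...) {
  cat(sprintf(
    "Gait signals: %d samples @ %g Hz; vGRF peak %.1f N; CoP defined on %d samples\n",
    length(x$vgrf), x$sample_rate, max(x$vgrf), sum(!is.nan(x$cop_ap))))
  invisible(x)
}

#' Per-frame vertical ground reaction force
#'
#' The vGRF is the sum of the per-tactel piecewise forces over all channels
#' of the frame.
#'
#' @param frame numeric vector of de-offset channel voltages (V).
#' @param cal a [tactel_calibration()].
#' @return Total force, N.
#' @export
compute_vgrf <- function(frame, cal) {
  if (!is.numeric(frame) || anyNA(frame) || any(!is.finite(frame))) {
    stop("invalid frame: non-finite channel voltage", call. = FALSE)
  }
  sum(force_from_voltage(cal, frame))
}

#' Per-frame antero-posterior center of pressure
#'
#' Density-weighted centroid of the tactel AP coordinates,
#' \deqn{CoP_{AP} = \frac{\sum_i F_i\, w_{AP_i}\, AP_i}{\sum_i F_i\, w_{AP_i}},}
#' defined only while the total force is at or above the foot-contact
#' threshold; during swing the value is `NaN` and is never interpolated.
#'
#' @param forces per-tactel forces, N, non-negative, one per layout tactel.
#' @param layout an [insole_layout()].
#' @param vgrf_thresh foot-contact threshold, N.
#' @return CoP_AP in cm, or `NaN` below threshold.
#' @export
compute_cop_ap <- function(forces, layout, vgrf_thresh) {
  stopifnot(inherits(layout, "insole_layout"))
  if (length(forces) != nrow(layout$positions)) {
    stop("force vector length must match layout size", call. = FALSE)
  }
  if (any(forces < 0)) stop("forces must be non-negative", call. = FALSE)
  if (sum(forces) < vgrf_thresh) return(NaN)
  w <- layout$positions$ap_weight
  denom <- sum(forces * w)
  if (denom <= 0) return(NaN)  # guard; unreachable when thresh > 0
  sum(forces * w * layout$positions$ap) / denom
}

#' Baseline (zero-load) voltage offsets
#'
#' Estimates the per-channel unloaded baseline as the median of an unloaded
#' window of the stream (default: the first 50 samples), for subtraction
#' before transduction. The on-device system de-offsets in hardware; offline
#' processing of raw recordings does it here.
#'
#' @param stream a [voltage_stream()].
#' @param window integer sample indices known to be unloaded.
#' @return Numeric vector of per-channel offsets.
#' @export
baseline_offsets <- function(stream, window = seq_len(min(50L, nrow(stream$frames)))) {
  stopifnot(inherits(stream, "voltage_stream"))
  apply(stream$frames[window, , drop = FALSE], 2, stats::median)
}

#' Process a voltage stream into gait signals
#'
#' Applies, per frame: optional zero-load de-offset subtraction, piecewise
#' transduction and summation to vGRF, and the weighted CoP_AP centroid.
#' The computation is strictly causal — sample `k` of the output depends only
#' on samples `<= k` of the input — so batch processing and one-sample-at-a-
#' time streaming give identical results.
#'
#' @param stream a [voltage_stream()].
#' @param cal a [tactel_calibration()].
#' @param layout an [insole_layout()] with as many tactels as stream channels.
#' @param vgrf_thresh foot-contact threshold, N; default
#'   [system_force_threshold()] for the channel count.
#' @param offsets optional per-channel baseline voltages to subtract
#'   (`NULL` = stream is already de-offset).
#' @return A [gait_signals()] object.
#' @export
process_stream <- function(stream, cal, layout,
                           vgrf_thresh = system_force_threshold(cal, ncol(stream$frames)),
                           offsets = NULL) {
  stopifnot(inherits(stream, "voltage_stream"),
            inherits(cal, "tactel_calibration"),
            inherits(layout, "insole_layout"))
  frames <- stream$frames
  if (ncol(frames) != nrow(layout$positions)) {
    stop("stream width must equal layout size", call. = FALSE)
  }
  if (!is.null(offsets)) {
    stopifnot(length(offsets) == ncol(frames))
    frames <- sweep(frames, 2, offsets)
  }
  if (anyNA(frames) || any(!is.finite(frames))) {
    stop("invalid frame: non-finite channel voltage", call. = FALSE)
  }
  # vectorized piecewise transduction over the whole matrix (per-sample
  # result identical to frame-at-a-time application)
  forces <- matrix(force_from_voltage(cal, as.numeric(frames)),
                   nrow = nrow(frames))
  vgrf <- rowSums(forces)
  w <- layout$positions$ap_weight
  ap <- layout$positions$ap
  num <- as.numeric(forces %*% (w * ap))
  den <- as.numeric(forces %*% w)
  cop <- ifelse(vgrf >= vgrf_thresh & den > 0, num / den, NaN)
  gait_signals(stream$timestamps, vgrf, cop,
               sample_rate = stream$sample_rate, vgrf_thresh = vgrf_thresh)
}
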