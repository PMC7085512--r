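#' Rank sensors by responsivity and amplitude around gait events
#'
#' Sensor-placement studies start from a dense grid of sensors and ask which
#' ones react earliest and strongest at each gait event. For every sensor
#' and every stride this computes:
#' \itemize{
#'   \item \strong{responsivity} — for heel-strike, the latency from the
#'     reference HS to the sensor's first activation within
#'     `[HS, HS + window]`; for toe-off, the lead from the sensor's last
#'     activation within `[TO - window, TO]` back to the reference TO. Both
#'     are >= 0, and 0 means perfectly synchronous;
#'   \item \strong{amplitude} — the peak sensor force within
#'     `[event - window, event + window]`.
#' }
#' Per-sensor scores are medians over strides; the composite order is the
#' rank-sum of (latency ascending, amplitude descending), ties broken by
#' sensor id. Sensors never active near an event get sentinel (`Inf`)
#' latency and rank last.
#'
#' @param forces samples-by-sensors matrix of per-sensor forces, N (zero =
#'   inactive; apply [force_from_voltage()] first for raw voltages).
#' @param timestamps sample times, s.
#' @param events a [stride_table()] detected on the full configuration.
#' @param window half-window around each event, s.
#' @param sensor_ids sensor identifiers (default column index).
#' @return A `sensor_ranking`: list with one data.frame per event (`hs`,
#'   `to`), each ordered by composite rank with columns `id`, `latency`,
#'   `amplitude`, `rank`.
#' @export
rank_sensors <- function(forces, timestamps, events, window = 0.15,
                         sensor_ids = seq_len(ncol(forces))) {
  forces <- as.matrix(forces)
  stopifnot(length(timestamps) == nrow(forces), nrow(events) >= 1L,
            window > 0, length(sensor_ids) == ncol(forces))
  score_event <- function(ev_times, mode) {
    lat <- amp <- matrix(NA_real_, nrow(events), ncol(forces))
    for (s in seq_along(ev_times)) {
      ev <- ev_times[s]
      if (mode == "hs") {
        sel <- which(timestamps >= ev & timestamps <= ev + window)
      } else {
        sel <- which(timestamps >= ev - window & timestamps <= ev)
      }
      wsel <- which(timestamps >= ev - window & timestamps <= ev + window)
      for (j in seq_len(ncol(forces))) {
        active <- sel[forces[sel, j] > 0]
        if (length(active) > 0L) {
          lat[s, j] <- if (mode == "hs") timestamps[active[1]] - ev
                       else ev - timestamps[active[length(active)]]
        }
        amp[s, j] <- max(forces[wsel, j])
      }
    }
    med_lat <- apply(lat, 2, function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0L) Inf else stats::median(x)
    })
    med_amp <- apply(amp, 2, stats::median)
    composite <- rank(med_lat, ties.method = "min") +
      rank(-med_amp, ties.method = "min")
    ord <- order(composite, sensor_ids)
    data.frame(id = sensor_ids[ord], latency = med_lat[ord],
               amplitude = med_amp[ord], rank = seq_along(ord))
  }
  structure(list(hs = score_event(events$hs_time, "hs"),
                 to = score_event(events$to_time, "to"),
                 window = window),
            class = "sensor_ranking")
}

#' @export
print.sensor_ranking <- function(x, ...) {
  cat(sprintf("Sensor ranking (window %.2f s)\n", x$window))
  cat("Heel-strike:\n"); print(utils::head(x$hs), row.names = FALSE)
  cat("Toe-off:\n"); print(utils::head(x$to), row.names = FALSE)
  invisible(x)
}

#' Score a sensor subset's event-detection synchrony against the full set
#'
#' Runs the vGRF + event-detection pipeline twice — once on all channels of
#' the stream, once on the given subset with the foot-contact threshold
#' rescaled proportionally (`n_subset * f(v_thresh)`), so the comparison is
#' not biased by threshold magnitude — and reports per-stride event-time
#' differences (subset minus full) and the fraction of strides detected
#' within a sample tolerance.
#'
#' @param subset_ids tactel ids of the subset, all present in `layout`.
#' @param stream full-configuration [voltage_stream()].
#' @param cal a [tactel_calibration()].
#' @param layout full [insole_layout()]; its id order must match the stream
#'   columns.
#' @param tol_samples synchrony tolerance, samples.
#' @param min_stance,min_swing see [detect_events()].
#' @return List: `diffs` (data.frame `hs_diff`, `to_diff`, s), `frac_hs`,
#'   `frac_to` (fractions within tolerance), `n_pairs`, `n_full`,
#'   `n_subset`, `n_unmatched`.
#' @export
evaluate_subset <- function(subset_ids, stream, cal, layout, tol_samples = 1,
                            min_stance = 0.1, min_swing = 0.1) {
  stopifnot(inherits(stream, "voltage_stream"),
            inherits(layout, "insole_layout"))
  ids <- layout$positions$id
  if (length(subset_ids) == 0L || !all(subset_ids %in% ids)) {
    stop("subset must be non-empty and contained in the layout", call. = FALSE)
  }
  cols <- match(subset_ids, ids)
  sub_frames <- stream$frames[, cols, drop = FALSE]
  if (all(force_from_voltage(cal, as.numeric(sub_frames)) == 0)) {
    stop("subset has no active sensors", call. = FALSE)
  }
  run <- function(frames, n_sensors, lay_pos) {
    lay <- insole_layout(lay_pos, foot_length = layout$foot_length,
                         bin_width = layout$bin_width)
    st <- voltage_stream(stream$timestamps, frames, stream$sample_rate)
    sig <- process_stream(st, cal, lay,
                          vgrf_thresh = system_force_threshold(cal, n_sensors))
    detect_events(sig, min_stance = min_stance, min_swing = min_swing)
  }
  ev_full <- run(stream$frames, length(ids), layout$positions[c("id", "ap", "ml")])
  ev_sub <- run(sub_frames, length(cols),
                layout$positions[cols, c("id", "ap", "ml")])
  pairs <- match_strides(ev_full, ev_sub)
  tol <- tol_samples / stream$sample_rate
  hs_diff <- ev_sub$hs_time[pairs$other] - ev_full$hs_time[pairs$ref]
  to_diff <- ev_sub$to_time[pairs$other] - ev_full$to_time[pairs$ref]
  list(
    diffs = data.frame(hs_diff = hs_diff, to_diff = to_diff),
    frac_hs = if (nrow(ev_full)) sum(abs(hs_diff) <= tol + 1e-9) / nrow(ev_full) else NA_real_,
    frac_to = if (nrow(ev_full)) sum(abs(to_diff) <= tol + 1e-9) / nrow(ev_full) else NA_real_,
    n_pairs = nrow(pairs), n_full = nrow(ev_full), n_subset = nrow(ev_sub),
    n_unmatched = nrow(ev_full) - nrow(pairs)
  )
}
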