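#' Stride table
#'
#' Per-stride gait events and temporal parameters. Heel-strike (HS) is the
#' first sample at or above the force threshold after a swing; toe-off (TO)
#' is the first sample below it after a stance.
#'
#' @param hs_time,to_time event times, s, one pair per stride; must
#'   alternate chronologically with `hs < to`.
#' @return A `stride_table` (data.frame with columns `stride_idx`, `hs_time`,
#'   `to_time`, `stance_duration`, `stride_time`, `stance_fraction`;
#'   `stride_time`/`stance_fraction` are `NA` for the last stride).
#' @export
stride_table <- function(hs_time = numeric(0), to_time = numeric(0)) {
  stopifnot(length(hs_time) == length(to_time))
  n <- length(hs_time)
  if (n > 0L) {
    if (any(to_time <= hs_time)) stop("each TO must follow its HS", call. = FALSE)
    if (n > 1L && any(diff(hs_time) <= 0 | utils::head(to_time, -1) >= hs_time[-1])) {
      stop("strides must be chronological and non-overlapping", call. = FALSE)
    }
  }
  stride_time <- if (n == 0L) numeric(0) else c(diff(hs_time), NA_real_)
  stance <- to_time - hs_time
  structure(
    data.frame(stride_idx = seq_len(n), hs_time = hs_time, to_time = to_time,
               stance_duration = stance, stride_time = stride_time,
               stance_fraction = stance / stride_time),
    class = c("stride_table", "data.frame")
  )
}

# merge interior phases shorter than their minimum duration into neighbours
debounce_phases <- function(stance, min_stance_n, min_swing_n) {
  repeat {
    r <- rle(stance)
    k <- length(r$lengths)
    if (k < 3L) return(stance)
    interior <- 2:(k - 1)
    min_n <- ifelse(r$values[interior], min_stance_n, min_swing_n)
    short <- interior[r$lengths[interior] < min_n]
    if (length(short) == 0L) return(stance)
    # flip the shortest offending run (ties: earliest) and re-scan
    j <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    idx <- (ends[j] - r$lengths[j] + 1L):ends[j]
    stance[idx] <- !r$values[j]
  }
}

#' Threshold-based gait event detection
#'
#' Segments the vGRF series into stance (`vgrf >= vgrf_thresh`) and swing
#' phases. The raw device algorithm is a bare threshold; on noisy signals
#' chatter near the threshold produces spurious phases, so candidate phases
#' shorter than `min_stance` / `min_swing` are merged into their neighbours
#' before events are extracted (set both to 0 to disable). Incomplete
#' phases at the edges of the recording are dropped: the first HS must
#' follow an observed swing, and a final stance without an observed TO is
#' discarded.
#'
#' Event timestamps are the first sample satisfying the condition — no
#' sub-sample interpolation, matching the sample-quantized real-time
#' behaviour of the device.
#'
#' @param signals a [gait_signals()] object (or anything with `timestamps`,
#'   `vgrf`, `sample_rate`).
#' @param vgrf_thresh detection threshold, N, > 0; defaults to the threshold
#'   stored in `signals`.
#' @param min_stance,min_swing debounce durations, s.
#' @return A [stride_table()].
#' @export
detect_events <- function(signals, vgrf_thresh = signals$vgrf_thresh,
                          min_stance = 0.1, min_swing = 0.1) {
  stopifnot(is.numeric(vgrf_thresh), vgrf_thresh > 0)
  vgrf <- signals$vgrf
  ts <- signals$timestamps
  if (length(vgrf) == 0L) return(stride_table())
  stance <- vgrf >= vgrf_thresh
  fs <- signals$sample_rate
  stance <- debounce_phases(stance, round(min_stance * fs), round(min_swing * fs))
  r <- rle(stance)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hs <- numeric(0); to <- numeric(0)
  for (j in seq_along(r$lengths)) {
    if (!r$values[j]) next
    if (j == 1L) next                      # stance at start: HS unobserved
    if (j == length(r$lengths)) next       # stance at end: TO unobserved
    hs <- c(hs, ts[starts[j]])
    to <- c(to, ts[ends[j] + 1L])
  }
  stride_table(hs, to)
}

#' Summarize per-stride temporal parameters
#'
#' Median and interquartile range of stance duration, stride time and stance
#' fraction over the strides of a table. Stance fraction uses the stride
#' time where available (all strides but the last).
#'
#' @param table a [stride_table()].
#' @return A data.frame with one row per parameter (`stance_duration`,
#'   `stride_time`, `stance_fraction`) and columns `median`, `iqr`, `n`;
#'   zero rows for an empty table.
#' @export
temporal_parameters <- function(table) {
  stopifnot(inherits(table, "stride_table"))
  if (nrow(table) == 0L) {
    return(data.frame(parameter = character(0), median = numeric(0),
                      iqr = numeric(0), n = integer(0)))
  }
  summ <- function(x) {
    x <- x[!is.na(x)]
    c(median = stats::median(x), iqr = stats::IQR(x), n = length(x))
  }
  vals <- rbind(summ(table$stance_duration), summ(table$stride_time),
                summ(table$stance_fraction))
  data.frame(parameter = c("stance_duration", "stride_time", "stance_fraction"),
             median = vals[, "median"], iqr = vals[, "iqr"],
             n = as.integer(vals[, "n"]))
}
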