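#' Delimited-text readers and writers
#'
#' All time series travel as comma-separated text with a single leading
#' comment line carrying the schema tag and metadata
#' (`# insoleGait <type> v1 key=value ...`). Timestamps are written with six
#' fractional digits (10 us resolution, far below the 10 ms sample period);
#' undefined CoP values are empty fields. Writing is format-stable: a
#' write-read-write round trip is byte-identical.
#'
#' @name insole_io
NULL

fmt6 <- function(x) {
  out <- sprintf("%.6f", x)
  out[!is.finite(x)] <- ""
  out
}

write_schema_csv <- function(df, path, type, meta = character(0)) {
  meta_str <- if (length(meta)) paste0(" ", paste(names(meta), meta, sep = "=",
                                                  collapse = " ")) else ""
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# insoleGait %s v1%s", type, meta_str), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

read_schema_csv <- function(path, type) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop(sprintf("truncated file: %s", path), call. = FALSE)
  header <- lines[1]
  if (!startsWith(header, sprintf("# insoleGait %s v1", type))) {
    stop(sprintf("%s: expected an insoleGait %s file", path, type), call. = FALSE)
  }
  toks <- strsplit(sub(sprintf("^# insoleGait %s v1 ?", type), "", header), " ")[[1]]
  meta <- list()
  for (tk in toks[nzchar(toks)]) {
    kv <- strsplit(tk, "=")[[1]]
    meta[[kv[1]]] <- as.numeric(kv[2])
  }
  df <- tryCatch(
    utils::read.csv(text = lines[-1], stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("%s: malformed rows (%s)",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  list(data = df, meta = meta)
}

#' @param stream a [voltage_stream()].
#' @param path file path.
#' @rdname insole_io
#' @export
write_voltage_stream <- function(stream, path) {
  stopifnot(inherits(stream, "voltage_stream"))
  n <- ncol(stream$frames)
  df <- data.frame(time_s = fmt6(stream$timestamps))
  vf <- apply(stream$frames, 2, fmt6)
  if (is.null(dim(vf))) vf <- matrix(vf, nrow = 1L)
  colnames(vf) <- sprintf("v%02d", seq_len(n))
  write_schema_csv(cbind(df, vf), path, "voltage_stream",
                   c(rate = stream$sample_rate))
}

#' @rdname insole_io
#' @export
read_voltage_stream <- function(path) {
  x <- read_schema_csv(path, "voltage_stream")
  vcols <- grep("^v[0-9]+$", names(x$data))
  if (length(vcols) == 0L || anyNA(x$data$time_s)) {
    stop(sprintf("%s: malformed voltage stream", path), call. = FALSE)
  }
  voltage_stream(x$data$time_s, as.matrix(x$data[vcols]),
                 sample_rate = x$meta$rate)
}

#' @param signals a [gait_signals()] object.
#' @rdname insole_io
#' @export
write_gait_signals <- function(signals, path) {
  stopifnot(inherits(signals, "gait_signals"))
  df <- data.frame(time_s = fmt6(signals$timestamps),
                   vgrf_N = fmt6(signals$vgrf),
                   cop_ap_cm = fmt6(signals$cop_ap))
  write_schema_csv(df, path, "gait_signals",
                   c(rate = signals$sample_rate,
                     thresh = sprintf("%.6f", signals$vgrf_thresh)))
}

#' @rdname insole_io
#' @export
read_gait_signals <- function(path) {
  x <- read_schema_csv(path, "gait_signals")
  cop <- x$data$cop_ap_cm
  cop[is.na(cop)] <- NaN
  gait_signals(x$data$time_s, x$data$vgrf_N, cop,
               sample_rate = x$meta$rate, vgrf_thresh = x$meta$thresh)
}

#' @param ref a [reference_recording()].
#' @rdname insole_io
#' @export
write_reference_recording <- function(ref, path) {
  stopifnot(inherits(ref, "reference_recording"))
  df <- data.frame(time_s = fmt6(ref$timestamps),
                   vgrf_N = fmt6(ref$vgrf),
                   cop_ap_cm = fmt6(ref$cop_ap))
  write_schema_csv(df, path, "reference",
                   c(rate = ref$sample_rate, thresh = ref$event_threshold))
}

#' @rdname insole_io
#' @export
read_reference_recording <- function(path) {
  x <- read_schema_csv(path, "reference")
  cop <- x$data$cop_ap_cm
  cop[is.na(cop)] <- NaN
  reference_recording(x$data$time_s, x$data$vgrf_N, cop,
                      sample_rate = x$meta$rate,
                      event_threshold = x$meta$thresh)
}

#' @param table a [stride_table()].
#' @rdname insole_io
#' @export
write_stride_table <- function(table, path) {
  stopifnot(inherits(table, "stride_table"))
  df <- data.frame(stride_idx = table$stride_idx,
                   hs_s = fmt6(table$hs_time), to_s = fmt6(table$to_time),
                   stance_s = fmt6(table$stance_duration),
                   stride_s = fmt6(table$stride_time),
                   stance_frac = fmt6(table$stance_fraction))
  write_schema_csv(df, path, "stride_table")
}

#' @rdname insole_io
#' @export
read_stride_table <- function(path) {
  x <- read_schema_csv(path, "stride_table")
  if (nrow(x$data) == 0L) return(stride_table())
  stride_table(x$data$hs_s, x$data$to_s)
}

#' @param report a `validation_report` from [validate_recordings()].
#' @rdname insole_io
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
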