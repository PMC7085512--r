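#' Tactel calibration: polynomial force-to-voltage model
#'
#' A tactel (one LED-photodiode optoelectronic sensing element under a
#' deformable silicone frustum) behaves as a force-to-voltage transducer.
#' After zero-load de-offsetting, applied load drives the output voltage
#' negative; the calibration maps volts to newtons with a quartic polynomial
#' \deqn{F(V) = p_1 V^4 + p_2 V^3 + p_3 V^2 + p_4 V + p_5.}
#' The default coefficients are the factory calibration obtained by averaging
#' quasi-static load-unload cycles over 32 sensors.
#'
#' The piecewise sensing rule treats voltages above the noise-floor threshold
#' `v_thresh` as unloaded (zero force). The polynomial is strictly decreasing
#' in voltage on the operational range `[v_saturation, 0]`, so force grows as
#' voltage goes negative, up to `f_saturation = F(v_saturation)`.
#'
#' @param p1,p2,p3,p4,p5 polynomial coefficients (N V^-4 ... N V^-1, N).
#' @param v_thresh noise-floor voltage threshold (V), must lie in
#'   `(v_saturation, 0)`.
#' @param v_saturation voltage at sensor saturation (V).
#' @return An object of class `tactel_calibration` with fields `p` (length-5
#'   coefficient vector, highest degree first), `v_thresh`, `v_saturation`,
#'   and the derived `f_saturation` (N).
#' @examples
#' cal <- tactel_calibration()
#' force_from_voltage(cal, -1)     # force at saturation, 44.95 N
#' system_force_threshold(cal, 16) # the ~3 N foot-contact threshold
#' @export
tactel_calibration <- function(p1 = 186.1, p2 = 224.5, p3 = 64.76,
                               p4 = -18.59, p5 = 0,
                               v_thresh = -0.01, v_saturation = -1.0) {
  p <- c(p1, p2, p3, p4, p5)
  stopifnot(is.numeric(p), length(p) == 5L, all(is.finite(p)))
  if (!is.finite(v_thresh) || !is.finite(v_saturation) ||
      !(v_saturation < v_thresh && v_thresh < 0)) {
    stop("require v_saturation < v_thresh < 0", call. = FALSE)
  }
  cal <- structure(
    list(p = p, v_thresh = v_thresh, v_saturation = v_saturation,
         f_saturation = NA_real_),
    class = "tactel_calibration"
  )
  cal$f_saturation <- poly_force(cal, v_saturation)
  cal
}

#' @export
print.tactel_calibration <- function(x, ...) {
  cat("Tactel calibration (quartic force-to-voltage model)\n")
  cat(sprintf("  p1..p5: %s\n", paste(format(x$p), collapse = ", ")))
  cat(sprintf("  v_thresh: %g V  v_saturation: %g V  f_saturation: %.4g N\n",
              x$v_thresh, x$v_saturation, x$f_saturation))
  invisible(x)
}

# raw polynomial, no piecewise rule, no clamping
poly_force <- function(cal, v) {
  p <- cal$p
  ((p[1] * v + p[2]) * v + p[3]) * v^2 + p[4] * v + p[5]
}

#' Convert tactel voltage to force
#'
#' Applies the piecewise sensing rule: voltages above the noise threshold
#' read zero force; otherwise the calibration polynomial is evaluated.
#' Voltages below saturation are clamped to `v_saturation` (the polynomial is
#' not trusted outside its fitted range), and tiny negative numerical residue
#' is clamped to zero.
#'
#' Note the deliberate discontinuity at `v_thresh`: the polynomial value
#' there (about 0.192 N with default coefficients) drops to 0 one epsilon
#' above the threshold. That is the device's literal definition and is kept,
#' not smoothed.
#'
#' @param cal a [tactel_calibration()].
#' @param v voltage(s), V; vectorized.
#' @return Force(s) in newtons, same length as `v`.
#' @export
force_from_voltage <- function(cal, v) {
  stopifnot(inherits(cal, "tactel_calibration"))
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
    stop("voltage must be finite", call. = FALSE)
  }
  v <- pmax(v, cal$v_saturation)
  f <- poly_force(cal, v)
  f[v > cal$v_thresh] <- 0
  pmax(f, 0)
}

#' Invert the calibration: force to voltage
#'
#' Numerical inverse of the calibration polynomial on the operational voltage
#' range, used by the simulator to synthesize raw channel voltages from known
#' per-tactel forces. The polynomial is strictly monotone on
#' `[v_saturation, 0]`, so a bracketed root search converges to machine
#' precision.
#'
#' `f = 0` maps to `v_thresh` by convention (the boundary of the sensing
#' branch). Because the sensing rule zeroes forces above `v_thresh`, the
#' round trip `force_from_voltage(voltage_from_force(f)) == f` holds exactly
#' for `f >= force_from_voltage(cal, v_thresh)` (about 0.192 N); smaller
#' positive forces invert to voltages inside the dead band.
#'
#' @param cal a [tactel_calibration()].
#' @param f force(s), N, each in `[0, f_saturation]`; vectorized.
#' @return Voltage(s) in volts.
#' @export
voltage_from_force <- function(cal, f) {
  stopifnot(inherits(cal, "tactel_calibration"))
  if (!is.numeric(f) || anyNA(f) || any(!is.finite(f))) {
    stop("force must be finite", call. = FALSE)
  }
  if (any(f < 0 | f > cal$f_saturation)) {
    stop(sprintf("force outside [0, f_saturation = %.4g N]", cal$f_saturation),
         call. = FALSE)
  }
  vapply(f, function(fi) {
    if (fi == 0) return(cal$v_thresh)
    if (fi == cal$f_saturation) return(cal$v_saturation)
    stats::uniroot(function(v) poly_force(cal, v) - fi,
                   lower = cal$v_saturation, upper = 0,
                   tol = 1e-12)$root
  }, numeric(1))
}

#' Foot-contact force threshold for an n-sensor system
#'
#' The system-level vGRF detection threshold is defined as all sensors
#' simultaneously reading the noise-floor voltage:
#' `n_sensors * f(v_thresh)` evaluated on the polynomial branch. With the
#' default 16-tactel calibration this is 3.074 N, the ~3 N foot-contact
#' threshold.
#'
#' @param cal a [tactel_calibration()].
#' @param n_sensors number of tactels (>= 1).
#' @return Threshold in newtons.
#' @export
system_force_threshold <- function(cal, n_sensors = 16L) {
  stopifnot(inherits(cal, "tactel_calibration"))
  if (!is.numeric(n_sensors) || length(n_sensors) != 1L || n_sensors < 1) {
    stop("n_sensors must be >= 1", call. = FALSE)
  }
  n_sensors * poly_force(cal, cal$v_thresh)
}

#' One quasi-static load-unload cycle of one tactel
#'
#' Container for a calibration bench recording: paired voltage/force samples
#' with a direction label per sample.
#'
#' @param voltage voltages (V).
#' @param force forces (N), non-negative.
#' @param direction per-sample `"loading"`/`"unloading"` labels (recycled if
#'   length 1).
#' @return A `load_unload_curve` object (data.frame-backed).
#' @export
load_unload_curve <- function(voltage, force, direction = "loading") {
  stopifnot(length(voltage) == length(force))
  if (any(force < 0)) stop("forces must be non-negative", call. = FALSE)
  direction <- rep_len(as.character(direction), length(voltage))
  if (!all(direction %in% c("loading", "unloading"))) {
    stop("direction must be 'loading' or 'unloading'", call. = FALSE)
  }
  structure(
    data.frame(voltage = voltage, force = force, direction = direction,
               stringsAsFactors = FALSE),
    class = c("load_unload_curve", "data.frame")
  )
}

#' Fit a tactel calibration from load-unload curves
#'
#' Reproduces the bench calibration workflow: for each cycle, the loading and
#' unloading branches are interpolated onto a common voltage grid and
#' averaged (removing hysteresis); the per-cycle mean curves are then
#' averaged across sensors; finally a degree-4 polynomial with zero intercept
#' (`p5 = 0`, so zero de-offset voltage means zero force) is least-squares
#' fitted to the grand mean curve.
#'
#' @param curves list of [load_unload_curve()] objects (>= 1, each with >= 10
#'   points).
#' @param n_grid number of points of the common voltage grid.
#' @param v_thresh,v_saturation thresholds to stamp on the returned
#'   calibration (the fit itself does not use them).
#' @return A [tactel_calibration()] with an extra `fit` field listing `sse`,
#'   `r_squared`, `adj_r_squared`, `rmse`, `n` (grid points used).
#' @export
fit_calibration <- function(curves, n_grid = 200L,
                            v_thresh = -0.01, v_saturation = -1.0) {
  if (!is.list(curves) || length(curves) < 1L) {
    stop("need at least one load-unload curve", call. = FALSE)
  }
  if (inherits(curves, "load_unload_curve")) curves <- list(curves)
  for (cv in curves) {
    if (!inherits(cv, "load_unload_curve")) {
      stop("curves must be load_unload_curve objects", call. = FALSE)
    }
    if (nrow(cv) < 10L) stop("each curve needs >= 10 points", call. = FALSE)
  }
  vmin <- max(vapply(curves, function(cv) min(cv$voltage), numeric(1)))
  vmax <- min(vapply(curves, function(cv) max(cv$voltage), numeric(1)))
  if (!(vmin < vmax)) stop("curves share no voltage overlap", call. = FALSE)
  # common grid = observed voltages inside the overlap (no invented lattice:
  # evaluating at actual sample points keeps noiseless recovery exact),
  # thinned evenly if denser than n_grid
  grid <- sort(unique(unlist(lapply(curves, function(cv) cv$voltage))))
  grid <- grid[grid >= vmin & grid <= vmax]
  if (length(grid) > n_grid) {
    grid <- grid[unique(round(seq(1, length(grid), length.out = n_grid)))]
  }
  if (length(grid) < 5L) {
    stop("degenerate grid: fewer than 5 distinct voltages", call. = FALSE)
  }

  branch_mean <- function(cv) {
    per_branch <- lapply(split(cv, cv$direction), function(b) {
      if (length(unique(b$voltage)) < 5L) return(NULL)
      stats::approx(b$voltage, b$force, xout = grid, rule = 2,
                    ties = mean)$y
    })
    per_branch <- Filter(Negate(is.null), per_branch)
    if (length(per_branch) == 0L) {
      stop("degenerate curve: fewer than 5 distinct voltages", call. = FALSE)
    }
    Reduce(`+`, per_branch) / length(per_branch)
  }
  mean_curve <- Reduce(`+`, lapply(curves, branch_mean)) / length(curves)

  # zero-intercept quartic least squares on the grand mean curve
  X <- cbind(grid^4, grid^3, grid^2, grid)
  fit <- stats::lm.fit(X, mean_curve)
  coefs <- unname(fit$coefficients)
  resid <- fit$residuals
  sse <- sum(resid^2)
  sst <- sum((mean_curve - mean(mean_curve))^2)
  n <- length(grid)
  k <- 4L
  r2 <- 1 - sse / sst
  cal <- tactel_calibration(coefs[1], coefs[2], coefs[3], coefs[4], 0,
                            v_thresh = v_thresh, v_saturation = v_saturation)
  cal$fit <- list(
    sse = sse,
    r_squared = r2,
    adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - k - 1),
    rmse = sqrt(sse / (n - k)),
    n = n
  )
  cal
}

#' Read/write a calibration as JSON
#'
#' The on-disk document is `{p1..p5, v_thresh, v_saturation}`;
#' `f_saturation` is re-derived on load.
#'
#' @param cal a [tactel_calibration()].
#' @param path file path.
#' @return `read_calibration` returns a [tactel_calibration()];
#'   `write_calibration` returns `path` invisibly.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "tactel_calibration"))
  doc <- list(p1 = cal$p[1], p2 = cal$p[2], p3 = cal$p[3], p4 = cal$p[4],
              p5 = cal$p[5], v_thresh = cal$v_thresh,
              v_saturation = cal$v_saturation)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  tactel_calibration(doc$p1, doc$p2, doc$p3, doc$p4, doc$p5,
                     v_thresh = doc$v_thresh,
                     v_saturation = doc$v_saturation)
}
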