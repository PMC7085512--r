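#' Insole sensor layout and spatial-density weights
#'
#' The insole carries a small number of tactels clustered in the plantar
#' regions most relevant for gait-event detection (heel, metatarsal heads,
#' hallux). Because the distribution along the antero-posterior (AP, heel to
#' toe) axis is non-uniform, the center-of-pressure estimate weights each
#' tactel by the inverse of the local sensor density: tactels sharing an AP
#' bin get weight `1 / bin count`, so a cluster of co-located sensors counts
#' once, not n times, in the CoP centroid.
#'
#' @param positions data.frame with columns `id` (unique integers), `ap`
#'   (antero-posterior coordinate, cm, 0 at heel) and optionally `ml`
#'   (medio-lateral coordinate, cm, informational).
#' @param foot_length foot length in cm; AP coordinates must fit in
#'   `[0, foot_length]`.
#' @param bin_width AP bin width (cm) used to decide which tactels share a
#'   coordinate. Bin edges are anchored at the heel (coordinate 0).
#' @return An `insole_layout` object: list with `positions` (including an
#'   `ap_weight` column), `foot_length`, `bin_width`.
#' @examples
#' lay <- insole_layout(data.frame(id = 1:4, ap = c(0, 0, 5, 10)),
#'                      foot_length = 26)
#' lay$positions$ap_weight  # 0.5 0.5 1 1
#' @export
insole_layout <- function(positions, foot_length, bin_width = 1) {
  if (!is.data.frame(positions) || nrow(positions) == 0L) {
    stop("positions must be a non-empty data.frame", call. = FALSE)
  }
  stopifnot(all(c("id", "ap") %in% names(positions)))
  if (anyDuplicated(positions$id)) stop("tactel ids must be unique", call. = FALSE)
  if (!is.numeric(foot_length) || foot_length <= 0) {
    stop("foot_length must be > 0", call. = FALSE)
  }
  if (any(positions$ap < 0 | positions$ap > foot_length)) {
    stop("AP coordinates must lie in [0, foot_length]", call. = FALSE)
  }
  if (is.null(positions$ml)) positions$ml <- NA_real_
  positions <- positions[c("id", "ap", "ml")]
  positions$ap_weight <- compute_ap_weights(positions, bin_width)
  structure(list(positions = positions, foot_length = foot_length,
                 bin_width = bin_width),
            class = "insole_layout")
}

#' @export
print.insole_layout <- function(x, ...) {
  cat(sprintf("Insole layout: %d tactels, foot length %g cm, AP bin %g cm\n",
              nrow(x$positions), x$foot_length, x$bin_width))
  print(x$positions, row.names = FALSE)
  invisible(x)
}

#' Compute antero-posterior spatial-density weights
#'
#' Tactels are grouped into fixed-width AP bins anchored at the heel; each
#' tactel's weight is the reciprocal of the number of tactels in its bin.
#' Weights therefore lie in (0, 1], and summing `count * weight` over
#' distinct bins recovers the number of distinct bins.
#'
#' @param positions data.frame with an `ap` column (cm).
#' @param bin_width bin width, cm, > 0.
#' @return Numeric vector of per-tactel weights, in input order.
#' @export
compute_ap_weights <- function(positions, bin_width = 1) {
  if (is.null(positions) || nrow(as.data.frame(positions)) == 0L) {
    stop("empty position list", call. = FALSE)
  }
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("bin_width must be > 0", call. = FALSE)
  }
  bin <- floor(positions$ap / bin_width)
  counts <- table(bin)
  as.numeric(1 / counts[as.character(bin)])
}

#' Scale a layout to a different foot length
#'
#' AP and ML coordinates are scaled proportionally; the AP bin width scales
#' with the foot so that clustering (and hence the weights) is invariant
#' under uniform scaling.
#'
#' @param layout an [insole_layout()].
#' @param new_foot_length target foot length, cm, > 0.
#' @return A scaled [insole_layout()].
#' @export
scale_layout <- function(layout, new_foot_length) {
  stopifnot(inherits(layout, "insole_layout"))
  if (!is.numeric(new_foot_length) || new_foot_length <= 0) {
    stop("new_foot_length must be > 0", call. = FALSE)
  }
  s <- new_foot_length / layout$foot_length
  pos <- layout$positions[c("id", "ap", "ml")]
  pos$ap <- pos$ap * s
  pos$ml <- pos$ml * s
  insole_layout(pos, foot_length = new_foot_length,
                bin_width = layout$bin_width * s)
}

#' Default 16-tactel layout
#'
#' Ships a synthetic 16-sensor arrangement qualitatively mimicking the
#' device: a 5-sensor heel cluster, 2 midfoot sensors, a 7-sensor metatarsal
#' cluster and 2 toe sensors on a 26 cm foot. The true PCB coordinates are
#' unpublished; this layout is a plausible stand-in, not a fidelity claim.
#'
#' @param foot_length foot length, cm.
#' @param bin_width AP bin width, cm.
#' @return An [insole_layout()].
#' @export
default_layout <- function(foot_length = 26, bin_width = 1) {
  base <- data.frame(
    id = 1:16,
    ap = c(2.0, 2.0, 2.5, 3.5, 3.5,        # heel cluster
           9.0, 12.0,                      # midfoot
           16.5, 16.5, 17.0, 17.5, 17.5, 18.0, 18.5,  # metatarsal cluster
           22.5, 24.0),                    # hallux / toe
    ml = c(-1.5, 1.5, 0.0, -1.8, 1.8,
           -2.0, -2.2,
           -3.0, 3.0, -1.5, 1.5, 0.0, -2.5, 2.5,
           0.5, 1.0)
  )
  base$ap <- base$ap * foot_length / 26
  base$ml <- base$ml * foot_length / 26
  insole_layout(base, foot_length = foot_length, bin_width = bin_width)
}

#' Read/write an insole layout as JSON
#'
#' Document shape: `{foot_length_cm, bin_width_cm, tactels: [{id, ap_cm,
#' ml_cm}]}`.
#'
#' @param layout an [insole_layout()].
#' @param path file path.
#' @return `read_layout` returns an [insole_layout()]; `write_layout`
#'   returns `path` invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "insole_layout"))
  doc <- list(
    foot_length_cm = layout$foot_length,
    bin_width_cm = layout$bin_width,
    tactels = data.frame(id = layout$positions$id,
                         ap_cm = layout$positions$ap,
                         ml_cm = layout$positions$ml)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  pos <- data.frame(id = doc$tactels$id, ap = doc$tactels$ap_cm,
                    ml = doc$tactels$ml_cm)
  insole_layout(pos, foot_length = doc$foot_length_cm,
                bin_width = doc$bin_width_cm)
}
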