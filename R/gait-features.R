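#' Knee flexion curve container
#'
#' A uniformly sampled knee flexion angle time series (degrees, flexion
#' positive).
#'
#' @param angle_deg Numeric vector of flexion angles in degrees.
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `kneeload_flexion` with elements `time`,
#'   `angle_deg` and `fs`.
#' @export
flexion_curve <- function(angle_deg, fs = 100, t0 = 0) {
  stopifnot(is.numeric(angle_deg), fs > 0)
  if (any(!is.finite(angle_deg))) {
    kneeload_abort("flexion curve contains non-finite values", "invalid_argument")
  }
  structure(
    list(time = t0 + (seq_along(angle_deg) - 1) / fs, angle_deg = as.numeric(angle_deg), fs = fs),
    class = "kneeload_flexion"
  )
}

#' @export
print.kneeload_flexion <- function(x, ...) {
  cat(sprintf(
    "<flexion curve: %d samples @ %g Hz, range %.1f..%.1f deg>\n",
    length(x$angle_deg), x$fs, min(x$angle_deg), max(x$angle_deg)
  ))
  invisible(x)
}

#' Stance window
#'
#' Half-open index window `[start, end)` (1-based) into a parent time series.
#'
#' @param start First sample index of stance (1-based, inclusive).
#' @param end One past the last stance sample (exclusive).
#' @return An object of class `kneeload_stance`.
#' @export
stance_window <- function(start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end <= start) {
    kneeload_abort("stance window must satisfy 1 <= start < end", "invalid_argument")
  }
  structure(list(start = start, end = end), class = "kneeload_stance")
}

stance_length <- function(stance) stance$end - stance$start

#' Medial/lateral knee contact force curve pair over stance
#'
#' @param medial,lateral Non-negative force curves (N), equal length,
#'   cropped to the stance phase.
#' @param fs Sampling rate in Hz.
#' @return An object of class `kneeload_kjcf` with elements `medial`,
#'   `lateral` and `summed` (their pointwise sum).
#' @export
kjcf_curve_pair <- function(medial, lateral, fs = 100) {
  if (length(medial) != length(lateral)) {
    kneeload_abort("medial and lateral curves must have equal length", "invalid_argument")
  }
  if (any(medial < 0) || any(lateral < 0)) {
    kneeload_abort("contact forces must be non-negative", "invalid_argument")
  }
  structure(
    list(medial = as.numeric(medial), lateral = as.numeric(lateral),
         summed = as.numeric(medial) + as.numeric(lateral), fs = fs),
    class = "kneeload_kjcf"
  )
}

#' Names of the nine loading-peak response variables
#'
#' Three peak types (loading response `lr`, terminal extension `te`,
#' full-stance maximum `max`) for each of the summed, medial and lateral
#' compartment curves.
#'
#' @return Character vector of length nine in canonical order.
#' @export
kjcf_peak_names <- function() {
  as.vector(outer(c("lr", "te", "max"), c("summed", "medial", "lateral"),
                  function(a, b) paste(a, b, sep = "_")))
}

#' Scalar knee flexion angle predictor
#'
#' The KFA predictor summarises a stance-phase flexion curve as the maximum
#' of its first half minus the minimum of its second half (degrees). The
#' half boundary is at `start + floor(len/2)`; the first half is
#' `[start, mid)` and the second `[mid, end)`.
#'
#' @param curve A [flexion_curve()].
#' @param stance A [stance_window()] into `curve` spanning at least 4 samples.
#' @return The predictor value in degrees (may be negative for atypical
#'   curves).
#' @export
compute_kfa_predictor <- function(curve, stance) {
  stopifnot(inherits(curve, "kneeload_flexion"), inherits(stance, "kneeload_stance"))
  n <- stance_length(stance)
  if (n < 4L) kneeload_abort("stance window must span at least 4 samples", "invalid_argument")
  if (stance$end - 1L > length(curve$angle_deg)) {
    kneeload_abort("stance window exceeds curve length", "invalid_argument")
  }
  mid <- stance$start + n %/% 2L
  first <- curve$angle_deg[stance$start:(mid - 1L)]
  second <- curve$angle_deg[mid:(stance$end - 1L)]
  max(first) - min(second)
}

# single-curve peak extraction used by extract_loading_peaks: locations come
# from strict local maxima of the 5-sample moving-average-smoothed curve,
# values are read off the raw curve at those locations (smoothing flattens
# narrow peaks, so reporting the smoothed value would bias heights low);
# fallback when a half holds no interior local maximum is the raw maximum of
# that half
curve_half_peaks <- function(x, smooth_n = 5L) {
  n <- length(x)
  sm <- moving_average(x, smooth_n)
  cand <- local_maxima(sm)
  nh <- n %/% 2L
  pick <- function(idx_range) {
    in_half <- cand[cand %in% idx_range]
    if (length(in_half)) {
      x[in_half[which.max(sm[in_half])]]
    } else {
      max(x[idx_range])
    }
  }
  lr <- pick(seq_len(nh))
  te <- pick((nh + 1L):n)
  c(lr = lr, te = te, max = max(lr, te))
}

#' Extract the nine stance-phase loading peaks
#'
#' For each of the summed, medial and lateral compartment curves the loading
#' response peak (largest local maximum in the first half of stance), the
#' terminal extension peak (largest local maximum in the second half) and
#' the full-stance maximum (the larger of the two) are extracted. Local
#' maxima are located on a 5-sample moving-average smoothed copy of the
#' curve; peak values are read from the raw curve. If a half contains no
#' interior local maximum, the raw maximum over that half is used.
#'
#' @param curves A [kjcf_curve_pair()] cropped to stance.
#' @param smooth_n Moving-average window (samples) used for peak location.
#' @return A list with `peaks` (named numeric vector of length nine, see
#'   [kjcf_peak_names()]) and `degenerate` (TRUE when every sample of the
#'   summed curve is zero).
#' @export
extract_loading_peaks <- function(curves, smooth_n = 5L) {
  stopifnot(inherits(curves, "kneeload_kjcf"))
  if (length(curves$summed) < 4L) {
    kneeload_abort("stance curves must span at least 4 samples", "invalid_argument")
  }
  res <- c(
    curve_half_peaks(curves$summed, smooth_n),
    curve_half_peaks(curves$medial, smooth_n),
    curve_half_peaks(curves$lateral, smooth_n)
  )
  names(res) <- kjcf_peak_names()
  list(peaks = res, degenerate = all(curves$summed == 0))
}

#' Maximum isometric muscle force scaling factor
#'
#' Muscle strength is assumed to scale allometrically with body mass
#' (cross-sectional area goes as mass^(2/3)); a multiplier of 1.5 keeps
#' activations submaximal at the fastest walking speeds.
#'
#' @param subject_mass,generic_mass Subject and generic-model body mass (kg).
#' @return The scale factor `1.5 * (subject_mass / generic_mass)^(2/3)`.
#' @export
scale_max_isometric_force <- function(subject_mass, generic_mass) {
  if (!is.finite(subject_mass) || !is.finite(generic_mass) ||
      subject_mass <= 0 || generic_mass <= 0) {
    kneeload_abort("masses must be positive", "invalid_argument")
  }
  1.5 * (subject_mass / generic_mass)^(2 / 3)
}

#' Segment the stance phase from a vertical force or contact series
#'
#' Returns the longest contiguous run of samples above `threshold` (for a
#' numeric series) or of TRUE values (for a logical series) as a stance
#' window.
#'
#' @param x Numeric vertical force series (N) or logical contact flags.
#' @param threshold Force threshold in N (ignored for logical input).
#' @return A [stance_window()].
#' @export
segment_stance <- function(x, threshold = 20) {
  above <- if (is.logical(x)) x else x > threshold
  if (!any(above)) kneeload_abort("no samples above the contact threshold", "no_stance")
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  stance_window(starts[best], ends[best] + 1L)
}
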