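# accessor: one landmark's pixel coordinates and confidence
kp_landmark <- function(series, name) {
  j <- body25_index()[[name]]
  list(x = series$xyc[, j, 1], y = series$xyc[, j, 2], c = series$xyc[, j, 3])
}

#' Estimate the camera scale from a keypoint series
#'
#' Uses the anthropometric ratio that the ankle-to-vertex distance is about
#' 0.936 of stature: on frames where the head (nose) and at least one ankle
#' are detected with confidence and the person is inside the central part of
#' the image, the pixel extent from head to the lower (planted) ankle is
#' measured, and `metres_per_pixel = 0.936 * height / median extent`. An
#' explicit override short-circuits the estimate.
#'
#' @param series A keypoint series (class `kneeload_keypoints`).
#' @param height_cm Subject stature (cm).
#' @param min_confidence Minimum landmark confidence for a frame to qualify.
#' @param override Optional known metres-per-pixel value, returned verbatim.
#' @param height_ratio Ankle-to-vertex stature fraction.
#' @return A list with `m_per_px` and `n_frames` used.
#' @export
estimate_scale <- function(series, height_cm, min_confidence = 0.5,
                           override = NULL, height_ratio = 0.936) {
  if (!is.null(override)) {
    if (override <= 0) kneeload_abort("scale override must be positive", "invalid_argument")
    return(list(m_per_px = override, n_frames = 0L))
  }
  stopifnot(inherits(series, "kneeload_keypoints"))
  nose <- kp_landmark(series, "nose")
  a_r <- kp_landmark(series, "ankle_r")
  a_l <- kp_landmark(series, "ankle_l")
  central <- nose$x >= 0.08 * series$image_width & nose$x <= 0.92 * series$image_width
  ok_r <- a_r$c >= min_confidence
  ok_l <- a_l$c >= min_confidence
  low_y <- pmax(ifelse(ok_r, a_r$y, -Inf), ifelse(ok_l, a_l$y, -Inf))
  use <- central & nose$c >= min_confidence & is.finite(low_y)
  if (!any(use)) {
    kneeload_abort("no frame qualifies for scale calibration", "calibration")
  }
  extent <- low_y[use] - nose$y[use]
  list(m_per_px = height_ratio * (height_cm / 100) / stats::median(extent),
       n_frames = sum(use))
}

#' Estimate walking speed from the hip keypoint
#'
#' Fits a least-absolute-deviations straight line to the mid-hip horizontal
#' pixel coordinate against time over frames with sufficient confidence;
#' the absolute slope, converted through the camera scale, is the walking
#' speed. The absolute value makes the estimate direction-agnostic, and the
#' robust fit tolerates keypoint dropouts.
#'
#' @param series A keypoint series.
#' @param scale Result of [estimate_scale()] (or a list with `m_per_px`).
#' @param min_confidence Minimum hip confidence for a frame to be used.
#' @return Walking speed in cm/s.
#' @export
estimate_walking_speed_vc <- function(series, scale, min_confidence = 0.3) {
  stopifnot(inherits(series, "kneeload_keypoints"))
  hip <- kp_landmark(series, "mid_hip")
  use <- hip$c >= min_confidence
  if (sum(use) < 10L) {
    kneeload_abort("fewer than 10 frames with a confident hip keypoint",
                   "insufficient_data")
  }
  beta <- lad_line(series$time[use], hip$x[use])
  abs(beta[2]) * scale$m_per_px * 100
}

#' Estimate the knee flexion angle series from keypoints
#'
#' Per frame, flexion is 180 degrees minus the included angle between the
#' knee-to-hip and knee-to-ankle vectors of the chosen leg (collinear
#' landmarks give 0, full extension). Frames where any of the three
#' landmarks falls below the confidence threshold are linearly interpolated
#' from neighbouring accepted frames so the series stays uniformly sampled.
#'
#' @param series A keypoint series.
#' @param leg `"right"` or `"left"`.
#' @param min_confidence Confidence threshold.
#' @param smooth Apply Savitzky-Golay smoothing to the angle series.
#' @return A [flexion_curve()] at the series frame rate.
#' @export
estimate_kfa_series_vc <- function(series, leg = c("right", "left"),
                                   min_confidence = 0.3, smooth = TRUE) {
  stopifnot(inherits(series, "kneeload_keypoints"))
  leg <- match.arg(leg)
  sfx <- substr(leg, 1, 1)
  hip <- kp_landmark(series, paste0("hip_", sfx))
  knee <- kp_landmark(series, paste0("knee_", sfx))
  ankle <- kp_landmark(series, paste0("ankle_", sfx))
  good <- hip$c >= min_confidence & knee$c >= min_confidence & ankle$c >= min_confidence
  if (mean(good) < 0.5) {
    kneeload_abort("more than half of the frames fall below the confidence threshold",
                   "low_quality")
  }
  interp <- function(v) {
    if (all(good)) return(v)
    approx(series$time[good], v[good], xout = series$time, rule = 2)$y
  }
  v1x <- interp(hip$x) - interp(knee$x)
  v1y <- interp(hip$y) - interp(knee$y)
  v2x <- interp(ankle$x) - interp(knee$x)
  v2y <- interp(ankle$y) - interp(knee$y)
  cosang <- (v1x * v2x + v1y * v2y) /
    pmax(sqrt(v1x^2 + v1y^2) * sqrt(v2x^2 + v2y^2), 1e-9)
  flex <- 180 - rad2deg(acos(clamp(cosang, -1, 1)))
  if (smooth) flex <- sg_smooth(flex)
  flexion_curve(flex, series$fs)
}

#' Detect proxy heel strikes from the ankle pixel trajectory
#'
#' In a sagittal view the planted foot holds the ankle at a stable ground
#' level (maximum pixel y, since the image y axis points down) while swing
#' lifts it. Ground-contact runs are found as frames whose smoothed ankle y
#' lies within a tolerance of the ground level; each run start is a proxy
#' heel strike.
#'
#' @param series A keypoint series.
#' @param leg Analyzed leg.
#' @param min_confidence Confidence threshold for interpolation.
#' @param contact_tol Contact tolerance as a fraction of the vertical ankle
#'   excursion.
#' @return List with `events_idx`, `events_t` and `gait_period_s`.
#' @export
detect_gait_cycles_vc <- function(series, leg = "right", min_confidence = 0.3,
                                  contact_tol = 0.15) {
  sfx <- substr(leg, 1, 1)
  ankle <- kp_landmark(series, paste0("ankle_", sfx))
  good <- ankle$c >= min_confidence
  if (sum(good) < 10L) kneeload_abort("too few confident ankle frames", "insufficient_data")
  y <- approx(series$time[good], ankle$y[good], xout = series$time, rule = 2)$y
  y <- lowpass(y, 6, series$fs)
  ground <- stats::quantile(y, 0.9)
  # robust excursion: inter-quantile range guards against residual edge
  # artefacts and jitter outliers
  rng <- as.numeric(stats::quantile(y, 0.98) - stats::quantile(y, 0.02))
  if (rng < 1e-6) kneeload_abort("ankle shows no vertical excursion", "insufficient_cycles")
  contact <- y >= ground - contact_tol * rng
  r <- rle(contact)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hs <- starts[r$values & starts > 1L]
  if (length(hs) < 2L) {
    kneeload_abort("fewer than two ground-contact episodes detected",
                   "insufficient_cycles")
  }
  list(events_idx = hs, events_t = series$time[hs],
       gait_period_s = stats::median(diff(series$time[hs])))
}

#' Estimate both portable predictors from a keypoint series
#'
#' Chains scale calibration, hip-tracking speed estimation, knee-angle
#' extraction and proxy heel-strike detection; the KFA predictor is computed
#' per detected stance window (heel strike to heel strike + stance fraction
#' x gait period) and summarised by the median.
#'
#' @param series A keypoint series.
#' @param height_cm Subject stature (cm).
#' @param leg Analyzed leg.
#' @param min_confidence Confidence threshold.
#' @param stance_fraction Stance duration as a fraction of the gait cycle.
#' @param trim_fraction Fraction of each stance window trimmed at both ends
#'   before the predictor is computed (absorbs proxy-heel-strike timing
#'   error; the KFA extrema are interior to stance).
#' @param scale_override Optional known metres-per-pixel value.
#' @param smooth Smooth the KFA series.
#' @return List with `speed_cm_s`, `kfa_predictor_deg`, `gait_period_s`,
#'   `m_per_px` and per-stance predictor values.
#' @export
estimate_predictors_vc <- function(series, height_cm, leg = "right",
                                   min_confidence = 0.3, stance_fraction = 0.62,
                                   trim_fraction = 0.15,
                                   scale_override = NULL, smooth = TRUE) {
  scale <- estimate_scale(series, height_cm, override = scale_override)
  speed <- estimate_walking_speed_vc(series, scale, min_confidence)
  curve <- estimate_kfa_series_vc(series, leg, min_confidence, smooth)
  ev <- detect_gait_cycles_vc(series, leg, min_confidence)
  n_st <- round(stance_fraction * ev$gait_period_s * series$fs)
  k <- round(trim_fraction * n_st)
  per_stance <- numeric(0)
  for (i0 in ev$events_idx) {
    ia <- i0 + k
    ib <- i0 + n_st - k
    if (ib - ia < 4L || ib - 1L > length(curve$angle_deg)) next
    per_stance <- c(per_stance,
                    compute_kfa_predictor(curve, stance_window(ia, ib)))
  }
  if (!length(per_stance)) {
    kneeload_abort("no complete stance windows for the KFA predictor",
                   "insufficient_cycles")
  }
  list(speed_cm_s = speed, kfa_predictor_deg = stats::median(per_stance),
       gait_period_s = ev$gait_period_s, m_per_px = scale$m_per_px,
       kfa_per_stance = per_stance)
}
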