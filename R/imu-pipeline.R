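#' Kinematic-chain and gait-event configuration for the IMU pipeline
#'
#' @param thigh_fraction,shank_fraction Segment lengths as fractions of
#'   stature (standard anthropometric table values).
#' @param stance_fraction Stance duration as a fraction of the gait cycle,
#'   used to place the stance window after each detected heel strike (no
#'   force plate is available in portable use).
#' @param lowpass_hz Low-pass cutoff for the acceleration magnitude before
#'   event detection.
#' @param min_separation_s Minimum separation between detected heel strikes.
#' @param prominence_factor Required peak prominence as a multiple of the
#'   filtered-signal SD.
#' @param trim_fraction Fraction of each stance window trimmed at both ends
#'   before displacement and KFA-predictor computation; absorbs heel-strike
#'   timing error (the detected acceleration peak can sit a few samples off
#'   the true foot-contact instant).
#' @param pos_avg_samples Number of samples averaged inward from each trimmed
#'   window endpoint when reading off foot displacement; averaging preserves
#'   the linear stance-phase trend while suppressing orientation noise.
#' @return An object of class `kneeload_chain`.
#' @export
chain_config <- function(thigh_fraction = 0.245, shank_fraction = 0.246,
                         stance_fraction = 0.62, lowpass_hz = 10,
                         min_separation_s = 0.4, prominence_factor = 0.5,
                         trim_fraction = 0.15, pos_avg_samples = 5L) {
  if (thigh_fraction <= 0 || thigh_fraction >= 0.5 ||
      shank_fraction <= 0 || shank_fraction >= 0.5) {
    kneeload_abort("segment fractions must lie in (0, 0.5)", "invalid_argument")
  }
  structure(as.list(environment()), class = "kneeload_chain")
}

#' Detect gait cycles from shank acceleration
#'
#' The dominant gait period is first estimated from the autocorrelation of
#' the low-pass-filtered acceleration magnitude (the strongest lag beyond
#' the minimum separation); heel strikes are then taken as peaks of the
#' filtered magnitude separated by at least 0.7 of that period, with a
#' minimum topographic prominence of `prominence_factor` times the filtered
#' signal's SD. The gait period is the median inter-event interval.
#'
#' @param stream A shank IMU stream (class `kneeload_imu`).
#' @param chain A [chain_config()].
#' @return List with `events_idx` (sample indices), `events_t` (seconds) and
#'   `gait_period_s`.
#' @export
detect_gait_cycles <- function(stream, chain = chain_config()) {
  stopifnot(inherits(stream, "kneeload_imu"))
  fs <- stream$fs
  if (nrow(stream$accel) < 2 * fs) {
    kneeload_abort("need at least 2 s of acceleration data", "insufficient_cycles")
  }
  mag <- sqrt(rowSums(stream$accel^2))
  filt <- lowpass(mag, chain$lowpass_hz, fs)
  s <- stats::sd(filt)
  # 1e-4 m/s^2 is far below any walking signal: treat as constant input
  if (!is.finite(s) || s < 1e-4 || stats::sd(mag) < 1e-4) {
    kneeload_abort("acceleration is constant; no gait cycles found", "insufficient_cycles")
  }
  # dominant cycle length from the autocorrelation: heel-strike transients
  # and the swing burst repeat once per gait cycle on a single shank
  lag_max <- min(length(filt) - 2L, round(2.5 * fs))
  ac <- stats::acf(filt, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  lag_min <- round(chain$min_separation_s * fs)
  if (lag_max <= lag_min + 2L) {
    kneeload_abort("series too short for period estimation", "insufficient_cycles")
  }
  cand <- (lag_min + 1L):lag_max
  period0 <- cand[which.max(ac[cand + 1L])]
  pk <- find_peaks(filt, min_dist = round(0.7 * period0),
                   min_prominence = chain$prominence_factor * s)
  if (length(pk) < 2L) {
    kneeload_abort("fewer than two gait events detected", "insufficient_cycles")
  }
  list(events_idx = pk, events_t = stream$time[pk],
       gait_period_s = stats::median(diff(stream$time[pk])))
}

# distal-shank endpoint position relative to the hip, from thigh and shank
# orientations rotating segment vectors that point straight down in neutral
foot_rel_hip <- function(thigh, shank, Lt, Ls) {
  quat_rotate(thigh$quat, c(0, -Lt, 0)) + quat_rotate(shank$quat, c(0, -Ls, 0))
}

# keep the longest run of events whose successive intervals match the gait
# period within tolerance; discards spurious detections (gait initiation,
# trial-end transients) that would corrupt stance windows
clean_events <- function(idx, period_samples, tol = 0.2) {
  if (length(idx) < 3L) return(idx)
  ok <- abs(diff(idx) - period_samples) / period_samples <= tol
  if (!any(ok)) return(idx)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  idx[starts[best]:(ends[best] + 1L)]
}

#' Estimate walking speed from IMU streams
#'
#' Thighs and shanks are treated as rigid bodies (lengths as fractions of
#' stature) hanging from a common hip point; per frame, the IMU orientations
#' rotate the segment vectors and the distal shank endpoints give the foot
#' positions. During each stance window (heel strike to heel strike +
#' `stance_fraction` x gait period) the planted foot is stationary in the
#' world, so the hip position equals the (unknown, constant) foot anchor
#' minus the measured foot-relative-to-hip vector. Consecutive stances of
#' opposite legs overlap in double support, which pins down the offset
#' between their anchors; chaining the offsets reconstructs the hip world
#' trajectory over the whole trial (foot-anchored odometry). Walking speed
#' is the hip displacement between two same-phase samples an integer number
#' of strides apart divided by the elapsed time, so periodic within-stride
#' speed fluctuation cancels; the stride length is speed times the gait
#' period. Using displacement norms keeps the estimate invariant to a
#' global rigid rotation of all orientations.
#'
#' @param streams Named list of IMU streams including `thigh_r`, `thigh_l`,
#'   `shank_r`, `shank_l`.
#' @param height_cm Subject stature (cm).
#' @param chain A [chain_config()].
#' @param events Optional named list (`right`, `left`) of precomputed
#'   [detect_gait_cycles()] results; detected from the shank streams when
#'   `NULL`.
#' @return Walking speed in cm/s.
#' @export
estimate_walking_speed_imu <- function(streams, height_cm, chain = chain_config(),
                                       events = NULL) {
  for (site in c("thigh_r", "thigh_l", "shank_r", "shank_l")) {
    if (is.null(streams[[site]])) {
      kneeload_abort(sprintf("missing IMU stream '%s'", site), "missing_stream")
    }
  }
  h_m <- height_cm / 100
  Lt <- chain$thigh_fraction * h_m
  Ls <- chain$shank_fraction * h_m
  if (is.null(events)) {
    events <- list(right = detect_gait_cycles(streams$shank_r, chain),
                   left = detect_gait_cycles(streams$shank_l, chain))
  }
  period <- stats::median(c(
    diff(events$right$events_t), diff(events$left$events_t)
  ))
  fs <- streams$shank_r$fs
  for (leg in c("right", "left")) {
    events[[leg]]$events_idx <- clean_events(events[[leg]]$events_idx, period * fs)
  }
  n_st <- round(chain$stance_fraction * period * fs)
  k <- round(chain$trim_fraction * n_st)
  m <- chain$pos_avg_samples
  p <- list(
    right = foot_rel_hip(streams$thigh_r, streams$shank_r, Lt, Ls),
    left = foot_rel_hip(streams$thigh_l, streams$shank_l, Lt, Ls)
  )
  n <- nrow(p$right)
  # all complete stances, time-ordered
  stances <- do.call(rbind, lapply(c("right", "left"), function(leg) {
    i0 <- events[[leg]]$events_idx
    data.frame(leg = leg, i0 = i0, i1 = i0 + n_st - 1L)
  }))
  stances <- stances[stances$i1 <= n, , drop = FALSE]
  stances <- stances[order(stances$i0), , drop = FALSE]
  if (nrow(stances) < 3L) {
    kneeload_abort("no complete stance windows inside the trial", "insufficient_cycles")
  }
  # stitch anchors through double-support overlaps; a break in the overlap
  # chain starts a new segment
  anchor <- matrix(NA_real_, nrow(stances), 3L)
  segment <- integer(nrow(stances))
  anchor[1L, ] <- 0
  segment[1L] <- 1L
  for (s in 2L:nrow(stances)) {
    ov_lo <- stances$i0[s]
    ov_hi <- min(stances$i1[s - 1L], stances$i1[s])
    # trim the double-support overlap edges as far as its length allows
    tr <- max(0L, min(2L, (ov_hi - ov_lo + 1L - 3L) %/% 2L))
    ov_lo <- ov_lo + tr
    ov_hi <- ov_hi - tr
    ov <- if (ov_hi >= ov_lo) ov_lo:ov_hi else integer(0)
    if (length(ov) >= 3L && stances$leg[s] != stances$leg[s - 1L]) {
      d <- p[[stances$leg[s]]][ov, , drop = FALSE] - p[[stances$leg[s - 1L]]][ov, , drop = FALSE]
      anchor[s, ] <- anchor[s - 1L, ] + colMeans(d)
      segment[s] <- segment[s - 1L]
    } else {
      anchor[s, ] <- 0
      segment[s] <- segment[s - 1L] + 1L
    }
  }
  # hip world position at the same in-stance phase of each stance (averaged
  # over a few samples to suppress orientation noise)
  hip_at <- function(s) {
    idx <- (stances$i0[s] + k):min(stances$i0[s] + k + m - 1L, stances$i1[s])
    anchor[s, ] - colMeans(p[[stances$leg[s]]][idx, , drop = FALSE])
  }
  speeds <- numeric(0)
  for (seg in unique(segment)) {
    for (leg in c("right", "left")) {
      rows <- which(segment == seg & stances$leg == leg)
      if (length(rows) < 2L) next
      f <- rows[1L]
      l <- rows[length(rows)]
      dt <- (stances$i0[l] - stances$i0[f]) / fs
      speeds <- c(speeds, sqrt(sum((hip_at(l) - hip_at(f))^2)) / dt)
    }
  }
  if (!length(speeds)) {
    kneeload_abort("too few stitched stances for a speed estimate", "insufficient_cycles")
  }
  # weight both legs' estimates equally; each already spans several strides
  mean(speeds) * 100
}

#' Estimate the knee flexion angle series from thigh and shank IMUs
#'
#' Orientations are expressed relative to the first frame (assumed neutral
#' standing) and converted to rotation vectors. For each sensor, the first
#' principal axis of its rotation vectors is taken as its axis of greatest
#' rotation (the flexion axis for sagittal walking); the signed rotation
#' about that axis gives a per-frame segment angle. The knee flexion series
#' is the difference between shank and thigh angles, zero at the first
#' frame, with the overall sign chosen so that the dominant excursion
#' (swing flexion) is positive.
#'
#' @param thigh,shank Thigh and shank IMU streams for the same leg.
#' @param smooth Apply light Savitzky-Golay smoothing to the angle series.
#' @return A [flexion_curve()].
#' @export
estimate_kfa_series_imu <- function(thigh, shank, smooth = TRUE) {
  stopifnot(inherits(thigh, "kneeload_imu"), inherits(shank, "kneeload_imu"))
  angle_about_main_axis <- function(stream) {
    q0 <- stream$quat[1L, , drop = FALSE]
    rel <- quat_mult(quat_conj(q0)[rep(1, nrow(stream$quat)), ], stream$quat)
    rv <- quat_to_rotvec(quat_normalize(rel))
    if (max(abs(rv)) < 1e-9) return(list(angle = rep(0, nrow(rv)), axis = c(0, 0, 1)))
    pc <- prcomp(rv, center = FALSE, scale. = FALSE)
    axis <- pc$rotation[, 1]
    list(angle = as.numeric(rv %*% axis), axis = axis)
  }
  th <- angle_about_main_axis(thigh)
  sh <- angle_about_main_axis(shank)
  if (sum(th$axis * sh$axis) < 0) sh$angle <- -sh$angle
  kfa <- rad2deg(sh$angle - th$angle)
  if (max(abs(kfa)) < 1e-9) {
    kneeload_warn("no relative thigh-shank motion; returning a flat 0 deg curve",
                  "degenerate_motion")
    return(flexion_curve(rep(0, length(kfa)), thigh$fs))
  }
  if (abs(min(kfa)) > abs(max(kfa))) kfa <- -kfa
  if (smooth) kfa <- sg_smooth(kfa)
  flexion_curve(kfa, thigh$fs)
}

#' Estimate both portable predictors from IMU streams
#'
#' Convenience wrapper chaining gait-event detection, walking-speed
#' estimation and KFA-series estimation for the analyzed (right) leg. The
#' KFA predictor is computed per detected stance window (heel strike to
#' heel strike + `stance_fraction` x period) and summarised by the median
#' across stances.
#'
#' @param streams Named list of IMU streams.
#' @param height_cm Subject stature (cm).
#' @param chain A [chain_config()].
#' @param leg Analyzed leg for the KFA predictor.
#' @param smooth Smooth the KFA series before the predictor is extracted.
#' @return List with `speed_cm_s`, `kfa_predictor_deg`, `gait_period_s` and
#'   the per-stance predictor values.
#' @export
estimate_predictors_imu <- function(streams, height_cm, chain = chain_config(),
                                    leg = "right", smooth = TRUE) {
  events <- list(right = detect_gait_cycles(streams$shank_r, chain),
                 left = detect_gait_cycles(streams$shank_l, chain))
  speed <- estimate_walking_speed_imu(streams, height_cm, chain, events)
  suffix <- substr(leg, 1, 1)
  curve <- estimate_kfa_series_imu(streams[[paste0("thigh_", suffix)]],
                                   streams[[paste0("shank_", suffix)]], smooth)
  period <- stats::median(diff(events[[leg]]$events_t))
  fs <- streams$shank_r$fs
  events[[leg]]$events_idx <- clean_events(events[[leg]]$events_idx, period * fs)
  n_st <- round(chain$stance_fraction * period * fs)
  # edge-trim the stance windows: the KFA extrema are interior (early-stance
  # peak, late-stance minimum), so trimming absorbs heel-strike timing error
  # without touching the predictor value
  k <- round(chain$trim_fraction * n_st)
  per_stance <- numeric(0)
  for (i0 in events[[leg]]$events_idx) {
    ia <- i0 + k
    ib <- i0 + n_st - k
    if (ib - 1L > length(curve$angle_deg) || ib - ia < 4L) next
    per_stance <- c(per_stance,
                    compute_kfa_predictor(curve, stance_window(ia, ib)))
  }
  if (!length(per_stance)) {
    kneeload_abort("no complete stance windows for the KFA predictor",
                   "insufficient_cycles")
  }
  list(speed_cm_s = speed, kfa_predictor_deg = stats::median(per_stance),
       gait_period_s = period, kfa_per_stance = per_stance)
}
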