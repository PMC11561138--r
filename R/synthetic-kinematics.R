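#' Gait simulator parameters
#'
#' Tunable constants of the planar (sagittal) gait generator. Segment-length
#' height fractions follow standard anthropometric tables; stance is fixed at
#' 0.62 of the gait cycle (typical adult walking). Stride length follows
#' `height * min(0.62 * (v / 1.335)^0.5, 0.68)` metres, capped so the planar
#' two-segment leg can always span the stance-phase hip travel over an
#' anchored ankle.
#'
#' @param fs Sampling rate (Hz).
#' @param n_cycles Full gait cycles generated per trial.
#' @param standing_s Duration of the initial neutral standing pose (s).
#' @param stance_fraction Stance duration as a fraction of the gait cycle.
#' @param thigh_fraction,shank_fraction Segment lengths as height fractions.
#' @param ankle_height_fraction Ankle joint height as a height fraction.
#' @param hip_osc_amp_m Amplitude of the periodic horizontal hip-speed
#'   oscillation (m), two cycles per stride.
#' @param flexion_hs_range,flexion_lr_range,flexion_te_range,flexion_to_range,flexion_swing_range
#'   Uniform sampling ranges (degrees) for the stance flexion template knots:
#'   heel strike, early-stance (loading response) peak, late-stance minimum,
#'   toe-off, and mid-swing peak.
#' @param swing_peak_pos Relative position of the swing flexion peak in swing.
#' @param step_lead_fraction Fraction of the stance-phase hip travel the foot
#'   lands ahead of the hip at heel strike.
#' @param gait_period Optional fixed gait period (s); overrides the
#'   speed-based stride model.
#' @param head_ratio Ankle-to-vertex distance as a fraction of height, used
#'   to place the synthetic head landmark.
#' @return A named list of class `kneeload_gait_params`.
#' @export
gait_params <- function(fs = 100, n_cycles = 4L, standing_s = 0.5,
                        stance_fraction = 0.62,
                        thigh_fraction = 0.245, shank_fraction = 0.246,
                        ankle_height_fraction = 0.039,
                        hip_osc_amp_m = 0.008,
                        flexion_hs_range = c(2, 6),
                        flexion_lr_range = c(10, 25),
                        flexion_te_range = c(0, 8),
                        flexion_to_range = c(30, 40),
                        flexion_swing_range = c(60, 72),
                        swing_peak_pos = 0.55,
                        step_lead_fraction = 0.52,
                        gait_period = NULL,
                        head_ratio = 0.936) {
  structure(as.list(environment()), class = "kneeload_gait_params")
}

velocity_factor <- function(velocity_class) {
  switch(velocity_class, slow = 0.75, comfortable = 1.0, fast = 1.25,
         kneeload_abort(sprintf("unknown velocity class '%s'", velocity_class),
                        "invalid_argument"))
}

# seeded per-trial truth draws; synthesize_kinematics consumes these, and the
# light-weight training-data path uses them directly without building the
# full kinematic chain. RNG order here is a compatibility contract.
sample_trial_truth <- function(profile, velocity_class, seed, params = gait_params()) {
  v_cm <- profile$comfortable_speed * velocity_factor(velocity_class)
  v <- v_cm / 100
  h_m <- profile$height / 100
  if (is.null(params$gait_period)) {
    stride_m <- h_m * min(0.62 * (v / 1.335)^0.5, 0.68)
    period_s <- stride_m / v
  } else {
    period_s <- params$gait_period
    stride_m <- v * period_s
  }
  phi <- withr::with_seed(as.integer(seed), {
    list(
      hs = runif(1, params$flexion_hs_range[1], params$flexion_hs_range[2]),
      lr = runif(1, params$flexion_lr_range[1], params$flexion_lr_range[2]),
      te = runif(1, params$flexion_te_range[1], params$flexion_te_range[2]),
      to = runif(1, params$flexion_to_range[1], params$flexion_to_range[2]),
      swing = runif(1, params$flexion_swing_range[1], params$flexion_swing_range[2])
    )
  })
  n_stance <- max(8L, round(params$stance_fraction * period_s * params$fs))
  list(
    true_speed_cm_s = v_cm, v_m_s = v, stride_m = stride_m, period_s = period_s,
    phi = phi, n_stance = n_stance,
    kfa_predictor = phi$lr - phi$te
  )
}

# stance flexion template over n samples: zero-slope cubic Hermite
# (smoothstep) segments through the four knots (heel strike, loading-response
# peak, terminal-stance minimum, toe-off); segments are monotone and the
# knots sit on sample indices, so the curve extrema equal the sampled knot
# values exactly
stance_flexion_template <- function(n, phi) {
  j <- unique(c(1L, 1L + round(0.25 * (n - 1L)), 1L + round(0.75 * (n - 1L)), n))
  vals <- c(phi$hs, phi$lr, phi$te, phi$to)[seq_along(j)]
  out <- numeric(n)
  for (k in seq_len(length(j) - 1L)) {
    seg <- hermite_segment(j[k + 1L] - j[k] + 1L, vals[k], vals[k + 1L], 0, 0)
    out[j[k]:j[k + 1L]] <- seg
  }
  out
}

# vectorised Newton solve of Lt*sin(th) + Ls*sin(th - phi) = r for the thigh
# angle th; r is the horizontal ankle-anchor offset from the hip
solve_thigh_angle <- function(r, phi_rad, Lt, Ls) {
  reach <- sqrt(Lt^2 + Ls^2 + 2 * Lt * Ls * cos(phi_rad))
  r <- clamp(r, -0.985 * reach, 0.985 * reach)
  theta <- asin(clamp(r / (Lt + Ls), -0.98, 0.98)) + phi_rad * Ls / (Lt + Ls)
  for (k in seq_len(60L)) {
    f <- Lt * sin(theta) + Ls * sin(theta - phi_rad) - r
    if (max(abs(f)) < 1e-12) break
    fp <- pmax(Lt * cos(theta) + Ls * cos(theta - phi_rad), 0.05)
    theta <- theta - clamp(f / fp, -0.3, 0.3)
  }
  theta
}

#' Synthesize planar gait kinematics for one trial
#'
#' Generates a sagittal two-segment-per-leg walking trial at 100 Hz: the
#' trial opens in a neutral standing pose, the hip then accelerates smoothly
#' to the target speed and advances with a small periodic speed oscillation.
#' During each stance the knee flexion follows a sampled double-bump template
#' and the thigh angle is solved per frame (Newton iteration) so that the
#' planted ankle stays horizontally anchored to the ground; swings are filled
#' with velocity-matched cubic Hermite segments. The vertical hip position
#' follows the planted-leg extent (inverted-pendulum rise and fall), cross-
#' faded between legs over double support.
#'
#' @param profile A [subject_profile()].
#' @param velocity_class One of `"slow"`, `"comfortable"`, `"fast"`
#'   (0.75x / 1x / 1.25x the subject's comfortable speed).
#' @param direction Walking direction, `"right"` (+x) or `"left"` (-x).
#' @param seed Integer seed for the per-trial template draws.
#' @param params A [gait_params()] object.
#' @return An object of class `kneeload_kinematics`; notable elements:
#'   `true_speed_cm_s`, `gait_period_s`, `flexion_truth` (right-knee
#'   [flexion_curve()]), `stance_truth` (mid-trial right-leg
#'   [stance_window()]), `kfa_predictor_truth` (degrees), `hip` / `joints` /
#'   `head` world positions (m), per-leg segment angles (rad) and heel-strike
#'   sample indices.
#' @export
synthesize_kinematics <- function(profile, velocity_class = c("comfortable", "slow", "fast"),
                                  direction = c("right", "left"),
                                  seed = 1L, params = gait_params()) {
  stopifnot(inherits(profile, "kneeload_subject"))
  velocity_class <- match.arg(velocity_class)
  direction <- match.arg(direction)
  truth <- sample_trial_truth(profile, velocity_class, seed, params)
  fs <- params$fs
  dt <- 1 / fs
  v <- truth$v_m_s
  T_g <- truth$period_s
  h_m <- profile$height / 100
  Lt <- params$thigh_fraction * h_m
  Ls <- params$shank_fraction * h_m
  ankle_h <- params$ankle_height_fraction * h_m
  hip_h <- ankle_h + Lt + Ls

  ts <- params$standing_s
  t1 <- ts + 0.6 * T_g
  n_cyc <- params$n_cycles
  stance_s <- params$stance_fraction * T_g
  t_end <- t1 + (n_cyc + 0.5) * T_g + stance_s + 0.03
  n_t <- floor(t_end * fs) + 1L
  t <- (seq_len(n_t) - 1L) * dt

  # hip forward position: standstill, quintic speed ramp, then constant speed
  # with a small two-per-stride oscillation faded in over the first cycle
  hipx_at <- function(tt) {
    x <- numeric(length(tt))
    ramp <- tt > ts & tt <= t1
    u <- (tt[ramp] - ts) / (t1 - ts)
    x[ramp] <- v * (t1 - ts) * (2.5 * u^4 - 3 * u^5 + u^6)
    after <- tt > t1
    ta <- tt[after] - t1
    x[after] <- v * (t1 - ts) * 0.5 + v * ta +
      params$hip_osc_amp_m * sin(4 * pi * ta / T_g) * smootherstep(ta / T_g)
    x
  }
  hipx <- hipx_at(t)

  hs_times <- list(right = t1 + (0:n_cyc) * T_g,
                   left = t1 + T_g / 2 + (0:n_cyc) * T_g)
  n_st <- truth$n_stance
  phi_stance <- stance_flexion_template(n_st, truth$phi)

  legs <- list()
  for (leg in c("right", "left")) {
    theta <- rep(NA_real_, n_t)
    phi <- rep(NA_real_, n_t)
    stances <- data.frame(hs_idx = integer(0), start = integer(0), end = integer(0))
    for (k in seq_along(hs_times[[leg]])) {
      hs <- hs_times[[leg]][k]
      i0 <- round(hs * fs) + 1L
      idx <- i0:min(i0 + n_st - 1L, n_t)
      travel <- hipx_at(hs + stance_s) - hipx_at(hs)
      anchor <- hipx_at(hs) + params$step_lead_fraction * travel
      ph <- phi_stance[seq_along(idx)]
      theta[idx] <- solve_thigh_angle(anchor - hipx[idx], deg2rad(ph), Lt, Ls)
      phi[idx] <- ph
      stances <- rbind(stances, data.frame(hs_idx = i0, start = i0, end = i0 + length(idx)))
    }
    # neutral standing up to the lead-in, then Hermite ease into the first
    # stance pose; swings and the tail are velocity-matched Hermite fills
    first_i <- stances$start[1]
    lead0 <- round(ts * fs) + 1L
    theta[seq_len(lead0)] <- 0
    phi[seq_len(lead0)] <- 0
    fill_gap <- function(x, a, b, mid_peak = NULL, peak_pos = params$swing_peak_pos) {
      # fill x[(a+1)..(b-1)] given known values at a and b
      n_g <- b - a - 1L
      if (n_g < 1L) return(x)
      m0 <- if (a > 1L && !is.na(x[a - 1L])) x[a] - x[a - 1L] else 0
      m1 <- if (b < n_t && !is.na(x[b + 1L])) x[b + 1L] - x[b] else 0
      # limit end tangents to three times the mean slope so short fills with
      # steep boundary velocities cannot overshoot (Fritsch-Carlson bound)
      cap <- 3 * abs(x[b] - x[a]) / (n_g + 1L) + 1e-9
      m0 <- sign(m0) * min(abs(m0), cap)
      m1 <- sign(m1) * min(abs(m1), cap)
      if (is.null(mid_peak)) {
        seg <- hermite_segment(n_g + 2L, x[a], x[b], m0, m1)
      } else {
        npk <- clamp(round(peak_pos * (n_g + 2L)), 2L, n_g + 1L)
        segA <- hermite_segment(npk, x[a], mid_peak, m0, 0)
        segB <- hermite_segment(n_g + 2L - npk + 1L, mid_peak, x[b], 0, m1)
        seg <- c(segA, segB[-1L])
      }
      x[(a + 1L):(b - 1L)] <- seg[2:(n_g + 1L)]
      x
    }
    theta <- fill_gap(theta, lead0, first_i)
    phi <- fill_gap(phi, lead0, first_i)
    for (k in seq_len(nrow(stances) - 1L)) {
      a <- stances$end[k] - 1L
      b <- stances$start[k + 1L]
      theta <- fill_gap(theta, a, b)
      phi <- fill_gap(phi, a, b, mid_peak = truth$phi$swing)
    }
    last_e <- stances$end[nrow(stances)] - 1L
    if (last_e < n_t) {
      n_tail <- n_t - last_e
      m <- theta[last_e] - theta[last_e - 1L]
      theta[(last_e + 1L):n_t] <- hermite_segment(n_tail + 1L, theta[last_e],
                                                  theta[last_e] + m * n_tail * 0.4, m, 0)[-1L]
      mp <- phi[last_e] - phi[last_e - 1L]
      phi[(last_e + 1L):n_t] <- clamp(hermite_segment(n_tail + 1L, phi[last_e],
                                                      phi[last_e] + mp * n_tail * 0.4, mp, 0)[-1L], -5, 85)
    }
    legs[[leg]] <- list(theta_thigh = theta, flexion_deg = phi,
                        theta_shank = theta - deg2rad(phi),
                        stances = stances,
                        hs_idx = stances$hs_idx)
  }

  # vertical hip position from the planted-leg extent, cross-faded over
  # double support (weights sum to one by construction)
  # double support lasts (2*stance_fraction - 1)/2 of a cycle at each
  # transition; expressed as a fraction of one stance it is the ramp width
  ds_frac <- max(0.05, (2 * params$stance_fraction - 1) / (2 * params$stance_fraction))
  wsum <- rep(0, n_t)
  ynum <- rep(0, n_t)
  for (leg in c("right", "left")) {
    L <- legs[[leg]]
    for (k in seq_len(nrow(L$stances))) {
      idx <- L$stances$start[k]:(L$stances$end[k] - 1L)
      p <- seq(0, 1, length.out = length(idx))
      w <- smootherstep(pmin(1, p / ds_frac)) * smootherstep(pmin(1, (1 - p) / ds_frac))
      ext <- Lt * cos(L$theta_thigh[idx]) + Ls * cos(L$theta_shank[idx])
      ynum[idx] <- ynum[idx] + w * (ankle_h + ext)
      wsum[idx] <- wsum[idx] + w
    }
  }
  w0 <- pmax(0, 1 - wsum)
  hipy <- (ynum + w0 * hip_h) / (wsum + w0)

  dir_sign <- if (direction == "left") -1 else 1
  hipx <- dir_sign * hipx
  for (leg in c("right", "left")) {
    legs[[leg]]$theta_thigh <- dir_sign * legs[[leg]]$theta_thigh
    legs[[leg]]$theta_shank <- dir_sign * legs[[leg]]$theta_shank
  }

  joints <- list()
  for (leg in c("right", "left")) {
    L <- legs[[leg]]
    knee <- cbind(hipx + Lt * sin(L$theta_thigh), hipy - Lt * cos(L$theta_thigh))
    ankle <- cbind(knee[, 1] + Ls * sin(L$theta_shank), knee[, 2] - Ls * cos(L$theta_shank))
    joints[[paste0("knee_", substr(leg, 1, 1))]] <- knee
    joints[[paste0("ankle_", substr(leg, 1, 1))]] <- ankle
  }
  head <- cbind(hipx, rep(ankle_h + params$head_ratio * h_m, n_t))
  neck <- cbind(hipx, rep(ankle_h + 0.82 * h_m, n_t))

  mid_k <- n_cyc %/% 2L + 1L
  st <- legs$right$stances[mid_k, ]
  structure(list(
    profile = profile, velocity_class = velocity_class, direction = direction,
    seed = seed, params = params, fs = fs, time = t,
    true_speed_cm_s = truth$true_speed_cm_s, gait_period_s = T_g,
    stride_m = truth$stride_m, template = truth$phi,
    segment_lengths = c(thigh = Lt, shank = Ls), ankle_height_m = ankle_h,
    hip = cbind(hipx, hipy), joints = joints, head = head, neck = neck,
    legs = legs,
    flexion_truth = flexion_curve(legs$right$flexion_deg, fs),
    stance_truth = stance_window(st$start, st$end),
    kfa_predictor_truth = truth$kfa_predictor
  ), class = "kneeload_kinematics")
}

#' @export
print.kneeload_kinematics <- function(x, ...) {
  cat(sprintf(
    "<synthetic gait trial: %s, %s/%s, %.1f cm/s, %.2f s period, %d samples @ %g Hz>\n",
    x$profile$subject_id, x$velocity_class, x$direction,
    x$true_speed_cm_s, x$gait_period_s, length(x$time), x$fs
  ))
  invisible(x)
}
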