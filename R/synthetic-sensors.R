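#' Measurement-noise configuration
#'
#' Noise settings applied when rendering IMU and video-keypoint streams from
#' synthetic kinematics. Two presets are provided: `"none"` (all noise off,
#' every trial valid) and `"realistic"`, whose levels are chosen so that
#' cohort-level speed and KFA-predictor estimation errors land in the same
#' range as published real-data errors for comparable wearable/video
#' pipelines (a few percent for speed, tens of percent for the KFA
#' predictor).
#'
#' @param preset `"none"` or `"realistic"`.
#' @param orientation_sd_deg Per-sample, per-axis SD of the IMU orientation
#'   noise rotation (degrees).
#' @param accel_sd Per-sample SD of IMU specific-force noise (m/s^2).
#' @param px_jitter_sd Keypoint pixel jitter SD (px).
#' @param conf_sd SD of keypoint confidence noise.
#' @param occlusion Whether the far-side leg is occluded when the legs cross.
#' @param occlusion_cross_px Horizontal knee separation (px) below which the
#'   legs are considered crossed and the far leg occluded.
#' @param occlusion_bias_px Pixel bias pulling occluded keypoints toward the
#'   near leg.
#' @param occlusion_conf_factor Multiplier on occluded-keypoint confidence.
#' @param p_invalid Probability that a trial is flagged invalid.
#' @param hs_pulse Amplitude of the heel-strike acceleration transient
#'   (m/s^2) added to shank and foot sensors.
#' @return An object of class `kneeload_noise`.
#' @export
noise_config <- function(preset = c("none", "realistic"),
                         orientation_sd_deg = NULL, accel_sd = NULL,
                         px_jitter_sd = NULL, conf_sd = NULL,
                         occlusion = NULL, occlusion_cross_px = 6,
                         occlusion_bias_px = 4,
                         occlusion_conf_factor = 0.25,
                         p_invalid = NULL, hs_pulse = 8) {
  preset <- match.arg(preset)
  def <- if (preset == "none") {
    list(orientation_sd_deg = 0, accel_sd = 0, px_jitter_sd = 0, conf_sd = 0,
         occlusion = FALSE, p_invalid = 0)
  } else {
    list(orientation_sd_deg = 1.5, accel_sd = 0.8, px_jitter_sd = 2, conf_sd = 0.05,
         occlusion = TRUE, p_invalid = 0.1)
  }
  pick <- function(x, d) if (is.null(x)) d else x
  structure(list(
    preset = preset,
    orientation_sd_deg = pick(orientation_sd_deg, def$orientation_sd_deg),
    accel_sd = pick(accel_sd, def$accel_sd),
    px_jitter_sd = pick(px_jitter_sd, def$px_jitter_sd),
    conf_sd = pick(conf_sd, def$conf_sd),
    occlusion = pick(occlusion, def$occlusion),
    occlusion_cross_px = occlusion_cross_px,
    occlusion_bias_px = occlusion_bias_px,
    occlusion_conf_factor = occlusion_conf_factor,
    p_invalid = pick(p_invalid, def$p_invalid),
    hs_pulse = hs_pulse
  ), class = "kneeload_noise")
}

imu_sites <- function() {
  c("pelvis", "thigh_r", "thigh_l", "shank_r", "shank_l", "foot_r", "foot_l")
}

imu_stream <- function(site, time, quat, accel, fs) {
  structure(list(site = site, time = time, fs = fs,
                 quat = quat, accel = accel), class = "kneeload_imu")
}

#' @export
print.kneeload_imu <- function(x, ...) {
  cat(sprintf("<IMU stream '%s': %d samples @ %g Hz>\n", x$site, nrow(x$quat), x$fs))
  invisible(x)
}

# half-sine heel-strike transient (duration_s wide, centred on the event)
add_hs_pulse <- function(a_y, hs_idx, fs, amp, duration_s = 0.06) {
  half <- round(duration_s * fs / 2)
  for (i0 in hs_idx) {
    idx <- (i0 - half):(i0 + half)
    keep <- idx >= 1L & idx <= length(a_y)
    a_y[idx[keep]] <- a_y[idx[keep]] + amp * cos(pi * (idx[keep] - i0) / (2 * half + 1))^2
  }
  a_y
}

#' Render IMU streams from synthetic kinematics
#'
#' Produces one stream per sensor site (pelvis, both thighs, shanks and
#' feet). Orientations are unit quaternions from the planar forward
#' kinematics (rotations about the world z axis; the first frame is the
#' neutral standing pose, so all orientations start at identity).
#' Accelerations are the specific force a sensor would measure: the
#' twice-differentiated sensor world position minus gravity, rotated into
#' the sensor frame. A brief half-sine transient is added to shank and foot
#' sensors at each heel strike (the impact transient real accelerometers
#' record), and configurable white noise corrupts both channels.
#'
#' @param kin A [synthesize_kinematics()] result.
#' @param noise A [noise_config()].
#' @param seed Integer seed for the sensor noise.
#' @return Named list of IMU streams (class `kneeload_imu`), one per site in
#'   [imu_sites()].
#' @export
render_imu <- function(kin, noise = noise_config(), seed = 1L) {
  stopifnot(inherits(kin, "kneeload_kinematics"))
  n <- length(kin$time)
  dt <- 1 / kin$fs
  Lt <- kin$segment_lengths["thigh"]
  Ls <- kin$segment_lengths["shank"]

  seg_angle <- list(
    pelvis = rep(0, n),
    thigh_r = kin$legs$right$theta_thigh, thigh_l = kin$legs$left$theta_thigh,
    shank_r = kin$legs$right$theta_shank, shank_l = kin$legs$left$theta_shank,
    foot_r = 0.4 * kin$legs$right$theta_shank, foot_l = 0.4 * kin$legs$left$theta_shank
  )
  # sensor world positions: pelvis at the hip point, thigh mid-segment,
  # shank distal, foot at the ankle
  pos_of <- function(site) {
    leg <- if (grepl("_r$", site)) "right" else "left"
    th_t <- kin$legs[[leg]]$theta_thigh
    th_s <- kin$legs[[leg]]$theta_shank
    knee <- cbind(kin$hip[, 1] + Lt * sin(th_t), kin$hip[, 2] - Lt * cos(th_t))
    switch(sub("_[rl]$", "", site),
      pelvis = kin$hip,
      thigh = cbind(kin$hip[, 1] + 0.55 * Lt * sin(th_t), kin$hip[, 2] - 0.55 * Lt * cos(th_t)),
      shank = cbind(knee[, 1] + 0.9 * Ls * sin(th_s), knee[, 2] - 0.9 * Ls * cos(th_s)),
      foot = cbind(knee[, 1] + Ls * sin(th_s), knee[, 2] - Ls * cos(th_s))
    )
  }

  withr::with_seed(as.integer(seed), {
    streams <- lapply(imu_sites(), function(site) {
      pos <- if (site == "pelvis") kin$hip else pos_of(site)
      a_w <- cbind(second_diff(pos[, 1], dt), second_diff(pos[, 2], dt), 0)
      # specific force: measured acceleration minus gravity (g points -y)
      f_w <- a_w
      f_w[, 2] <- f_w[, 2] + 9.81
      if (grepl("^(shank|foot)", site)) {
        leg <- if (grepl("_r$", site)) "right" else "left"
        f_w[, 2] <- add_hs_pulse(f_w[, 2], kin$legs[[leg]]$hs_idx, kin$fs, noise$hs_pulse)
      }
      q <- quat_about_z(seg_angle[[site]])
      f_b <- quat_rotate(quat_conj(q), f_w)
      if (noise$accel_sd > 0) {
        f_b <- f_b + matrix(rnorm(3 * n, 0, noise$accel_sd), ncol = 3)
      }
      if (noise$orientation_sd_deg > 0) {
        rv <- matrix(rnorm(3 * n, 0, deg2rad(noise$orientation_sd_deg)), ncol = 3)
        q <- quat_normalize(quat_mult(q, quat_from_rotvec(rv)))
      }
      imu_stream(site, kin$time, q, f_b, kin$fs)
    })
  })
  names(streams) <- imu_sites()
  streams
}

#' Camera configuration for keypoint rendering
#'
#' @param image_width,image_height Image size in pixels.
#' @param m_per_px Metres per pixel of the (orthographic sagittal) camera.
#' @param centre_x_m Horizontal world coordinate mapped to the image centre;
#'   `NULL` centres the camera on the hip trajectory midpoint.
#' @param top_margin_m World clearance above the head landmark.
#' @return An object of class `kneeload_camera`.
#' @export
camera_config <- function(image_width = 480, image_height = 272,
                          m_per_px = 0.0125, centre_x_m = NULL,
                          top_margin_m = 0.5) {
  if (m_per_px <= 0) kneeload_abort("m_per_px must be positive", "invalid_argument")
  structure(as.list(environment()), class = "kneeload_camera")
}

body25_index <- function() {
  c(nose = 0, neck = 1, mid_hip = 8,
    hip_r = 9, knee_r = 10, ankle_r = 11,
    hip_l = 12, knee_l = 13, ankle_l = 14) + 1L
}

keypoint_series <- function(arr, fs, image_width, image_height) {
  structure(list(xyc = arr, fs = fs, time = (seq_len(dim(arr)[1]) - 1) / fs,
                 image_width = image_width, image_height = image_height),
            class = "kneeload_keypoints")
}

#' @export
print.kneeload_keypoints <- function(x, ...) {
  cat(sprintf("<keypoint series: %d frames @ %g Hz, %dx%d px>\n",
              dim(x$xyc)[1], x$fs, x$image_width, x$image_height))
  invisible(x)
}

#' Render 2D pose keypoints from synthetic kinematics
#'
#' Projects the planar joint positions into an orthographic sagittal camera
#' (pixel y points down) and emits a body-25-style keypoint series: nose,
#' neck, mid-hip, and hip/knee/ankle of both legs, each with a confidence
#' score. Pixel jitter and confidence noise are configurable. When occlusion
#' is enabled, frames where the knees cross put the far-side leg (determined
#' by walking direction: the right leg is occluded when walking `"left"`)
#' behind the near leg: its keypoints are biased toward the near-leg joints
#' and its confidence is scaled down. Keypoints outside the image are
#' reported as (0, 0) with confidence 0, as pose estimators do.
#'
#' @param kin A [synthesize_kinematics()] result.
#' @param camera A [camera_config()].
#' @param noise A [noise_config()].
#' @param seed Integer seed for jitter/confidence noise.
#' @return A keypoint series (class `kneeload_keypoints`) whose `xyc` array
#'   is frames x 25 landmarks x (x, y, confidence).
#' @export
render_keypoints <- function(kin, camera = camera_config(), noise = noise_config(),
                             seed = 1L) {
  stopifnot(inherits(kin, "kneeload_kinematics"))
  n <- length(kin$time)
  mpp <- camera$m_per_px
  cx <- if (is.null(camera$centre_x_m)) mean(range(kin$hip[, 1])) else camera$centre_x_m
  x_left <- cx - camera$image_width * mpp / 2
  y_top <- kin$head[1, 2] + camera$top_margin_m

  world <- list(
    nose = kin$head, neck = kin$neck, mid_hip = kin$hip,
    hip_r = kin$hip, knee_r = kin$joints$knee_r, ankle_r = kin$joints$ankle_r,
    hip_l = kin$hip, knee_l = kin$joints$knee_l, ankle_l = kin$joints$ankle_l
  )
  idx <- body25_index()
  arr <- array(0, dim = c(n, 25L, 3L))
  withr::with_seed(as.integer(seed), {
    for (nm in names(world)) {
      px <- (world[[nm]][, 1] - x_left) / mpp
      py <- (y_top - world[[nm]][, 2]) / mpp
      conf <- clamp(0.85 + rnorm(n, 0, noise$conf_sd), 0, 1)
      if (noise$px_jitter_sd > 0) {
        px <- px + rnorm(n, 0, noise$px_jitter_sd)
        py <- py + rnorm(n, 0, noise$px_jitter_sd)
      }
      arr[, idx[[nm]], 1] <- px
      arr[, idx[[nm]], 2] <- py
      arr[, idx[[nm]], 3] <- conf
    }
    if (noise$occlusion) {
      far <- if (kin$direction == "left") "r" else "l"
      near <- if (far == "r") "l" else "r"
      kr <- arr[, idx[["knee_r"]], 1]
      kl <- arr[, idx[["knee_l"]], 1]
      crossed <- abs(kr - kl) < noise$occlusion_cross_px
      for (joint in c("hip", "knee", "ankle")) {
        jf <- idx[[paste(joint, far, sep = "_")]]
        jn <- idx[[paste(joint, near, sep = "_")]]
        dx <- arr[, jn, 1] - arr[, jf, 1]
        dy <- arr[, jn, 2] - arr[, jf, 2]
        len <- pmax(sqrt(dx^2 + dy^2), 1e-6)
        bias <- pmin(noise$occlusion_bias_px, len)
        arr[crossed, jf, 1] <- arr[crossed, jf, 1] + (bias * dx / len)[crossed]
        arr[crossed, jf, 2] <- arr[crossed, jf, 2] + (bias * dy / len)[crossed]
        arr[crossed, jf, 3] <- arr[crossed, jf, 3] * noise$occlusion_conf_factor
      }
    }
  })
  # out-of-view detection: zeroed like an undetected keypoint
  for (j in unname(idx)) {
    out <- arr[, j, 1] < 0 | arr[, j, 1] > camera$image_width |
      arr[, j, 2] < 0 | arr[, j, 2] > camera$image_height
    arr[out, j, ] <- 0
  }
  keypoint_series(arr, kin$fs, camera$image_width, camera$image_height)
}
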