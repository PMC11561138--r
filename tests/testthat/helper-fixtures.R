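# shared fixtures; heavyweight objects are cached per test run

.fixture_env <- new.env(parent = emptyenv())

fixture_profile <- function() {
  subject_profile("S001", mass = 74, height = 172, age = 29, sex = 1,
                  comfortable_speed = 140)
}

# one cached noise-free trial reused by round-trip tests
fixture_trial <- function(velocity = "comfortable", direction = "right",
                          seed = 11, preset = "none") {
  key <- paste(velocity, direction, seed, preset, sep = "|")
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_trial(
      fixture_profile(), velocity, direction, seed = seed,
      noise = noise_config(preset)
    )
  }
  .fixture_env[[key]]
}

# independent loop-based re-implementation of the nine-peak definition used
# as the oracle: moving average by explicit index clamping (equivalent to
# edge replication), strict local maxima by scanning, fallback raw maximum
brute_force_peaks <- function(medial, lateral, smooth_n = 5L) {
  one <- function(x) {
    n <- length(x)
    half <- (smooth_n - 1L) %/% 2L
    sm <- numeric(n)
    for (i in seq_len(n)) {
      idx <- pmin(pmax((i - half):(i + half), 1L), n)
      sm[i] <- mean(x[idx])
    }
    is_max <- rep(FALSE, n)
    for (i in 2L:(n - 1L)) is_max[i] <- sm[i] > sm[i - 1L] && sm[i] > sm[i + 1L]
    nh <- n %/% 2L
    pick <- function(range) {
      cand <- range[is_max[range]]
      if (length(cand)) x[cand[which.max(sm[cand])]] else max(x[range])
    }
    lr <- pick(seq_len(nh))
    te <- pick((nh + 1L):n)
    c(lr = lr, te = te, max = max(lr, te))
  }
  res <- c(one(medial + lateral), one(medial), one(lateral))
  names(res) <- kjcf_peak_names()
  res
}

# minimal hand-built keypoint series: landmarks given as a list of n x 2
# matrices (pixel coordinates), constant confidence
manual_keypoints <- function(landmarks, conf = 1, fs = 100,
                             image_width = 480, image_height = 272) {
  idx <- c(nose = 1, neck = 2, mid_hip = 9, hip_r = 10, knee_r = 11,
           ankle_r = 12, hip_l = 13, knee_l = 14, ankle_l = 15)
  n <- nrow(landmarks[[1]])
  arr <- array(0, dim = c(n, 25, 3))
  for (nm in names(landmarks)) {
    arr[, idx[[nm]], 1] <- landmarks[[nm]][, 1]
    arr[, idx[[nm]], 2] <- landmarks[[nm]][, 2]
    arr[, idx[[nm]], 3] <- conf
  }
  kneeload:::keypoint_series(arr, fs, image_width, image_height)
}

# hand-built standing-only kinematics for zero-motion sensor tests
standing_kinematics <- function(n = 250, height_cm = 172) {
  p <- fixture_profile()
  h <- height_cm / 100
  Lt <- 0.245 * h
  Ls <- 0.246 * h
  ankle_h <- 0.039 * h
  zeros <- rep(0, n)
  leg <- list(theta_thigh = zeros, theta_shank = zeros, flexion_deg = zeros,
              stances = data.frame(hs_idx = integer(0), start = integer(0),
                                   end = integer(0)),
              hs_idx = integer(0))
  hip <- cbind(zeros, rep(ankle_h + Lt + Ls, n))
  structure(list(
    profile = p, velocity_class = "comfortable", direction = "right",
    seed = 1L, params = gait_params(), fs = 100,
    time = (seq_len(n) - 1) / 100,
    true_speed_cm_s = 0, gait_period_s = NA_real_, stride_m = NA_real_,
    template = NULL, segment_lengths = c(thigh = Lt, shank = Ls),
    ankle_height_m = ankle_h, hip = hip,
    joints = list(knee_r = cbind(zeros, hip[, 2] - Lt),
                  ankle_r = cbind(zeros, rep(ankle_h, n)),
                  knee_l = cbind(zeros, hip[, 2] - Lt),
                  ankle_l = cbind(zeros, rep(ankle_h, n))),
    head = cbind(zeros, rep(ankle_h + 0.936 * h, n)),
    neck = cbind(zeros, rep(ankle_h + 0.82 * h, n)),
    legs = list(right = leg, left = leg),
    flexion_truth = flexion_curve(zeros, 100),
    stance_truth = stance_window(1, 10),
    kfa_predictor_truth = 0
  ), class = "kneeload_kinematics")
}
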