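test_that("cohort sampling respects the documented ranges and is seeded", {
  cohort <- sample_cohort(46, seed = 1)
  df <- cohort_to_df(cohort)
  expect_true(all(df$age >= 20 & df$age <= 45))
  bmi <- df$mass / (df$height / 100)^2
  expect_true(all(bmi >= 18.8 & bmi <= 40.4))
  expect_true(all(df$comfortable_speed >= 80 & df$comfortable_speed <= 200))
  expect_true(all(df$sex %in% c(0, 1)))

  expect_identical(sample_cohort(1, seed = 7), sample_cohort(1, seed = 7))
  expect_error(sample_cohort(0, seed = 1), class = "kneeload_invalid_argument")
})

test_that("sampled male fraction converges to 29/46", {
  df <- cohort_to_df(sample_cohort(10000, seed = 2))
  expect_lt(abs(mean(df$sex) - 29 / 46), 0.02)
})

test_that("instructed velocity scales comfortable speed by exactly 25%", {
  prof <- fixture_profile()
  expect_equal(synthesize_kinematics(prof, "comfortable", seed = 1)$true_speed_cm_s, 140)
  expect_equal(synthesize_kinematics(prof, "fast", seed = 1)$true_speed_cm_s, 175)
  expect_equal(synthesize_kinematics(prof, "slow", seed = 1)$true_speed_cm_s, 105)
  expect_error(kneeload:::velocity_factor("sprint"),
               class = "kneeload_invalid_argument")
})

test_that("generated stance flexion matches the sampled template exactly", {
  for (s in c(3, 17, 91)) {
    kin <- synthesize_kinematics(fixture_profile(), "comfortable", "right", seed = s)
    expect_equal(compute_kfa_predictor(kin$flexion_truth, kin$stance_truth),
                 kin$kfa_predictor_truth, tolerance = 1e-12)
    st <- kin$stance_truth
    ang <- kin$flexion_truth$angle_deg[st$start:(st$end - 1)]
    expect_equal(max(ang[1:(length(ang) %/% 2)]), kin$template$lr, tolerance = 1e-9)
  }
})

test_that("trial generation is deterministic under a fixed seed", {
  a <- simulate_trial(fixture_profile(), "comfortable", "right", seed = 5)
  b <- simulate_trial(fixture_profile(), "comfortable", "right", seed = 5)
  expect_identical(a$imu$shank_r$quat, b$imu$shank_r$quat)
  expect_identical(a$keypoints$xyc, b$keypoints$xyc)
  expect_identical(a$peaks_truth, b$peaks_truth)
})

test_that("noiseless loading curves reproduce the linear peak predictions", {
  prof <- fixture_profile()
  md <- load_model(peak_noise_sd = 0)
  kj <- synthesize_kjcf(prof, 140, 16, md, seed = 3, n_stance = 62)
  got <- extract_loading_peaks(kj$curves)$peaks
  expect_equal(got, kj$peaks_linear, tolerance = 0.005)

  # zero coefficients, intercept 2000: flat heights, split by the share
  md0 <- load_model(
    coef_lr = c(intercept = 2000, mass = 0, height = 0, age = 0, sex = 0, speed = 0, kfa = 0),
    coef_te = c(intercept = 2000, mass = 0, height = 0, age = 0, sex = 0, speed = 0, kfa = 0),
    medial_share = 0.7, peak_noise_sd = 0
  )
  kj0 <- synthesize_kjcf(prof, 140, 16, md0, seed = 1)
  expect_equal(unname(kj0$peaks_linear[c("lr_summed", "te_summed", "max_summed")]),
               c(2000, 2000, 2000))
  # share arithmetic: summed LR 3000 with share 0.7
  md1 <- load_model(
    coef_lr = c(intercept = 3000, mass = 0, height = 0, age = 0, sex = 0, speed = 0, kfa = 0),
    coef_te = c(intercept = 1000, mass = 0, height = 0, age = 0, sex = 0, speed = 0, kfa = 0),
    medial_share = 0.7, peak_noise_sd = 0
  )
  kj1 <- synthesize_kjcf(prof, 140, 16, md1, seed = 1)
  expect_equal(unname(kj1$peaks_linear["lr_medial"]), 2100)
  expect_equal(unname(kj1$peaks_linear["lr_lateral"]), 900)

  # negative linear prediction flags the trial degenerate
  mdn <- load_model(
    coef_lr = c(intercept = -5000, mass = 0, height = 0, age = 0, sex = 0, speed = 0, kfa = 0),
    coef_te = c(intercept = 1000, mass = 0, height = 0, age = 0, sex = 0, speed = 0, kfa = 0),
    peak_noise_sd = 0
  )
  expect_true(synthesize_kjcf(prof, 140, 16, mdn, seed = 1)$degenerate)
})

test_that("nine-peak invariants hold across random trials", {
  prof <- fixture_profile()
  for (s in 1:50) {
    kj <- synthesize_kjcf(prof, runif(1, 80, 240), runif(1, 3, 30), seed = s)
    pk <- extract_loading_peaks(kj$curves)$peaks
    for (comp in c("summed", "medial", "lateral")) {
      expect_identical(unname(pk[paste0("max_", comp)]),
                       max(pk[paste0("lr_", comp)], pk[paste0("te_", comp)]))
    }
    expect_equal(kj$curves$summed, kj$curves$medial + kj$curves$lateral)
  }
})

test_that("IMU rendering yields unit quaternions and a neutral first frame", {
  tr <- fixture_trial()
  for (s in tr$imu) {
    expect_true(all(abs(sqrt(rowSums(s$quat^2)) - 1) < 1e-9))
    expect_equal(unname(s$quat[1, ]), c(1, 0, 0, 0), tolerance = 1e-9)
  }
})

test_that("a zero-motion trial renders identity orientations and pure gravity", {
  kin <- standing_kinematics()
  streams <- render_imu(kin, noise_config("none"), seed = 1)
  for (s in streams) {
    expect_true(all(abs(s$quat[, 1] - 1) < 1e-12))
    expect_equal(unname(colMeans(s$accel)), c(0, 9.81, 0), tolerance = 1e-9)
  }
})

test_that("noise-free orientations round-trip the knee flexion angle", {
  tr <- fixture_trial()
  kfa <- estimate_kfa_series_imu(tr$imu$thigh_r, tr$imu$shank_r, smooth = FALSE)
  expect_lt(max(abs(kfa$angle_deg - tr$flexion_truth$angle_deg)), 1e-6)
})

test_that("keypoint rendering stays in bounds with valid confidences", {
  tr <- fixture_trial(preset = "realistic")
  conf <- tr$keypoints$xyc[, , 3]
  expect_true(all(conf >= 0 & conf <= 1))
  x <- tr$keypoints$xyc[, , 1]
  expect_true(all(x >= 0 & x <= tr$keypoints$image_width))
})

test_that("noise-free keypoints reproduce the flexion curve through projection", {
  tr <- fixture_trial()
  kfa <- estimate_kfa_series_vc(tr$keypoints, "right", smooth = FALSE)
  expect_lt(max(abs(kfa$angle_deg - tr$flexion_truth$angle_deg)), 1e-6)
})

test_that("walking direction controls which leg the occlusion degrades", {
  mean_conf <- function(direction, leg) {
    kin <- synthesize_kinematics(fixture_profile(), "comfortable", direction, seed = 8)
    kp <- render_keypoints(kin, noise = noise_config("realistic"), seed = 9)
    idx <- if (leg == "right") 11 else 14
    mean(kp$xyc[, idx, 3])
  }
  # walking "left": right leg is far from the camera and occluded
  expect_lt(mean_conf("left", "right"), mean_conf("right", "right"))
  expect_lt(mean_conf("right", "left"), mean_conf("left", "left"))
})
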