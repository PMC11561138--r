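test_that("camera scale is recovered from body extent or taken verbatim", {
  tr <- fixture_trial()
  sc <- estimate_scale(tr$keypoints, 172)
  expect_lt(abs(sc$m_per_px / 0.0125 - 1), 0.03)

  ov <- estimate_scale(tr$keypoints, 172, override = 0.004)
  expect_identical(ov$m_per_px, 0.004)

  low <- tr$keypoints
  low$xyc[, , 3] <- 0.01
  expect_error(estimate_scale(low, 172), class = "kneeload_calibration")
})

test_that("hip-tracking speed follows exact pixel arithmetic", {
  # hip advancing 2 px/frame at 100 Hz with scale 0.005 m/px -> 100 cm/s
  n <- 120
  hip <- cbind(10 + 2 * (0:(n - 1)), rep(100, n))
  series <- manual_keypoints(list(mid_hip = hip))
  v <- estimate_walking_speed_vc(series, list(m_per_px = 0.005))
  expect_equal(v, 100, tolerance = 1e-9)

  still <- manual_keypoints(list(mid_hip = cbind(rep(50, n), rep(100, n))))
  expect_equal(estimate_walking_speed_vc(still, list(m_per_px = 0.005)), 0)

  few <- manual_keypoints(list(mid_hip = hip[1:5, ]))
  expect_error(estimate_walking_speed_vc(few, list(m_per_px = 0.005)),
               class = "kneeload_insufficient_data")
})

test_that("noise-free video speed lands within 2% of truth", {
  tr <- fixture_trial()
  sc <- estimate_scale(tr$keypoints, 172)
  v <- estimate_walking_speed_vc(tr$keypoints, sc)
  expect_lt(abs(v / tr$true_speed_cm_s - 1), 0.02)
})

test_that("speed is invariant to horizontal mirroring of the pixel frame", {
  tr <- fixture_trial()
  sc <- estimate_scale(tr$keypoints, 172)
  mirrored <- tr$keypoints
  det <- mirrored$xyc[, , 3] > 0
  mirrored$xyc[, , 1][det] <- mirrored$image_width - mirrored$xyc[, , 1][det]
  # IRLS convergence paths differ slightly between mirror images
  expect_equal(estimate_walking_speed_vc(mirrored, sc),
               estimate_walking_speed_vc(tr$keypoints, sc), tolerance = 1e-6)
})

test_that("keypoint flexion angles follow hand geometry", {
  n <- 20
  # collinear hip-knee-ankle: full extension, 0 degrees
  col <- manual_keypoints(list(
    hip_r = cbind(rep(50, n), rep(40, n)),
    knee_r = cbind(rep(50, n), rep(80, n)),
    ankle_r = cbind(rep(50, n), rep(120, n))
  ))
  expect_equal(max(abs(estimate_kfa_series_vc(col, "right", smooth = FALSE)$angle_deg)),
               0, tolerance = 1e-9)

  # knee->hip (0,-1), knee->ankle (1,1): included 135 -> flexion 45
  bent <- manual_keypoints(list(
    hip_r = cbind(rep(50, n), rep(49, n)),
    knee_r = cbind(rep(50, n), rep(50, n)),
    ankle_r = cbind(rep(51, n), rep(51, n))
  ))
  expect_equal(estimate_kfa_series_vc(bent, "right", smooth = FALSE)$angle_deg,
               rep(45, n), tolerance = 1e-9)
})

test_that("flexion angles are invariant to pixel scaling and translation", {
  tr <- fixture_trial()
  base <- estimate_kfa_series_vc(tr$keypoints, "right", smooth = FALSE)
  tf <- tr$keypoints
  det <- tf$xyc[, , 3] > 0
  tf$xyc[, , 1][det] <- tf$xyc[, , 1][det] * 1.7 + 31
  tf$xyc[, , 2][det] <- tf$xyc[, , 2][det] * 1.7 - 12
  tf$image_width <- tf$image_width * 3
  tf$image_height <- tf$image_height * 3
  got <- estimate_kfa_series_vc(tf, "right", smooth = FALSE)
  expect_equal(got$angle_deg, base$angle_deg, tolerance = 1e-9)
})

test_that("mostly low-confidence series raise a quality error", {
  tr <- fixture_trial()
  bad <- tr$keypoints
  n <- dim(bad$xyc)[1]
  bad$xyc[seq_len(round(0.6 * n)), 12, 3] <- 0.05
  expect_error(estimate_kfa_series_vc(bad, "right"), class = "kneeload_low_quality")
})

test_that("occlusion bias degrades the occluded-leg KFA but not hip speed", {
  prof <- fixture_profile()
  res <- vapply(c(0, 4, 10), function(bias) {
    kin <- synthesize_kinematics(prof, "comfortable", "left", seed = 6)
    kp <- render_keypoints(kin, noise = noise_config(
      "none", occlusion = TRUE, occlusion_bias_px = bias,
      occlusion_conf_factor = 0.45
    ), seed = 7)
    est <- estimate_predictors_vc(kp, prof$height)
    c(kfa_err = abs(est$kfa_predictor_deg - kin$kfa_predictor_truth),
      sp_err = abs(est$speed_cm_s - kin$true_speed_cm_s))
  }, numeric(2))
  expect_true(all(diff(res["kfa_err", ]) >= -1e-9))
  expect_lt(max(res["sp_err", ]) / 140, 0.02)
})

test_that("the full video predictor wrapper recovers truth on noise-free trials", {
  tr <- fixture_trial()
  est <- estimate_predictors_vc(tr$keypoints, 172)
  expect_lt(abs(est$speed_cm_s / tr$true_speed_cm_s - 1), 0.02)
  expect_lt(abs(est$kfa_predictor_deg - tr$kfa_predictor_truth), 1)
})
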