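# records fixture: one subject with a chosen validity pattern per config
make_records <- function(sid, valid_per_config, n_trials = 8) {
  cfgs <- walking_configurations()
  do.call(rbind, lapply(seq_len(nrow(cfgs)), function(ci) {
    nv <- valid_per_config[ci]
    data.frame(
      subject_id = sid, velocity_class = cfgs$velocity_class[ci],
      direction = cfgs$direction[ci], order = seq_len(n_trials),
      valid = seq_len(n_trials) <= nv
    )
  }))
}

test_that("the balanced-set filter eliminates subjects and keeps first five valid", {
  rec <- rbind(
    make_records("A", rep(8, 6)),       # plenty everywhere
    make_records("B", c(4, 8, 8, 8, 8, 8)), # one configuration short
    make_records("C", rep(5, 6)),       # exactly enough
    make_records("D", c(7, 5, 6, 5, 8, 5))
  )
  out <- build_balanced_test_set(rec)
  expect_identical(out$excluded_subjects, "B")
  tab <- table(out$included$subject_id)
  expect_true(all(tab == 30))
  expect_setequal(names(tab), c("A", "C", "D"))
  # the five kept per configuration are those with the smallest order index
  a_cfg <- out$included[out$included$subject_id == "A" &
                          out$included$velocity_class == "slow" &
                          out$included$direction == "left", ]
  expect_identical(sort(a_cfg$order), 1:5)
})

test_that("interleaved valid/invalid trials keep the first five by order", {
  rec <- make_records("E", rep(8, 6))
  # invalidate trials 1 and 3 of one configuration: kept set shifts
  sel <- rec$velocity_class == "comfortable" & rec$direction == "right"
  rec$valid[sel & rec$order %in% c(1, 3)] <- FALSE
  out <- build_balanced_test_set(rec)
  kept <- out$included[out$included$subject_id == "E" & sel[match(
    paste(out$included$velocity_class, out$included$direction, out$included$order),
    paste(rec$velocity_class, rec$direction, rec$order))], ]
  cfg_kept <- out$included[out$included$velocity_class == "comfortable" &
                             out$included$direction == "right", ]
  expect_identical(sort(cfg_kept$order), c(2L, 4L, 5L, 6L, 7L))
})

test_that("the balanced-set filter is idempotent and bounded at 30 per subject", {
  rec <- rbind(make_records("A", rep(8, 6)), make_records("B", rep(6, 6)))
  out1 <- build_balanced_test_set(rec)
  out2 <- build_balanced_test_set(out1$included)
  expect_identical(out1$included, out2$included)
  expect_true(all(table(out1$included$subject_id) <= 30))
})

test_that("pooled peak metrics match hand arithmetic", {
  obs <- data.frame(modality = "baseline", response = "max_summed",
                    predicted = c(2100, 2900), reference = c(2000, 3000))
  m <- compute_peak_metrics(obs)
  expect_equal(m$rmse, 100)
  expect_equal(m$nrmse, 0.04)

  # perfect predictions: zero errors; R undefined on constant references
  obs2 <- data.frame(modality = "m", response = "r",
                     predicted = rep(5, 4), reference = rep(5, 4))
  m2 <- compute_peak_metrics(obs2)
  expect_equal(m2$rmse, 0)
  expect_true(m2$r_undefined)

  # predicting the mean: NRMSE equals population CV of the references
  refs <- c(1800, 2200, 2600, 2000)
  obs3 <- data.frame(modality = "m", response = "r",
                     predicted = rep(mean(refs), 4), reference = refs)
  m3 <- compute_peak_metrics(obs3)
  expect_equal(m3$nrmse, kneeload:::sd_pop(refs) / mean(refs))
})

test_that("NRMSE and R are invariant to a common positive rescaling", {
  withr::with_seed(40, {
    ref <- runif(30, 1500, 3500)
    pred <- ref + rnorm(30, 0, 200)
  })
  m1 <- compute_peak_metrics(data.frame(modality = "m", response = "r",
                                        predicted = pred, reference = ref))
  m2 <- compute_peak_metrics(data.frame(modality = "m", response = "r",
                                        predicted = 3.7 * pred, reference = 3.7 * ref))
  expect_equal(m1$nrmse, m2$nrmse, tolerance = 1e-12)
  expect_equal(m1$r, m2$r, tolerance = 1e-12)
})

test_that("predictor metrics aggregate within subjects then across them", {
  # two subjects with constructed intra-subject RMSEs of 4 and 8
  obs <- rbind(
    data.frame(subject_id = "A", predictor = "speed", modality = "imu",
               estimate = c(104, 96), reference = c(100, 100)),
    data.frame(subject_id = "B", predictor = "speed", modality = "imu",
               estimate = c(108, 92), reference = c(100, 100))
  )
  m <- compute_predictor_metrics(obs)
  expect_equal(m$rmse_mean, 6)
  expect_equal(m$rmse_sd, 2) # population SD across the two subjects

  # perfect estimates: zero mean and spread
  perfect <- data.frame(subject_id = rep(c("A", "B"), each = 3),
                        predictor = "kfa", modality = "vc",
                        estimate = 1:6, reference = 1:6)
  mp <- compute_predictor_metrics(perfect)
  expect_equal(mp$rmse_mean, 0)
  expect_equal(mp$rmse_sd, 0)

  # single subject: SD over one value is zero
  single <- data.frame(subject_id = "A", predictor = "kfa", modality = "vc",
                       estimate = c(10, 14), reference = c(12, 12))
  expect_equal(compute_predictor_metrics(single)$rmse_sd, 0)
})

test_that("MAE change from baseline follows its definition", {
  base <- data.frame(
    subject_id = rep(c("A", "B"), each = 4),
    direction = rep(c("left", "right"), 4),
    response = "max_summed",
    reference = rep(c(2000, 2400), 4)
  )
  base$baseline <- base$reference + c(100, -50, 80, -120, 60, 90, -40, 110)
  same <- base
  same$predicted <- same$baseline
  ch0 <- mae_change_from_baseline(same)
  expect_true(all(abs(ch0$mean_change) < 1e-12))

  doubled <- base
  doubled$predicted <- doubled$reference + 2 * (doubled$baseline - doubled$reference)
  ch2 <- mae_change_from_baseline(doubled)
  expect_true(all(abs(ch2$mean_change - 1) < 1e-12))

  # hand-computed fixture: subject A left has baseline MAE 90, modality 120
  fix <- data.frame(subject_id = "A", direction = "left", response = "r",
                    reference = c(1000, 1000),
                    baseline = c(1100, 920), predicted = c(1120, 880))
  ch <- mae_change_from_baseline(fix)
  expect_equal(ch$mean_change, (120 - 90) / 90)
})
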