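test_that("KFA predictor follows the half-window max-minus-min definition", {
  # constant curve: no excursion
  curve <- flexion_curve(rep(10, 60))
  expect_equal(compute_kfa_predictor(curve, stance_window(1, 61)), 0)

  # sampled sinusoid: compare against direct evaluation on the same grid
  p <- seq(0, 1, length.out = 101)
  ang <- 20 * sin(pi * p)
  curve <- flexion_curve(ang)
  st <- stance_window(1, 102)
  mid <- 1 + 101 %/% 2
  expected <- max(ang[1:(mid - 1)]) - min(ang[mid:101])
  expect_equal(compute_kfa_predictor(curve, st), expected)
  expect_equal(expected, 20, tolerance = 1e-3)

  # simulator ground truth: equals the sampled template difference exactly
  tr <- fixture_trial()
  expect_equal(compute_kfa_predictor(tr$flexion_truth, tr$stance_truth),
               tr$kfa_predictor_truth, tolerance = 1e-12)
})

test_that("KFA predictor is shift-invariant and scales with amplitude", {
  p <- seq(0, 1, length.out = 80)
  ang <- 15 * sin(pi * p) + 3 * cos(3 * pi * p)
  st <- stance_window(1, 81)
  v0 <- compute_kfa_predictor(flexion_curve(ang), st)
  expect_equal(compute_kfa_predictor(flexion_curve(ang + 7.3), st), v0)
  expect_equal(compute_kfa_predictor(flexion_curve(2.5 * ang), st), 2.5 * v0)
})

test_that("KFA predictor rejects too-short stance windows", {
  curve <- flexion_curve(rep(1, 10))
  expect_error(compute_kfa_predictor(curve, stance_window(1, 4)),
               class = "kneeload_invalid_argument")
})

test_that("loading peaks are extracted per the half-window local-maximum rule", {
  # double bump with known heights: LR 2400 at 25%, TE 2000 at 75%
  # (odd grid so the bump centres sit exactly on samples)
  n <- 101
  p <- seq(0, 1, length.out = n)
  bump <- function(c0, w) ifelse(abs(p - c0) <= w, 0.5 * (1 + cos(pi * (p - c0) / w)), 0)
  medial <- 0.6 * (2400 * bump(0.25, 0.2) + 2000 * bump(0.75, 0.2))
  lateral <- 0.4 * (2400 * bump(0.25, 0.2) + 2000 * bump(0.75, 0.2))
  pk <- extract_loading_peaks(kjcf_curve_pair(medial, lateral))
  expect_false(pk$degenerate)
  expect_equal(unname(pk$peaks["lr_summed"]), 2400, tolerance = 1e-6)
  expect_equal(unname(pk$peaks["te_summed"]), 2000, tolerance = 1e-6)
  expect_equal(unname(pk$peaks["max_summed"]), 2400, tolerance = 1e-6)
  expect_equal(unname(pk$peaks["lr_medial"]), 0.6 * 2400, tolerance = 1e-6)
  expect_equal(unname(pk$peaks["lr_lateral"]), 0.4 * 2400, tolerance = 1e-6)

  # all-zero curves: all peaks zero and flagged degenerate
  z <- extract_loading_peaks(kjcf_curve_pair(rep(0, 50), rep(0, 50)))
  expect_true(z$degenerate)
  expect_true(all(z$peaks == 0))

  # monotone ramp: no interior maxima, fallback to the half maxima
  ramp <- seq(0, 1000, length.out = 60)
  pk <- extract_loading_peaks(kjcf_curve_pair(0.5 * ramp, 0.5 * ramp))
  expect_equal(unname(pk$peaks["lr_summed"]), ramp[30], tolerance = 1e-9)
  expect_equal(unname(pk$peaks["te_summed"]), 1000)
  expect_equal(unname(pk$peaks["max_summed"]), 1000)
})

test_that("peak extraction matches a brute-force scan on random generated curves", {
  prof <- fixture_profile()
  model <- load_model()
  for (i in 1:200) {
    kj <- synthesize_kjcf(prof, true_speed = runif(1, 80, 250),
                          kfa_predictor = runif(1, 2, 30), model = model,
                          seed = i, n_stance = sample(40:90, 1))
    got <- extract_loading_peaks(kj$curves)$peaks
    want <- brute_force_peaks(kj$curves$medial, kj$curves$lateral)
    expect_equal(got, want)
    # structural invariants
    for (comp in c("summed", "medial", "lateral")) {
      expect_identical(unname(got[paste0("max_", comp)]),
                       max(got[paste0("lr_", comp)], got[paste0("te_", comp)]))
    }
    expect_lte(got["max_summed"], got["max_medial"] + got["max_lateral"] + 1e-9)
  }
})

test_that("maximum isometric force scaling follows the allometric formula", {
  expect_equal(scale_max_isometric_force(75, 75), 1.5)
  expect_equal(scale_max_isometric_force(8 * 75, 75), 6.0)
  expect_equal(scale_max_isometric_force(0.125 * 75, 75), 0.375)
  expect_error(scale_max_isometric_force(-1, 75),
               class = "kneeload_invalid_argument")
})

test_that("stance segmentation picks the longest suprathreshold run", {
  expect_equal(unclass(segment_stance(c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE)))[c("start", "end")],
               list(start = 3L, end = 6L))
  expect_error(segment_stance(rep(0, 50)), class = "kneeload_no_stance")
  f <- c(rep(0, 10), rep(500, 62), rep(0, 8))
  st <- segment_stance(f, threshold = 20)
  expect_equal(st$end - st$start, 62L)
})
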