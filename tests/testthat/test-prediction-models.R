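linear_data <- function(n, seed, noise_sd = 0) {
  withr::with_seed(seed, {
    df <- data.frame(
      mass = runif(n, 50, 110), height = runif(n, 150, 195),
      age = runif(n, 20, 45), sex = rbinom(n, 1, 0.5),
      speed = runif(n, 80, 240), kfa = runif(n, 2, 30)
    )
    df$y <- 24 * df$mass + 3 * df$height - 2 * df$age + 80 * df$sex +
      7 * df$speed + 22 * df$kfa - 1000 + rnorm(n, 0, noise_sd)
    df
  })
}

test_that("min-max normalization maps, inverts and extrapolates as an affine map", {
  nm <- fit_normalization(data.frame(mass = c(50, 100, 75)))
  expect_equal(as.numeric(norm_apply(nm, data.frame(mass = c(50, 100, 75)))),
               c(-1, 1, 0))
  # extrapolation beyond the training range is plain affine arithmetic
  expect_equal(as.numeric(norm_apply(nm, data.frame(mass = 110))), 1.4)
  x <- data.frame(mass = runif(20, 30, 130))
  expect_equal(as.numeric(norm_invert(nm, norm_apply(nm, x))), x$mass,
               tolerance = 1e-12)
  expect_warning(fit_normalization(data.frame(a = rep(3, 5))),
                 class = "kneeload_constant_predictor")
  expect_error(fit_normalization(data.frame(a = numeric(0))),
               class = "kneeload_invalid_argument")
})

test_that("MLR matches the normal-equations oracle on random designs", {
  for (i in 1:50) {
    df <- withr::with_seed(1000 + i, {
      d <- data.frame(
        mass = rnorm(40, 75, 12), height = rnorm(40, 172, 8),
        age = rnorm(40, 30, 6), sex = rbinom(40, 1, 0.5),
        speed = rnorm(40, 135, 25), kfa = rnorm(40, 15, 5)
      )
      d$y <- rnorm(40, 2500, 400)
      d
    })
    fit <- fit_mlr(df, "y", "full")
    X <- cbind(as.matrix(df[c("mass", "height", "age", "sex", "speed", "kfa")]), 1)
    oracle <- solve(crossprod(X), crossprod(X, df$y))
    expect_equal(unname(fit$coefficients), as.numeric(oracle), tolerance = 1e-8)
    # residuals orthogonal to every active column
    resid <- df$y - predict_mlr(fit, df)
    expect_lt(max(abs(crossprod(X, resid))) / nrow(df), 1e-6)
  }
})

test_that("MLR recovers noiseless coefficients exactly and flags rank deficiency", {
  df <- linear_data(100, seed = 7)
  df$y <- 20 * df$mass + 100
  fit <- fit_mlr(df, "y", "full")
  expect_equal(unname(fit$coefficients["mass"]), 20, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["intercept"]), 100, tolerance = 1e-8)
  expect_lt(max(abs(fit$coefficients[c("height", "age", "sex", "speed", "kfa")])), 1e-8)

  dg <- df
  dg$sex <- 1 # constant column is collinear with the intercept
  expect_error(fit_mlr(dg, "y", "full"), class = "kneeload_singular_design")
})

test_that("inactive predictor-set coefficients are zero", {
  df <- linear_data(80, seed = 9, noise_sd = 50)
  fit <- fit_mlr(df, "y", "demographic+speed")
  expect_identical(unname(fit$coefficients["kfa"]), 0)
})

test_that("a constant-target network predicts the constant", {
  df <- linear_data(60, seed = 3)
  df$y <- 2500
  suppressWarnings(ann <- train_ann(df, "y", "full", training_config(seed = 1)))
  expect_lt(max(abs(predict_ann(ann, df) - 2500)), 1)
})

test_that("the network fits noiseless linear data and ties the MLR baseline", {
  train <- linear_data(500, seed = 11)
  test <- linear_data(200, seed = 12)
  ann <- train_ann(train, "y", "full", training_config(seed = 2))
  mlr <- fit_mlr(train, "y", "full")
  nrmse <- function(pred, ref) sqrt(mean((pred - ref)^2)) / mean(ref)
  ann_nrmse <- nrmse(predict_ann(ann, test), test$y)
  mlr_nrmse <- nrmse(predict_mlr(mlr, test), test$y)
  expect_lt(ann_nrmse, 0.02)
  expect_lt(abs(ann_nrmse - mlr_nrmse), 0.02)
})

test_that("training is bit-deterministic under a fixed seed", {
  df <- linear_data(120, seed = 5, noise_sd = 150)
  a <- train_ann(df, "y", "full", training_config(seed = 4))
  b <- train_ann(df, "y", "full", training_config(seed = 4))
  expect_identical(a$weights, b$weights)
  expect_identical(a$alpha, b$alpha)
})

test_that("a single tanh unit gives a monotone response surface", {
  df <- linear_data(200, seed = 6, noise_sd = 100)
  ann <- train_ann(df, "y", "full", training_config(seed = 3))
  base <- df[1, ]
  for (col in c("mass", "speed", "kfa")) {
    grid <- base[rep(1, 41), ]
    grid[[col]] <- seq(min(df[[col]]), max(df[[col]]), length.out = 41)
    pred <- predict_ann(ann, grid)
    d <- diff(pred)
    expect_true(all(d >= -1e-9) || all(d <= 1e-9))
  }
})

test_that("prediction equals an independent evaluation of the composed formula", {
  df <- linear_data(100, seed = 13, noise_sd = 80)
  ann <- train_ann(df, "y", "full", training_config(seed = 5))
  x <- df[7, ]
  cols <- ann$columns
  lo <- ann$norm_x$lo
  hi <- ann$norm_x$hi
  z <- 2 * (as.numeric(x[cols]) - lo) / (hi - lo) - 1
  w <- ann$weights
  yn <- w$a * tanh(sum(w$w * z) + w$b1) + w$b2
  y <- (yn + 1) / 2 * (ann$norm_y$hi - ann$norm_y$lo) + ann$norm_y$lo
  expect_equal(predict_ann(ann, x), unname(y), tolerance = 1e-12)
})

test_that("effective parameter count shrinks as target noise grows", {
  gammas <- vapply(c(25, 400, 3000), function(noise_sd) {
    mean(vapply(1:4, function(s) {
      df <- linear_data(150, seed = 100 * s + round(noise_sd), noise_sd = noise_sd)
      train_ann(df, "y", "full", training_config(seed = s))$gamma
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(gammas) < 0))
})

test_that("fine-tuning never worsens the second-cohort data misfit", {
  pre <- linear_data(150, seed = 21, noise_sd = 120)
  main <- linear_data(150, seed = 22, noise_sd = 120)
  cfg <- training_config(seed = 6)
  norm_x <- fit_normalization(main[predictor_set_columns("full")])
  norm_y <- fit_normalization(main["y"])
  pre_fit <- train_ann(pre, "y", "full", cfg, norm_x = norm_x, norm_y = norm_y)
  fine <- train_ann(main, "y", "full", cfg, init = pre_fit$weights,
                    norm_x = norm_x, norm_y = norm_y)
  # data misfit of the pre-trained weights on the second cohort
  X <- norm_apply(norm_x, main[predictor_set_columns("full")])
  y <- as.numeric(norm_apply(norm_y, main["y"]))
  sse_init <- sum((y - kneeload:::ann_forward(pre_fit$weights, X)$yhat)^2)
  expect_lte(fine$sse_norm, sse_init * (1 + 1e-9))
})

test_that("one network and one MLR model are trained per peak and serialized", {
  cohort <- sample_cohort(20, seed = 31)
  df <- make_training_data(cohort, 4, seed = 32)
  pre_cohort <- sample_cohort(8, seed = 33, age_mean = 60, age_range = c(45, 75))
  pre_df <- make_training_data(pre_cohort, 4, seed = 34)
  ms <- train_all_peaks(df, "full", training_config(seed = 7, max_epochs = 60), pre_df)
  expect_length(ms$models, 9L)
  expect_setequal(names(ms$models), kjcf_peak_names())
  # each model beats the intercept-only predictor in training NRMSE
  for (peak in kjcf_peak_names()) {
    pred <- predict_ann(ms$models[[peak]]$ann, df)
    sse <- mean((pred - df[[peak]])^2)
    sse0 <- mean((mean(df[[peak]]) - df[[peak]])^2)
    expect_lte(sse, sse0)
  }
  # JSON round trip preserves predictions
  path <- tempfile(fileext = ".json")
  save_models_json(ms, path)
  ms2 <- load_models_json(path)
  newx <- df[1:5, ]
  for (peak in c("max_summed", "lr_lateral")) {
    expect_equal(predict_ann(ms2$models[[peak]]$ann, newx),
                 predict_ann(ms$models[[peak]]$ann, newx), tolerance = 1e-12)
    expect_equal(predict_mlr(ms2$models[[peak]]$mlr, newx),
                 predict_mlr(ms$models[[peak]]$mlr, newx), tolerance = 1e-12)
  }
})
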