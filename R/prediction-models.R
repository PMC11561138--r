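#' Predictor sets
#'
#' The four nested predictor sets used for the loading-peak models:
#' demographics only (mass, height, age, sex), demographics plus the KFA
#' predictor, demographics plus walking speed, and the full set.
#'
#' @param set One of `"demographic"`, `"demographic+kfa"`,
#'   `"demographic+speed"`, `"full"`.
#' @return Character vector of active predictor column names.
#' @export
predictor_set_columns <- function(set = c("full", "demographic",
                                          "demographic+kfa", "demographic+speed")) {
  set <- match.arg(set)
  base <- c("mass", "height", "age", "sex")
  switch(set,
    demographic = base,
    `demographic+kfa` = c(base, "kfa"),
    `demographic+speed` = c(base, "speed"),
    full = c(base, "speed", "kfa")
  )
}

all_predictor_columns <- function() c("mass", "height", "age", "sex", "speed", "kfa")

#' Fit a min-max normalization to training predictors
#'
#' Maps each column to \[-1, 1\] by its training minimum and maximum (the
#' usual input scaling for small feedforward networks). A constant column is
#' mapped to 0 with a warning and inverted back to its constant.
#'
#' @param x Data frame or matrix of training values.
#' @return An object of class `kneeload_norm`.
#' @export
fit_normalization <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) kneeload_abort("empty training set", "invalid_argument")
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  if (any(hi - lo < .Machine$double.eps)) {
    kneeload_warn("constant predictor column(s) mapped to 0", "constant_predictor")
  }
  structure(list(lo = lo, hi = hi, names = colnames(x)), class = "kneeload_norm")
}

#' Apply a min-max normalization
#' @param norm A [fit_normalization()] object.
#' @param x Values on the original scale (matrix/data frame/vector).
#' @return Values mapped to \[-1, 1\] (training range; values outside the
#'   range extrapolate beyond \[-1, 1\]).
#' @export
norm_apply <- function(norm, x) {
  x <- as.matrix(x)
  span <- norm$hi - norm$lo
  out <- sweep(sweep(x, 2, norm$lo), 2, ifelse(span > 0, span, 1), "/") * 2 - 1
  out[, span <= 0] <- 0
  out
}

#' Invert a min-max normalization
#' @param norm A [fit_normalization()] object.
#' @param z Values on the \[-1, 1\] scale.
#' @return Values on the original scale.
#' @export
norm_invert <- function(norm, z) {
  z <- as.matrix(z)
  span <- norm$hi - norm$lo
  out <- sweep(sweep((z + 1) / 2, 2, ifelse(span > 0, span, 0), "*"), 2, norm$lo, "+")
  out
}

#' Training configuration for the loading-peak networks
#'
#' @param seed Integer seed for the weight initialization.
#' @param max_epochs Maximum Levenberg-Marquardt epochs.
#' @param tol Relative objective-change convergence tolerance.
#' @param evidence_interval Re-estimate the regularization hyperparameters
#'   every this many accepted steps.
#' @param pretrain Whether [train_all_peaks()] should pre-train on the
#'   auxiliary dataset before fine-tuning.
#' @return An object of class `kneeload_training_config`.
#' @export
training_config <- function(seed = 1L, max_epochs = 300L, tol = 1e-10,
                            evidence_interval = 1L, pretrain = TRUE) {
  if (max_epochs < 1L) kneeload_abort("max_epochs must be >= 1", "invalid_argument")
  structure(as.list(environment()), class = "kneeload_training_config")
}

ann_forward <- function(w, X) {
  z <- as.numeric(X %*% w$w + w$b1)
  h <- tanh(z)
  list(yhat = w$a * h + w$b2, z = z, h = h)
}

ann_pack <- function(w) c(w$w, w$b1, w$a, w$b2)

ann_unpack <- function(theta, p) {
  list(w = theta[seq_len(p)], b1 = theta[p + 1L], a = theta[p + 2L], b2 = theta[p + 3L])
}

# Jacobian of predictions wrt the packed parameter vector
ann_jacobian <- function(w, X, fwd) {
  d <- w$a * (1 - fwd$h^2)
  cbind(X * d, d, fwd$h, rep(1, nrow(X)))
}

#' Train a single-hidden-node network with Bayesian regularization
#'
#' Fits the model `y = a * tanh(w . x + b1) + b2` (inputs and target
#' min-max-normalized to \[-1, 1\]) by Levenberg-Marquardt minimization of
#' the regularized objective `F = beta * Ed + alpha * Ew`, where
#' `Ed = sum(residual^2)` and `Ew = sum(parameter^2)`. The hyperparameters
#' are re-estimated by the evidence framework: with `H = 2 beta J'J +
#' 2 alpha I`, the effective number of parameters is
#' `gamma = Nw - 2 alpha tr(H^-1)`, then `alpha = gamma / (2 Ew)` and
#' `beta = (N - gamma) / (2 Ed)`. No validation split is needed; the
#' evidence updates control overfitting. Training is deterministic given
#' the data and the configuration seed.
#'
#' @param data Data frame containing the predictor columns and the response.
#' @param response Name of the response column (N).
#' @param set Predictor set (see [predictor_set_columns()]).
#' @param cfg A [training_config()].
#' @param init Optional starting weights (a list `w`, `b1`, `a`, `b2`), used
#'   to continue optimization from a pre-trained network.
#' @param norm_x,norm_y Optional pre-computed normalizations (shared between
#'   pre-training and fine-tuning phases).
#' @return An object of class `kneeload_ann` with the weights,
#'   normalizations, hyperparameters (`alpha`, `beta`, `gamma`) and
#'   diagnostics.
#' @export
train_ann <- function(data, response, set = "full", cfg = training_config(),
                      init = NULL, norm_x = NULL, norm_y = NULL) {
  cols <- predictor_set_columns(set)
  if (nrow(data) < 10L) kneeload_abort("need at least 10 training pairs", "invalid_argument")
  if (!all(c(cols, response) %in% names(data))) {
    kneeload_abort("missing predictor or response columns", "invalid_argument")
  }
  if (is.null(norm_x)) norm_x <- fit_normalization(data[cols])
  if (is.null(norm_y)) norm_y <- fit_normalization(data[response])
  X <- norm_apply(norm_x, data[cols])
  y <- as.numeric(norm_apply(norm_y, data[response]))
  N <- length(y)
  p <- length(cols)
  Nw <- p + 3L

  if (is.null(init)) {
    # bounded uniform initialization in the Nguyen-Widrow spirit: input
    # weights scaled so the single unit's active region covers the inputs
    init <- withr::with_seed(as.integer(cfg$seed), {
      scale <- 0.7
      list(w = runif(p, -scale, scale) / sqrt(p), b1 = runif(1, -0.5, 0.5),
           a = runif(1, 0.5, 1), b2 = 0)
    })
  }
  w <- init
  alpha <- 0
  beta <- 1
  mu <- 0.005
  objective <- function(w, alpha, beta) {
    fwd <- ann_forward(w, X)
    e <- y - fwd$yhat
    Ed <- sum(e^2)
    Ew <- sum(ann_pack(w)^2)
    list(F = beta * Ed + alpha * Ew, Ed = Ed, Ew = Ew, e = e, fwd = fwd)
  }
  ob <- objective(w, alpha, beta)
  gamma <- Nw
  epochs <- 0L
  converged <- FALSE
  for (epoch in seq_len(cfg$max_epochs)) {
    epochs <- epoch
    J <- ann_jacobian(w, X, ob$fwd)
    theta <- ann_pack(w)
    g <- -2 * beta * crossprod(J, ob$e) + 2 * alpha * theta
    H <- 2 * beta * crossprod(J) + 2 * alpha * diag(Nw)
    accepted <- FALSE
    for (try in seq_len(30L)) {
      step <- tryCatch(solve(H + mu * diag(Nw), -g), error = function(e) NULL)
      if (!is.null(step)) {
        w_new <- ann_unpack(theta + as.numeric(step), p)
        ob_new <- objective(w_new, alpha, beta)
        if (is.finite(ob_new$F) && ob_new$F < ob$F) {
          w <- w_new
          dF <- ob$F - ob_new$F
          ob <- ob_new
          mu <- max(mu / 10, 1e-12)
          accepted <- TRUE
          if (dF < cfg$tol * max(ob$F, 1e-12)) converged <- TRUE
          break
        }
      }
      mu <- mu * 10
      if (mu > 1e12) break
    }
    if (!accepted) {
      converged <- TRUE
    } else if (epoch %% cfg$evidence_interval == 0L) {
      # MacKay evidence update of the regularization hyperparameters
      J <- ann_jacobian(w, X, ob$fwd)
      H <- 2 * beta * crossprod(J) + 2 * alpha * diag(Nw)
      Hinv <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(Hinv)) {
        gamma <- Nw - 2 * alpha * sum(diag(Hinv))
        alpha <- gamma / max(2 * ob$Ew, 1e-12)
        beta <- max(N - gamma, 1e-3) / max(2 * ob$Ed, 1e-12)
        ob <- objective(w, alpha, beta)
      }
    }
    if (converged) break
  }
  if (!is.finite(ob$F)) {
    kneeload_abort("training diverged to a non-finite objective", "training_failure")
  }
  structure(list(
    weights = w, norm_x = norm_x, norm_y = norm_y, set = set, columns = cols,
    response = response, alpha = alpha, beta = beta, gamma = gamma,
    n_train = N, epochs = epochs, converged = converged,
    sse_norm = ob$Ed
  ), class = "kneeload_ann")
}

#' @export
print.kneeload_ann <- function(x, ...) {
  cat(sprintf(
    "<ANN '%s' (%s): gamma %.2f, alpha %.3g, beta %.3g, %d epochs%s>\n",
    x$response, x$set, x$gamma, x$alpha, x$beta, x$epochs,
    if (x$converged) "" else " (not converged)"
  ))
  invisible(x)
}

#' Predict a loading peak with a trained network
#'
#' @param model A [train_ann()] model.
#' @param newdata Data frame with the model's predictor columns.
#' @return Predicted peak values (N).
#' @export
predict_ann <- function(model, newdata) {
  stopifnot(inherits(model, "kneeload_ann"))
  if (!all(model$columns %in% names(newdata))) {
    kneeload_abort("newdata lacks required predictor columns", "invalid_argument")
  }
  X <- norm_apply(model$norm_x, newdata[model$columns])
  if (any(!is.finite(X))) kneeload_abort("non-finite predictor values", "invalid_argument")
  z <- ann_forward(model$weights, X)$yhat
  as.numeric(norm_invert(model$norm_y, matrix(z, ncol = 1)))
}

#' Fit the first-order multiple linear regression baseline
#'
#' Ordinary least squares fit of
#' `y = a*mass + b*height + c*age + d*sex + e*speed + f*kfa + g`;
#' predictors outside the chosen set get coefficient 0.
#'
#' @param data Data frame with predictors and the response column.
#' @param response Response column name.
#' @param set Predictor set.
#' @return An object of class `kneeload_mlr` with the full-length
#'   coefficient vector (`mass`, `height`, `age`, `sex`, `speed`, `kfa`,
#'   `intercept`).
#' @export
fit_mlr <- function(data, response, set = "full") {
  cols <- predictor_set_columns(set)
  X <- cbind(as.matrix(data[cols]), intercept = 1)
  y <- as.numeric(data[[response]])
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    kneeload_abort("design matrix is rank deficient", "singular_design")
  }
  coefs <- setNames(numeric(7), c(all_predictor_columns(), "intercept"))
  coefs[names(fit$coefficients)] <- fit$coefficients
  structure(list(coefficients = coefs, set = set, columns = cols,
                 response = response, n_train = length(y)),
            class = "kneeload_mlr")
}

#' Predict with the MLR baseline
#' @param model A [fit_mlr()] model.
#' @param newdata Data frame with the predictor columns.
#' @return Predicted peak values (N).
#' @export
predict_mlr <- function(model, newdata) {
  stopifnot(inherits(model, "kneeload_mlr"))
  co <- model$coefficients
  # evaluate on the full predictor vector; inactive coefficients are zero
  avail <- intersect(all_predictor_columns(), names(newdata))
  if (length(setdiff(model$columns, avail))) {
    kneeload_abort("newdata lacks required predictor columns", "invalid_argument")
  }
  out <- rep(unname(co["intercept"]), nrow(newdata))
  for (nm in avail) out <- out + co[nm] * newdata[[nm]]
  as.numeric(out)
}

#' Train one network and one MLR model per loading peak
#'
#' A separate model is trained for each of the nine response variables.
#' When `pretrain_df` is supplied and `cfg$pretrain` is TRUE, each network
#' is first trained on that auxiliary dataset (sharing the main dataset's
#' normalizations) and then fine-tuned on `data` starting from the
#' pre-trained weights, mirroring a two-stage curriculum where a smaller
#' clinical cohort seeds the weights before the main healthy-cohort
#' training.
#'
#' @param data Training data frame: six predictor columns plus the nine
#'   peak columns of [kjcf_peak_names()].
#' @param set Predictor set.
#' @param cfg A [training_config()].
#' @param pretrain_df Optional pre-training data frame with the same layout.
#' @return An object of class `kneeload_model_set`: a list with one
#'   `(ann, mlr)` pair per peak.
#' @export
train_all_peaks <- function(data, set = "full", cfg = training_config(),
                            pretrain_df = NULL) {
  cols <- predictor_set_columns(set)
  models <- lapply(kjcf_peak_names(), function(peak) {
    norm_x <- fit_normalization(data[cols])
    norm_y <- fit_normalization(data[peak])
    init <- NULL
    if (!is.null(pretrain_df) && isTRUE(cfg$pretrain)) {
      pre <- train_ann(pretrain_df, peak, set, cfg, norm_x = norm_x, norm_y = norm_y)
      init <- pre$weights
    }
    ann <- train_ann(data, peak, set, cfg, init = init, norm_x = norm_x, norm_y = norm_y)
    mlr <- fit_mlr(data, peak, set)
    list(ann = ann, mlr = mlr)
  })
  names(models) <- kjcf_peak_names()
  structure(list(models = models, set = set, cfg = cfg,
                 pretrained = !is.null(pretrain_df) && isTRUE(cfg$pretrain)),
            class = "kneeload_model_set")
}

#' @export
print.kneeload_model_set <- function(x, ...) {
  cat(sprintf("<model set: %d peaks, predictor set '%s'%s>\n",
              length(x$models), x$set,
              if (x$pretrained) ", pre-trained" else ""))
  invisible(x)
}

#' Serialize trained models to JSON
#'
#' Writes a version-tagged JSON file holding, for every peak, the network
#' weights, normalization bounds and hyperparameters, and the MLR
#' coefficients; [load_models_json()] restores them.
#'
#' @param model_set A [train_all_peaks()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_models_json <- function(model_set, path) {
  stopifnot(inherits(model_set, "kneeload_model_set"))
  ser_norm <- function(nm) list(lo = as.list(nm$lo), hi = as.list(nm$hi))
  payload <- list(
    format = "kneeload-models",
    version = 1L,
    predictor_set = model_set$set,
    peaks = lapply(model_set$models, function(m) {
      list(
        response = m$ann$response,
        ann = list(
          w = m$ann$weights$w, b1 = m$ann$weights$b1,
          a = m$ann$weights$a, b2 = m$ann$weights$b2,
          alpha = m$ann$alpha, beta = m$ann$beta, gamma = m$ann$gamma,
          norm_x = ser_norm(m$ann$norm_x), norm_y = ser_norm(m$ann$norm_y),
          columns = m$ann$columns
        ),
        mlr = list(coefficients = as.list(m$mlr$coefficients))
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Restore models saved by [save_models_json()]
#'
#' @param path JSON file path.
#' @return A `kneeload_model_set`.
#' @export
load_models_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "kneeload-models")) {
    kneeload_abort("not a kneeload model file", "invalid_argument")
  }
  des_norm <- function(x) {
    structure(list(lo = unlist(x$lo), hi = unlist(x$hi), names = names(x$lo)),
              class = "kneeload_norm")
  }
  models <- lapply(names(payload$peaks), function(peak) {
    m <- payload$peaks[[peak]]
    ann <- structure(list(
      weights = list(w = as.numeric(m$ann$w), b1 = m$ann$b1, a = m$ann$a, b2 = m$ann$b2),
      norm_x = des_norm(m$ann$norm_x), norm_y = des_norm(m$ann$norm_y),
      set = payload$predictor_set, columns = as.character(m$ann$columns),
      response = m$response, alpha = m$ann$alpha, beta = m$ann$beta,
      gamma = m$ann$gamma, n_train = NA_integer_, epochs = NA_integer_,
      converged = NA
    ), class = "kneeload_ann")
    co <- unlist(m$mlr$coefficients)
    mlr <- structure(list(coefficients = co, set = payload$predictor_set,
                          columns = as.character(m$ann$columns),
                          response = m$response, n_train = NA_integer_),
                     class = "kneeload_mlr")
    list(ann = ann, mlr = mlr)
  })
  names(models) <- names(payload$peaks)
  structure(list(models = models, set = payload$predictor_set,
                 cfg = NULL, pretrained = NA), class = "kneeload_model_set")
}
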