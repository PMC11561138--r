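#' Generative knee-loading model
#'
#' Ground-truth surrogate for musculoskeletal-analysis loading peaks: the
#' summed (medial + lateral) loading-response and terminal-extension peak
#' heights are linear functions of the six predictors (mass kg, height cm,
#' age years, sex 0/1, walking speed cm/s, KFA predictor degrees), a fixed
#' medial share splits each summed peak into compartments, and the stance
#' curves are two raised-cosine bumps per compartment centred at the peak
#' timings.
#'
#' @param coef_lr,coef_te Named numeric vectors with elements `intercept`,
#'   `mass`, `height`, `age`, `sex`, `speed`, `kfa` (units N per predictor
#'   unit) for the summed loading-response and terminal-extension peaks.
#' @param medial_share Medial fraction of each summed peak, in (0, 1).
#' @param peak_noise_sd SD of Gaussian noise added to the summed peak
#'   heights (N).
#' @param lr_timing,te_timing Peak centres as fractions of stance.
#' @param bump_width Half-width of each raised-cosine bump (stance fraction);
#'   at the default the two bumps do not overlap and curve peaks equal the
#'   bump heights exactly.
#' @return An object of class `kneeload_load_model`.
#' @export
load_model <- function(coef_lr = c(intercept = -1000, mass = 24, height = 3,
                                   age = -2, sex = 80, speed = 7, kfa = 22),
                       coef_te = c(intercept = -800, mass = 22, height = 3,
                                   age = -2.5, sex = 60, speed = 5.5, kfa = 8),
                       medial_share = 0.65, peak_noise_sd = 350,
                       lr_timing = 0.25, te_timing = 0.75, bump_width = 0.24) {
  if (medial_share <= 0 || medial_share >= 1) {
    kneeload_abort("medial_share must lie in (0, 1)", "invalid_argument")
  }
  if (!(lr_timing < 0.5 && 0.5 < te_timing)) {
    kneeload_abort("peak timings must satisfy lr < 0.5 < te", "invalid_argument")
  }
  structure(as.list(environment()), class = "kneeload_load_model")
}

load_model_predict <- function(coefs, profile, speed_cm_s, kfa_deg) {
  unname(coefs["intercept"] + coefs["mass"] * profile$mass +
           coefs["height"] * profile$height + coefs["age"] * profile$age +
           coefs["sex"] * profile$sex + coefs["speed"] * speed_cm_s +
           coefs["kfa"] * kfa_deg)
}

raised_cosine_bump <- function(p, centre, width) {
  u <- (p - centre) / width
  ifelse(abs(u) <= 1, 0.5 * (1 + cos(pi * u)), 0)
}

#' Synthesize medial/lateral knee loading curves for one trial
#'
#' Builds stance-phase compartment loading curves whose bump heights are the
#' generative model's linear peak predictions plus optional Gaussian noise
#' (clipped at zero). The noiseless linear predictions are returned alongside
#' so model-recovery experiments have exact targets.
#'
#' @param profile A [subject_profile()].
#' @param true_speed Walking speed (cm/s).
#' @param kfa_predictor KFA predictor (degrees).
#' @param model A [load_model()].
#' @param seed Integer seed for the peak-height noise.
#' @param n_stance Number of stance samples for the curves.
#' @param fs Sampling rate (Hz).
#' @return A list with `curves` (a [kjcf_curve_pair()]), `peaks_linear`
#'   (noiseless nine-peak vector, see [kjcf_peak_names()]), `peaks_noisy`
#'   (nine peaks implied by the noisy bump heights) and `degenerate` (TRUE
#'   when a linear prediction was non-positive before clipping).
#' @export
synthesize_kjcf <- function(profile, true_speed, kfa_predictor, model = load_model(),
                            seed = 1L, n_stance = 62L, fs = 100) {
  stopifnot(inherits(model, "kneeload_load_model"))
  lr_sum <- load_model_predict(model$coef_lr, profile, true_speed, kfa_predictor)
  te_sum <- load_model_predict(model$coef_te, profile, true_speed, kfa_predictor)
  degenerate <- lr_sum <= 0 || te_sum <= 0
  noise <- withr::with_seed(as.integer(seed), rnorm(2, 0, model$peak_noise_sd))
  lr_n <- max(0, lr_sum + noise[1])
  te_n <- max(0, te_sum + noise[2])

  nine <- function(lr, te) {
    sh <- model$medial_share
    out <- c(
      lr_summed = lr, te_summed = te, max_summed = max(lr, te),
      lr_medial = sh * lr, te_medial = sh * te, max_medial = sh * max(lr, te),
      lr_lateral = (1 - sh) * lr, te_lateral = (1 - sh) * te,
      max_lateral = (1 - sh) * max(lr, te)
    )
    out[kjcf_peak_names()]
  }

  p <- seq(0, 1, length.out = n_stance)
  # centre the bumps on sample indices so curve maxima equal bump heights
  c_lr <- p[1L + round(model$lr_timing * (n_stance - 1L))]
  c_te <- p[1L + round(model$te_timing * (n_stance - 1L))]
  shape <- function(h_lr, h_te) {
    h_lr * raised_cosine_bump(p, c_lr, model$bump_width) +
      h_te * raised_cosine_bump(p, c_te, model$bump_width)
  }
  sh <- model$medial_share
  medial <- shape(sh * lr_n, sh * te_n)
  lateral <- shape((1 - sh) * lr_n, (1 - sh) * te_n)
  list(
    curves = kjcf_curve_pair(medial, lateral, fs),
    peaks_linear = nine(lr_sum, te_sum),
    peaks_noisy = nine(lr_n, te_n),
    degenerate = degenerate
  )
}
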