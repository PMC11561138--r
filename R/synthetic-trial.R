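#' Simulate one complete walking trial
#'
#' Chains the kinematic generator, the loading-curve generator and the two
#' sensor renderers into a fully observed synthetic trial with ground truth.
#' The trial-level validity flag (emulating force-plate/GRF inspection in a
#' laboratory workflow) is drawn as a Bernoulli variable with the noise
#' configuration's `p_invalid`.
#'
#' @param profile A [subject_profile()].
#' @param velocity_class `"slow"`, `"comfortable"` or `"fast"`.
#' @param direction `"right"` or `"left"`.
#' @param seed Integer trial seed; all randomness derives from it.
#' @param noise A [noise_config()].
#' @param model A [load_model()].
#' @param params A [gait_params()].
#' @param camera A [camera_config()].
#' @param keep_kinematics Keep the full kinematics object on the trial
#'   (memory-heavy; off by default).
#' @return An object of class `kneeload_trial` with ground truth
#'   (`true_speed_cm_s`, `kfa_predictor_truth`, `flexion_truth`,
#'   `stance_truth`, `kjcf_truth`, `peaks_truth`), rendered `imu` streams and
#'   `keypoints`, and bookkeeping (`valid`, `degenerate`, configuration).
#' @export
simulate_trial <- function(profile, velocity_class = "comfortable",
                           direction = "right", seed = 1L,
                           noise = noise_config(), model = load_model(),
                           params = gait_params(), camera = camera_config(),
                           keep_kinematics = FALSE) {
  seed <- as.integer(seed)
  kin <- synthesize_kinematics(profile, velocity_class, direction, seed, params)
  kj <- synthesize_kjcf(profile, kin$true_speed_cm_s, kin$kfa_predictor_truth,
                        model, seed + 1L,
                        n_stance = stance_length(kin$stance_truth), fs = kin$fs)
  peaks <- extract_loading_peaks(kj$curves)
  imu <- render_imu(kin, noise, seed + 2L)
  kp <- render_keypoints(kin, camera, noise, seed + 3L)
  valid <- withr::with_seed(seed + 4L, runif(1) >= noise$p_invalid)
  structure(list(
    profile = profile, velocity_class = velocity_class, direction = direction,
    seed = seed, fs = kin$fs,
    true_speed_cm_s = kin$true_speed_cm_s,
    gait_period_s = kin$gait_period_s,
    kfa_predictor_truth = kin$kfa_predictor_truth,
    flexion_truth = kin$flexion_truth,
    stance_truth = kin$stance_truth,
    hs_idx = list(right = kin$legs$right$hs_idx, left = kin$legs$left$hs_idx),
    kjcf_truth = kj$curves,
    peaks_truth = peaks$peaks,
    peaks_linear = kj$peaks_linear,
    degenerate = kj$degenerate,
    imu = imu, keypoints = kp,
    valid = valid,
    kinematics = if (keep_kinematics) kin else NULL
  ), class = "kneeload_trial")
}

#' @export
print.kneeload_trial <- function(x, ...) {
  cat(sprintf(
    "<trial: %s %s/%s, speed %.1f cm/s, KFA predictor %.1f deg, %s>\n",
    x$profile$subject_id, x$velocity_class, x$direction,
    x$true_speed_cm_s, x$kfa_predictor_truth,
    if (x$valid) "valid" else "invalid"
  ))
  invisible(x)
}

#' All six walking configurations
#'
#' @return Data frame of the 3 instructed velocities x 2 directions.
#' @export
walking_configurations <- function() {
  expand.grid(velocity_class = c("slow", "comfortable", "fast"),
              direction = c("left", "right"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

trial_seed <- function(base_seed, subject_idx, config_idx, trial_idx) {
  as.integer(base_seed) + 100003L * subject_idx + 509L * config_idx + 17L * trial_idx
}

#' Simulate training data without sensor rendering
#'
#' Fast path for building model-training datasets: draws the per-trial truth
#' (speed, KFA template) and the loading curves, extracts the nine peaks,
#' and returns one row per trial with the six predictors (ground-truth
#' walking speed and KFA predictor, as a motion-capture pipeline would
#' provide) and the nine peak responses. No IMU or video streams are built.
#'
#' @param cohort List of [subject_profile()]s.
#' @param trials_per_subject Trials per subject; instructed velocities cycle
#'   slow/comfortable/fast.
#' @param seed Integer seed.
#' @param model A [load_model()].
#' @param params A [gait_params()].
#' @return Data frame with columns `subject_id`, the six predictors and the
#'   nine peaks of [kjcf_peak_names()].
#' @export
make_training_data <- function(cohort, trials_per_subject = 6L, seed = 1L,
                               model = load_model(), params = gait_params()) {
  classes <- c("slow", "comfortable", "fast")
  rows <- vector("list", length(cohort) * trials_per_subject)
  k <- 0L
  for (si in seq_along(cohort)) {
    prof <- cohort[[si]]
    for (ti in seq_len(trials_per_subject)) {
      s <- trial_seed(seed, si, 0L, ti)
      truth <- sample_trial_truth(prof, classes[(ti - 1L) %% 3L + 1L], s, params)
      kj <- synthesize_kjcf(prof, truth$true_speed_cm_s, truth$kfa_predictor,
                            model, s + 1L, n_stance = truth$n_stance, fs = params$fs)
      pk <- extract_loading_peaks(kj$curves)$peaks
      k <- k + 1L
      rows[[k]] <- data.frame(
        subject_id = prof$subject_id, mass = prof$mass, height = prof$height,
        age = prof$age, sex = prof$sex, speed = truth$true_speed_cm_s,
        kfa = truth$kfa_predictor, t(pk)
      )
    }
  }
  do.call(rbind, rows)
}
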