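#' Experiment configuration
#'
#' Declarative configuration for [run_experiment()]: cohort sizes, noise
#' preset, predictor set, modalities and the single root seed from which
#' every source of randomness derives.
#'
#' @param seed Root integer seed.
#' @param n_train_subjects Healthy training-cohort size.
#' @param n_pretrain_subjects Pre-training cohort size (an older, heavier,
#'   slower cohort emulating a clinical knee-osteoarthritis dataset); 0
#'   disables pre-training.
#' @param n_test_subjects Test-cohort size.
#' @param trials_per_subject_train Training trials per subject.
#' @param trials_per_config Test trials per walking configuration (x6).
#' @param noise_profile `"none"` or `"realistic"`.
#' @param predictor_set Predictor set for the trained models.
#' @param modalities Portable modalities to evaluate against baseline.
#' @param min_valid,keep_per_config Balanced-test-set filter settings.
#' @param out_dir Output directory (`NULL` for in-memory only).
#' @return An object of class `kneeload_experiment_config`.
#' @export
experiment_config <- function(seed = 1L,
                              n_train_subjects = 60L,
                              n_pretrain_subjects = 20L,
                              n_test_subjects = 20L,
                              trials_per_subject_train = 6L,
                              trials_per_config = 7L,
                              noise_profile = "realistic",
                              predictor_set = "full",
                              modalities = c("imu", "vc"),
                              min_valid = 5L, keep_per_config = 5L,
                              out_dir = NULL) {
  structure(as.list(environment()), class = "kneeload_experiment_config")
}

#' Simulate test-cohort trial records with portable-modality estimates
#'
#' Simulates `trials_per_config` trials for each of the six walking
#' configurations per subject, runs the requested portable estimation
#' pipelines on the rendered streams, and returns one row per trial with
#' ground-truth (baseline) and estimated predictors plus the reference
#' peaks. Estimation failures leave NA estimates and mark the trial
#' invalid, as an unprocessable laboratory trial would be.
#'
#' @param cohort List of [subject_profile()]s.
#' @param trials_per_config Trials per walking configuration.
#' @param seed Integer seed.
#' @param noise A [noise_config()].
#' @param model A [load_model()].
#' @param modalities Subset of `c("imu", "vc")`.
#' @param params A [gait_params()].
#' @param camera A [camera_config()].
#' @param quiet Suppress progress output.
#' @return Data frame of trial records.
#' @export
simulate_test_records <- function(cohort, trials_per_config = 7L, seed = 1L,
                                  noise = noise_config("realistic"),
                                  model = load_model(),
                                  modalities = c("imu", "vc"),
                                  params = gait_params(),
                                  camera = camera_config(), quiet = TRUE) {
  cfgs <- walking_configurations()
  rows <- list()
  for (si in seq_along(cohort)) {
    prof <- cohort[[si]]
    if (!quiet) message(sprintf("simulating subject %d/%d", si, length(cohort)))
    for (ci in seq_len(nrow(cfgs))) {
      for (ti in seq_len(trials_per_config)) {
        s <- trial_seed(seed, si, ci, ti)
        tr <- simulate_trial(prof, cfgs$velocity_class[ci], cfgs$direction[ci],
                             seed = s, noise = noise, model = model,
                             params = params, camera = camera)
        row <- data.frame(
          subject_id = prof$subject_id, mass = prof$mass, height = prof$height,
          age = prof$age, sex = prof$sex,
          velocity_class = cfgs$velocity_class[ci], direction = cfgs$direction[ci],
          order = ti, valid = tr$valid,
          speed_baseline = tr$true_speed_cm_s,
          kfa_baseline = tr$kfa_predictor_truth,
          speed_imu = NA_real_, kfa_imu = NA_real_,
          speed_vc = NA_real_, kfa_vc = NA_real_,
          t(tr$peaks_truth)
        )
        if ("imu" %in% modalities) {
          est <- tryCatch(estimate_predictors_imu(tr$imu, prof$height),
                          error = function(e) NULL)
          if (is.null(est)) row$valid <- FALSE else {
            row$speed_imu <- est$speed_cm_s
            row$kfa_imu <- est$kfa_predictor_deg
          }
        }
        if ("vc" %in% modalities) {
          est <- tryCatch(estimate_predictors_vc(tr$keypoints, prof$height),
                          error = function(e) NULL)
          if (is.null(est)) row$valid <- FALSE else {
            row$speed_vc <- est$speed_cm_s
            row$kfa_vc <- est$kfa_predictor_deg
          }
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

modality_predictors <- function(records, modality) {
  df <- records[c("subject_id", "mass", "height", "age", "sex")]
  df$speed <- records[[paste0("speed_", modality)]]
  df$kfa <- records[[paste0("kfa_", modality)]]
  df
}

#' Run the full synthetic experiment
#'
#' Chains every stage of the pipeline: (1) sample training, pre-training
#' and test cohorts; (2) build motion-capture-grade training data and train
#' one network and one MLR model per peak; (3) simulate test trials and
#' estimate walking speed and the KFA predictor from the rendered IMU and
#' keypoint streams; (4) apply the balanced test-set filter; (5) predict
#' the nine peaks per modality and compute all evaluation metrics. When
#' `config$out_dir` is set, the artefacts (cohort, training table,
#' predictor estimates, predictions, metrics, a manifest with the
#' configuration hash) are written as CSV/JSON under it.
#'
#' @param config An [experiment_config()].
#' @param quiet Suppress progress messages.
#' @return A list with the trained `models`, the filtered `records`, the
#'   long observation table `observations`, `peak_metrics`,
#'   `predictor_metrics`, `mae_change`, the `excluded_subjects` and the
#'   `config`.
#' @export
run_experiment <- function(config = experiment_config(), quiet = TRUE) {
  stopifnot(inherits(config, "kneeload_experiment_config"))
  seed <- as.integer(config$seed)
  noise <- noise_config(config$noise_profile)
  model <- load_model()

  # 1) cohorts ----------------------------------------------------------
  train_cohort <- sample_cohort(config$n_train_subjects, seed + 1L, id_prefix = "TR")
  pretrain_cohort <- if (config$n_pretrain_subjects > 0L) {
    # older, heavier, slower cohort standing in for a clinical dataset
    sample_cohort(config$n_pretrain_subjects, seed + 2L,
                  age_mean = 60, age_sd = 8, age_range = c(45, 75),
                  bmi_mean = 29, bmi_sd = 4.5, bmi_range = c(20, 40.4),
                  speed_mean = 115, speed_sd = 20, speed_range = c(60, 180),
                  id_prefix = "KOA")
  } else NULL
  test_cohort <- sample_cohort(config$n_test_subjects, seed + 3L, id_prefix = "TE")

  # 2) training ---------------------------------------------------------
  if (!quiet) message("building training data and fitting models")
  train_df <- make_training_data(train_cohort, config$trials_per_subject_train,
                                 seed + 4L, model = model)
  pretrain_df <- if (!is.null(pretrain_cohort)) {
    make_training_data(pretrain_cohort, config$trials_per_subject_train,
                       seed + 5L, model = model)
  } else NULL
  cfg_train <- training_config(seed = seed + 6L, pretrain = !is.null(pretrain_df))
  models <- train_all_peaks(train_df, config$predictor_set, cfg_train, pretrain_df)

  # 3) test simulation + portable estimation ----------------------------
  if (!quiet) message("simulating test cohort")
  records <- simulate_test_records(test_cohort, config$trials_per_config,
                                   seed + 7L, noise = noise, model = model,
                                   modalities = config$modalities, quiet = quiet)

  # 4) balanced test set -------------------------------------------------
  bal <- build_balanced_test_set(records, config$min_valid, config$keep_per_config)
  inc <- bal$included

  # 5) predictions + metrics --------------------------------------------
  modalities <- c("baseline", config$modalities)
  obs <- list()
  for (mod in modalities) {
    pred_df <- modality_predictors(inc, mod)
    for (peak in kjcf_peak_names()) {
      m <- models$models[[peak]]
      obs[[length(obs) + 1L]] <- data.frame(
        subject_id = inc$subject_id, velocity_class = inc$velocity_class,
        direction = inc$direction, modality = mod, response = peak,
        model = "ann", predicted = predict_ann(m$ann, pred_df),
        reference = inc[[peak]]
      )
      obs[[length(obs) + 1L]] <- data.frame(
        subject_id = inc$subject_id, velocity_class = inc$velocity_class,
        direction = inc$direction, modality = mod, response = peak,
        model = "mlr", predicted = predict_mlr(m$mlr, pred_df),
        reference = inc[[peak]]
      )
    }
  }
  obs <- do.call(rbind, obs)
  peak_metrics <- compute_peak_metrics(obs, by = c("model", "modality", "response"))

  pred_obs <- do.call(rbind, lapply(config$modalities, function(mod) {
    rbind(
      data.frame(subject_id = inc$subject_id, predictor = "speed", modality = mod,
                 estimate = inc[[paste0("speed_", mod)]],
                 reference = inc$speed_baseline),
      data.frame(subject_id = inc$subject_id, predictor = "kfa", modality = mod,
                 estimate = inc[[paste0("kfa_", mod)]],
                 reference = inc$kfa_baseline)
    )
  }))
  predictor_metrics <- if (!is.null(pred_obs) && nrow(pred_obs)) {
    compute_predictor_metrics(pred_obs)
  } else NULL

  ann_obs <- obs[obs$model == "ann", , drop = FALSE]
  base_key <- interaction(ann_obs$subject_id, ann_obs$velocity_class,
                          ann_obs$direction, ann_obs$response, drop = FALSE)
  mae_change <- do.call(rbind, lapply(config$modalities, function(mod) {
    mo <- ann_obs[ann_obs$modality == mod, , drop = FALSE]
    ba <- ann_obs[ann_obs$modality == "baseline", , drop = FALSE]
    mo$baseline <- ba$predicted[match(base_key[ann_obs$modality == mod],
                                      base_key[ann_obs$modality == "baseline"])]
    ch <- mae_change_from_baseline(mo)
    ch$modality <- mod
    ch
  }))

  result <- list(models = models, records = inc, observations = obs,
                 peak_metrics = peak_metrics, predictor_metrics = predictor_metrics,
                 mae_change = mae_change, excluded_subjects = bal$excluded_subjects,
                 train_df = train_df, config = config)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_csv(test_cohort, file.path(config$out_dir, "cohort.csv"))
    write.csv(train_df, file.path(config$out_dir, "training_data.csv"), row.names = FALSE)
    write.csv(inc, file.path(config$out_dir, "records.csv"), row.names = FALSE)
    write.csv(obs, file.path(config$out_dir, "observations.csv"), row.names = FALSE)
    write.csv(peak_metrics, file.path(config$out_dir, "metrics.csv"), row.names = FALSE)
    if (!is.null(predictor_metrics)) {
      write.csv(predictor_metrics, file.path(config$out_dir, "predictor_metrics.csv"),
                row.names = FALSE)
    }
    write.csv(mae_change, file.path(config$out_dir, "mae_change.csv"), row.names = FALSE)
    save_models_json(models, file.path(config$out_dir, "models.json"))
    # hash the scientific configuration only, not output paths
    cfg_hashable <- unclass(config)
    cfg_hashable$out_dir <- NULL
    cfg_json <- jsonlite::toJSON(cfg_hashable, auto_unbox = TRUE, digits = NA,
                                 null = "null")
    manifest <- list(
      package = "kneeload",
      version = tryCatch(as.character(utils::packageVersion("kneeload")),
                         error = function(e) "dev"),
      seed = seed,
      config = jsonlite::fromJSON(cfg_json),
      config_hash = config_hash(cfg_json),
      n_test_trials = nrow(inc),
      excluded_subjects = bal$excluded_subjects
    )
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

# stable hash of the serialized configuration (md5 over the JSON bytes)
config_hash <- function(cfg_json) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(cfg_json, tmp)
  unname(tools::md5sum(tmp))
}
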