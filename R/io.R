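#' Write a synthetic trial to a directory
#'
#' Produces the on-disk layout consumed by the estimation pipelines:
#' `imu_<site>.csv` (columns `t, qw, qx, qy, qz, ax, ay, az`), one
#' OpenPose-style JSON per frame under `keypoints/`
#' (`people[[1]]$pose_keypoints_2d` as flat x, y, confidence triplets),
#' `camera.json` (frame rate and image size, which the keypoint JSON
#' dialect itself does not carry) and `truth.json` (ground-truth speed, KFA
#' predictor, nine peaks and validity).
#'
#' @param trial A [simulate_trial()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trial_dir <- function(trial, dir) {
  stopifnot(inherits(trial, "kneeload_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (site in names(trial$imu)) {
    s <- trial$imu[[site]]
    df <- data.frame(t = s$time, qw = s$quat[, 1], qx = s$quat[, 2],
                     qy = s$quat[, 3], qz = s$quat[, 4],
                     ax = s$accel[, 1], ay = s$accel[, 2], az = s$accel[, 3])
    write.csv(df, file.path(dir, sprintf("imu_%s.csv", site)), row.names = FALSE)
  }
  kdir <- file.path(dir, "keypoints")
  dir.create(kdir, showWarnings = FALSE)
  kp <- trial$keypoints
  for (i in seq_len(dim(kp$xyc)[1])) {
    flat <- as.numeric(t(kp$xyc[i, , ]))
    payload <- list(version = 1.3,
                    people = list(list(pose_keypoints_2d = flat)))
    jsonlite::write_json(payload, file.path(kdir, sprintf("frame_%06d.json", i - 1L)),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    list(fs = kp$fs, image_width = kp$image_width, image_height = kp$image_height),
    file.path(dir, "camera.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(list(
    subject_id = trial$profile$subject_id,
    velocity_class = trial$velocity_class, direction = trial$direction,
    true_speed_cm_s = trial$true_speed_cm_s,
    kfa_predictor_deg = trial$kfa_predictor_truth,
    gait_period_s = trial$gait_period_s,
    peaks = as.list(trial$peaks_truth),
    valid = trial$valid
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read one IMU stream CSV
#'
#' @param path CSV with columns `t, qw, qx, qy, qz, ax, ay, az`.
#' @param site Sensor site label.
#' @return A `kneeload_imu` stream.
#' @export
read_imu_csv <- function(path, site = sub("^imu_(.*)\\.csv$", "\\1", basename(path))) {
  df <- read.csv(path)
  need <- c("t", "qw", "qx", "qy", "qz", "ax", "ay", "az")
  if (!all(need %in% names(df))) {
    kneeload_abort("IMU CSV lacks required columns", "invalid_argument")
  }
  fs <- 1 / stats::median(diff(df$t))
  q <- unname(as.matrix(df[c("qw", "qx", "qy", "qz")]))
  a <- unname(as.matrix(df[c("ax", "ay", "az")]))
  imu_stream(site, df$t, q, a, fs)
}

#' Read all IMU streams of a trial directory
#' @param dir Directory written by [write_trial_dir()].
#' @return Named list of `kneeload_imu` streams.
#' @export
read_trial_imu <- function(dir) {
  files <- list.files(dir, pattern = "^imu_.*\\.csv$", full.names = TRUE)
  if (!length(files)) kneeload_abort("no IMU CSV files found", "missing_stream")
  streams <- lapply(files, read_imu_csv)
  names(streams) <- sub("^imu_(.*)\\.csv$", "\\1", basename(files))
  streams
}

#' Read a per-frame keypoint JSON directory
#'
#' Parses OpenPose-style body-25 JSON frames (tolerating frames with an
#' empty `people` list, which become zero-confidence keypoints).
#'
#' @param dir Directory containing `frame_*.json` files (sorted by name) and
#'   optionally a `camera.json` with `fs`, `image_width`, `image_height`.
#' @param fs,image_width,image_height Used when no `camera.json` is present.
#' @return A `kneeload_keypoints` series.
#' @export
read_keypoints_dir <- function(dir, fs = 100, image_width = 480, image_height = 272) {
  cam <- file.path(dirname(dir), "camera.json")
  if (file.exists(cam)) {
    cj <- jsonlite::read_json(cam, simplifyVector = TRUE)
    fs <- as.numeric(cj$fs)
    image_width <- as.numeric(cj$image_width)
    image_height <- as.numeric(cj$image_height)
  }
  files <- sort(list.files(dir, pattern = "^frame_.*\\.json$", full.names = TRUE))
  if (!length(files)) kneeload_abort("no keypoint frames found", "invalid_argument")
  arr <- array(0, dim = c(length(files), 25L, 3L))
  for (i in seq_along(files)) {
    fr <- jsonlite::read_json(files[i], simplifyVector = TRUE)
    if (length(fr$people) >= 1L) {
      flat <- if (is.data.frame(fr$people)) unlist(fr$people$pose_keypoints_2d[1])
              else unlist(fr$people[[1]]$pose_keypoints_2d)
      k <- min(25L, length(flat) %/% 3L)
      arr[i, seq_len(k), ] <- matrix(flat[seq_len(3L * k)], ncol = 3L, byrow = TRUE)
    }
  }
  keypoint_series(arr, fs, image_width, image_height)
}

#' Write a cohort table
#' @param cohort List of [subject_profile()]s.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort_to_df(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table written by [write_cohort_csv()]
#' @param path CSV path.
#' @return List of [subject_profile()]s.
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path)
  lapply(seq_len(nrow(df)), function(i) {
    subject_profile(df$subject_id[i], df$mass[i], df$height[i], df$age[i],
                    df$sex[i], df$comfortable_speed[i])
  })
}

#' Write a per-trial peaks/predictors table
#'
#' @param df Data frame with `subject_id`, `trial_id`, the nine peak columns
#'   (N), `kfa` (degrees) and `speed` (cm/s).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_peaks_csv <- function(df, path) {
  need <- c("subject_id", "trial_id", kjcf_peak_names(), "kfa", "speed")
  if (!all(need %in% names(df))) {
    kneeload_abort("peaks table lacks required columns", "invalid_argument")
  }
  write.csv(df[need], path, row.names = FALSE)
  invisible(path)
}
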