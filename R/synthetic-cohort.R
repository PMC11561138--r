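#' Subject profile
#'
#' Demographics and anthropometrics used both by the gait simulator and as
#' model predictors.
#'
#' @param subject_id Character id.
#' @param mass Body mass (kg), positive.
#' @param height Stature (cm), positive.
#' @param age Age (years), non-negative.
#' @param sex Coded sex: 0 = female, 1 = male.
#' @param comfortable_speed Self-selected walking speed (cm/s), in (0, 400).
#' @return An object of class `kneeload_subject`.
#' @export
subject_profile <- function(subject_id, mass, height, age, sex, comfortable_speed) {
  if (mass <= 0 || height <= 0 || age < 0 ||
      comfortable_speed <= 0 || comfortable_speed >= 400 || !(sex %in% c(0, 1))) {
    kneeload_abort("invalid subject profile", "invalid_argument")
  }
  structure(
    list(subject_id = as.character(subject_id), mass = mass, height = height,
         age = age, sex = sex, comfortable_speed = comfortable_speed),
    class = "kneeload_subject"
  )
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Sample a synthetic walking cohort
#'
#' Draws subject profiles emulating a healthy adult gait-laboratory cohort:
#' ages from a truncated normal on \[20, 45\] (mean 29, SD 6), BMI from a
#' truncated normal on \[18.8, 40.4\] (mean 25.1, SD 4.2), sex male with
#' probability 29/46, height from a sex-specific normal, mass derived as
#' BMI * (height/100)^2, and comfortable walking speed from a truncated
#' normal on \[80, 200\] cm/s (mean 133.56, SD 20). All arguments are
#' exposed so that shifted cohorts (for example an older, heavier, slower
#' pre-training cohort emulating knee-osteoarthritis patients) can be drawn
#' with the same machinery.
#'
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed; sampling is deterministic given (arguments, seed).
#' @param age_mean,age_sd,age_range Age distribution (years).
#' @param bmi_mean,bmi_sd,bmi_range BMI distribution (kg/m^2).
#' @param p_male Probability of sex = 1.
#' @param speed_mean,speed_sd,speed_range Comfortable-speed distribution (cm/s).
#' @param height_female,height_male Mean stature by sex (cm); SD 6 cm.
#' @param id_prefix Prefix for subject ids.
#' @return A list of [subject_profile()] objects.
#' @export
sample_cohort <- function(n, seed,
                          age_mean = 29, age_sd = 6, age_range = c(20, 45),
                          bmi_mean = 25.1, bmi_sd = 4.2, bmi_range = c(18.8, 40.4),
                          p_male = 29 / 46,
                          speed_mean = 133.56, speed_sd = 20, speed_range = c(80, 200),
                          height_female = 165, height_male = 178,
                          id_prefix = "S") {
  if (!is.numeric(n) || n < 1) kneeload_abort("n must be >= 1", "invalid_argument")
  n <- as.integer(n)
  withr::with_seed(as.integer(seed), {
    age <- rtruncnorm1(n, age_mean, age_sd, age_range[1], age_range[2])
    bmi <- rtruncnorm1(n, bmi_mean, bmi_sd, bmi_range[1], bmi_range[2])
    sex <- rbinom(n, 1L, p_male)
    height <- rtruncnorm1(n, ifelse(sex == 1, height_male, height_female), 6, 150, 200)
    speed <- rtruncnorm1(n, speed_mean, speed_sd, speed_range[1], speed_range[2])
  })
  mass <- bmi * (height / 100)^2
  lapply(seq_len(n), function(i) {
    subject_profile(sprintf("%s%03d", id_prefix, i), mass[i], height[i],
                    age[i], sex[i], speed[i])
  })
}

#' Convert a cohort to a data frame
#'
#' @param cohort List of [subject_profile()] objects.
#' @return Data frame with one row per subject.
#' @export
cohort_to_df <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p) {
    data.frame(subject_id = p$subject_id, mass = p$mass, height = p$height,
               age = p$age, sex = p$sex, comfortable_speed = p$comfortable_speed)
  }))
}
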