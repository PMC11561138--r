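#' Build the balanced test set
#'
#' Applies the study's filtering rules to trial records: a participant is
#' eliminated entirely if any walking configuration (instructed velocity x
#' direction) has fewer than `min_valid` valid trials; for the remaining
#' participants exactly the first `keep` valid trials (by trial order) of
#' every configuration are retained, so each surviving subject contributes
#' `keep * 6` records.
#'
#' @param records Data frame with at least `subject_id`, `velocity_class`,
#'   `direction`, `order` (within-configuration trial order) and `valid`.
#' @param min_valid Minimum number of valid trials per configuration.
#' @param keep Number of valid trials kept per configuration.
#' @return A list with `included` (the filtered records) and
#'   `excluded_subjects` (character vector).
#' @export
build_balanced_test_set <- function(records, min_valid = 5L, keep = 5L) {
  needed <- c("subject_id", "velocity_class", "direction", "order", "valid")
  if (!all(needed %in% names(records))) {
    kneeload_abort("records lack required columns", "invalid_argument")
  }
  cfgs <- walking_configurations()
  excluded <- character(0)
  kept <- vector("list", 0L)
  for (sid in unique(records$subject_id)) {
    rs <- records[records$subject_id == sid, , drop = FALSE]
    ok <- TRUE
    sel <- vector("list", nrow(cfgs))
    for (ci in seq_len(nrow(cfgs))) {
      rc <- rs[rs$velocity_class == cfgs$velocity_class[ci] &
                 rs$direction == cfgs$direction[ci] & rs$valid, , drop = FALSE]
      if (nrow(rc) < min_valid) {
        ok <- FALSE
        break
      }
      rc <- rc[order(rc$order), , drop = FALSE]
      sel[[ci]] <- rc[seq_len(keep), , drop = FALSE]
    }
    if (ok) kept <- c(kept, sel) else excluded <- c(excluded, sid)
  }
  included <- if (length(kept)) do.call(rbind, kept) else records[0, , drop = FALSE]
  rownames(included) <- NULL
  list(included = included, excluded_subjects = excluded)
}

# core pooled metrics for one prediction/reference pairing
peak_metric_values <- function(pred, ref) {
  stopifnot(length(pred) == length(ref))
  err <- pred - ref
  rmse <- sqrt(mean(err^2))
  nrmse <- rmse / mean(ref)
  r <- if (sd_pop(ref) < 1e-12 || sd_pop(pred) < 1e-12) NA_real_ else cor(pred, ref)
  list(rmse = rmse, nrmse = nrmse, r = r, mae = mean(abs(err)),
       r_undefined = sd_pop(ref) < 1e-12)
}

#' Pooled loading-peak prediction metrics
#'
#' Computes RMSE, RMSE normalized to the mean of the reference values
#' (NRMSE), Pearson correlation and MAE, pooled over trials, for every
#' group in the long-format observation table.
#'
#' @param obs Data frame with columns `predicted`, `reference` and the
#'   grouping columns named in `by` (for example modality and response).
#' @param by Character vector of grouping column names.
#' @return Data frame with one row per group and columns `rmse`, `nrmse`,
#'   `r`, `mae`, `n` (and a logical `r_undefined` flag for constant
#'   references).
#' @export
compute_peak_metrics <- function(obs, by = c("modality", "response")) {
  if (!all(c("predicted", "reference", by) %in% names(obs))) {
    kneeload_abort("observation table lacks required columns", "invalid_argument")
  }
  groups <- split(obs, obs[by], drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    m <- peak_metric_values(g$predicted, g$reference)
    cbind(g[1L, by, drop = FALSE],
          data.frame(rmse = m$rmse, nrmse = m$nrmse, r = m$r, mae = m$mae,
                     n = nrow(g), r_undefined = m$r_undefined))
  }))
  rownames(out) <- NULL
  out
}

#' Inter-subject predictor estimation metrics
#'
#' RMSE and Pearson correlation between estimated and reference predictor
#' values are computed within each subject and then averaged across
#' subjects with equal weight; the spread is the population SD of the
#' per-subject values.
#'
#' @param obs Data frame with columns `subject_id`, `estimate`, `reference`
#'   and the grouping columns in `by` (for example `predictor` and
#'   `modality`).
#' @param by Character vector of grouping column names.
#' @return Data frame with `rmse_mean`, `rmse_sd`, `r_mean`, `r_sd` and
#'   `n_subjects` per group.
#' @export
compute_predictor_metrics <- function(obs, by = c("predictor", "modality")) {
  if (!all(c("subject_id", "estimate", "reference", by) %in% names(obs))) {
    kneeload_abort("observation table lacks required columns", "invalid_argument")
  }
  groups <- split(obs, obs[by], drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    per <- lapply(split(g, g$subject_id), function(s) {
      data.frame(
        rmse = sqrt(mean((s$estimate - s$reference)^2)),
        r = if (nrow(s) >= 3L && sd_pop(s$reference) > 1e-12 &&
                sd_pop(s$estimate) > 1e-12) cor(s$estimate, s$reference) else NA_real_
      )
    })
    per <- do.call(rbind, per)
    cbind(g[1L, by, drop = FALSE], data.frame(
      rmse_mean = mean(per$rmse), rmse_sd = sd_pop(per$rmse),
      r_mean = mean(per$r, na.rm = TRUE),
      r_sd = sd_pop(per$r[!is.na(per$r)]),
      n_subjects = nrow(per)
    ))
  }))
  rownames(out) <- NULL
  out
}

#' Relative MAE change from the baseline modality
#'
#' For every subject, walking direction and response variable, computes the
#' mean absolute prediction error of a portable modality and of the
#' baseline, takes the relative change `(MAE_modality - MAE_baseline) /
#' MAE_baseline` per subject, and averages it across subjects by direction
#' and response.
#'
#' @param obs Data frame with columns `subject_id`, `direction`, `response`,
#'   `reference`, `predicted` and `baseline` (baseline predictions for the
#'   same trials).
#' @return Data frame with `direction`, `response`, `mean_change`,
#'   `sd_change` (population SD across subjects) and `n_subjects`.
#' @export
mae_change_from_baseline <- function(obs) {
  needed <- c("subject_id", "direction", "response", "reference", "predicted", "baseline")
  if (!all(needed %in% names(obs))) {
    kneeload_abort("observation table lacks required columns", "invalid_argument")
  }
  per <- do.call(rbind, lapply(
    split(obs, obs[c("subject_id", "direction", "response")], drop = TRUE),
    function(g) {
      mae_mod <- mean(abs(g$predicted - g$reference))
      mae_base <- mean(abs(g$baseline - g$reference))
      data.frame(subject_id = g$subject_id[1L], direction = g$direction[1L],
                 response = g$response[1L],
                 change = (mae_mod - mae_base) / mae_base)
    }
  ))
  out <- do.call(rbind, lapply(split(per, per[c("direction", "response")], drop = TRUE),
                               function(g) {
    data.frame(direction = g$direction[1L], response = g$response[1L],
               mean_change = mean(g$change), sd_change = sd_pop(g$change),
               n_subjects = nrow(g))
  }))
  rownames(out) <- NULL
  out
}
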