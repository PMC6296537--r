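# In-memory pipeline: optics -> threshold -> region statistics -> patient
# aggregation. The CLI wraps these around file I/O.

#' Analyse one frame: estimation, threshold filter, region statistics
#'
#' @param frame a [polar_frame()].
#' @param mask a [region_mask()] for the frame.
#' @param threshold_mm minimum-attenuation threshold (mm^-1), default 0.15.
#' @param optics named list of overrides passed to [estimate_attenuation()]
#'   (e.g. `tail_guard_fraction`, `method`, `smooth`, `mu_cap`, `noise_floor`)
#'   and `gain` for [estimate_backscatter()].
#' @return a `region_statistics` object.
#' @export
analyze_frame <- function(frame, mask, threshold_mm = 0.15, optics = list()) {
  gain <- optics$gain %||% 5
  att_args <- optics[setdiff(names(optics), "gain")]
  att <- do.call(estimate_attenuation, c(list(frame = frame), att_args))
  bsc <- estimate_backscatter(frame, att, gain = gain)
  filt <- apply_attenuation_threshold(mask, att, min_att_mm = threshold_mm)
  region_statistics(frame, att, bsc, filt, threshold_mm = threshold_mm)
}

#' Analyse one patient's frames into a pixel-count-weighted summary
#'
#' @param frames list of [polar_frame()] (typically the 3 cross-sections with
#'   the largest thrombus areas).
#' @param masks list of [region_mask()], parallel to `frames`.
#' @inheritParams analyze_frame
#' @return list with `patient` (a `patient_summary`) and `frames` (list of
#'   `region_statistics`).
#' @export
analyze_patient <- function(frames, masks, threshold_mm = 0.15, optics = list()) {
  if (length(frames) != length(masks))
    abort_validation("frames and masks must be parallel lists")
  stats_list <- Map(function(fr, mk) analyze_frame(fr, mk, threshold_mm, optics),
                    frames, masks)
  list(patient = patient_summary(stats_list), frames = stats_list)
}

#' Analyse a simulated cohort into a per-patient parameter table
#'
#' Runs [analyze_patient()] for every patient of an `oct_cohort` and returns
#' one row per patient with the headline parameters plus truth columns, ready
#' for ROC analysis.
#'
#' @param cohort an `oct_cohort` from [simulate_cohort()].
#' @inheritParams analyze_frame
#' @return data.frame with columns `patient_id`, `class`, `tas`,
#'   `median_attenuation`, `mean_attenuation`, `mean_backscatter`,
#'   `median_backscatter`, `mean_grayscale`, `median_grayscale`,
#'   `ratio_att95_over_medint`, `total_pixels`.
#' @export
analyze_cohort <- function(cohort, threshold_mm = 0.15, optics = list()) {
  if (!inherits(cohort, "oct_cohort")) abort_validation("cohort must be an oct_cohort")
  rows <- lapply(seq_len(nrow(cohort$truth)), function(i) {
    res <- analyze_patient(cohort$frames[[i]], cohort$masks[[i]],
                           threshold_mm, optics)$patient
    w <- res$weighted
    data.frame(patient_id = cohort$truth$patient_id[i],
               class = cohort$truth$class[i], tas = cohort$truth$tas[i],
               median_attenuation = w["attenuation", "median"],
               mean_attenuation = w["attenuation", "mean"],
               mean_backscatter = w["backscatter", "mean"],
               median_backscatter = w["backscatter", "median"],
               mean_grayscale = w["grayscale", "mean"],
               median_grayscale = w["grayscale", "median"],
               ratio_att95_over_medint = res$ratio_att95_over_medint,
               total_pixels = res$total_pixels,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
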