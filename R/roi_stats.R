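# Threshold-filtered ROI statistics, fragment selection, and patient-level
# pixel-count-weighted aggregation.

CHANNELS <- c("attenuation", "backscatter", "grayscale")
STATISTICS <- c("median", "mean", "sd", "skewness", "kurtosis",
                "p5", "p10", "p90", "p95")

#' Apply a minimum-attenuation threshold to a region mask
#'
#' Keeps member pixels whose attenuation estimate is valid and at or above the
#' threshold; invalid pixels and pixels below the threshold are excluded. This
#' is the noise/dark-pixel filter applied before any region statistics.
#'
#' @param mask a [region_mask()].
#' @param att an `attenuation_map` for the same frame.
#' @param min_att_mm minimum attenuation (mm^-1), >= 0. The shipped analysis
#'   thresholds are 0.15 (default) and 0.5.
#' @return list with `keep` (logical matrix of retained pixels),
#'   `excluded_fraction` (`NA` for an empty mask), `n_included`, `n_excluded`.
#' @export
apply_attenuation_threshold <- function(mask, att, min_att_mm = 0.15) {
  stopifnot_scalar_number(min_att_mm, "min_att_mm", min = 0)
  member <- mask$member
  if (!all(dim(member) == dim(att$valid)))
    abort_format("mask and attenuation map dimensions differ")
  keep <- member & att$valid & !is.na(att$mu) & att$mu >= min_att_mm
  n_member <- sum(member)
  n_keep <- sum(keep)
  list(keep = keep,
       excluded_fraction = if (n_member == 0L) NA_real_ else (n_member - n_keep) / n_member,
       n_included = n_keep, n_excluded = n_member - n_keep)
}

# Nine summary statistics of a numeric vector. Percentiles use linear
# interpolation between order statistics (quantile type 7). Skewness is the
# moment coefficient g1 (no small-sample correction); kurtosis is excess
# (Fisher). Both are undefined (NA) when the second moment is zero or n < 2.
summary_statistics <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) return(stats::setNames(rep(NA_real_, 9L), STATISTICS))
  q <- stats::quantile(x, c(0.05, 0.10, 0.50, 0.90, 0.95), names = FALSE, type = 7)
  m <- mean(x)
  s <- if (n >= 2L) stats::sd(x) else NA_real_
  m2 <- mean((x - m)^2)
  if (n >= 2L && m2 > 0) {
    skew <- mean((x - m)^3) / m2^1.5
    kurt <- mean((x - m)^4) / m2^2 - 3
  } else {
    skew <- NA_real_; kurt <- NA_real_
  }
  c(median = q[3L], mean = m, sd = s, skewness = skew, kurtosis = kurt,
    p5 = q[1L], p10 = q[2L], p90 = q[4L], p95 = q[5L])
}

#' Region statistics for the three channels over a filtered pixel set
#'
#' Statistics are computed over exactly the same included pixel set for
#' attenuation, backscatter and grayscale (the attenuation threshold defines
#' one membership per run; it is not re-applied per channel). Non-finite
#' backscatter values inside the set (possible only at threshold 0) are
#' dropped from that channel.
#'
#' @param frame a [polar_frame()] (grayscale channel source).
#' @param att an `attenuation_map`.
#' @param bsc a `backscatter_map`.
#' @param filtered result of [apply_attenuation_threshold()].
#' @param threshold_mm the threshold that produced `filtered` (recorded).
#' @return object of class `region_statistics`: `stats` (3 x 9 matrix,
#'   channels x statistics), `included_pixels`, `excluded_pixels`, `frame_id`,
#'   `patient_id`, `threshold_mm`.
#' @export
region_statistics <- function(frame, att, bsc, filtered, threshold_mm = NA_real_) {
  keep <- filtered$keep
  stats_m <- rbind(attenuation = summary_statistics(att$mu[keep]),
                   backscatter = summary_statistics(bsc$b[keep]),
                   grayscale   = summary_statistics(frame$intensity[keep]))
  colnames(stats_m) <- STATISTICS
  structure(list(stats = stats_m,
                 included_pixels = filtered$n_included,
                 excluded_pixels = filtered$n_excluded,
                 frame_id = frame$frame_id, patient_id = frame$patient_id,
                 threshold_mm = threshold_mm),
            class = "region_statistics")
}

#' Select the reference fragment of a multi-fragment mask
#'
#' The reading rules for a cross-section with several thrombus fragments:
#' grade the largest fragment; break area ties toward the fragment with the
#' higher mean valid attenuation (the most strongly attenuating part);
#' remaining ties go to the lowest label.
#'
#' @param mask a [region_mask()] with at least one fragment.
#' @param att an `attenuation_map` (tie-break only).
#' @return the selected fragment label (integer).
#' @export
select_reference_fragment <- function(mask, att) {
  k <- mask$n_fragments
  if (k < 1L) abort_validation("mask has no fragments")
  areas <- tabulate(mask$fragment_labels[mask$fragment_labels > 0L], nbins = k)
  cand <- which(areas == max(areas))
  if (length(cand) > 1L) {
    mean_mu <- vapply(cand, function(lbl) {
      v <- att$mu[mask$fragment_labels == lbl]
      v <- v[is.finite(v)]
      if (length(v)) mean(v) else -Inf
    }, numeric(1L))
    cand <- cand[mean_mu == max(mean_mu)]
  }
  min(cand)
}

#' Pixel-count-weighted patient-level aggregation of region statistics
#'
#' Each (channel, statistic) is aggregated across frames as
#' `sum(w_i * v_i) / sum(w_i)` with `w_i` the included pixel count of frame i;
#' frames where a statistic is missing are dropped from that cell. The
#' normalized ratio variable is the weighted 95th-percentile attenuation
#' divided by the weighted median grayscale intensity (mm^-1).
#'
#' @param stats_list list of `region_statistics` sharing patient and threshold.
#' @param patient_id optional override for the patient identifier.
#' @return object of class `patient_summary`: `weighted` (3 x 9 matrix),
#'   `total_pixels`, `ratio_att95_over_medint`, `patient_id`, `threshold_mm`,
#'   `n_frames`.
#' @export
patient_summary <- function(stats_list, patient_id = NULL) {
  if (!length(stats_list)) abort_validation("no region statistics supplied")
  w <- vapply(stats_list, `[[`, numeric(1L), "included_pixels")
  if (sum(w) == 0) abort_validation("zero included pixels across all frames")
  pid <- patient_id %||% stats_list[[1L]]$patient_id
  thr <- stats_list[[1L]]$threshold_mm
  weighted <- matrix(NA_real_, length(CHANNELS), length(STATISTICS),
                     dimnames = list(CHANNELS, STATISTICS))
  for (ch in CHANNELS) for (st in STATISTICS) {
    v <- vapply(stats_list, function(s) s$stats[ch, st], numeric(1L))
    weighted[ch, st] <- wmean_na(v, w)
  }
  med_gray <- weighted["grayscale", "median"]
  ratio <- if (!is.finite(med_gray) || med_gray == 0) NA_real_
           else weighted["attenuation", "p95"] / med_gray
  structure(list(weighted = weighted, total_pixels = sum(w),
                 ratio_att95_over_medint = ratio, patient_id = pid,
                 threshold_mm = thr, n_frames = length(stats_list)),
            class = "patient_summary")
}

#' Tidy one frame's region statistics as a data.frame
#' @param x a `region_statistics`.
#' @param ... unused.
#' @return data.frame with one row per (channel, statistic).
#' @export
as.data.frame.region_statistics <- function(x, ...) {
  grid <- expand.grid(statistic = STATISTICS, channel = CHANNELS,
                      stringsAsFactors = FALSE)[, 2:1]
  data.frame(patient_id = x$patient_id, frame_id = x$frame_id,
             channel = grid$channel, statistic = grid$statistic,
             value = x$stats[cbind(grid$channel, grid$statistic)],
             included_pixels = x$included_pixels,
             excluded_pixels = x$excluded_pixels,
             threshold_mm = x$threshold_mm,
             stringsAsFactors = FALSE)
}

#' Tidy a patient summary as a data.frame
#'
#' The 27 weighted (channel, statistic) rows are followed by one `ratio`
#' channel row holding the attenuation-p95 / median-grayscale ratio.
#'
#' @param x a `patient_summary`.
#' @param ... unused.
#' @return data.frame.
#' @export
as.data.frame.patient_summary <- function(x, ...) {
  grid <- expand.grid(statistic = STATISTICS, channel = CHANNELS,
                      stringsAsFactors = FALSE)[, 2:1]
  rbind(
    data.frame(patient_id = x$patient_id, channel = grid$channel,
               statistic = grid$statistic,
               value = x$weighted[cbind(grid$channel, grid$statistic)],
               total_pixels = x$total_pixels, threshold_mm = x$threshold_mm,
               stringsAsFactors = FALSE),
    data.frame(patient_id = x$patient_id, channel = "ratio",
               statistic = "att95_over_median_grayscale",
               value = x$ratio_att95_over_medint,
               total_pixels = x$total_pixels, threshold_mm = x$threshold_mm,
               stringsAsFactors = FALSE))
}
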