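# Forward OCT phantom generator: polar frames with region-dependent
# attenuation/backscatter, multiplicative exponential speckle, catheter and
# lumen geometry, thrombus masks, class labels, and synthetic observer
# readings. Red-thrombus shadowing is never painted in: it emerges from the
# forward physics (high mu), so the estimators are genuinely exercised.

#' Specify a single-frame OCT phantom
#'
#' The phantom is a polar frame with, along each A-line: catheter interior
#' (noise only), contrast-filled lumen (near-zero signal), optionally a
#' thrombus block over an angular span and depth span, and vessel wall behind.
#' Class defaults follow the red/white phenomenology: red thrombus is strongly
#' attenuating (`mu_thrombus` 4.5 mm^-1) with a brighter luminal cap, white is
#' moderately attenuating (1.2 mm^-1) with the abluminal wall still visible.
#'
#' @param n_alines,n_depth frame dimensions (rows, columns).
#' @param axial_pitch_mm depth sampling pitch (mm), default 0.005.
#' @param catheter_offset first tissue-usable depth sample (0-based).
#' @param lumen_radius_samples depth sample where tissue begins.
#' @param thrombus_alines integer vector of A-line rows carrying thrombus
#'   (1-based; `NULL` for no thrombus).
#' @param thrombus_depth_samples thrombus thickness in depth samples.
#' @param class `"white"` or `"red"` (sets `mu_thrombus`/`beta_thrombus`
#'   defaults: white 1.2 / 0.10, red 4.5 / 0.05).
#' @param mu_thrombus,beta_thrombus thrombus attenuation (mm^-1) and relative
#'   backscatter level; `NULL` uses the class default.
#' @param mu_wall,beta_wall,mu_lumen,beta_lumen vessel wall and lumen optics.
#' @param noise_floor additive detector-noise level in grayscale units.
#' @param speckle logical; multiplicative unit-mean exponential speckle on the
#'   signal and, independently, on the noise floor.
#' @param intensity_scale source intensity scale (default 1023); output is not
#'   clipped.
#' @param guidewire logical; if `TRUE`, a narrow guidewire shadow band is
#'   blanked beyond the catheter (mask hygiene only, default off).
#' @param seed RNG seed for the speckle draw (global RNG state is restored).
#' @return validated object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_alines = 256L, n_depth = 512L,
                         axial_pitch_mm = 0.005, catheter_offset = 20L,
                         lumen_radius_samples = 60L,
                         thrombus_alines = 65:192,
                         thrombus_depth_samples = 160L,
                         class = c("white", "red"),
                         mu_thrombus = NULL, beta_thrombus = NULL,
                         mu_wall = 2.0, beta_wall = 0.12,
                         mu_lumen = 0.1, beta_lumen = 0.001,
                         noise_floor = 5, speckle = TRUE,
                         intensity_scale = 1023, guidewire = FALSE,
                         seed = NULL) {
  class <- match.arg(class)
  mu_thrombus <- mu_thrombus %||% switch(class, white = 1.2, red = 4.5)
  beta_thrombus <- beta_thrombus %||% switch(class, white = 0.10, red = 0.05)
  spec <- list(n_alines = as.integer(n_alines), n_depth = as.integer(n_depth),
               axial_pitch_mm = axial_pitch_mm,
               catheter_offset = as.integer(catheter_offset),
               lumen_radius_samples = as.integer(lumen_radius_samples),
               thrombus_alines = as.integer(thrombus_alines),
               thrombus_depth_samples = as.integer(thrombus_depth_samples),
               class = class, mu_thrombus = mu_thrombus,
               beta_thrombus = beta_thrombus, mu_wall = mu_wall,
               beta_wall = beta_wall, mu_lumen = mu_lumen,
               beta_lumen = beta_lumen, noise_floor = noise_floor,
               speckle = isTRUE(speckle), intensity_scale = intensity_scale,
               guidewire = isTRUE(guidewire), seed = seed)
  if (spec$catheter_offset < 0L || spec$catheter_offset >= spec$n_depth)
    abort_validation("catheter_offset outside frame depth")
  if (spec$lumen_radius_samples < spec$catheter_offset ||
      spec$lumen_radius_samples >= spec$n_depth)
    abort_validation("lumen radius outside frame depth")
  if (length(spec$thrombus_alines) &&
      (min(spec$thrombus_alines) < 1L || max(spec$thrombus_alines) > spec$n_alines))
    abort_validation("thrombus angular span outside frame bounds")
  if (length(spec$thrombus_alines) &&
      spec$lumen_radius_samples + spec$thrombus_depth_samples > spec$n_depth)
    abort_validation("thrombus depth span outside frame bounds")
  if (min(spec$mu_thrombus, spec$mu_wall, spec$mu_lumen) < 0)
    abort_validation("attenuation coefficients must be >= 0")
  class(spec) <- "phantom_spec"
  spec
}

# mu and beta depth profiles for every A-line of a phantom.
.phantom_optics <- function(spec) {
  nr <- spec$n_alines; nc <- spec$n_depth
  mu <- matrix(0, nr, nc); beta <- matrix(0, nr, nc)
  lum <- (spec$catheter_offset + 1L):spec$lumen_radius_samples
  if (spec$lumen_radius_samples > spec$catheter_offset) {
    mu[, lum] <- spec$mu_lumen
    beta[, lum] <- spec$beta_lumen
  }
  wall_from <- rep(spec$lumen_radius_samples + 1L, nr)
  member <- matrix(FALSE, nr, nc)
  if (length(spec$thrombus_alines)) {
    jt <- (spec$lumen_radius_samples + 1L):
          (spec$lumen_radius_samples + spec$thrombus_depth_samples)
    mu[spec$thrombus_alines, jt] <- spec$mu_thrombus
    beta[spec$thrombus_alines, jt] <- spec$beta_thrombus
    member[spec$thrombus_alines, jt] <- TRUE
    wall_from[spec$thrombus_alines] <- max(jt) + 1L
  }
  for (i in seq_len(nr)) if (wall_from[i] <= nc) {
    mu[i, wall_from[i]:nc] <- spec$mu_wall
    beta[i, wall_from[i]:nc] <- spec$beta_wall
  }
  list(mu = mu, beta = beta, member = member)
}

#' Simulate one polar OCT frame and its ground-truth thrombus mask
#'
#' Forward single-scattering model per A-line:
#' `I(z) = intensity_scale * beta(z) * mu(z) * exp(-2 * integral_0^z mu du)`,
#' with the depth integral accumulated exclusively (so a homogeneous medium
#' reproduces the analytic decay exactly). With `speckle = TRUE` the signal is
#' multiplied by unit-mean exponential speckle and the noise floor by an
#' independent unit-mean exponential draw (detector noise fluctuates; a
#' noiseless floor would let the depth-resolved estimator see through the
#' shadow). With `speckle = FALSE`, `I = signal + noise_floor` deterministically.
#'
#' @param spec a [phantom_spec()].
#' @param frame_id,patient_id identifiers for the returned frame.
#' @return list with `frame` ([polar_frame()]) and `mask` ([region_mask()]).
#' @export
simulate_frame <- function(spec, frame_id = "frame1", patient_id = "patient1") {
  if (!inherits(spec, "phantom_spec")) abort_validation("spec must be a phantom_spec")
  opt <- .phantom_optics(spec)
  dz <- spec$axial_pitch_mm
  # exclusive cumulative attenuation: integral_0^{z_j} mu du = dz * sum_{k<j} mu_k
  cum <- t(apply(opt$mu, 1L, cumsum)) - opt$mu
  signal <- spec$intensity_scale * opt$beta * opt$mu * exp(-2 * dz * cum)
  if (spec$guidewire) {
    gw <- seq_len(min(8L, spec$n_alines))
    signal[gw, (spec$catheter_offset + 1L):spec$n_depth] <- 0
  }
  I <- with_seed(spec$seed, {
    if (spec$speckle) {
      s1 <- matrix(stats::rexp(length(signal)), nrow(signal))
      s2 <- matrix(stats::rexp(length(signal)), nrow(signal))
      signal * s1 + spec$noise_floor * s2
    } else signal + spec$noise_floor
  })
  frame <- polar_frame(I, dz, spec$catheter_offset,
                       frame_id = frame_id, patient_id = patient_id)
  list(frame = frame, mask = region_mask(opt$member, frame_id = frame_id))
}

#' Specify a synthetic two-class patient cohort
#'
#' Per-patient thrombus attenuation and backscatter are drawn from class-wise
#' normal distributions (truncated at physical lower bounds); each patient
#' contributes `frames_per_patient` frames with mild geometric jitter of the
#' thrombus arc and depth span, mimicking the three analysed cross-sections
#' per pullback. Setting both class parameter sets equal gives a null cohort.
#'
#' @param n_white,n_red class sizes (defaults mirror a 13 white / 17 red
#'   cohort).
#' @param frames_per_patient frames per patient (default 3).
#' @param class_params list with elements `white` and `red`, each
#'   `list(mu_mean, mu_sd, beta_mean, beta_sd)`.
#' @param confusion_prob per-reading probability that a synthetic observer
#'   misgrades the true TAS by one step (default 0.1).
#' @param phantom base [phantom_spec()] arguments shared by all frames
#'   (a named list overriding [phantom_spec()] defaults).
#' @param seed cohort RNG seed.
#' @return validated object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_white = 13L, n_red = 17L, frames_per_patient = 3L,
                        class_params = list(
                          white = list(mu_mean = 1.2, mu_sd = 0.15,
                                       beta_mean = 0.10, beta_sd = 0.012),
                          red = list(mu_mean = 4.5, mu_sd = 0.50,
                                     beta_mean = 0.05, beta_sd = 0.006)),
                        confusion_prob = 0.1, phantom = list(), seed = NULL) {
  spec <- list(n_white = as.integer(n_white), n_red = as.integer(n_red),
               n_patients = as.integer(n_white) + as.integer(n_red),
               frames_per_patient = as.integer(frames_per_patient),
               class_params = class_params, confusion_prob = confusion_prob,
               phantom = phantom, seed = seed)
  if (spec$n_white < 0L || spec$n_red < 0L || spec$n_patients < 1L)
    abort_validation("class sizes must be non-negative and sum to >= 1")
  stopifnot_scalar_number(confusion_prob, "confusion_prob", 0, 1)
  class(spec) <- "cohort_spec"
  spec
}

#' Simulate a two-class cohort of OCT pullbacks
#'
#' @param spec a [cohort_spec()].
#' @return object of class `oct_cohort`: `frames` and `masks` (lists of
#'   per-patient lists), and `truth` (data.frame with `patient_id`, `class`,
#'   `tas`, `mu_thrombus`, `beta_thrombus`).
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort_validation("spec must be a cohort_spec")
  with_seed(spec$seed, {
    classes <- c(rep("white", spec$n_white), rep("red", spec$n_red))
    n <- spec$n_patients
    ids <- sprintf("P%03d", seq_len(n))
    mu <- beta <- numeric(n)
    for (i in seq_len(n)) {
      p <- spec$class_params[[classes[i]]]
      mu[i] <- max(0.3, stats::rnorm(1, p$mu_mean, p$mu_sd))
      beta[i] <- max(0.01, stats::rnorm(1, p$beta_mean, p$beta_sd))
    }
    # True six-stage TAS: class fixes the half (white 1-3, red 4-6); the
    # within-class tercile of the drawn attenuation picks the step.
    tas <- integer(n)
    for (cl in c("white", "red")) {
      idx <- which(classes == cl)
      if (!length(idx)) next
      q <- (rank(mu[idx], ties.method = "first") - 0.5) / length(idx)
      tas[idx] <- (if (cl == "white") 1L else 4L) + pmin(2L, as.integer(q * 3))
    }
    frames <- masks <- vector("list", n)
    base <- spec$phantom
    na <- base$n_alines %||% 256L
    arc0 <- max(16L, round(na / 2))
    span0 <- base$thrombus_depth_samples %||% 160L
    for (i in seq_len(n)) {
      fr <- vector("list", spec$frames_per_patient)
      mk <- vector("list", spec$frames_per_patient)
      for (f in seq_len(spec$frames_per_patient)) {
        arc_len <- min(na, max(16L, round(arc0 * stats::runif(1, 0.85, 1.15))))
        arc_start <- sample.int(max(1L, na - arc_len), 1L)
        depth_span <- max(40L, round(span0 * stats::runif(1, 0.9, 1.1)))
        args <- utils::modifyList(list(
          class = classes[i], mu_thrombus = mu[i], beta_thrombus = beta[i],
          thrombus_alines = arc_start:(arc_start + arc_len - 1L),
          thrombus_depth_samples = depth_span,
          seed = sample.int(.Machine$integer.max, 1L)), base)
        ps <- do.call(phantom_spec, args)
        sim <- simulate_frame(ps, frame_id = sprintf("%s_f%d", ids[i], f),
                              patient_id = ids[i])
        fr[[f]] <- sim$frame
        mk[[f]] <- sim$mask
      }
      frames[[i]] <- fr
      masks[[i]] <- mk
    }
    structure(list(frames = stats::setNames(frames, ids),
                   masks = stats::setNames(masks, ids),
                   truth = data.frame(patient_id = ids, class = classes,
                                      tas = tas, mu_thrombus = mu,
                                      beta_thrombus = beta,
                                      stringsAsFactors = FALSE),
                   spec = spec),
              class = "oct_cohort")
  })
}

#' Simulate observer TAS readings from true scores
#'
#' Each reading equals the true TAS, perturbed by one step up or down (equal
#' probability) with probability `confusion_prob`, then clamped to 1..6.
#'
#' @param true_tas data.frame with `patient_id` and `tas`, or an integer
#'   vector (patients auto-named).
#' @param confusion_prob per-reading misgrading probability in `[0, 1]`.
#' @param n_observers,n_sessions table dimensions (defaults 2 and 2).
#' @param seed RNG seed.
#' @return an [observer_readings()] table with one row per
#'   (patient, observer, session).
#' @export
simulate_observers <- function(true_tas, confusion_prob = 0.1,
                               n_observers = 2L, n_sessions = 2L, seed = NULL) {
  stopifnot_scalar_number(confusion_prob, "confusion_prob", 0, 1)
  if (!is.data.frame(true_tas))
    true_tas <- data.frame(patient_id = sprintf("P%03d", seq_along(true_tas)),
                           tas = as.integer(true_tas))
  with_seed(seed, {
    grid <- expand.grid(patient_id = true_tas$patient_id,
                        observer_id = sprintf("obs%d", seq_len(n_observers)),
                        session = seq_len(n_sessions),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    true <- true_tas$tas[match(grid$patient_id, true_tas$patient_id)]
    flip <- stats::runif(nrow(grid)) < confusion_prob
    step <- ifelse(flip, sample(c(-1L, 1L), nrow(grid), replace = TRUE), 0L)
    grid$tas <- pmin(6L, pmax(1L, true + step))
    observer_readings(grid)
  })
}
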