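# TAS handling, binary red/white labels, cutoff classification, and ROC
# analysis with Youden-index cutoff selection.

#' Collapse a six-stage thrombus attenuation score to a binary label
#'
#' TAS 1 is purely white (platelet-rich, abluminal border visible) and 6 purely
#' red (erythrocyte-rich, shadowing); scores 1-3 map to `"white"`, 4-6 to
#' `"red"`.
#'
#' @param tas integer vector with values in 1..6.
#' @return character vector of `"white"` / `"red"`.
#' @export
tas_to_binary <- function(tas) {
  if (!all(tas %in% 1:6)) abort_validation("tas values must be integers in 1..6")
  ifelse(tas >= 4, "red", "white")
}

#' Default cutoff registry for the headline discriminating parameters
#'
#' Published reference cutoffs for red-vs-white discrimination: median
#' attenuation < 0.568 mm^-1, mean backscatter < 5.35, mean grayscale
#' intensity < 120.1, and attenuation-p95 / median-grayscale ratio
#' > 0.022 mm^-1 indicate red thrombus. These were derived on clinical OCT
#' data; they are defaults, not properties of the synthetic phantoms.
#'
#' @return named list of `list(cutoff, direction)` entries; `direction` is
#'   `"lower"` when values below the cutoff indicate red.
#' @export
default_cutoffs <- function() {
  list(
    median_attenuation = list(cutoff = 0.568, direction = "lower"),
    mean_backscatter = list(cutoff = 5.35, direction = "lower"),
    mean_grayscale = list(cutoff = 120.1, direction = "lower"),
    ratio_att95_over_medint = list(cutoff = 0.022, direction = "higher")
  )
}

#' Classify a parameter value as red or white by a cutoff
#'
#' Strict inequality: a value exactly at the cutoff is classified white
#' (boundary handling at printed cutoffs is a documented convention).
#'
#' @param value numeric vector of parameter values.
#' @param parameter_name name in [default_cutoffs()]; ignored when `cutoff`
#'   and `direction` are supplied explicitly.
#' @param cutoff,direction explicit cutoff and side (`"lower"`/`"higher"`
#'   = red below/above the cutoff).
#' @return character vector of `"red"` / `"white"` (`NA` for missing values).
#' @export
classify_by_cutoff <- function(value, parameter_name = NULL,
                               cutoff = NULL, direction = NULL) {
  if (is.null(cutoff) || is.null(direction)) {
    reg <- default_cutoffs()[[parameter_name %||% ""]]
    if (is.null(reg))
      abort_config("no default cutoff for parameter '", parameter_name,
                   "'; supply cutoff and direction explicitly")
    cutoff <- cutoff %||% reg$cutoff
    direction <- direction %||% reg$direction
  }
  stopifnot_scalar_number(cutoff, "cutoff")
  direction <- match.arg(direction, c("lower", "higher"))
  red <- if (direction == "lower") value < cutoff else value > cutoff
  ifelse(is.na(value), NA_character_, ifelse(red, "red", "white"))
}

# Mann-Whitney AUC with ties counted 0.5, no orientation applied:
# P(value_red > value_white) + 0.5 * P(equal).
#' Mann-Whitney AUC (higher values = positive class, ties 0.5)
#' @param values numeric vector.
#' @param labels vector of class labels.
#' @param positive the positive-class label (default `"red"`).
#' @return AUC, a number between 0 and 1.
#' @export
auc_mann_whitney <- function(values, labels, positive = "red") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) abort_validation("both classes must be present")
  r <- rank(values, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong variance of the AUC from placement values.
.delong_ci <- function(values, labels, positive, auc, level = 0.95) {
  x <- values[labels == positive]
  y <- values[labels != positive]
  n <- length(x); m <- length(y)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  s10 <- if (n > 1L) stats::var(v10) else 0
  s01 <- if (m > 1L) stats::var(v01) else 0
  se <- sqrt(s10 / n + s01 / m)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(low = max(0, auc - z * se), high = min(1, auc + z * se))
}

#' ROC analysis with Youden-index cutoff selection
#'
#' Orientation is chosen automatically so that AUC >= 0.5: if higher values
#' associate with the positive class the direction is `"higher"`, otherwise
#' values are negated internally and the direction is `"lower"` (values below
#' the cutoff indicate red). The AUC is the Mann-Whitney statistic with ties
#' counted 0.5. The reported cutoff is the midpoint between the adjacent
#' distinct observed values that maximises Youden's J = sensitivity +
#' specificity - 1; J ties are broken toward higher specificity, remaining
#' ties toward the cutoff excluding fewer positives (deterministic). The 95%
#' CI of the AUC is computed by the DeLong method.
#'
#' @param values numeric parameter values (finite).
#' @param labels class labels.
#' @param positive positive-class label (default `"red"`).
#' @return object of class `roc_result`: `auc`, `auc_ci_low`, `auc_ci_high`,
#'   `cutoff`, `sensitivity`, `specificity`, `j`, `direction`, `n_red`,
#'   `n_white`, and `table` (threshold, sens, spec, J for every candidate).
#' @export
roc_curve <- function(values, labels, positive = "red") {
  if (any(!is.finite(values))) abort_validation("values must be finite")
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) abort_validation("both classes must be present")

  auc_raw <- auc_mann_whitney(values, labels, positive)
  direction <- if (auc_raw >= 0.5) "higher" else "lower"
  v <- if (direction == "higher") values else -values
  auc <- max(auc_raw, 1 - auc_raw)

  sv <- sort(unique(v))
  if (length(sv) == 1L) {
    res <- list(auc = 0.5, auc_ci_low = 0.5, auc_ci_high = 0.5,
                cutoff = NA_real_, sensitivity = NA_real_,
                specificity = NA_real_, j = NA_real_, direction = direction,
                n_red = n1, n_white = n0, table = NULL)
    class(res) <- "roc_result"
    return(res)
  }
  cand <- (sv[-1L] + sv[-length(sv)]) / 2      # midpoints of adjacent values
  cand_full <- c(-Inf, cand, Inf)              # endpoints for the full curve
  tp_f <- vapply(cand_full, function(cut) sum(v[pos] > cut), numeric(1L))
  tn_f <- vapply(cand_full, function(cut) sum(v[!pos] <= cut), numeric(1L))
  sens_f <- tp_f / n1
  spec_f <- tn_f / n0
  fin <- is.finite(cand_full)
  sens <- sens_f[fin]; spec <- spec_f[fin]
  j <- sens + spec - 1
  # J compared in exact integer form (J * n1 * n0 up to a constant) so that
  # mathematically tied cutoffs tie exactly and fall through to specificity
  j_int <- tp_f[fin] * n0 + tn_f[fin] * n1
  best <- order(-j_int, -tn_f[fin], -cand)[1L] # higher spec, then keep more
                                               # positives above the cut
  ci <- .delong_ci(v, labels, positive, auc)
  cutoff <- if (direction == "higher") cand[best] else -cand[best]
  jf <- sens_f + spec_f - 1
  tab <- data.frame(threshold = if (direction == "higher") cand_full else rev(-cand_full),
                    sensitivity = if (direction == "higher") sens_f else rev(sens_f),
                    specificity = if (direction == "higher") spec_f else rev(spec_f),
                    j = if (direction == "higher") jf else rev(jf))
  res <- list(auc = auc, auc_ci_low = unname(ci["low"]),
              auc_ci_high = unname(ci["high"]), cutoff = cutoff,
              sensitivity = sens[best], specificity = spec[best], j = j[best],
              direction = direction, n_red = n1, n_white = n0, table = tab)
  class(res) <- "roc_result"
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result AUC %.3f (95%% CI %.2f-%.2f), cutoff %s (%s = red), sens %.2f spec %.2f, n = %d red / %d white>\n",
              x$auc, x$auc_ci_low, x$auc_ci_high,
              format(x$cutoff, digits = 4), x$direction,
              x$sensitivity, x$specificity, x$n_red, x$n_white))
  invisible(x)
}
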