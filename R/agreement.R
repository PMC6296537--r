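# Observer-agreement statistics: Bland-Altman limits of agreement,
# absolute-agreement intraclass correlation, Cohen's kappa, and Spearman
# rank correlation.

#' Bland-Altman analysis of two paired measurement series
#'
#' Differences are `d = x - y`. The limits of agreement are
#' `mean(d) +/- 1.96 * sd(d)` with the sample (n-1) standard deviation. The
#' mean relative difference is the mean difference expressed as a percentage
#' of the grand mean of all pooled paired values (the mean of observers 1
#' and 2).
#'
#' @param x,y paired numeric series of equal length >= 2, no missing values.
#' @return object of class `bland_altman`: `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`, `mean_relative_diff_pct`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) abort_validation("x and y must be paired (equal length)")
  if (length(x) < 2L) abort_validation("at least 2 pairs are required")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort_validation("missing pairs are not allowed")
  d <- x - y
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  grand <- mean(c(x, y))
  structure(list(mean_diff = mean_diff, sd_diff = sd_diff,
                 loa_low = mean_diff - 1.96 * sd_diff,
                 loa_high = mean_diff + 1.96 * sd_diff,
                 mean_relative_diff_pct = if (grand == 0) NA_real_ else 100 * mean_diff / grand,
                 n = length(x)),
            class = "bland_altman")
}

#' Absolute-agreement intraclass correlation, ICC(A,1)
#'
#' Two-way model, absolute agreement, single measures (each cell is one
#' reading): from the two-way ANOVA decomposition with n subjects (rows) and
#' k raters (columns),
#' `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' The 95% CI uses the F-based interval with Satterthwaite degrees of freedom
#' (McGraw & Wong).
#'
#' @param ratings numeric matrix, subjects x raters, complete, >= 2 rows and
#'   >= 2 columns.
#' @param level confidence level (default 0.95).
#' @return object of class `icc_result`: `icc`, `ci_low`, `ci_high`, `model`.
#'   `icc` is `NA` when the total variance is zero.
#' @export
icc_absolute_agreement <- function(ratings, level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) abort_validation("need >= 2 subjects and >= 2 raters")
  if (any(!is.finite(ratings))) abort_validation("ratings must be complete")
  grand <- mean(ratings)
  if (all(ratings == grand))
    return(structure(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                          model = "two-way mixed, absolute agreement, single measures"),
                     class = "icc_result"))
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_total <- sum((ratings - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # F-based CI with Satterthwaite df for the rater/error composite.
  alpha <- 1 - level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  if (!is.finite(ci_low)) ci_low <- NA_real_
  if (!is.finite(ci_high)) ci_high <- NA_real_
  structure(list(icc = icc, ci_low = ci_low, ci_high = ci_high,
                 model = "two-way mixed, absolute agreement, single measures"),
            class = "icc_result")
}

#' Cohen's kappa for two categorical series
#'
#' `kappa = (po - pe) / (1 - pe)` with observed agreement `po` and chance
#' agreement `pe` from the marginal products.
#'
#' @param a,b categorical vectors of equal length over a shared category set.
#' @return object of class `kappa_result`: `kappa` (`NA` when `pe == 1`),
#'   `observed_agreement`, `expected_agreement`, `n`.
#' @export
cohen_kappa <- function(a, b) {
  if (length(a) != length(b)) abort_validation("a and b must have equal length")
  lev <- sort(unique(c(as.character(a), as.character(b))))
  a <- factor(as.character(a), levels = lev)
  b <- factor(as.character(b), levels = lev)
  n <- length(a)
  tab <- table(a, b) / n
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  kappa <- if (abs(1 - pe) < .Machine$double.eps^0.5) NA_real_ else (po - pe) / (1 - pe)
  structure(list(kappa = kappa, observed_agreement = po,
                 expected_agreement = pe, n = n),
            class = "kappa_result")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' `rho` is the Pearson correlation of mid-ranks;
#' `p = 2 * P(T_{n-2} > |rho| * sqrt((n-2)/(1-rho^2)))`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho` and `p` (`NA` when either rank variance is zero).
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) abort_validation("x and y must have equal length")
  n <- length(x)
  if (n < 3L) abort_validation("at least 3 pairs are required")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(t), df = n - 2))
}
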