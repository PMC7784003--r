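# Evaluation statistics for rater-agreement and classification studies:
# ICC(2,1) with its F-based confidence interval and agreement-power labels,
# ROC analysis with Youden-optimal confusion metrics, and a guarded Pearson
# correlation.

ICC_POWER_LEVELS <- c("negligible", "weak", "moderate", "strong", "very_strong")

#' Intraclass correlation ICC(2,1): two-way random, single measures,
#' absolute agreement
#'
#' Computed from the two-way ANOVA mean squares (subjects x raters):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with `n`
#' subjects and `k` raters, where MSR, MSC and MSE are the subject, rater and
#' residual mean squares. The 95% confidence interval is the standard F-based
#' interval for the absolute-agreement single-measure coefficient. Agreement
#' strength is labelled negligible (< 0.2), weak (0.2-0.4), moderate
#' (0.4-0.7), strong (0.7-0.9) or very strong (at or above 0.9); intervals
#' are left-closed.
#'
#' @param m Numeric matrix, subjects in rows (>= 2) and raters in columns
#'   (>= 2), no missing cells (e.g. per-subject FoG episode counts from two
#'   raters, or rater vs algorithm).
#' @param conf_level Confidence level, default 0.95.
#' @return list of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `power_label`, `n_subjects`, `n_raters`, and the mean squares.
#' @export
icc_2_1 <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("rating matrix must have no missing cells", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters", call. = FALSE)
  gm <- mean(m)
  if (sum((m - gm)^2) == 0) {
    stop("zero total variance: the intraclass correlation is undefined", call. = FALSE)
  }
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - conf_level
  if (sse <= 1e-12 * sst && ssc <= 1e-12 * sst) {
    # perfect agreement: the F-based interval degenerates
    ci <- c(icc, icc)
  } else {
    # McGraw & Wong (1996) interval for ICC(A,1)
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lower, upper)
  }
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2],
                 power_label = icc_power_label(icc),
                 n_subjects = n, n_raters = k,
                 msr = msr, msc = msc, mse = mse),
            class = "icc_result")
}

#' Label the agreement strength of an ICC value
#'
#' @param icc Numeric vector of ICC values.
#' @return Factor with levels `negligible`, `weak`, `moderate`, `strong`,
#'   `very_strong` (cut points 0.2, 0.4, 0.7, 0.9; left-closed).
#' @export
icc_power_label <- function(icc) {
  cut(icc, breaks = c(-Inf, 0.2, 0.4, 0.7, 0.9, Inf), right = FALSE,
      labels = ICC_POWER_LEVELS)
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.4f, %s agreement (95%% CI %.4f to %.4f; n = %d subjects, k = %d raters)\n",
              x$icc, gsub("_", " ", x$power_label), x$ci_low, x$ci_high,
              x$n_subjects, x$n_raters))
  invisible(x)
}

#' ROC analysis of a freezer/non-freezer score
#'
#' Empirical ROC curve and trapezoidal AUC, with the operating point chosen
#' by Youden's J (ties resolved towards the lower threshold) and the
#' confusion metrics at that point. Classification convention: a subject
#' scoring strictly above the threshold is called a freezer.
#'
#' @param scores Numeric per-subject scores (e.g. mean fraction of walking
#'   time spent frozen).
#' @param labels Logical (or 2-level coercible) vector: `TRUE` = freezer.
#' @return list of class `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`,
#'   `best_threshold`, `accuracy`, `sensitivity`, `specificity`,
#'   `false_positive_rate`, `false_negative_rate`.
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length", call. = FALSE)
  if (length(unique(labels)) < 2) {
    stop("both classes (freezer and non-freezer) must be present", call. = FALSE)
  }
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  tpr <- r$sensitivities
  fpr <- 1 - r$specificities
  j <- r$sensitivities + r$specificities - 1
  best_idx <- which(j == max(j))
  best <- min(r$thresholds[best_idx])
  if (!is.finite(best)) best <- min(scores) - 1  # degenerate all-positive point
  pos <- scores[labels]; neg <- scores[!labels]
  sens <- mean(pos > best)
  spec <- mean(neg <= best)
  acc <- (sum(pos > best) + sum(neg <= best)) / length(scores)
  structure(list(thresholds = r$thresholds, tpr = tpr, fpr = fpr,
                 auc = as.numeric(pROC::auc(r)),
                 best_threshold = best,
                 accuracy = acc, sensitivity = sens, specificity = spec,
                 false_positive_rate = 1 - spec, false_negative_rate = 1 - sens),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f | best threshold %.4g (Youden)\n", x$auc, x$best_threshold))
  cat(sprintf("  accuracy %.3f, sensitivity %.3f, specificity %.3f, FPR %.3f, FNR %.3f\n",
              x$accuracy, x$sensitivity, x$specificity,
              x$false_positive_rate, x$false_negative_rate))
  invisible(x)
}

#' Pearson correlation with input validation
#'
#' @param x,y Numeric vectors of equal length (>= 3), both non-constant.
#' @return Product-moment correlation.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}
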