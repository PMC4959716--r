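#' Wilson score confidence interval for a binomial proportion
#'
#' Inverts the score test at fixed z (default 1.96, the conventional 95%
#' value): centre `(p + z^2/2n) / (1 + z^2/n)`, half-width
#' `z sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n)`. Bounds are always in [0, 1].
#'
#' @param successes number of successes (0..trials).
#' @param trials number of trials (>= 1).
#' @param z normal quantile; the fixed value 1.96 reproduces conventionally
#'   reported 95% intervals.
#' @return named numeric vector `c(lower, upper)` on the proportion scale.
#' @export
wilson_ci <- function(successes, trials, z = 1.96) {
  if (trials < 1) stop("trials must be >= 1")
  if (successes < 0 || successes > trials)
    stop("successes must be between 0 and trials")
  p <- successes / trials
  denom <- 1 + z^2 / trials
  centre <- (p + z^2 / (2 * trials)) / denom
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
  c(lower = max(centre - half, 0), upper = min(centre + half, 1))
}

#' Confusion counts for patient-level detection
#'
#' @param tp,fn,tn,fp non-negative integer patient counts.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fn, tn, fp) {
  v <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  structure(as.list(v), class = "confusion_counts")
}

#' Tally patient scores into confusion counts
#' @param categories character vector of "TP"/"TN"/"FP"/"FN" (or a list of
#'   `patient_score` objects).
#' @export
tally_patients <- function(categories) {
  if (is.list(categories) && length(categories) &&
      inherits(categories[[1]], "patient_score"))
    categories <- vapply(categories, `[[`, character(1), "category")
  confusion_counts(sum(categories == "TP"), sum(categories == "FN"),
                   sum(categories == "TN"), sum(categories == "FP"))
}

#' Sensitivity, specificity and accuracy with Wilson intervals
#'
#' Point estimates sens = TP/(TP+FN), spec = TN/(TN+FP),
#' accuracy = (TP+TN)/total, each with its 95% Wilson interval. Values are
#' kept unrounded internally; the print method reports percentages rounded
#' half-up to two decimals.
#'
#' @param counts a [confusion_counts()].
#' @param z normal quantile for the Wilson intervals.
#' @return object of class `diagnostic_summary`: list of `estimate` and `ci`
#'   (proportions), plus the counts.
#' @export
summarize_diagnostics <- function(counts, z = 1.96) {
  stopifnot(inherits(counts, "confusion_counts"))
  pos <- counts$tp + counts$fn; neg <- counts$tn + counts$fp
  if (pos < 1 || neg < 1) stop("both classes must be non-empty")
  n <- pos + neg
  est <- c(sensitivity = counts$tp / pos, specificity = counts$tn / neg,
           accuracy = (counts$tp + counts$tn) / n)
  ci <- rbind(sensitivity = wilson_ci(counts$tp, pos, z),
              specificity = wilson_ci(counts$tn, neg, z),
              accuracy = wilson_ci(counts$tp + counts$tn, n, z))
  structure(list(estimate = est, ci = ci, counts = counts, z = z),
            class = "diagnostic_summary")
}

#' Youden index with combined Wilson-bound interval
#'
#' J = sensitivity + specificity - 1 from the unrounded proportions. The
#' reported interval combines the unrounded Wilson bounds of the two
#' proportions: lower = sens_lower + spec_lower - 1, upper = sens_upper +
#' spec_upper - 1. This bound-summing construction is not a standard interval
#' for J; it is the package's reproduction policy for published tables that
#' pair Youden indices with per-proportion Wilson intervals (a bootstrap over
#' patient scores is the statistically conventional alternative). Bounds are
#' combined before any rounding; tables assembled from already-rounded
#' percentages can differ in the last printed digit.
#'
#' @param counts a [confusion_counts()].
#' @param z normal quantile.
#' @return list with `j` and `ci` (proportions, can be negative).
#' @export
youden_with_ci <- function(counts, z = 1.96) {
  s <- summarize_diagnostics(counts, z)
  j <- s$estimate[["sensitivity"]] + s$estimate[["specificity"]] - 1
  ci <- c(lower = s$ci["sensitivity", "lower"] + s$ci["specificity", "lower"] - 1,
          upper = s$ci["sensitivity", "upper"] + s$ci["specificity", "upper"] - 1)
  list(j = j, ci = ci)
}

#' ROC points and trapezoidal AUC from operating points
#'
#' Maps (sensitivity, specificity) operating points to ROC space
#' (1 - specificity, sensitivity), appends the trivial endpoints (0,0) and
#' (1,1), sorts by false-positive rate and integrates by the trapezoid rule.
#'
#' @param sens,spec numeric vectors of operating-point proportions in [0, 1].
#' @return list with `roc` (data.frame fpr, tpr, sorted) and `auc`.
#' @export
roc_auc <- function(sens, spec) {
  if (length(sens) != length(spec) || length(sens) < 1)
    stop("need at least one (sens, spec) operating point")
  if (any(sens < 0 | sens > 1 | spec < 0 | spec > 1))
    stop("operating points must lie in [0, 1]")
  fpr <- c(0, 1 - spec, 1); tpr <- c(0, sens, 1)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Diagnostic table over a sweep of mean-MAI thresholds
#'
#' Re-scores every patient at each mean-MAI threshold (the max-MAI gate stays
#' fixed) and assembles the per-threshold confusion counts, proportions with
#' Wilson intervals, Youden indices and the ROC/AUC over the sweep.
#'
#' @param patient_categories matrix or data.frame of patient categories
#'   (patients x thresholds, entries "TP"/"TN"/"FP"/"FN"), or a list of
#'   per-threshold `confusion_counts`.
#' @param thresholds the mean-MAI thresholds of the sweep.
#' @param z normal quantile.
#' @return object of class `threshold_sweep`: list with `thresholds`,
#'   `summaries`, `youden`, `roc`, `auc`, `optimum` (threshold maximizing J).
#' @export
threshold_sweep_table <- function(patient_categories, thresholds, z = 1.96) {
  counts <- if (is.list(patient_categories) && length(patient_categories) &&
                inherits(patient_categories[[1]], "confusion_counts"))
    patient_categories
  else {
    m <- as.matrix(patient_categories)
    lapply(seq_len(ncol(m)), function(i) tally_patients(m[, i]))
  }
  if (length(counts) != length(thresholds))
    stop("one set of counts per threshold required")
  summaries <- lapply(counts, summarize_diagnostics, z = z)
  youden <- lapply(counts, youden_with_ci, z = z)
  sens <- vapply(summaries, function(s) s$estimate[["sensitivity"]], numeric(1))
  spec <- vapply(summaries, function(s) s$estimate[["specificity"]], numeric(1))
  ra <- roc_auc(sens, spec)
  j <- vapply(youden, `[[`, numeric(1), "j")
  structure(list(thresholds = thresholds, counts = counts,
                 summaries = summaries, youden = youden,
                 roc = ra$roc, auc = ra$auc,
                 optimum = thresholds[which.max(j)]),
            class = "threshold_sweep")
}

pct <- function(x) round_half_up(100 * x, 2)

#' @export
print.diagnostic_summary <- function(x, ...) {
  for (m in rownames(x$ci))
    cat(sprintf("%-12s %6.2f%% (%.2f-%.2f)\n", m, pct(x$estimate[[m]]),
                pct(x$ci[m, "lower"]), pct(x$ci[m, "upper"])))
  invisible(x)
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat("Mean MAI threshold sweep (max MAI gate fixed)\n")
  for (i in seq_along(x$thresholds)) {
    s <- x$summaries[[i]]; y <- x$youden[[i]]
    cat(sprintf("  %.2f%s: sens %.2f%% (%.2f-%.2f), spec %.2f%% (%.2f-%.2f), acc %.2f%% (%.2f-%.2f), Youden %.2f%% (%.2f-%.2f)\n",
                x$thresholds[i],
                if (x$thresholds[i] == x$optimum) " (optimum)" else "",
                pct(s$estimate[["sensitivity"]]),
                pct(s$ci["sensitivity", "lower"]), pct(s$ci["sensitivity", "upper"]),
                pct(s$estimate[["specificity"]]),
                pct(s$ci["specificity", "lower"]), pct(s$ci["specificity", "upper"]),
                pct(s$estimate[["accuracy"]]),
                pct(s$ci["accuracy", "lower"]), pct(s$ci["accuracy", "upper"]),
                pct(y$j), pct(y$ci[["lower"]]), pct(y$ci[["upper"]])))
  }
  cat(sprintf("  AUC (trapezoid over sweep): %.2f\n", x$auc))
  invisible(x)
}

#' Plot the ROC curve of a threshold sweep
#' @param x a `threshold_sweep`.
#' @param ... passed to plot().
#' @export
plot.threshold_sweep <- function(x, ...) {
  plot(x$roc$fpr, x$roc$tpr, type = "b", pch = 19, xlim = c(0, 1),
       ylim = c(0, 1), xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC over mean-MAI thresholds (AUC %.2f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
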