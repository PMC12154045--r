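# Diagnostic-test evaluation statistics: 2x2 confusion tables, rates with
# normal-approximation confidence intervals, association statistics,
# calibration, ROC/AUC and Youden-optimal operating points.

#' Build or construct a 2x2 confusion table
#'
#' `confusion()` tabulates predicted against true labels under a declared
#' positive label set; `confusion_table()` wraps already-known counts.
#'
#' @param predicted,truth equal-length label vectors (any type with
#'   well-defined `%in%`; stage factors work).
#' @param positive the label(s) counted as positive, e.g. `c("II", "III")`
#'   for the stage II/III screen or `c("I", "II", "III")` for periodontitis
#'   detection.
#' @return Object of class `confusion_table` with integer fields
#'   `tp`, `fp`, `fn`, `tn` and the `positive_label` tag.
#' @examples
#' confusion_table(tp = 82, fp = 11, fn = 22, tn = 34)
#' @export
confusion <- function(predicted, truth, positive) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length")
  }
  if (length(predicted) == 0) stop("empty input")
  pred_pos <- predicted %in% positive
  true_pos <- truth %in% positive
  confusion_table(tp = sum(pred_pos & true_pos),
                  fp = sum(pred_pos & !true_pos),
                  fn = sum(!pred_pos & true_pos),
                  tn = sum(!pred_pos & !true_pos),
                  positive_label = paste(positive, collapse = "|"))
}

#' @rdname confusion
#' @param tp,fp,fn,tn non-negative integer counts.
#' @param positive_label semantic tag of the positive class.
#' @export
confusion_table <- function(tp, fp, fn, tn, positive_label = "positive") {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (sum(counts) == 0) stop("confusion table must have n > 0")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 positive_label = positive_label),
            class = "confusion_table")
}

#' Basic diagnostic rates of a confusion table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
#' `(tp+tn)/n`, F1 `2tp/(2tp+fp+fn)` and Youden's index
#' `sensitivity + specificity - 1`. A rate with a zero denominator is
#' reported as `NA` (absent), never as 0, and Youden is then `NA` too.
#'
#' @param t a `confusion_table`.
#' @return Named list with `sensitivity`, `specificity`, `accuracy`, `f1`,
#'   `youden` and `n`.
#' @examples
#' basic_rates(confusion_table(82, 11, 22, 34))$youden # 0.5440
#' @export
basic_rates <- function(t) {
  stopifnot(inherits(t, "confusion_table"))
  n <- t$tp + t$fp + t$fn + t$tn
  se <- if (t$tp + t$fn > 0) t$tp / (t$tp + t$fn) else NA_real_
  sp <- if (t$tn + t$fp > 0) t$tn / (t$tn + t$fp) else NA_real_
  f1 <- if (2 * t$tp + t$fp + t$fn > 0) {
    2 * t$tp / (2 * t$tp + t$fp + t$fn)
  } else NA_real_
  list(sensitivity = se, specificity = sp,
       accuracy = (t$tp + t$tn) / n, f1 = f1,
       youden = se + sp - 1, n = n)
}

#' Phi coefficient of a 2x2 table
#'
#' Pearson correlation of the two dichotomies:
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, in \[-1, 1\].
#' Satisfies `phi^2 * n = ` the Pearson chi-square statistic.
#'
#' @inheritParams basic_rates
#' @return Numeric phi, or `NA` with a warning if any margin is zero.
#' @export
phi_coefficient <- function(t) {
  stopifnot(inherits(t, "confusion_table"))
  m <- c(t$tp + t$fp, t$tp + t$fn, t$tn + t$fp, t$tn + t$fn)
  if (any(m == 0)) {
    warning("phi undefined: a table margin is zero")
    return(NA_real_)
  }
  (t$tp * t$tn - t$fp * t$fn) / sqrt(prod(m))
}

#' Pearson chi-square test of independence for a 2x2 table
#'
#' The uncorrected statistic
#' `n (tp*tn - fp*fn)^2 / ((tp+fp)(fn+tn)(tp+fn)(fp+tn))` with 1 df, equal to
#' `n * phi^2`. No continuity correction is applied, preserving that
#' identity.
#'
#' @inheritParams basic_rates
#' @return List with `statistic`, `df` (1) and `p`.
#' @export
chi_square_2x2 <- function(t) {
  stopifnot(inherits(t, "confusion_table"))
  m <- c(t$tp + t$fp, t$tp + t$fn, t$tn + t$fp, t$tn + t$fn)
  if (any(m == 0)) stop("chi-square undefined: a table margin is zero")
  n <- t$tp + t$fp + t$fn + t$tn
  stat <- n * (t$tp * t$tn - t$fp * t$fn)^2 / prod(m)
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Normal-approximation (Wald) confidence interval for a proportion
#'
#' `p +/- z * sqrt(p(1-p)/n)`. At the default 95% level `z` is fixed at
#' 1.96, the conventional two-decimal value. The interval is not clipped to
#' \[0,1\]; a bound outside the unit interval is reported as computed.
#'
#' @param successes,n counts with `0 <= successes <= n`, `n > 0`.
#' @param level confidence level; 0.95 uses `z = 1.96` exactly, other
#'   levels use the corresponding normal quantile.
#' @return Named numeric `c(lower, upper)`.
#' @examples
#' wald_ci(113, 118) # 0.921 - 0.994
#' @export
wald_ci <- function(successes, n, level = 0.95) {
  stopifnot(n > 0, successes >= 0, successes <= n)
  z <- if (isTRUE(all.equal(level, 0.95))) 1.96 else {
    stats::qnorm(1 - (1 - level) / 2)
  }
  p <- successes / n
  half <- z * sqrt(p * (1 - p) / n)
  c(lower = p - half, upper = p + half)
}

#' Hosmer-Lemeshow goodness-of-fit (calibration) test
#'
#' Groups observations into `groups` equal-count bins of increasing
#' predicted probability (ties on the score are kept in the same bin) and
#' compares observed to expected event counts:
#' `sum over bins of (O - E)^2 / (E (1 - E/m))` with `df = groups - 2`.
#'
#' @param scores predicted probabilities in \[0,1\].
#' @param labels binary outcomes (0/1 or logical).
#' @param groups number of bins (>= 2); 10 gives the usual deciles of risk.
#' @return List with `statistic`, `df` and `p`.
#' @export
hosmer_lemeshow <- function(scores, labels, groups = 10) {
  stopifnot(length(scores) == length(labels), groups >= 2,
            all(scores >= 0 & scores <= 1))
  y <- as.numeric(labels)
  stopifnot(all(y %in% c(0, 1)))
  # Equal-count grouping on score rank; identical scores share a bin.
  qs <- stats::quantile(scores, probs = seq_len(groups - 1) / groups,
                        type = 1)
  bin <- findInterval(scores, unique(qs), left.open = TRUE) + 1L
  obs <- tapply(y, bin, sum)
  exp_ <- tapply(scores, bin, sum)
  m <- tapply(y, bin, length)
  if (any(exp_ <= 0) || any(exp_ >= m)) {
    bad <- which(exp_ <= 0 | exp_ >= m)[1]
    stop("degenerate grouping: expected count 0 or m in group ", bad)
  }
  stat <- sum((obs - exp_)^2 / (exp_ * (1 - exp_ / m)))
  df <- length(obs) - 2L
  p <- if (df >= 1) stats::pchisq(stat, df = df, lower.tail = FALSE)
       else NA_real_
  list(statistic = stat, df = df, p = p)
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold over the unique score values (rule:
#' positive when `score >= threshold`), yielding a stepwise curve from
#' (0,0) (threshold above every score) to (1,1). The AUC is the trapezoid
#' area, which with this tie handling equals the normalized Mann-Whitney U
#' statistic (ties counted 1/2). Scores are oriented "higher = more
#' diseased"; an AUC below 0.5 triggers a warning (inputs are not
#' auto-flipped).
#'
#' @inheritParams hosmer_lemeshow
#' @return List with `curve` (data.frame `threshold`, `tpr`, `fpr`,
#'   thresholds descending, first row `Inf`) and `auc`.
#' @examples
#' roc_and_auc(c(.9, .8, .3, .2), c(1, 1, 0, 0))$auc # 1
#' @export
roc_and_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  y <- as.numeric(labels)
  stopifnot(all(y %in% c(0, 1)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / n0, 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  if (auc < 0.5) {
    warning(sprintf("AUC = %.3f < 0.5: scores may be oriented backwards",
                    auc))
  }
  list(curve = data.frame(threshold = thr, tpr = tpr, fpr = fpr), auc = auc)
}

#' Youden-optimal operating point of a ROC curve
#'
#' Returns the threshold maximizing `J = tpr - fpr` (equivalently
#' sensitivity + specificity - 1). Ties are broken toward the higher
#' threshold, i.e. the more specific operating point.
#'
#' @param roc the `curve` data.frame of [roc_and_auc()] (or the list itself).
#' @return List with `threshold` and `youden`.
#' @export
youden_optimal_cutoff <- function(roc) {
  curve <- if (is.data.frame(roc)) roc else roc$curve
  stopifnot(all(c("threshold", "tpr", "fpr") %in% names(curve)))
  j <- curve$tpr - curve$fpr
  finite <- is.finite(curve$threshold)
  if (!any(finite)) stop("degenerate ROC curve")
  jf <- j[finite]; thrf <- curve$threshold[finite]
  best <- which(jf == max(jf))
  pick <- best[which.max(thrf[best])]
  list(threshold = thrf[pick], youden = jf[pick])
}

#' Full metric report for a confusion table
#'
#' Bundles the basic rates, phi, the Pearson chi-square test and Wald
#' confidence intervals for sensitivity, specificity and accuracy; when
#' scores and binary labels are supplied the ROC/AUC is added.
#'
#' @inheritParams basic_rates
#' @param level confidence level for the Wald intervals.
#' @param scores,labels optional score/outcome vectors for the ROC block.
#' @return List of class `metric_report`.
#' @export
metric_report <- function(t, level = 0.95, scores = NULL, labels = NULL) {
  r <- basic_rates(t)
  rep <- list(
    sensitivity = r$sensitivity, specificity = r$specificity,
    accuracy = r$accuracy, f1 = r$f1, youden = r$youden,
    phi = phi_coefficient(t),
    chi2 = tryCatch(chi_square_2x2(t), error = function(e) {
      list(statistic = NA_real_, df = 1L, p = NA_real_)
    }),
    ci_sensitivity = wald_ci(t$tp, t$tp + t$fn, level),
    ci_specificity = wald_ci(t$tn, t$tn + t$fp, level),
    ci_accuracy = wald_ci(t$tp + t$tn, r$n, level),
    n = r$n, positive_label = t$positive_label
  )
  if (!is.null(scores) && !is.null(labels)) {
    rep$auc <- roc_and_auc(scores, labels)$auc
  }
  class(rep) <- "metric_report"
  rep
}

#' Staged-prediction performance report
#'
#' Evaluates cascade output against true stage labels the way a staged
#' screening model is reported: first periodontitis detection (positive =
#' any stage I-III), then, among true periodontitis cases that the model
#' also detected as periodontitis, the proportion assigned the correct
#' stage, overall and per true stage, each with Wald confidence intervals.
#'
#' @param results a `cascade_result` from [classify_cohort()], or any
#'   data.frame with `predicted_stage`.
#' @param truth true stage labels (coercible by [stage_factor()]), in the
#'   same order; defaults to `results$true_stage` if present.
#' @param level confidence level.
#' @return List of class `staging_report` with elements `detection`
#'   (a [metric_report()]), `overall` (`correct`, `n`, `accuracy`, `ci`) and
#'   `per_stage` (data.frame with one row per stage I-III). When no
#'   detected periodontitis cases exist the staging elements are `NULL`.
#' @export
staging_report <- function(results, truth, level = 0.95) {
  pred <- stage_factor(results$predicted_stage)
  truth <- stage_factor(truth)
  if (length(pred) != length(truth)) stop("results/truth length mismatch")
  if (anyNA(truth)) stop("truth labels required for every record")
  perio <- c("I", "II", "III")
  det <- metric_report(confusion(as.character(pred), as.character(truth),
                                 positive = perio), level = level)

  detected <- pred %in% perio & truth %in% perio
  out <- list(detection = det, overall = NULL, per_stage = NULL)
  if (any(detected)) {
    correct <- pred[detected] == truth[detected]
    ci <- wald_ci(sum(correct), sum(detected), level)
    out$overall <- list(correct = sum(correct), n = sum(detected),
                        accuracy = mean(correct), ci = ci)
    per <- lapply(perio, function(s) {
      idx <- detected & truth == s
      k <- sum(pred[idx] == s); m <- sum(idx)
      if (m == 0) {
        data.frame(stage = s, correct = 0L, n = 0L, accuracy = NA_real_,
                   lower = NA_real_, upper = NA_real_)
      } else {
        ci <- wald_ci(k, m, level)
        data.frame(stage = s, correct = k, n = m, accuracy = k / m,
                   lower = ci[["lower"]], upper = ci[["upper"]])
      }
    })
    out$per_stage <- do.call(rbind, per)
  }
  class(out) <- "staging_report"
  out
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> positive = %s\n", x$positive_label))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("pos", "neg"),
                              predicted = c("pos", "neg")))
  print(t(m))
  invisible(x)
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  cat("<metric_report> positive =", x$positive_label, " n =", x$n, "\n")
  cat(sprintf("  sensitivity %.3f (%.3f-%.3f)  specificity %.3f (%.3f-%.3f)\n",
              x$sensitivity, x$ci_sensitivity[1], x$ci_sensitivity[2],
              x$specificity, x$ci_specificity[1], x$ci_specificity[2]))
  cat(sprintf("  accuracy %.3f (%.3f-%.3f)  F1 %.3f  phi %.3f  J %.4f\n",
              x$accuracy, x$ci_accuracy[1], x$ci_accuracy[2],
              x$f1, x$phi, x$youden))
  cat(sprintf("  chi-square(1) = %.2f, p = %.3g\n",
              x$chi2$statistic, x$chi2$p))
  if (!is.null(x$auc)) cat(sprintf("  AUC %.3f\n", x$auc))
  invisible(x)
}

#' @export
print.staging_report <- function(x, ...) {
  cat("<staging_report>\n-- periodontitis detection --\n")
  print(x$detection)
  if (!is.null(x$overall)) {
    cat(sprintf("-- staging among detected: %d/%d = %.3f (%.3f-%.3f) --\n",
                x$overall$correct, x$overall$n, x$overall$accuracy,
                x$overall$ci[1], x$overall$ci[2]))
    print(x$per_stage, row.names = FALSE)
  } else {
    cat("-- no detected periodontitis cases; staging accuracies absent --\n")
  }
  invisible(x)
}
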