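# Diagnostic-test evaluation statistics.

# Operating tables of the two screens, reconstructed from their
# sensitivity/specificity fractions (82/104 with 34/45; 15/23 with 65/81).
ct_screen <- confusion_table(tp = 82, fp = 11, fn = 22, tn = 34)
ct_split <- confusion_table(tp = 15, fp = 16, fn = 8, tn = 65)

test_that("confusion tabulates labels under a declared positive set", {
  pred <- c("II", "III", "healthy", "I", "II")
  truth <- c("II", "II", "healthy", "II", "healthy")
  ct <- confusion(pred, truth, positive = c("II", "III"))
  expect_equal(c(ct$tp, ct$fp, ct$fn, ct$tn), c(2L, 1L, 1L, 1L))
  perfect <- confusion(1:10 > 5, 1:10 > 5, positive = TRUE)
  expect_equal(c(perfect$fp, perfect$fn), c(0L, 0L))
  expect_error(confusion(1, c(1, 2), TRUE), "length")
  expect_error(confusion(logical(0), logical(0), TRUE), "empty")
})

test_that("basic rates reproduce the operating-table fractions", {
  r <- basic_rates(ct_screen)
  expect_equal(r$sensitivity, 82 / 104)
  expect_equal(r$specificity, 34 / 45)
  expect_equal(r$accuracy, 116 / 149)
  expect_equal(r$youden, 82 / 104 + 34 / 45 - 1)
  expect_equal(r$f1, 2 * 82 / (2 * 82 + 11 + 22))
  r2 <- basic_rates(ct_split)
  expect_equal(r2$youden, 15 / 23 + 65 / 81 - 1)
  # undefined rates are absent, not zero
  r3 <- basic_rates(confusion_table(0, 5, 0, 5))
  expect_true(is.na(r3$sensitivity))
  expect_true(is.na(r3$youden))
  expect_equal(r3$specificity, 0.5)
})

test_that("phi and chi-square obey phi^2 * n = statistic on random tables", {
  expect_equal(phi_coefficient(confusion_table(7, 0, 0, 7)), 1)
  expect_warning(phi_coefficient(confusion_table(5, 0, 5, 0)), "margin")
  set.seed(9)
  for (i in 1:50) {
    ct <- confusion_table(sample(1:50, 1), sample(1:50, 1),
                          sample(1:50, 1), sample(1:50, 1))
    n <- ct$tp + ct$fp + ct$fn + ct$tn
    expect_equal(chi_square_2x2(ct)$statistic, n * phi_coefficient(ct)^2,
                 tolerance = 1e-12)
  }
  # a table with independent proportional rows carries no association
  expect_equal(chi_square_2x2(confusion_table(10, 20, 5, 10))$statistic, 0)
})

test_that("accuracy decomposes as the prevalence-weighted rate mix", {
  set.seed(10)
  for (i in 1:20) {
    ct <- confusion_table(sample(1:40, 1), sample(1:40, 1),
                          sample(1:40, 1), sample(1:40, 1))
    r <- basic_rates(ct)
    P <- ct$tp + ct$fn; N <- ct$tn + ct$fp
    expect_equal(r$accuracy, (r$sensitivity * P + r$specificity * N) / r$n)
  }
})

test_that("Wald intervals match hand calculation and scale as 1/sqrt(n)", {
  expect_equal(unname(round(wald_ci(113, 118), 3)), c(0.921, 0.994))
  expect_equal(unname(round(wald_ci(22, 31), 3)), c(0.550, 0.869))
  expect_equal(unname(wald_ci(50, 50)), c(1, 1))
  expect_error(wald_ci(5, 0), "n > 0")
  h1 <- diff(wald_ci(30, 100)); h2 <- diff(wald_ci(60, 200))
  expect_equal(unname(h1 / h2), sqrt(2))
  # intervals are not clipped
  expect_gt(wald_ci(113, 118)[["upper"]], 0.99)
})

test_that("Hosmer-Lemeshow separates calibrated from anti-calibrated scores", {
  set.seed(77)
  n <- 20000
  p <- runif(n, 0.05, 0.95)
  y <- rbinom(n, 1, p)
  hl <- hosmer_lemeshow(p, y, groups = 10)
  expect_equal(hl$df, 8)
  # calibrated: statistic ~ chi-square(8); bound at its 99.9% quantile
  expect_lt(hl$statistic, qchisq(0.999, df = 8))
  anti <- hosmer_lemeshow(1 - p, y, groups = 10)
  expect_gt(anti$statistic, 50 * anti$df)
  # scores constant at the observed prevalence fit perfectly
  y2 <- rep(c(0, 1), each = 10)
  expect_equal(hosmer_lemeshow(rep(0.5, 20), y2, groups = 2)$statistic, 0)
  expect_error(hosmer_lemeshow(c(0, 0, 0.6, 0.7), c(0, 0, 1, 0), groups = 2),
               "degenerate")
})

test_that("trapezoid AUC equals the normalized Mann-Whitney U", {
  expect_equal(roc_and_auc(c(.9, .8, .3, .2), c(1, 1, 0, 0))$auc, 1)
  set.seed(13)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    scores <- round(runif(n), 1) # coarse grid forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    u <- 0
    for (a in scores[y == 1]) {
      u <- u + sum(a > scores[y == 0]) + 0.5 * sum(a == scores[y == 0])
    }
    expect_equal(suppressWarnings(roc_and_auc(scores, y))$auc,
                 u / (sum(y == 1) * sum(y == 0)), tolerance = 1e-12)
  }
  # labels independent of scores: AUC near 1/2
  set.seed(14)
  s <- runif(1e4); y <- rbinom(1e4, 1, 0.5)
  expect_lt(abs(suppressWarnings(roc_and_auc(s, y))$auc - 0.5), 0.02)
  expect_error(roc_and_auc(runif(5), rep(1, 5)), "both classes")
  expect_warning(roc_and_auc(c(.1, .2, .8, .9), c(1, 1, 0, 0)), "backwards")
  # independent implementation cross-check
  set.seed(16)
  s2 <- round(runif(80), 2); y2 <- rbinom(80, 1, plogis(3 * s2 - 1.5))
  ref <- as.numeric(pROC::auc(pROC::roc(y2, s2, quiet = TRUE,
                                        direction = "<")))
  expect_equal(suppressWarnings(roc_and_auc(s2, y2))$auc, ref,
               tolerance = 1e-12)
})

test_that("Youden-optimal cut-off agrees with an exhaustive scan", {
  # separated classes: J = 1 at the lowest positive score (highest threshold)
  r <- roc_and_auc(c(.9, .7, .3, .2), c(1, 1, 0, 0))
  best <- youden_optimal_cutoff(r)
  expect_equal(best$youden, 1)
  expect_equal(best$threshold, 0.7)
  set.seed(15)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    scores <- round(runif(n), 2)
    y <- rbinom(n, 1, plogis(4 * scores - 2))
    if (length(unique(y)) < 2) next
    got <- youden_optimal_cutoff(suppressWarnings(roc_and_auc(scores, y)))
    # brute force over candidate thresholds
    cand <- sort(unique(scores), decreasing = TRUE)
    js <- vapply(cand, function(t) {
      mean(scores[y == 1] >= t) - mean(scores[y == 0] >= t)
    }, 0)
    expect_equal(got$youden, max(js), tolerance = 1e-12)
    expect_equal(got$threshold, max(cand[js == max(js)]))
  }
})

test_that("the split screen's operating point is Youden-optimal on a matching fixture", {
  # 23 positives (15 scoring at the top level) and 81 negatives (16 there):
  # the stage II/III operating fractions 15/23 and 65/81
  scores <- c(rep(0.500, 15), rep(0.024, 8), rep(0.500, 16), rep(0.024, 65))
  y <- c(rep(1, 23), rep(0, 81))
  best <- youden_optimal_cutoff(roc_and_auc(scores, y))
  expect_equal(best$threshold, 0.5)
  expect_equal(best$youden, 15 / 23 + 65 / 81 - 1, tolerance = 1e-12)
})

test_that("staging report reproduces its fixture's fractions and invariants", {
  # truth: 31 healthy, 14 I, 81 II, 23 III; detection misses 5 true II;
  # among the 113 detected, 9 + 46 + 14 get the correct stage
  truth <- c(rep("healthy", 31), rep("I", 14), rep("II", 81), rep("III", 23))
  pred <- c(rep("healthy", 22), rep("I", 9),            # healthy: 9 false pos
            rep("I", 9), rep("II", 5),                  # true I
            rep("healthy", 5), rep("II", 46), rep("III", 30), # true II
            rep("III", 14), rep("II", 9))               # true III
  rep_ <- staging_report(data.frame(predicted_stage = pred), truth)
  expect_equal(rep_$detection$sensitivity, 113 / 118)
  expect_equal(rep_$detection$specificity, 22 / 31)
  expect_equal(rep_$overall$accuracy, 69 / 113)
  expect_equal(rep_$per_stage$accuracy, c(9 / 14, 46 / 76, 14 / 23))
  expect_equal(sum(rep_$per_stage$correct), rep_$overall$correct)
  expect_equal(sum(rep_$per_stage$n), rep_$overall$n)
  # a perfect classifier is perfect throughout
  perfect <- staging_report(data.frame(predicted_stage = truth), truth)
  expect_equal(perfect$overall$accuracy, 1)
  expect_true(all(perfect$per_stage$accuracy == 1))
  # with no detected periodontitis, staging accuracies are absent
  none <- suppressWarnings(staging_report(
    data.frame(predicted_stage = rep("healthy", 10)),
    c(rep("healthy", 5), rep("II", 5))))
  expect_null(none$overall)
})
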