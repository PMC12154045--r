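# Maximum-likelihood logistic fitting, Wald inference and backward stepwise
# selection. stats::glm is used as an independent cross-check of the same
# likelihood optimum, never as the implementation.

test_that("intercept-only fit on a balanced outcome gives B0 = 0", {
  y <- rep(c(0, 1), 25)
  fit <- fit_logistic(matrix(1, 50, 1), y)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), 0, tolerance = 1e-8)
})

test_that("the likelihood optimum matches a brute-force grid oracle on tiny data", {
  x <- c(0, 0, 1, 1, 0, 1, 0, 1)
  y <- c(0, 0, 1, 0, 0, 1, 1, 1)
  fit <- fit_logistic(cbind(1, x), y)
  oracle <- grid_loglik_max(x, y)
  expect_equal(fit$log_likelihood, oracle$loglik, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients), oracle$b, tolerance = 1e-3)
})

test_that("coefficients, standard errors and likelihood agree with glm", {
  set.seed(21)
  n <- 400
  X <- cbind(x1 = rbinom(n, 1, .4), x2 = rnorm(n), x3 = rbinom(n, 1, .2))
  y <- rbinom(n, 1, plogis(-1 + X %*% c(1.2, -0.7, 0.5)))
  fit <- fit_logistic(cbind(`(Intercept)` = 1, X), y)
  ref <- glm(y ~ X, family = binomial)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$standard_errors),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-6)
  expect_equal(fit$log_likelihood, as.numeric(logLik(ref)), tolerance = 1e-8)
  # score-equation identity: fitted probabilities sum to the event count
  expect_equal(sum(fit$fitted), sum(y), tolerance = 1e-6)
  # fitting improved on the null likelihood
  expect_gt(fit$log_likelihood, loglik_at_zero <- sum(log(0.5)) * n)
})

test_that("perfect separation is detected and reported, not silently returned", {
  x <- c(rep(0, 10), rep(1, 10))
  y <- x
  expect_warning(fit <- fit_logistic(cbind(1, x), y), "separation")
  expect_true(fit$separation)
  expect_false(fit$converged)
})

test_that("degenerate designs are rejected up front", {
  expect_error(fit_logistic(matrix(1, 10, 1), rep(1, 10)), "single-valued")
  expect_error(fit_logistic(cbind(1, rep(0, 10)), rep(c(0, 1), 5)),
               "all-zero")
  expect_error(fit_logistic(matrix(1, 2, 3), c(0, 1)), "more observations")
})

test_that("Wald statistics reproduce the coefficient-table transform", {
  w <- wald_statistics(1.997, 0.598)
  expect_equal(w$wald, (1.997 / 0.598)^2)
  expect_equal(round(w$wald, 2), 11.15)
  expect_equal(round(w$exp_b, 3), 7.367)
  z <- wald_statistics(0, 1)
  expect_equal(c(z$wald, z$exp_b, z$p), c(0, 1, 1))
  expect_error(wald_statistics(1, 0), "zero standard error")
  # wald_inference exposes the same quantities per fitted term
  set.seed(22)
  x <- rbinom(100, 1, .5); y <- rbinom(100, 1, plogis(x - .5))
  fit <- fit_logistic(cbind(`(Intercept)` = 1, x = x), y)
  inf <- wald_inference(fit)
  expect_equal(inf$wald, (inf$b / inf$se)^2)
  expect_equal(inf$exp_b, exp(inf$b))
  expect_equal(inf$p, pchisq(inf$wald, 1, lower.tail = FALSE))
})

test_that("backward stepwise drops null predictors and keeps strong ones", {
  set.seed(23)
  removed_null <- 0
  for (r in 1:100) {
    n <- 2000
    X <- cbind(strong = rbinom(n, 1, .5), null = rbinom(n, 1, .5))
    y <- rbinom(n, 1, plogis(-1 + 2 * X[, "strong"]))
    sel <- backward_stepwise(X, y)
    if (!"null" %in% sel$final_terms) removed_null <- removed_null + 1
    expect_true("strong" %in% sel$final_terms)
    # invariant: no retained term exceeds the threshold
    p <- sel$fit$p_values[setdiff(names(sel$fit$p_values), "(Intercept)")]
    expect_true(all(p <= 0.05))
  }
  expect_gte(removed_null, 90)
})

test_that("stepwise keeps all informative terms and strips pure noise", {
  set.seed(24)
  n <- 3000
  X <- cbind(a = rbinom(n, 1, .5), b = rbinom(n, 1, .5))
  y <- rbinom(n, 1, plogis(-1 + 1.5 * X[, "a"] + 2 * X[, "b"]))
  sel <- backward_stepwise(X, y)
  expect_equal(nrow(sel$trace), 0)
  expect_setequal(sel$final_terms, c("a", "b"))

  intercept_only <- 0
  for (r in 1:40) {
    Xn <- cbind(n1 = rbinom(500, 1, .5), n2 = rbinom(500, 1, .5))
    yn <- rbinom(500, 1, 0.4)
    seln <- backward_stepwise(Xn, yn)
    if (length(seln$final_terms) == 0) intercept_only <- intercept_only + 1
    # removal order is recorded with its p-value
    if (nrow(seln$trace) > 0) {
      expect_true(all(seln$trace$p_at_removal > 0.05))
    }
  }
  expect_gt(intercept_only, 20) # majority of pure-noise replicates
})

test_that("events-per-variable admissibility follows the arithmetic rule", {
  y_split <- c(rep(1, 23), rep(0, 81))
  got <- epv_check(y_split, n_terms = 2)
  expect_equal(got$epv, 11.5)
  expect_true(got$pass)
  got4 <- epv_check(c(rep(1, 104), rep(0, 45)), n_terms = 4)
  expect_equal(got4$events, 45) # the smaller class counts as events
  expect_equal(got4$epv, 11.25)
  expect_true(got4$pass)
  expect_false(epv_check(c(rep(1, 9), rep(0, 100)), n_terms = 1)$pass)
})
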