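# Maximum-likelihood logistic regression with Wald inference and backward
# stepwise selection. The fitter is Newton-Raphson on the Bernoulli
# log-likelihood (equivalently iteratively reweighted least squares) with
# step halving, so the log-likelihood is non-decreasing across iterations;
# standard errors come from the inverse observed information.

#' Fit a logistic regression by maximum likelihood
#'
#' @param X numeric design matrix including the intercept column (use
#'   `cbind(`(Intercept)` = 1, predictors)`); column names become term names.
#' @param y binary outcome vector (0/1 or logical), `length(y) == nrow(X)`.
#' @param tol convergence tolerance on the max-norm of the score (gradient).
#' @param max_iter iteration cap.
#' @return Object of class `logistic_fit` with `coefficients`,
#'   `standard_errors`, `wald` (`(B/S.E.)^2`), `df` (1 per term), `p_values`
#'   (upper-tail chi-square(1)), `exp_b`, `log_likelihood`, `fitted`,
#'   `vcov`, `converged`, `n_iter`, and `separation` (`TRUE` when the
#'   likelihood is still improving along diverging coefficients, the
#'   signature of perfect separation; such fits are reported, not silently
#'   returned as converged).
#' @examples
#' X <- cbind(1, c(0, 0, 1, 1, 0, 1, 0, 1))
#' y <- c(0, 0, 1, 0, 0, 1, 1, 1)
#' fit_logistic(X, y)$coefficients
#' @export
fit_logistic <- function(X, y, tol = 1e-8, max_iter = 100) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("y is single-valued; nothing to fit")
  if (nrow(X) <= ncol(X)) stop("need more observations than terms")
  if (any(apply(X, 2, function(c) all(c == 0)))) {
    stop("design matrix has an all-zero column")
  }
  if (is.null(colnames(X))) {
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))[
      seq_len(ncol(X))]
  }

  beta <- rep(0, ncol(X))
  ll <- loglik_bernoulli(X, y, beta)
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    p <- plogis_raw(drop(X %*% beta))
    w <- p * (1 - p)
    score <- drop(crossprod(X, y - p))
    if (max(abs(score)) <= tol) { converged <- TRUE; break }
    info <- crossprod(X * w, X)
    step <- tryCatch(solve(info, score),
                     error = function(e) stop("information matrix singular ",
                                              "(collinear design?)"))
    # Step halving: never accept a likelihood decrease.
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ll_new <- loglik_bernoulli(X, y, cand)
      if (ll_new >= ll - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    beta <- cand
    ll <- ll_new
  }
  p <- plogis_raw(drop(X %*% beta))
  # Under (quasi-)separation the likelihood has no interior maximum: the
  # Newton iteration drifts to huge coefficients (the score still shrinks,
  # so it can "converge" numerically). Diverging |B| is the signature.
  separation <- max(abs(beta)) > 15
  if (separation) {
    converged <- FALSE
    warning("perfect or quasi-perfect separation detected: ",
            "coefficients diverge and standard errors are meaningless")
  }
  info <- crossprod(X * (p * (1 - p)), X)
  vc <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  se <- sqrt(diag(vc))
  wald <- (beta / se)^2
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    standard_errors = stats::setNames(se, colnames(X)),
    wald = stats::setNames(wald, colnames(X)),
    df = stats::setNames(rep(1L, ncol(X)), colnames(X)),
    p_values = stats::setNames(
      stats::pchisq(wald, df = 1, lower.tail = FALSE), colnames(X)),
    exp_b = stats::setNames(exp(beta), colnames(X)),
    log_likelihood = ll, fitted = p, vcov = vc,
    converged = converged, n_iter = iter, separation = separation,
    X = X, y = y), class = "logistic_fit")
}

#' Wald statistic, p-value and odds ratio from a coefficient and its S.E.
#'
#' The elementwise reporting transform of logistic-regression output tables:
#' `wald = (b/se)^2`, `p = P(chi-square(1) >= wald)`, `exp_b = exp(b)`.
#'
#' @param b coefficient estimate(s).
#' @param se standard error(s), same length, all positive.
#' @return data.frame with columns `b`, `se`, `wald`, `df`, `p`, `exp_b`.
#' @examples
#' wald_statistics(1.997, 0.598) # wald 11.15, exp_b 7.367
#' @export
wald_statistics <- function(b, se) {
  stopifnot(length(b) == length(se))
  if (any(se <= 0, na.rm = TRUE)) stop("zero standard error")
  wald <- (b / se)^2
  data.frame(b = b, se = se, wald = wald, df = 1L,
             p = stats::pchisq(wald, df = 1, lower.tail = FALSE),
             exp_b = exp(b))
}

loglik_bernoulli <- function(X, y, beta) {
  lp <- drop(X %*% beta)
  # log(1 + exp(lp)) computed stably
  sum(y * lp - ifelse(lp > 30, lp, log1p(exp(lp))))
}

#' Per-term Wald inference of a logistic fit
#'
#' The reporting convention of standard regression output tables: the Wald
#' statistic `(B/S.E.)^2` on 1 df, its upper-tail chi-square p-value, and
#' the odds ratio `exp(B)`.
#'
#' @param fit a `logistic_fit`.
#' @return data.frame with columns `term`, `b`, `se`, `wald`, `df`, `p`,
#'   `exp_b`.
#' @export
wald_inference <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (any(fit$standard_errors == 0, na.rm = TRUE)) {
    stop("zero standard error")
  }
  data.frame(term = names(fit$coefficients),
             b = unname(fit$coefficients),
             se = unname(fit$standard_errors),
             wald = unname(fit$wald),
             df = unname(fit$df),
             p = unname(fit$p_values),
             exp_b = unname(fit$exp_b),
             row.names = NULL)
}

#' Backward stepwise selection by Wald p-value
#'
#' Starts from the full model and repeatedly removes the predictor with the
#' largest Wald p-value among those exceeding `p_threshold`, refitting after
#' each removal, until every remaining predictor satisfies
#' `p <= p_threshold` or only the intercept remains. The intercept is never
#' removed.
#'
#' @param X numeric matrix of predictors (no intercept column; one is added
#'   internally and retained throughout).
#' @param y binary outcome vector.
#' @param p_threshold retention threshold (0.05 in the development study).
#' @param ... passed to [fit_logistic()].
#' @return List with `fit` (final `logistic_fit`), `final_terms`
#'   (character), and `trace` (data.frame `step`, `removed`,
#'   `p_at_removal`).
#' @export
backward_stepwise <- function(X, y, p_threshold = 0.05, ...) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  terms <- colnames(X)
  trace <- data.frame(step = integer(), removed = character(),
                      p_at_removal = numeric())
  step_i <- 0
  repeat {
    design <- cbind(`(Intercept)` = 1, X[, terms, drop = FALSE])
    fit <- fit_logistic(design, y, ...)
    p <- fit$p_values[setdiff(names(fit$p_values), "(Intercept)")]
    if (length(p) == 0 || max(p) <= p_threshold) break
    worst <- names(p)[which.max(p)]
    step_i <- step_i + 1
    trace <- rbind(trace, data.frame(step = step_i, removed = worst,
                                     p_at_removal = unname(max(p))))
    terms <- setdiff(terms, worst)
  }
  list(fit = fit, final_terms = terms, trace = trace)
}

#' Events-per-variable admissibility check
#'
#' The number of events is the smaller of the two outcome-class counts; the
#' EPV is events divided by the number of model terms (intercept excluded).
#' The admissibility rule requires EPV >= 10.
#'
#' @param y binary outcome vector.
#' @param n_terms number of candidate predictors (excluding the intercept).
#' @return List with `events`, `epv` and `pass`.
#' @examples
#' epv_check(c(rep(1, 23), rep(0, 81)), n_terms = 2) # 11.5, pass
#' @export
epv_check <- function(y, n_terms) {
  stopifnot(n_terms >= 1)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  events <- min(sum(y == 1), sum(y == 0))
  epv <- events / n_terms
  list(events = events, epv = epv, pass = epv >= 10)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, logLik = %.4f, %s in %d iteration(s)%s\n",
              length(x$y), x$log_likelihood,
              if (x$converged) "converged" else "NOT converged", x$n_iter,
              if (x$separation) " [separation]" else ""))
  print(wald_inference(x), row.names = FALSE, digits = 4)
  invisible(x)
}
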