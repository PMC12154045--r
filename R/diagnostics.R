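# Regression diagnostics of the model-development framework: collinearity
# (VIF), per-observation influence and outliers (Cook's distance,
# standardized Pearson residuals), and a residual-order autocorrelation
# statistic standing in for the visual residual-versus-time check.

#' Diagnostics for a fitted logistic model
#'
#' Computes, from a converged [fit_logistic()] result:
#' \describe{
#'   \item{vif}{variance inflation factor `1/(1 - R^2)` per non-intercept
#'     predictor, with `R^2` from the auxiliary linear regression of that
#'     predictor on all the others. A singular auxiliary regression
#'     (duplicated predictor) yields `Inf` with a warning.}
#'   \item{standardized_residuals}{Pearson residuals divided by
#'     `sqrt(1 - h)`, with leverages `h` from the weighted hat matrix of
#'     the final IRLS step.}
#'   \item{cooks_distance}{the generalized Cook's distance
#'     `r_sp^2 h / (k (1 - h))` on the IRLS working response, `k` = number
#'     of model terms including the intercept (matches the standard GLM
#'     influence measures).}
#'   \item{durbin_watson}{`sum(diff(r)^2) / sum(r^2)` on the standardized
#'     residuals taken in record order (order stands in for time); values
#'     near 2 indicate no serial correlation.}
#'   \item{flags}{indices of observations with Cook's distance > 0.5 or
#'     |standardized residual| > 3.0, the influence screen of the
#'     development protocol.}
#' }
#'
#' @param fit a converged `logistic_fit` (carries its design matrix and
#'   outcome).
#' @param order optional permutation giving the chronological record order
#'   for the autocorrelation statistic; defaults to row order.
#' @return List of class `model_diagnostics` with the elements above plus
#'   `leverage`.
#' @export
model_diagnostics <- function(fit, order = NULL) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged) stop("diagnostics require a converged fit")
  X <- fit$X
  y <- fit$y
  p <- fit$fitted
  k <- ncol(X)
  n <- nrow(X)
  order <- order %||% seq_len(n)
  stopifnot(length(order) == n)

  w <- p * (1 - p)
  Xw <- X * sqrt(w)
  qr_xw <- qr(Xw)
  h <- rowSums(qr.Q(qr_xw)[, seq_len(qr_xw$rank), drop = FALSE]^2)

  r_pearson <- (y - p) / sqrt(w)
  r_std <- r_pearson / sqrt(1 - h)
  cooks <- r_std^2 * h / (k * (1 - h))

  predictors <- setdiff(colnames(X), "(Intercept)")
  vif <- vapply(predictors, function(j) {
    others <- cbind(1, X[, setdiff(predictors, j), drop = FALSE])
    zj <- X[, j]
    tss <- sum((zj - mean(zj))^2)
    if (tss == 0) return(NA_real_)
    cf <- tryCatch(qr.coef(qr(others), zj), error = function(e) NULL)
    if (is.null(cf)) return(Inf)
    cf[is.na(cf)] <- 0
    rss <- sum((zj - drop(others %*% cf))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) {
      warning(sprintf("VIF infinite for '%s': predictor is an exact linear ",
                      j), "combination of the others")
      return(Inf)
    }
    1 / (1 - r2)
  }, 0)

  r_ord <- r_std[order]
  dw <- sum(diff(r_ord)^2) / sum(r_ord^2)

  flags <- which(cooks > 0.5 | abs(r_std) > 3.0)
  structure(list(vif = vif, leverage = h,
                 standardized_residuals = r_std,
                 cooks_distance = cooks, durbin_watson = dw,
                 flags = flags),
            class = "model_diagnostics")
}

#' @export
print.model_diagnostics <- function(x, ...) {
  cat("<model_diagnostics>\n  VIF:",
      paste(sprintf("%s=%.3f", names(x$vif), x$vif), collapse = ", "), "\n")
  cat(sprintf("  Durbin-Watson %.3f; max Cook's %.3f; max |std resid| %.2f\n",
              x$durbin_watson, max(x$cooks_distance),
              max(abs(x$standardized_residuals))))
  if (length(x$flags)) {
    cat("  flagged observation(s):", paste(x$flags, collapse = ", "), "\n")
  } else {
    cat("  no observation exceeds Cook's 0.5 or |residual| 3.0\n")
  }
  invisible(x)
}
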