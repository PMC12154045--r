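# The three published logistic scoring functions and the decision tree that
# maps a patient record to a final stage.

#' Construct a logistic scoring function
#'
#' @param name display name.
#' @param coefficients numeric slope vector (one per feature).
#' @param intercept numeric intercept.
#' @param cutoff probability threshold of the positive branch; the decision
#'   is positive when the score is `>= cutoff` for every function.
#' @param positive_meaning semantic tag of the `>= cutoff` branch.
#' @return An object of class `logistic_function`.
#' @seealso [periostage_functions()] for the shipped fixtures.
#' @export
logistic_function <- function(name, coefficients, intercept, cutoff,
                              positive_meaning) {
  stopifnot(is.numeric(coefficients), length(coefficients) >= 1,
            is.numeric(intercept), length(intercept) == 1,
            is.numeric(cutoff), cutoff > 0, cutoff < 1)
  structure(list(name = name, coefficients = as.numeric(coefficients),
                 intercept = as.numeric(intercept), cutoff = cutoff,
                 positive_meaning = positive_meaning),
            class = "logistic_function")
}

#' The shipped scoring-function fixtures
#'
#' The three published logistic functions of the staging cascade, with their
#' coefficients and operating cut-offs:
#' \describe{
#'   \item{periostage1}{slopes (1.997, 1.615, 1.653, 1.180) on the
#'     [periostage1_features()], intercept -2.649, cut-off 0.598. Score
#'     `>= 0.598` sends the patient to the stage II/III branch.}
#'   \item{periorisk}{slopes (3.392, 0.002, 1.858) on the
#'     [periorisk_features()], intercept -9.151, cut-off 0.55. Score
#'     `>= 0.55` means periodontitis, i.e. stage I on this branch.}
#'   \item{periostage23}{slopes (1.719, 1.988) on the
#'     [periostage23_features()], intercept -3.706, cut-off 0.326. Score
#'     `>= 0.326` means stage III, otherwise stage II.}
#' }
#' All scores are oriented so that higher values mean the more severe branch
#' (every slope is positive on risk-coded features).
#'
#' @return Named list of three [logistic_function()] objects.
#' @examples
#' fns <- periostage_functions()
#' logistic_score(fns$periostage23, c(1, 1)) # 0.50025
#' @export
periostage_functions <- function() {
  list(
    periostage1 = logistic_function(
      name = "PERIOSTAGE I",
      coefficients = c(1.997, 1.615, 1.653, 1.180),
      intercept = -2.649, cutoff = 0.598,
      positive_meaning = "stage II or III"),
    periorisk = logistic_function(
      name = "PERIORISK",
      coefficients = c(3.392, 0.002, 1.858),
      intercept = -9.151, cutoff = 0.55,
      positive_meaning = "periodontitis (stage I on this branch)"),
    periostage23 = logistic_function(
      name = "PERIOSTAGE II/III",
      coefficients = c(1.719, 1.988),
      intercept = -3.706, cutoff = 0.326,
      positive_meaning = "stage III")
  )
}

#' Evaluate a logistic scoring function
#'
#' Computes `1 / (1 + exp(-(beta . x + beta0)))` in double precision, applied
#' to the full-precision linear predictor (no rounding, no clipping).
#'
#' @param fn a [logistic_function()].
#' @param x numeric feature vector of length `length(fn$coefficients)`, or a
#'   matrix/data.frame with that many columns (one row per record).
#' @return Numeric probability vector in (0, 1).
#' @export
logistic_score <- function(fn, x) {
  stopifnot(inherits(fn, "logistic_function"))
  x <- if (is.data.frame(x)) as.matrix(x) else x
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(fn$coefficients)) {
    stop(sprintf("'%s' expects %d feature(s), got %d",
                 fn$name, length(fn$coefficients), ncol(x)))
  }
  lp <- drop(x %*% fn$coefficients) + fn$intercept
  plogis_raw(lp)
}

# Stable logistic; written out so the scoring path has no hidden dependence
# on the fitting machinery.
plogis_raw <- function(lp) {
  ifelse(lp >= 0, 1 / (1 + exp(-lp)), exp(lp) / (1 + exp(lp)))
}

#' Decision rule of a scoring function
#'
#' All three functions declare the positive (more severe) branch at score
#' `>= cutoff`; in particular PERIORISK scores `< 0.55` mean "no
#' periodontitis". The cut-off is applied to the full-precision score.
#'
#' @inheritParams logistic_score
#' @param p probability in \[0,1\] (vectorized).
#' @return Logical: `TRUE` on the positive branch.
#' @export
decide <- function(fn, p) {
  stopifnot(inherits(fn, "logistic_function"), all(p >= 0 & p <= 1))
  p >= fn$cutoff
}

#' Classify a cohort through the staging cascade
#'
#' For each record: PERIOSTAGE I is scored first. Scores `>= 0.598` take the
#' stage II/III branch, where PERIOSTAGE II/III assigns stage III at
#' `>= 0.326` and stage II below. Scores `< 0.598` take the healthy/stage I
#' branch, where PERIORISK assigns stage I at `>= 0.55` and health below.
#' Exactly one of `srisk`/`s23` is populated per record, matching the branch.
#'
#' @param cohort a `perio_cohort` or data.frame with the cohort columns.
#' @param functions list of fixtures as returned by [periostage_functions()].
#' @return data.frame of class `cascade_result` with columns `id`, `s1`,
#'   `srisk`, `s23`, `predicted_stage` (ordered factor) and `path`
#'   (functions evaluated, separated by `" > "`), in cohort order.
#' @examples
#' cohort <- generate_cohort(n = 10, seed = 7)
#' classify_cohort(cohort)
#' @export
classify_cohort <- function(cohort, functions = periostage_functions()) {
  n <- nrow(cohort)
  ids <- if (!is.null(cohort$id)) as.character(cohort$id)
         else sprintf("R%03d", seq_len(n))
  out <- data.frame(id = ids, s1 = numeric(n), srisk = rep(NA_real_, n),
                    s23 = rep(NA_real_, n),
                    predicted_stage = factor(rep(NA_character_, n),
                                             levels = stage_levels(),
                                             ordered = TRUE),
                    path = character(n), stringsAsFactors = FALSE)
  if (n == 0) {
    class(out) <- c("cascade_result", "data.frame")
    return(out)
  }
  out$s1 <- logistic_score(functions$periostage1,
                           periostage1_features(cohort))
  severe <- decide(functions$periostage1, out$s1)

  if (any(!severe)) {
    idx <- which(!severe)
    srisk <- logistic_score(functions$periorisk,
                            periorisk_features(cohort[idx, , drop = FALSE]))
    out$srisk[idx] <- srisk
    out$predicted_stage[idx] <- ifelse(decide(functions$periorisk, srisk),
                                       "I", "healthy")
    out$path[idx] <- paste(functions$periostage1$name, ">",
                           functions$periorisk$name)
  }
  if (any(severe)) {
    idx <- which(severe)
    s23 <- logistic_score(functions$periostage23,
                          periostage23_features(cohort[idx, , drop = FALSE]))
    out$s23[idx] <- s23
    out$predicted_stage[idx] <- ifelse(decide(functions$periostage23, s23),
                                       "III", "II")
    out$path[idx] <- paste(functions$periostage1$name, ">",
                           functions$periostage23$name)
  }
  class(out) <- c("cascade_result", "data.frame")
  out
}

#' @rdname classify_cohort
#' @param record a single patient record (1-row data.frame).
#' @export
classify <- function(record, functions = periostage_functions()) {
  stopifnot(is.data.frame(record), nrow(record) == 1)
  classify_cohort(record, functions = functions)
}

#' @export
print.logistic_function <- function(x, ...) {
  cat(sprintf("<logistic_function> %s\n", x$name))
  cat("  slopes:", paste(format(x$coefficients), collapse = ", "), "\n")
  cat("  intercept:", format(x$intercept),
      " cut-off:", format(x$cutoff), "\n")
  cat("  score >= cut-off means:", x$positive_meaning, "\n")
  invisible(x)
}
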