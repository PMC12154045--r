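# Composite predictors of the three scoring functions.
#
# All binary features are coded in the direction of risk (1 = riskier), so
# with the published positive slopes every score is increasing in every
# feature. The "two decimal places" cut-off comparisons are implemented as
# round-half-up to 2 dp followed by the comparison exactly as stated
# (25.99 < 26, 49.99 < 50, 69.99 < 70).

#' Composite predictors for the stage II/III screen (PERIOSTAGE I)
#'
#' Builds the four binary features of the function that separates healthy and
#' stage I subjects from stage II and III subjects:
#' \describe{
#'   \item{x1}{1 if aMMP-8 positive (>= 20 ng/mL) or diabetic.}
#'   \item{x2}{0 if age x waist-to-height ratio, rounded to 2 dp, is < 26;
#'     else 1. Waist-to-height ratio is waist_cm / height_cm (dimensionless).}
#'   \item{x3}{0 if VPI < 50.00\% and the patient visits a dental clinic
#'     annually; else 1.}
#'   \item{x4}{0 if full 28-tooth dentition (third molars excluded) and a
#'     non-smoker; else 1.}
#' }
#'
#' @param cohort a `perio_cohort` or data.frame with the cohort columns.
#' @return data.frame of integer 0/1 columns `x1..x4`, one row per record.
#' @export
periostage1_features <- function(cohort) {
  if (any(cohort$height_cm <= 0)) stop("height_cm must be positive")
  pos <- derive_ammp8_positive(cohort)
  awh <- round_half_up(cohort$age * cohort$waist_cm / cohort$height_cm, 2)
  data.frame(
    x1 = as.integer(pos | cohort$diabetic),
    x2 = as.integer(!(awh < 26)),
    x3 = as.integer(!(cohort$vpi_percent < 50 & cohort$annual_dental_visit)),
    x4 = as.integer(!(cohort$teeth_present == 28L & !cohort$smoker))
  )
}

#' Composite predictors for the health vs stage I screen (PERIORISK)
#'
#' \describe{
#'   \item{x1}{1 if aMMP-8 positive or a tobacco smoker.}
#'   \item{x2}{age x waist circumference (years x cm), unrounded. The
#'     published advisory input window is 2200-8772; values outside it are
#'     scored with a warning.}
#'   \item{x3}{1 if the patient or a parent of the patient is diabetic.}
#' }
#'
#' @inheritParams periostage1_features
#' @return data.frame with integer `x1`, numeric `x2`, integer `x3`.
#' @export
periorisk_features <- function(cohort) {
  pos <- derive_ammp8_positive(cohort)
  x2 <- cohort$age * cohort$waist_cm
  warn_ids(x2 < 2200 | x2 > 8772, cohort$id %||% seq_along(x2),
           "age x waist circumference outside the advisory window 2200-8772")
  data.frame(
    x1 = as.integer(pos | cohort$smoker),
    x2 = x2,
    x3 = as.integer(cohort$diabetic | cohort$parent_diabetic)
  )
}

#' Composite predictors for the stage II vs III split (PERIOSTAGE II/III)
#'
#' Missing teeth are always derived as `28 - teeth_present` (third molars
#' excluded), never stored.
#' \describe{
#'   \item{x1}{1 if aMMP-8 positive or more than 6 teeth are missing.}
#'   \item{x2}{1 if VPI >= 70.00\% or a smoker or diabetic.}
#' }
#'
#' @inheritParams periostage1_features
#' @return data.frame of integer 0/1 columns `x1`, `x2`.
#' @export
periostage23_features <- function(cohort) {
  pos <- derive_ammp8_positive(cohort)
  missing_teeth <- 28L - cohort$teeth_present
  data.frame(
    x1 = as.integer(pos | missing_teeth > 6L),
    x2 = as.integer(cohort$vpi_percent >= 70 | cohort$smoker | cohort$diabetic)
  )
}

# Dispatch by scoring-function key.
feature_matrix <- function(cohort, which = c("periostage1", "periorisk",
                                             "periostage23")) {
  which <- match.arg(which)
  f <- switch(which,
              periostage1 = periostage1_features,
              periorisk = periorisk_features,
              periostage23 = periostage23_features)
  as.matrix(f(cohort))
}
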