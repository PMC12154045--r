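# Cohort container and CSV interchange.
#
# A cohort is a data.frame with one row per patient and the columns listed in
# `cohort_columns()`, carrying class "perio_cohort" and a "provenance"
# attribute. Row order is meaningful: it stands in for time in the
# residual-autocorrelation check of the model-development module.

cohort_columns <- function() {
  c(id = "character", age = "integer", gender = "character",
    smoker = "logical", diabetic = "logical", parent_diabetic = "logical",
    annual_dental_visit = "logical", waist_cm = "numeric",
    height_cm = "numeric", weight_kg = "numeric", vpi_percent = "numeric",
    teeth_present = "integer", ammp8_ng_ml = "numeric",
    ammp8_positive = "logical", true_stage = "character")
}

#' Construct a validated cohort
#'
#' Validates a patient table against the data model and returns it as a
#' `perio_cohort`. Hard invariants (unique ids, VPI in \[0,100\], tooth count
#' in \[0,28\], at least one aMMP-8 field per row, consistency of the
#' concentration with the stored positivity flag under the 20 ng/mL rule)
#' always reject. The scoring-validity windows of the published functions
#' (age 25-78 years, waist circumference 60-152 cm, height 150-193 cm) are
#' advisory: violations warn and are flagged in the logical column
#' `in_scoring_window`, or reject when `strict = TRUE`.
#'
#' VPI is carried at two-decimal precision (rounded half-up on ingest), the
#' convention under which the published cut-off comparisons such as
#' `49.99 < 50` are stated.
#'
#' @param records data.frame with the columns of the cohort schema (see
#'   [read_cohort()] for the CSV rendering). `ammp8_ng_ml`, `ammp8_positive`
#'   and `true_stage` may be `NA` subject to the invariants above.
#' @param provenance free-text origin note stored as an attribute.
#' @param strict logical; escalate scoring-window violations to errors.
#' @return A `perio_cohort` data.frame with normalized column types, the
#'   derived `in_scoring_window` flag, and `true_stage` as an ordered factor.
#' @seealso [read_cohort()], [write_cohort()], [generate_cohort()]
#' @export
as_cohort <- function(records, provenance = "unspecified", strict = FALSE) {
  stopifnot(is.data.frame(records))
  cols <- cohort_columns()
  missing_cols <- setdiff(names(cols), names(records))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(records)[names(cols)]

  x$id <- as.character(x$id)
  if (anyNA(x$id) || any(x$id == "")) stop("every record needs a non-empty id")
  if (anyDuplicated(x$id)) {
    stop("duplicate id(s): ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "))
  }

  to_logical <- function(v, field) {
    if (is.logical(v)) return(v)
    if (is.numeric(v)) {
      if (!all(v %in% c(0, 1) | is.na(v))) {
        stop(sprintf("field '%s' must be 0/1", field))
      }
      return(v == 1)
    }
    v <- trimws(as.character(v))
    v[v %in% c("", "NA")] <- NA_character_
    ok <- v %in% c("0", "1", "TRUE", "FALSE", "true", "false") | is.na(v)
    if (!all(ok)) stop(sprintf("field '%s' must be 0/1", field))
    out <- v %in% c("1", "TRUE", "true")
    out[is.na(v)] <- NA
    out
  }
  for (f in c("smoker", "diabetic", "parent_diabetic", "annual_dental_visit")) {
    x[[f]] <- to_logical(x[[f]], f)
    if (anyNA(x[[f]])) {
      stop(sprintf("field '%s' is required for all records", f))
    }
  }
  x$ammp8_positive <- to_logical(x$ammp8_positive, "ammp8_positive")

  num <- function(v, field) {
    out <- suppressWarnings(as.numeric(v))
    bad <- is.na(out) & !is.na(v) &
      !(is.character(v) & trimws(v) %in% c("", "NA"))
    if (any(bad)) {
      stop(sprintf("unparseable value in field '%s' for record(s): %s",
                   field, paste(x$id[bad], collapse = ", ")))
    }
    out
  }
  x$age <- as.integer(num(x$age, "age"))
  x$waist_cm <- num(x$waist_cm, "waist_cm")
  x$height_cm <- num(x$height_cm, "height_cm")
  x$weight_kg <- num(x$weight_kg, "weight_kg")
  x$vpi_percent <- round_half_up(num(x$vpi_percent, "vpi_percent"), 2)
  x$teeth_present <- as.integer(num(x$teeth_present, "teeth_present"))
  x$ammp8_ng_ml <- num(x$ammp8_ng_ml, "ammp8_ng_ml")

  x$gender <- toupper(trimws(as.character(x$gender)))
  if (!all(x$gender %in% c("F", "M"))) stop("gender must be 'F' or 'M'")

  core <- c("age", "gender", "smoker", "diabetic", "parent_diabetic",
            "annual_dental_visit", "waist_cm", "height_cm", "weight_kg",
            "vpi_percent", "teeth_present")
  for (f in core) {
    if (anyNA(x[[f]])) {
      stop(sprintf("missing value in required field '%s' for record(s): %s",
                   f, paste(x$id[is.na(x[[f]])], collapse = ", ")))
    }
  }

  if (any(x$vpi_percent < 0 | x$vpi_percent > 100)) {
    stop("vpi_percent must lie in [0, 100] for record(s): ",
         paste(x$id[x$vpi_percent < 0 | x$vpi_percent > 100], collapse = ", "))
  }
  if (any(x$teeth_present < 0L | x$teeth_present > 28L)) {
    stop("teeth_present must lie in [0, 28] for record(s): ",
         paste(x$id[x$teeth_present < 0L | x$teeth_present > 28L],
               collapse = ", "))
  }
  if (any(x$height_cm <= 0)) stop("height_cm must be positive")
  if (any(!is.na(x$ammp8_ng_ml) & x$ammp8_ng_ml < 0)) {
    stop("ammp8_ng_ml must be non-negative")
  }

  no_ammp8 <- is.na(x$ammp8_ng_ml) & is.na(x$ammp8_positive)
  if (any(no_ammp8)) {
    stop("neither ammp8_ng_ml nor ammp8_positive present for record(s): ",
         paste(x$id[no_ammp8], collapse = ", "))
  }
  both <- !is.na(x$ammp8_ng_ml) & !is.na(x$ammp8_positive)
  clash <- both & ((x$ammp8_ng_ml >= 20) != x$ammp8_positive)
  if (any(clash)) {
    stop("ammp8_positive inconsistent with the 20 ng/mL rule for record(s): ",
         paste(x$id[clash], collapse = ", "))
  }

  x$true_stage <- stage_factor(x$true_stage)

  in_window <- x$age >= 25 & x$age <= 78 &
    x$waist_cm >= 60 & x$waist_cm <= 152 &
    x$height_cm >= 150 & x$height_cm <= 193
  if (any(!in_window)) {
    msg <- paste("outside the scoring-validity window",
                 "(age 25-78, waist 60-152 cm, height 150-193 cm)")
    if (strict) {
      stop(msg, " for record(s): ", paste(x$id[!in_window], collapse = ", "))
    }
    warn_ids(!in_window, x$id, msg)
  }
  x$in_scoring_window <- in_window

  rownames(x) <- NULL
  class(x) <- c("perio_cohort", "data.frame")
  attr(x, "provenance") <- provenance
  x
}

#' Read a patient cohort from CSV
#'
#' The file is comma-separated UTF-8 with a header row, `.` decimal mark and
#' booleans serialized as 0/1. Expected columns:
#' `id,age,gender,smoker,diabetic,parent_diabetic,annual_dental_visit,`
#' `waist_cm,height_cm,weight_kg,vpi_percent,teeth_present,ammp8_ng_ml,`
#' `ammp8_positive,true_stage`, with `true_stage` in
#' `{healthy,I,II,III}` or empty. `ammp8_ng_ml` and `ammp8_positive` may each
#' be empty, but not both on the same row.
#'
#' @param path CSV file path.
#' @param strict logical; escalate scoring-window violations to errors
#'   (see [as_cohort()]).
#' @return A validated `perio_cohort`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_cohort(generate_cohort(n = 5, seed = 1), f)
#' read_cohort(f)
#' @export
read_cohort <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = TRUE, na.strings = character())
  as_cohort(raw, provenance = paste0("csv:", path), strict = strict)
}

#' Write a cohort to CSV
#'
#' Serialization is the exact inverse of [read_cohort()]: booleans as 0/1,
#' VPI at two decimals, waist/height/weight at one decimal, aMMP-8
#' concentration at two decimals, empty string for absent optional fields.
#' `read_cohort(write_cohort(x))` reproduces every field at these documented
#' precisions.
#'
#' @param cohort a `perio_cohort` (or coercible data.frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (!inherits(cohort, "perio_cohort")) cohort <- as_cohort(cohort)
  fmt <- function(v, digits) {
    out <- ifelse(is.na(v), "", formatC(v, format = "f", digits = digits))
    out
  }
  bool <- function(v) ifelse(is.na(v), "", ifelse(v, "1", "0"))
  out <- data.frame(
    id = cohort$id,
    age = as.integer(cohort$age),
    gender = cohort$gender,
    smoker = bool(cohort$smoker),
    diabetic = bool(cohort$diabetic),
    parent_diabetic = bool(cohort$parent_diabetic),
    annual_dental_visit = bool(cohort$annual_dental_visit),
    waist_cm = fmt(cohort$waist_cm, 1),
    height_cm = fmt(cohort$height_cm, 1),
    weight_kg = fmt(cohort$weight_kg, 1),
    vpi_percent = fmt(cohort$vpi_percent, 2),
    teeth_present = as.integer(cohort$teeth_present),
    ammp8_ng_ml = fmt(cohort$ammp8_ng_ml, 2),
    ammp8_positive = bool(cohort$ammp8_positive),
    true_stage = ifelse(is.na(cohort$true_stage), "",
                        as.character(cohort$true_stage)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' aMMP-8 positivity under the 20 ng/mL rule
#'
#' A mouth-rinse point-of-care test is positive when the aMMP-8 concentration
#' is at or above 20 ng/mL (boundary inclusive). When only the positivity
#' flag is stored, it is passed through.
#'
#' @param x a `perio_cohort`/data.frame with columns `ammp8_ng_ml` and
#'   `ammp8_positive` (either may be `NA` per row, not both).
#' @return Logical vector, one element per record.
#' @examples
#' derive_ammp8_positive(data.frame(ammp8_ng_ml = c(20, 19.99),
#'                                  ammp8_positive = NA))
#' @export
derive_ammp8_positive <- function(x) {
  conc <- x$ammp8_ng_ml
  flag <- x$ammp8_positive
  if (is.null(conc) && is.null(flag)) {
    stop("need ammp8_ng_ml or ammp8_positive")
  }
  conc <- conc %||% rep(NA_real_, length(flag))
  flag <- flag %||% rep(NA, length(conc))
  if (any(is.na(conc) & is.na(flag))) {
    stop("record(s) lack both ammp8_ng_ml and ammp8_positive")
  }
  ifelse(!is.na(conc), conc >= 20, flag)
}

#' @export
print.perio_cohort <- function(x, ...) {
  cat(sprintf("<perio_cohort> %d record(s); provenance: %s\n",
              nrow(x), attr(x, "provenance") %||% "unspecified"))
  if (nrow(x) > 0) {
    print.data.frame(utils::head(as.data.frame(x), 6))
    if (nrow(x) > 6) cat("...", nrow(x) - 6, "more row(s)\n")
  }
  invisible(x)
}
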