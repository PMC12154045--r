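#' Stage labels
#'
#' The four-level ordered outcome of the cascade: periodontal health or
#' periodontitis stage I, II or III (the 2018 classification; no stage IV
#' subjects occur in the development data). The ordering
#' `healthy < I < II < III` is total.
#'
#' @param x character, factor or `stage_labels` vector using the levels
#'   `"healthy"`, `"I"`, `"II"`, `"III"` (case-insensitive; empty strings and
#'   `NA` become `NA`).
#' @return An ordered factor with levels `healthy < I < II < III`.
#' @examples
#' stage_factor(c("healthy", "III", "I"))
#' @export
stage_factor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  x <- trimws(as.character(x))
  x[x %in% c("", "NA")] <- NA_character_
  low <- tolower(x)
  map <- c(healthy = "healthy", i = "I", ii = "II", iii = "III",
           stage_i = "I", stage_ii = "II", stage_iii = "III")
  out <- unname(map[low])
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop("unknown stage label(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  factor(out, levels = stage_levels(), ordered = TRUE)
}

#' @rdname stage_factor
#' @export
stage_levels <- function() c("healthy", "I", "II", "III")

#' Does a stage label denote periodontitis?
#'
#' @param stage vector coercible by [stage_factor()].
#' @return Logical: `TRUE` for stages I-III, `FALSE` for health.
#' @export
is_periodontitis <- function(stage) {
  stage_factor(stage) != "healthy"
}
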