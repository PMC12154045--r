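# Round half away from zero (commercial rounding), as opposed to base R's
# round-half-even. The scoring rules compare quantities "with two decimal
# places" (49.99 < 50, 25.99 < 26), which pins the comparison after a
# conventional half-up rounding.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Collapse a logical "problem" vector into one warning naming offending ids.
warn_ids <- function(bad, ids, what) {
  if (any(bad, na.rm = TRUE)) {
    offenders <- ids[which(bad)]
    warning(sprintf("%s for record(s): %s", what,
                    paste(offenders, collapse = ", ")), call. = FALSE)
  }
  invisible(any(bad, na.rm = TRUE))
}
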