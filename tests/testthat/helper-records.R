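# Programmatic fixtures: a valid single patient record with overridable
# fields, and small cohorts built from it.

make_record <- function(id = "P001", age = 40L, gender = "M",
                        smoker = FALSE, diabetic = FALSE,
                        parent_diabetic = FALSE, annual_dental_visit = TRUE,
                        waist_cm = 100, height_cm = 170, weight_kg = 85,
                        vpi_percent = 30, teeth_present = 28L,
                        ammp8_ng_ml = 10, ammp8_positive = NA,
                        true_stage = NA_character_) {
  data.frame(id = id, age = age, gender = gender, smoker = smoker,
             diabetic = diabetic, parent_diabetic = parent_diabetic,
             annual_dental_visit = annual_dental_visit, waist_cm = waist_cm,
             height_cm = height_cm, weight_kg = weight_kg,
             vpi_percent = vpi_percent, teeth_present = teeth_present,
             ammp8_ng_ml = ammp8_ng_ml, ammp8_positive = ammp8_positive,
             true_stage = true_stage, stringsAsFactors = FALSE)
}

make_cohort <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

# Brute-force log-likelihood grid maximizer for a one-predictor logistic
# model: coarse-to-fine scan over (b0, b1) in [-10, 10]^2, independent of
# the IRLS code path.
grid_loglik_max <- function(x, y) {
  ll <- function(b0, b1) {
    lp <- b0 + b1 * x
    sum(y * lp - log1p(exp(lp)))
  }
  centre <- c(0, 0)
  width <- 10
  step <- 0.5
  for (level in 1:6) {
    b0s <- seq(centre[1] - width, centre[1] + width, by = step)
    b1s <- seq(centre[2] - width, centre[2] + width, by = step)
    vals <- outer(b0s, b1s, Vectorize(ll))
    idx <- arrayInd(which.max(vals), dim(vals))
    centre <- c(b0s[idx[1]], b1s[idx[2]])
    width <- 2 * step
    step <- step / 10
  }
  list(b = centre, loglik = ll(centre[1], centre[2]))
}
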