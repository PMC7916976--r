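# small study config for fast tests
smallConfig <- function(..., n_subjects = 6, seed = 1) {
  studyConfig(n_subjects = n_subjects, seed = seed, ...)
}

# noise-free config: no technical/extraction noise, no censoring
noiselessConfig <- function(..., n_subjects = 6, seed = 1) {
  cp <- defaultClassParams()
  cp$tech_cv_pct <- 0
  studyConfig(n_subjects = n_subjects, class_params = cp,
              censor_quantile = 0, extraction_cv_pct = 0, seed = seed, ...)
}

# balanced one-way dataset (2 records per subject, intercept only)
balancedOneWay <- function(m, s2b, s2w = 1, mu = 10) {
  b <- rnorm(m, sd = sqrt(s2b))
  y <- mu + rep(b, each = 2) + rnorm(2 * m, sd = sqrt(s2w))
  data.frame(subject_id = rep(sprintf("S%02d", seq_len(m)), each = 2),
             concentration = y)
}

# method-of-moments oracle for the balanced one-way random-intercept model:
# MSW over within-subject deviations, MSB over subject means, k = 2 records
# per subject; REML equals this closed form away from the boundary
anovaOracle <- function(d) {
  y <- d$concentration
  g <- factor(d$subject_id)
  m <- nlevels(g)
  ybar <- tapply(y, g, mean)
  msw <- sum((y - ybar[g])^2) / m          # df = n - m = m for k = 2
  msb <- 2 * sum((ybar - mean(y))^2) / (m - 1)
  s2b <- (msb - msw) / 2
  if (s2b > 0) list(sigma2_bs = s2b, sigma2_ws = msw, boundary = FALSE)
  else list(sigma2_bs = 0, sigma2_ws = var(y), boundary = TRUE)
}
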