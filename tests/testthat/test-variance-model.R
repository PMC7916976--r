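test_that("profiled REML matches the balanced one-way ANOVA closed form", {
  set.seed(21)
  for (r in 1:20) {
    d <- balancedOneWay(m = 15, s2b = runif(1, 0.5, 4))
    fit <- fitRandomIntercept(d, fixed = ~ 1)
    oracle <- anovaOracle(d)
    expect_equal(fit@sigma2_bs, oracle$sigma2_bs, tolerance = 1e-10)
    expect_equal(fit@sigma2_ws, oracle$sigma2_ws, tolerance = 1e-10)
  }
})

test_that("REML agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  set.seed(22)
  m <- 14
  d <- expand.grid(subject_id = sprintf("S%02d", 1:m),
                   timepoint = c("morning", "evening"))
  d$order <- factor(rep(c("morning-first", "evening-first"),
                        length.out = m)[as.integer(factor(d$subject_id))],
                    levels = c("morning-first", "evening-first"))
  d$concentration <- 10 + 1.5 * (d$timepoint == "evening") +
    rnorm(m, sd = 1.2)[as.integer(factor(d$subject_id))] + rnorm(nrow(d))
  d <- d[-c(5, 20), ]   # unbalanced on purpose
  fit <- fitRandomIntercept(d)
  lf <- lme4::lmer(concentration ~ timepoint + order + (1 | subject_id),
                   data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit@sigma2_bs, vc$vcov[1], tolerance = 1e-6)
  expect_equal(fit@sigma2_ws, vc$vcov[2], tolerance = 1e-6)
  expect_equal(unname(fit@beta), unname(lme4::fixef(lf)[names(fit@beta)]),
               tolerance = 1e-6)
  expect_equal(unname(fit@se_beta),
               unname(sqrt(diag(as.matrix(vcov(lf))))[c(1, 2, 3)]),
               tolerance = 1e-5)
  expect_equal(fit@reml_loglik, as.numeric(logLik(lf)), tolerance = 1e-6)
})

test_that("Wald SE matches the balanced expected-information closed form", {
  set.seed(23)
  d <- balancedOneWay(m = 20, s2b = 2.846)
  fit <- fitRandomIntercept(d, fixed = ~ 1)
  tau <- fit@sigma2_ws + 2 * fit@sigma2_bs   # variance of a subject total/2
  se_cf <- sqrt((2 * tau^2 / (20 - 1) + 2 * fit@sigma2_ws^2 / 20) / 4)
  expect_equal(fit@se_sigma2_bs, se_cf, tolerance = 1e-3)
})

test_that("null between-subject variance lands on the boundary", {
  set.seed(24)
  hits <- 0L
  for (r in 1:40) {
    d <- balancedOneWay(m = 10, s2b = 0)
    fit <- fitRandomIntercept(d, fixed = ~ 1)
    if (fit@boundary) {
      hits <- hits + 1L
      expect_equal(fit@sigma2_bs, 0)
      expect_equal(waldZTest(fit)$p, 1)
    }
  }
  expect_gt(hits, 10)  # boundary is hit in a substantial share of nulls
  # degenerate constant response
  dc <- data.frame(subject_id = rep(1:4, each = 2), concentration = 3)
  fc <- fitRandomIntercept(dc, fixed = ~ 1)
  expect_true(fc@degenerate)
  expect_equal(fc@sigma2_bs + fc@sigma2_ws, 0)
})

test_that("ICC formula, benchmark labels and affine invariance", {
  f <- methods::new("VarianceComponentsFit", sigma2_bs = 3, sigma2_ws = 1,
                    se_sigma2_bs = 1.2, beta = c(`(Intercept)` = 10),
                    se_beta = c(`(Intercept)` = 0.5), reml_loglik = -10,
                    n_obs = 40L, n_subjects = 20L, terms = "(Intercept)",
                    boundary = FALSE, degenerate = FALSE,
                    convergence = list(within = logical(0)))
  ic <- iccFromFit(f)
  expect_equal(ic$icc, 0.75)
  expect_equal(ic$label, "substantial")
  expect_equal(iccLabel(c(0.1, 0.4, 0.59, 0.6, 0.74, 0.8, 1.0)),
               c("below-moderate", "moderate", "moderate", "substantial",
                 "substantial", "almost perfect", "almost perfect"))
  # affine rescaling of concentrations leaves the ICC unchanged
  set.seed(25)
  d <- balancedOneWay(m = 12, s2b = 1.7)
  i1 <- iccFromFit(fitRandomIntercept(d, fixed = ~ 1))$icc
  d2 <- d; d2$concentration <- 5.3 * d$concentration - 40
  i2 <- iccFromFit(fitRandomIntercept(d2, fixed = ~ 1))$icc
  expect_equal(i1, i2, tolerance = 1e-8)
})

test_that("Wald Z p-value is the upper Normal tail and monotone in z", {
  f0 <- methods::new("VarianceComponentsFit", sigma2_bs = 0, sigma2_ws = 1,
                     se_sigma2_bs = 1, beta = c(`(Intercept)` = 0),
                     se_beta = c(`(Intercept)` = 1), reml_loglik = -1,
                     n_obs = 40L, n_subjects = 20L, terms = "(Intercept)",
                     boundary = FALSE, degenerate = FALSE,
                     convergence = list(within = logical(0)))
  expect_equal(waldZTest(f0)$p, 0.5)   # z = 0
  zs <- seq(0, 4, by = 0.25)
  ps <- vapply(zs, function(z) {
    f0@sigma2_bs <- z; waldZTest(f0)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("fixed-effect F uses containment df (18 in the 20 x 2 design)", {
  set.seed(26)
  m <- 20
  d <- expand.grid(subject_id = sprintf("S%02d", 1:m),
                   timepoint = c("morning", "evening"))
  d$order <- rep(c("morning-first", "evening-first"), length.out = m)[
    as.integer(factor(d$subject_id))]
  d$concentration <- 10 + 0.8 * (d$timepoint == "evening") +
    rnorm(m, sd = 1)[as.integer(factor(d$subject_id))] + rnorm(nrow(d))
  fit <- fitRandomIntercept(d)
  ft <- fixedEffectFTest(fit, "timepoint")
  fo <- fixedEffectFTest(fit, "order")
  expect_equal(ft$df_den, 18L)
  expect_equal(fo$df_den, 18L)
  expect_equal(ft$df_num, 1L)
  expect_equal(ft$p, pf(ft$f, 1, 18, lower.tail = FALSE))
  expect_error(fixedEffectFTest(fit, "diet"), "diet")
  # zero effect gives F = 0, p = 1
  f2 <- fit; f2@beta["timepointevening"] <- 0
  ft0 <- fixedEffectFTest(f2, "timepoint")
  expect_equal(ft0$f, 0)
  expect_equal(ft0$p, 1)
})

test_that("reference table Z/p and time F/p pairs reproduce under the
           one-sided Normal and F(1,18) conventions", {
  ref <- classVarianceReference()
  # printed statistics are rounded to 2 dp: accept any p reachable within
  # the half-ulp band of the printed statistic
  band_ok <- function(stat, p_printed, tail, digits) {
    lo <- tail(stat + 0.005); hi <- tail(stat - 0.005)
    any(abs(round(seq(min(lo, hi), max(lo, hi), length.out = 201),
                  digits) - p_printed) < 1e-12)
  }
  for (i in seq_len(nrow(ref))) {
    expect_true(band_ok(ref$z[i], ref$p_z[i],
                        function(z) pnorm(z, lower.tail = FALSE), 3))
    expect_true(band_ok(ref$f_time[i], ref$p_time[i],
                        function(f) pf(f, 1, 18, lower.tail = FALSE), 3))
    # order column agrees to within a printed unit
    expect_lt(abs(pf(ref$f_order[i], 1, 18, lower.tail = FALSE) -
                    ref$p_order[i]), 0.011)
  }
})

test_that("panel fitting is consistent with the single-lipid path", {
  sim <- simulateStudy(noiselessConfig(n_subjects = 10, seed = 30))
  exp <- normalizeToIstd(sim$experiment)
  res <- fitVariancePanel(exp, level = "species")
  expect_equal(nrow(res), 237L)
  lip <- "PE 34:1"
  d <- data.frame(SummarizedExperiment::colData(sim$experiment))
  d$concentration <- SummarizedExperiment::assay(exp, "concentrations")[lip, ]
  single <- fitRandomIntercept(d)
  row <- res[res$lipid == lip, ]
  expect_equal(row$sigma2_bs, single@sigma2_bs)
  expect_equal(row$sigma2_ws, single@sigma2_ws)
  expect_equal(row$icc, iccFromFit(single)$icc)
  expect_equal(row$p_time, fixedEffectFTest(single, "timepoint")$p)
  # class mode sums member species before fitting
  resc <- fitVariancePanel(exp, level = "class")
  expect_equal(sort(resc$lipid), sort(lipidClasses()))
  conc <- SummarizedExperiment::assay(exp, "concentrations")
  pe <- colSums(conc[parseLipidNames(rownames(conc))$lipid_class == "PE", ])
  d$concentration <- pe
  fpe <- fitRandomIntercept(d)
  expect_equal(resc$sigma2_bs[resc$lipid == "PE"], fpe@sigma2_bs)
})
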