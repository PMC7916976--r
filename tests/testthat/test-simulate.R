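test_that("study layout: one record per subject and timepoint, counterbalanced", {
  sim <- simulateStudy(studyConfig(n_subjects = 20, seed = 4))
  cd <- data.frame(SummarizedExperiment::colData(sim$experiment))
  expect_equal(nrow(cd), 40L)
  expect_true(all(table(cd$subject_id, cd$timepoint) == 1))
  firsts <- unique(cd[, c("subject_id", "order")])$order
  expect_equal(sum(firsts == "morning-first"), 10L)
  expect_warning(simulateStudy(studyConfig(n_subjects = 5, seed = 1)),
                 "odd")
})

test_that("truth obeys ICC = s2b / (s2b + s2w) and zero-variance edge", {
  sim <- simulateStudy(smallConfig())
  lt <- sim$truth$lipids
  expect_equal(lt$icc, lt$sigma2_bs / (lt$sigma2_bs + lt$sigma2_ws))
  cp <- defaultClassParams()
  cp$icc <- 0
  sim0 <- simulateStudy(smallConfig(class_params = cp))
  expect_true(all(sim0$truth$lipids$icc == 0))
  expect_true(all(sim0$truth$lipids$sigma2_bs == 0))
})

test_that("identical config and seed give identical output tables", {
  a <- simulateDataset(smallConfig(seed = 9))
  b <- simulateDataset(smallConfig(seed = 9))
  expect_identical(SummarizedExperiment::assay(a$experiment, "areas"),
                   SummarizedExperiment::assay(b$experiment, "areas"))
  expect_identical(istdAreas(a$experiment), istdAreas(b$experiment))
  c <- simulateDataset(smallConfig(seed = 10))
  expect_false(identical(SummarizedExperiment::assay(a$experiment, "areas"),
                         SummarizedExperiment::assay(c$experiment, "areas")))
})

test_that("noise-free areas pipe through quantification back to the truth", {
  sim <- simulateStudy(noiselessConfig(n_subjects = 4, seed = 5))
  conc <- SummarizedExperiment::assay(normalizeToIstd(sim$experiment),
                                      "concentrations")
  expect_equal(conc, sim$truth$concentrations, tolerance = 1e-12)
})

test_that("empirical variance components converge to the configured truth", {
  # large-subject check of the generative model itself (noise-free)
  panel <- parseLipidNames(c("PC 34:1", "TAG 48:2"))
  cp <- defaultClassParams()
  cp <- cp[cp$lipid_class %in% c("PC", "TAG"), ]
  cp$tech_cv_pct <- 0
  # moderate CVs so the positivity floor has negligible mass and the
  # configured variances are the moments of the realized distribution
  cp$bio_cv <- c(0.30, 0.34)
  cfg <- studyConfig(n_subjects = 2000, lipid_panel = panel,
                     class_params = cp, censor_quantile = 0,
                     extraction_cv_pct = 0, seed = 12)
  sim <- simulateStudy(cfg)
  conc <- sim$truth$concentrations
  cd <- data.frame(SummarizedExperiment::colData(sim$experiment))
  evening <- cd$timepoint == "evening"
  for (j in 1:2) {
    y <- conc[j, ]
    y[evening] <- y[evening] - (sim$truth$lipids$evening_fold[j] - 1) *
      sim$truth$lipids$mean_conc[j]
    pair <- matrix(y[order(cd$subject_id, cd$timepoint)], nrow = 2)
    s2w_hat <- sum((pair[1, ] - pair[2, ])^2) / (2 * ncol(pair))
    s2b_hat <- var(colMeans(pair)) - s2w_hat / 2
    expect_equal(s2b_hat, sim$truth$lipids$sigma2_bs[j], tolerance = 0.05)
    expect_equal(s2w_hat, sim$truth$lipids$sigma2_ws[j], tolerance = 0.05)
  }
})

test_that("censoring is sparse under default conditions", {
  sim <- simulateStudy(studyConfig(n_subjects = 20, seed = 2))
  areas <- SummarizedExperiment::assay(sim$experiment, "areas")
  expect_gt(sum(is.na(areas)), 0)
  expect_lt(sum(is.na(areas)), 20)  # ~4 expected over 237 x 40
})

test_that("censoring removes only a lipid's lowest-quantile values", {
  panel <- defaultLipidPanel()
  panel <- panel[panel$lipid_class == "PC", ]
  cp <- defaultClassParams()[defaultClassParams()$lipid_class == "PC", ]
  cp$evening_fold <- 1   # keep one distribution per lipid for the check
  cfg <- studyConfig(n_subjects = 20, lipid_panel = panel,
                     class_params = cp, censor_quantile = 0.02, seed = 6)
  sim <- simulateStudy(cfg)
  areas <- SummarizedExperiment::assay(sim$experiment, "areas")
  miss <- which(is.na(areas), arr.ind = TRUE)
  expect_gt(nrow(miss), 0)
  conc <- sim$truth$concentrations
  for (k in unique(miss[, 1])) {
    jj <- miss[miss[, 1] == k, 2]
    gone <- conc[k, jj]
    kept <- conc[k, -jj]
    expect_lt(max(gone), quantile(kept, 0.10))
  }
})

test_that("QC series layout and degenerate-noise behavior", {
  cfg <- smallConfig()
  sim <- simulateStudy(cfg)
  qc <- simulateQcSeries(cfg, sim$truth)
  roles <- sampleRoles(qc)
  expect_equal(sum(roles == "dilution"), 2L * length(cfg$dilution_levels))
  expect_equal(sum(roles == "tqc"), cfg$n_tqc)
  expect_error(studyConfig(n_tqc = 1), "n_tqc")
  # zero technical noise: TQC replicate areas identical, linearity exact
  cfg0 <- noiselessConfig()
  sim0 <- simulateStudy(cfg0)
  qc0 <- simulateQcSeries(cfg0, sim0$truth)
  a0 <- SummarizedExperiment::assay(qc0, "areas")
  tqc <- a0[, sampleRoles(qc0) == "tqc", drop = FALSE]
  expect_true(all(abs(tqc - tqc[, 1]) < 1e-9 * abs(tqc[, 1])))
  vf <- SummarizedExperiment::colData(qc0)$volume_fraction
  dsel <- sampleRoles(qc0) == "dilution"
  fit <- linearityFit(vf[dsel], a0[1, dsel])
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("config validation rejects impossible designs", {
  expect_error(studyConfig(n_subjects = 1), "n_subjects")
  cp <- defaultClassParams(); cp$mean_conc[1] <- -1
  expect_error(studyConfig(class_params = cp), "positive")
  cp <- defaultClassParams(); cp$evening_fold[1] <- 0
  expect_error(studyConfig(class_params = cp), "evening_fold")
  expect_error(studyConfig(dilution_levels = c(0.8, 0.4)), "increasing")
})
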