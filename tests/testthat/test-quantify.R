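# independent oracle: enumerate the binomial pmf by products, no dbinom
bruteIsotopeFraction <- function(carbons, shift, p = 0.0107) {
  comb <- prod(seq(carbons, carbons - shift + 1)) / prod(seq_len(max(shift, 1)))
  if (shift == 0) comb <- 1
  num <- comb * p^shift * (1 - p)^(carbons - shift)
  den <- (1 - p)^carbons
  num / den
}

test_that("isotopologue fraction matches brute-force binomial enumeration", {
  for (carbons in c(10L, 34L, 42L, 60L)) {
    for (shift in 0:3) {
      expect_equal(isotopologueFraction(carbons, shift),
                   bruteIsotopeFraction(carbons, shift), tolerance = 1e-12)
    }
  }
  expect_equal(isotopologueFraction(42, 0), 1)
  expect_equal(isotopologueFraction(0, 0), 1)
  expect_error(isotopologueFraction(0, 1), "exceeds")
  # monotone in carbons for fixed shift >= 1
  f <- isotopologueFraction(10:80, 3)
  expect_true(all(diff(f) > 0))
})

test_that("isotope correction inverts injected interference exactly", {
  sim <- simulateStudy(smallConfig(seed = 3))
  a0 <- SummarizedExperiment::assay(sim$experiment, "areas")
  injected <- injectIsotopeInterference(sim$experiment)
  a1 <- SummarizedExperiment::assay(injected, "areas")
  pairs <- smPcPairs(defaultLipidPanel())
  expect_true(all(a1[pairs$pc, ] > a0[pairs$pc, ], na.rm = TRUE))
  back <- SummarizedExperiment::assay(correctIsotopeOverlap(injected), "areas")
  expect_identical(is.na(back), is.na(a0))   # censoring mask untouched
  expect_lt(max(abs(back / a0 - 1), na.rm = TRUE), 1e-9)
})

test_that("correction never increases areas, floors at zero, skips others", {
  m <- matrix(c(100, 5, 50), nrow = 3,
              dimnames = list(c("SM 34:1", "PC 30:0", "PE 34:1"), "s1"))
  out <- correctIsotopeOverlap(m)
  r3 <- isotopologueFraction(34, 3)
  expect_equal(out["PC 30:0", 1], max(5 - r3 * 100, 0))
  expect_equal(out["SM 34:1", 1], 100)   # interferent untouched
  expect_equal(out["PE 34:1", 1], 50)    # non-PC untouched
  expect_true(all(out <= m))
  # r3 * SM exceeding the PC area floors at zero
  m2 <- m; m2["SM 34:1", 1] <- 1e6
  expect_equal(correctIsotopeOverlap(m2)["PC 30:0", 1], 0)
  # empty pairing: identity
  m3 <- m[c("PE 34:1", "PC 30:0"), , drop = FALSE]
  expect_identical(injectIsotopeInterference(m3), m3)
  expect_identical(correctIsotopeOverlap(m3), m3)
  # zero SM area leaves the paired PC unchanged
  m4 <- m; m4["SM 34:1", 1] <- 0
  expect_equal(correctIsotopeOverlap(m4)["PC 30:0", 1], 5)
  # explicit pair not in the panel errors with the species name
  expect_error(correctIsotopeOverlap(m3, pairs = data.frame(
    sm = "SM 34:1", pc = "PC 30:0")), "SM 34:1")
})

test_that("ISTD normalization is ratio x spike with the cross-class map", {
  map <- defaultIstdMap()
  areas <- matrix(c(2e4, 4e4, 1e4), nrow = 3,
                  dimnames = list(c("DAG 36:2", "TAG 48:2", "PC 34:1"), "s1"))
  ist <- matrix(c(2e4, 1e4, 5e3), nrow = 3,
                dimnames = list(c("TAG 48:0 d5", "TAG 17:0_17:0_17:0",
                                  "PC 13:0_13:0"), "s1"))
  conc <- normalizeToIstd(areas, istdMap = map, istdAreas = ist)
  # lipid area equal to its standard's area -> concentration = spike
  spike <- setNames(map$spike_amount, map$lipid_class)
  expect_equal(conc["DAG 36:2", 1], unname(spike["DAG"]))  # DAG / TAG 48:0 d5
  expect_equal(conc["TAG 48:2", 1], 4 * unname(spike["TAG"]))
  expect_equal(conc["PC 34:1", 1], 2 * unname(spike["PC"]))
  # linearity: doubling a lipid area doubles its concentration
  areas2 <- areas; areas2["PC 34:1", 1] <- 2 * areas["PC 34:1", 1]
  expect_equal(normalizeToIstd(areas2, map, ist)["PC 34:1", 1],
               2 * conc["PC 34:1", 1])
  # scale equivariance in the sample
  conc_k <- normalizeToIstd(3.7 * areas, map, 3.7 * ist)
  expect_equal(conc_k, conc)
  # zero ISTD area names the affected sample
  ist0 <- ist; ist0["PC 13:0_13:0", 1] <- 0
  expect_error(normalizeToIstd(areas, map, ist0), "s1")
  # missing input areas stay missing
  areas_na <- areas; areas_na["PC 34:1", 1] <- NA
  expect_true(is.na(normalizeToIstd(areas_na, map, ist)["PC 34:1", 1]))
})

test_that("spike recovery arithmetic and replicate CV", {
  stds <- sprintf("STD%02d", 1:3)
  neat <- matrix(1000, 3, 6, dimnames = list(stds, NULL))
  unspiked <- matrix(100, 3, 6, dimnames = list(stds, NULL))
  spiked <- matrix(100 + c(900, 850, 700), 3, 6, dimnames = list(stds, NULL))
  rec <- computeRecovery(spiked, unspiked, neat)
  expect_equal(rec$per_standard$recovery_pct, c(90, 85, 70))
  expect_equal(rec$per_standard$cv_pct, c(0, 0, 0))
  expect_equal(rec$mean_recovery_pct, mean(c(90, 85, 70)))
  expect_error(computeRecovery(spiked[, 1, drop = FALSE],
                               unspiked[, 1, drop = FALSE],
                               neat[, 1, drop = FALSE]), "replicates")
  neat0 <- neat; neat0[1, ] <- 0
  expect_error(computeRecovery(spiked, unspiked, neat0), "STD01")
})

test_that("the shipped recovery fixture averages near the expected 88%", {
  path <- system.file("extdata", "synthetic_recovery_replicates.csv",
                      package = "milkvar")
  df <- read.csv(path, stringsAsFactors = FALSE)
  split_mat <- function(cond) {
    sub <- df[df$condition == cond, ]
    m <- as.matrix(sub[, grep("^rep", colnames(sub))])
    rownames(m) <- sub$standard
    m
  }
  rec <- computeRecovery(split_mat("spiked"), split_mat("unspiked"),
                         split_mat("neat"))
  expect_equal(nrow(rec$per_standard), 12L)
  expect_equal(rec$mean_recovery_pct, 88, tolerance = 0.02)
  # lysolipid recoveries are the low outliers but reproducible
  lyso <- rec$per_standard[grepl("^LP", rec$per_standard$standard), ]
  expect_true(all(lyso$recovery_pct < 85))
  expect_true(all(lyso$cv_pct < 10))
})
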