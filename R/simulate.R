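.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# lognormal multiplier with unit mean and the given CV (fraction)
.technicalNoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

#' Default 237-species lipid panel
#'
#' Thirteen classes mirroring a targeted human-milk panel: 108 TAGs and 20
#' DAGs (neutral lipids measured by direct infusion) plus 109 phospholipid
#' and sphingolipid species (reversed-phase MRM), including 22 SMs whose
#' M+3 isotopologues can overlap panel PCs.
#'
#' @return data.frame as returned by [parseLipidNames()].
#' @export
defaultLipidPanel <- function() {
  tag <- expand.grid(c = seq(34, 60, by = 2), d = 0:7)
  tag <- tag[!(paste(tag$c, tag$d) %in%
                 c("34 5", "34 6", "34 7", "36 7")), ]
  tag <- sprintf("TAG %d:%d", tag$c, tag$d)
  dag <- expand.grid(c = c(32, 34, 36, 38), d = 0:4)
  dag <- sprintf("DAG %d:%d", dag$c, dag$d)
  sm <- sprintf("SM %s", c("34:1", "34:2", "36:0", "36:1", "36:2", "37:1",
                           "38:0", "38:1", "38:2", "39:1", "40:0", "40:1",
                           "40:2", "40:3", "41:1", "41:2", "42:1", "42:2",
                           "43:1", "43:2", "44:1", "44:2"))
  pc <- sprintf("PC %s", c("30:0", "32:0", "32:1", "32:2", "34:0", "34:1",
                           "34:2", "34:3", "36:0", "36:1", "36:2", "36:3",
                           "36:4", "38:2", "38:3", "38:4", "38:5", "38:6",
                           "40:4", "40:5", "40:6", "40:7", "42:5", "42:6"))
  pe <- sprintf("PE %s", c("32:0", "32:1", "32:2", "34:0", "34:1", "34:2",
                           "36:1", "36:2", "36:3", "36:4", "38:1", "38:2",
                           "38:3", "38:4", "38:5", "38:6", "40:2", "40:4",
                           "40:6", "40:7"))
  pi <- sprintf("PI %s", c("34:1", "34:2", "36:1", "36:2", "36:4", "38:4"))
  ps <- sprintf("PS %s", c("36:1", "36:2", "38:4", "40:5", "40:6"))
  lpc <- sprintf("LPC %s", c("14:0", "16:0", "16:1", "18:0", "18:1", "18:2",
                             "20:1", "22:5"))
  lpe <- sprintf("LPE %s", c("16:0", "18:0", "18:1", "18:2", "20:1", "22:1",
                             "22:6"))
  cer <- sprintf("Cer d18:1/%s", c("16:0", "18:0", "20:0", "22:0", "23:0",
                                   "24:0", "24:1"))
  cer <- c(cer, "Cer d18:2/24:0")
  h1 <- sprintf("Hex1Cer %s", c("d18:1/16:0", "d18:1/22:0", "d18:1/24:0",
                                "d18:1/24:1", "d18:2/22:0"))
  h2 <- sprintf("Hex2Cer %s", c("d18:1/16:0", "d18:1/24:1"))
  gm3 <- sprintf("GM3 %s", c("d18:1/18:0", "d18:1/22:0"))
  parseLipidNames(c(tag, dag, pc, pe, pi, ps, lpc, lpe, sm, cer, h1, h2, gm3))
}

#' Default per-class generative parameters
#'
#' Class mean concentrations span the orders of magnitude separating
#' neutral from polar milk lipids (TAG/DAG far above phospholipids and
#' sphingolipids, in arbitrary relative-concentration units).  Per-class
#' intraclass correlations, biological CVs, evening fold-changes and
#' technical CVs are set to the operating points characteristic of a
#' 20-donor morning/evening milk collection: ICC 0.35-0.74, technical CV
#' 5-21%, evening increases up to ~1.5-fold for PE and TAG, neutral-lipid
#' biological CVs around 80-100% versus 30-40% for polar classes.
#'
#' @return data.frame with one row per class: \code{lipid_class},
#'   \code{mean_conc}, \code{bio_cv} (fraction), \code{icc},
#'   \code{evening_fold}, \code{tech_cv_pct}.
#' @export
defaultClassParams <- function() {
  data.frame(
    lipid_class  = c("TAG", "DAG", "PC", "PE", "PI", "PS", "LPC", "LPE",
                     "SM", "Cer", "Hex1Cer", "Hex2Cer", "GM3"),
    mean_conc    = c(2000, 150, 10, 5, 2, 1.5, 1, 0.5,
                     8, 1, 0.8, 0.3, 0.5),
    bio_cv       = c(0.80, 0.95, 0.34, 0.35, 0.35, 0.40, 0.35, 0.38,
                     0.31, 0.40, 0.40, 0.60, 0.35),
    icc          = c(0.48, 0.74, 0.53, 0.55, 0.56, 0.49, 0.70, 0.72,
                     0.49, 0.61, 0.68, 0.46, 0.35),
    evening_fold = c(1.40, 1.05, 1.15, 1.50, 1.25, 1.15, 1.05, 1.10,
                     1.10, 1.05, 1.10, 1.10, 1.25),
    tech_cv_pct  = c(10, 6.5, 10, 8, 9, 10, 15, 7, 12, 10, 8, 11, 15),
    stringsAsFactors = FALSE)
}

#' Configuration of a synthetic morning/evening milk study
#'
#' Bundles the study design (subjects, two counterbalanced time points),
#' the lipid panel, the per-class generative parameters, the technical QC
#' layout, the dilution series and the censoring model into a validated
#' config object from which all simulation draws flow deterministically.
#'
#' @param n_subjects number of donors (>= 2), default 20.
#' @param timepoints ordered pair of time-of-day labels.
#' @param lipid_panel species table from [parseLipidNames()] /
#'   [defaultLipidPanel()].
#' @param class_params per-class generative parameters, see
#'   [defaultClassParams()]; must cover every class in the panel and have
#'   positive means, non-negative varito (via \code{bio_cv}, \code{icc})
#'   and positive \code{evening_fold}.
#' @param istd_map internal-standard map, see [defaultIstdMap()].
#' @param censor_quantile left-censoring probability: a study value is
#'   recorded missing when its latent biological (subject + residual)
#'   Gaussian score falls in this lowest quantile of the lipid's
#'   distribution; the default 4.2e-4 yields ~4 expected missing values
#'   across a 237 x 40 study table.
#' @param n_tqc,n_bqc,n_blank numbers of technical QC, batch QC and blank
#'   injections (\code{n_tqc >= 2}).
#' @param dilution_levels strictly increasing positive volume fractions of
#'   the standard extraction volume, analysed in duplicate.
#' @param bqc_cv_ratio multiplier on the technical CV for batch QCs
#'   (independently extracted, so noisier; must be >= 1).
#' @param extraction_cv_pct per-sample extraction-efficiency CV; applies
#'   equally to endogenous species and internal standards, so it cancels
#'   under normalization.
#' @param saturation detector saturation area (response is divided by
#'   \code{1 + area / saturation}); \code{Inf} disables it.
#' @param lognormal_biology simulate subject and residual effects on the
#'   log scale instead of the default additive-Normal concentration scale
#'   (robustness switch).
#' @param floor_frac truncation floor for Normal concentration draws, as a
#'   fraction of the lipid mean.
#' @param seed integer seed fixing every downstream draw.
#' @return A validated list of class \code{"milkvar_study_config"}.
#' @export
studyConfig <- function(n_subjects = 20,
                        timepoints = c("morning", "evening"),
                        lipid_panel = defaultLipidPanel(),
                        class_params = defaultClassParams(),
                        istd_map = defaultIstdMap(),
                        censor_quantile = 4.2e-4,
                        n_tqc = 5, n_bqc = 8, n_blank = 2,
                        dilution_levels = c(0.4, 0.6, 0.8, 1.0, 1.2, 1.6),
                        bqc_cv_ratio = 1.3,
                        extraction_cv_pct = 8,
                        saturation = Inf,
                        lognormal_biology = FALSE,
                        floor_frac = 1e-9,
                        seed = 1L) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  stopifnot(length(timepoints) == 2L, is.data.frame(lipid_panel))
  class_params <- as.data.frame(class_params)
  need <- c("lipid_class", "mean_conc", "bio_cv", "icc", "evening_fold",
            "tech_cv_pct")
  if (!all(need %in% colnames(class_params)))
    stop("class_params needs columns: ", paste(need, collapse = ", "))
  unmapped <- setdiff(unique(lipid_panel$lipid_class), class_params$lipid_class)
  if (length(unmapped))
    stop("class_params missing class(es): ", paste(unmapped, collapse = ", "))
  if (any(class_params$mean_conc <= 0))
    stop("class mean concentrations must be positive")
  if (any(class_params$bio_cv < 0) || any(class_params$icc < 0) ||
      any(class_params$icc > 1))
    stop("bio_cv must be >= 0 and icc in [0, 1] (variances must be >= 0)")
  if (any(class_params$evening_fold <= 0))
    stop("evening_fold must be > 0")
  if (any(class_params$tech_cv_pct < 0))
    stop("tech_cv_pct must be >= 0")
  if (n_tqc < 2)
    stop("n_tqc must be >= 2 (replicate CV is undefined otherwise)")
  if (any(dilution_levels <= 0) || is.unsorted(dilution_levels, strictly = TRUE))
    stop("dilution_levels must be positive and strictly increasing")
  if (bqc_cv_ratio < 1) stop("bqc_cv_ratio must be >= 1")
  if (censor_quantile < 0 || censor_quantile >= 0.5)
    stop("censor_quantile must be in [0, 0.5)")
  structure(list(
    n_subjects = as.integer(n_subjects), timepoints = timepoints,
    lipid_panel = lipid_panel, class_params = class_params,
    istd_map = .checkIstdMap(istd_map, unique(lipid_panel$lipid_class)),
    censor_quantile = censor_quantile,
    n_tqc = as.integer(n_tqc), n_bqc = as.integer(n_bqc),
    n_blank = as.integer(n_blank),
    dilution_levels = dilution_levels, bqc_cv_ratio = bqc_cv_ratio,
    extraction_cv_pct = extraction_cv_pct, saturation = saturation,
    lognormal_biology = lognormal_biology, floor_frac = floor_frac,
    seed = as.integer(seed)),
    class = "milkvar_study_config")
}

# per-lipid generative parameters derived from the class table:
# lipid means fan out deterministically within a class (geometric spread),
# variances split total biological variance by the class ICC so every
# lipid inherits its class's true ICC.
.lipidTruth <- function(config) {
  panel <- config$lipid_panel
  cp <- config$class_params
  idx <- match(panel$lipid_class, cp$lipid_class)
  w <- numeric(nrow(panel))
  for (cl in unique(panel$lipid_class)) {
    ii <- which(panel$lipid_class == cl)
    w[ii] <- if (length(ii) == 1L) 1
             else exp(seq(log(2.5), log(0.3), length.out = length(ii)))
  }
  mean_j <- cp$mean_conc[idx] * w
  tot_var <- (cp$bio_cv[idx] * mean_j)^2
  data.frame(name = panel$name, lipid_class = panel$lipid_class,
             mean_conc = mean_j,
             sigma2_bs = cp$icc[idx] * tot_var,
             sigma2_ws = (1 - cp$icc[idx]) * tot_var,
             icc = ifelse(tot_var > 0, cp$icc[idx], 0),
             evening_fold = cp$evening_fold[idx],
             tech_cv_pct = cp$tech_cv_pct[idx],
             stringsAsFactors = FALSE)
}

# nominal internal-standard areas: one arbitrary instrument response per
# standard, constant across the run before extraction noise
.istdNominal <- function(istd_map) {
  stds <- unique(istd_map$standard_name)
  setNames(rep(1e5, length(stds)), stds)
}

# concentrations -> raw areas under the generative response model
# (response factor 1): area = conc * istd_area / spike
.areasFromConc <- function(conc, istd_area_mat, istd_map, panel,
                           saturation = Inf) {
  idx <- match(panel$lipid_class, istd_map$lipid_class)
  std_of <- istd_map$standard_name[idx]
  spike <- istd_map$spike_amount[idx]
  a <- conc * istd_area_mat[std_of, , drop = FALSE] / spike
  if (is.finite(saturation)) a <- a / (1 + a / saturation)
  a
}

#' Generate a synthetic morning/evening milk study
#'
#' Draws one biological study per config: for lipid \eqn{j}, subject
#' \eqn{i} and time point \eqn{t},
#' \deqn{y_{ijt} = \mu_j + \beta_j \, 1[t = \mathrm{evening}] + b_{ij} +
#'   e_{ijt}}
#' on the concentration scale, with \eqn{b_{ij} \sim N(0, \sigma^2_{BS,j})},
#' \eqn{e_{ijt} \sim N(0, \sigma^2_{WS,j})} and
#' \eqn{\beta_j = (\mathrm{fold}_j - 1)\mu_j} (a multiplicative evening
#' effect applied before noise); draws are truncated at a small positive
#' floor.  Concentrations are converted to raw peak areas through the
#' internal-standard response model, multiplied by lognormal technical
#' noise at the class technical CV, and left-censored (recorded as
#' \code{NA}) when the latent biological draw falls in the lowest
#' \code{censor_quantile} of the lipid's distribution.  Collection order
#' (morning-first / evening-first) is counterbalanced across subjects.
#'
#' @param config a [studyConfig()].
#' @return list with \code{experiment} (a
#'   \linkS4class{LipidomicsExperiment} of raw areas with
#'   internal-standard areas attached), \code{truth} (list: per-lipid
#'   \code{lipids} table with true \code{sigma2_bs}, \code{sigma2_ws},
#'   \code{icc}, \code{evening_fold}; \code{concentrations}, the
#'   noise-free lipids x samples matrix; \code{pooled}, per-lipid pooled
#'   mean concentrations) and \code{config}.  The truth is kept out of all
#'   pipeline input files.
#' @examples
#' sim <- simulateStudy(studyConfig(n_subjects = 6, seed = 7))
#' dim(sim$experiment)
#' @export
simulateStudy <- function(config) {
  stopifnot(inherits(config, "milkvar_study_config"))
  m <- config$n_subjects
  tp <- config$timepoints
  truth <- .lipidTruth(config)
  nlip <- nrow(truth)
  if (m %% 2L == 1L)
    warning("odd n_subjects: order counterbalance is unequal by one")
  .withSeed(config$seed, {
    perm <- sample.int(m)
    orders <- character(m)
    orders[perm] <- rep_len(c("morning-first", "evening-first"), m)
    subj <- sprintf("S%02d", seq_len(m))
    meta <- data.frame(
      sample_id = as.vector(t(outer(subj, c("M", "E"), paste0))),
      subject_id = rep(subj, each = 2L),
      timepoint = rep(tp, times = m),
      order = rep(orders, each = 2L),
      role = "study", volume_fraction = NA_real_,
      stringsAsFactors = FALSE)
    ns <- nrow(meta)
    evening <- as.numeric(meta$timepoint == tp[2])
    beta <- (truth$evening_fold - 1) * truth$mean_conc
    zb <- matrix(rnorm(nlip * m), nlip, m)[, match(meta$subject_id, subj),
                                           drop = FALSE]
    ze <- matrix(rnorm(nlip * ns), nlip, ns)
    if (config$lognormal_biology) {
      # lognormal alternative: same per-lipid biological CVs on the
      # multiplicative scale, unit-mean factors
      sb <- sqrt(log(1 + truth$sigma2_bs / truth$mean_conc^2))
      sw <- sqrt(log(1 + truth$sigma2_ws / truth$mean_conc^2))
      conc <- (truth$mean_conc * truth$evening_fold^rep(evening, each = nlip)) *
        exp(zb * sb - sb^2 / 2 + ze * sw - sw^2 / 2)
    } else {
      conc <- truth$mean_conc + outer(beta, evening) +
        zb * sqrt(truth$sigma2_bs) + ze * sqrt(truth$sigma2_ws)
      conc <- pmax(conc, config$floor_frac * truth$mean_conc)
    }
    dimnames(conc) <- list(truth$name, meta$sample_id)
    # extraction factor per sample rides on endogenous AND standard areas
    extr <- .technicalNoise(ns, config$extraction_cv_pct / 100)
    nominal <- .istdNominal(config$istd_map)
    ist <- outer(nominal, extr)
    colnames(ist) <- meta$sample_id
    areas <- .areasFromConc(conc, ist, config$istd_map, truth,
                            saturation = config$saturation)
    tech <- matrix(0, nlip, ns)
    for (k in seq_len(nlip))
      tech[k, ] <- .technicalNoise(ns, truth$tech_cv_pct[k] / 100)
    areas <- areas * tech
    # left-censoring: a value is missing when its latent biological draw
    # falls in the lowest censor_quantile of the lipid's distribution
    # (the combined subject + residual Gaussian score), so the censoring
    # probability is exactly censor_quantile for every lipid
    if (config$censor_quantile > 0) {
      s_tot <- sqrt(truth$sigma2_bs + truth$sigma2_ws)
      zc <- (zb * sqrt(truth$sigma2_bs) + ze * sqrt(truth$sigma2_ws)) /
        ifelse(s_tot > 0, s_tot, Inf)
      areas[zc < qnorm(config$censor_quantile)] <- NA_real_
    }
    exp <- LipidomicsExperiment(areas, meta, istdAreas = ist,
                                samplesAsRows = FALSE)
    list(experiment = exp,
         truth = list(lipids = truth, concentrations = conc,
                      pooled = rowMeans(conc)),
         config = config)
  })
}

#' Generate QC injections for a synthetic study
#'
#' Adds the quality-control layer around a generated study: \code{n_tqc}
#' technical QCs (replicate injections of one pooled extract -- only
#' injection noise at the class technical CV), \code{n_bqc} batch QCs
#' (independently extracted pooled aliquots -- technical noise inflated by
#' \code{bqc_cv_ratio} plus extraction noise), a duplicated dilution
#' series whose response is proportional to the volume fraction (with an
#' optional saturation knob), and near-zero blanks.
#'
#' @param config the [studyConfig()] used for the study.
#' @param truth the \code{truth} element returned by [simulateStudy()].
#' @return A \linkS4class{LipidomicsExperiment} of QC injections with
#'   internal-standard areas attached.
#' @export
simulateQcSeries <- function(config, truth) {
  stopifnot(inherits(config, "milkvar_study_config"),
            is.list(truth), !is.null(truth$pooled))
  lt <- truth$lipids
  nlip <- nrow(lt)
  pooled <- truth$pooled
  dil <- rep(config$dilution_levels, each = 2L)
  meta <- data.frame(
    sample_id = c(sprintf("TQC%02d", seq_len(config$n_tqc)),
                  sprintf("BQC%02d", seq_len(config$n_bqc)),
                  sprintf("DIL%02d", seq_along(dil)),
                  sprintf("BLK%02d", seq_len(config$n_blank))),
    subject_id = NA_character_, timepoint = NA_character_,
    order = NA_character_,
    role = c(rep("tqc", config$n_tqc), rep("bqc", config$n_bqc),
             rep("dilution", length(dil)), rep("blank", config$n_blank)),
    volume_fraction = c(rep(NA_real_, config$n_tqc + config$n_bqc), dil,
                        rep(NA_real_, config$n_blank)),
    stringsAsFactors = FALSE)
  ns <- nrow(meta)
  .withSeed(config$seed + 1L, {
    vf <- ifelse(is.na(meta$volume_fraction), 1, meta$volume_fraction)
    conc <- outer(pooled, vf)
    conc[, meta$role == "blank"] <- 0
    dimnames(conc) <- list(lt$name, meta$sample_id)
    # one shared extract for all TQCs; fresh extraction elsewhere
    extr <- .technicalNoise(ns, config$extraction_cv_pct / 100)
    extr[meta$role == "tqc"] <- .technicalNoise(1, config$extraction_cv_pct / 100)
    nominal <- .istdNominal(config$istd_map)
    ist <- outer(nominal, extr)
    colnames(ist) <- meta$sample_id
    areas <- .areasFromConc(conc, ist, config$istd_map, lt,
                            saturation = config$saturation)
    for (k in seq_len(nlip)) {
      cv <- lt$tech_cv_pct[k] / 100
      noise <- .technicalNoise(ns, cv)
      bq <- meta$role == "bqc"
      noise[bq] <- .technicalNoise(sum(bq), cv * config$bqc_cv_ratio)
      areas[k, ] <- areas[k, ] * noise
    }
    blank <- meta$role == "blank"
    if (any(blank)) {
      base <- 2e-3 * rowMeans(.areasFromConc(
        matrix(pooled, nlip, 1, dimnames = list(lt$name, "p")),
        matrix(nominal, length(nominal), 1,
               dimnames = list(names(nominal), "p")),
        config$istd_map, lt))
      areas[, blank] <- base * matrix(.technicalNoise(nlip * sum(blank), 0.5),
                                      nlip, sum(blank))
    }
    LipidomicsExperiment(areas, meta, istdAreas = ist, samplesAsRows = FALSE)
  })
}

#' One-call synthetic dataset: study + isotope interference + QC
#'
#' Convenience wrapper chaining [simulateStudy()],
#' [injectIsotopeInterference()] (structural SM/PC pairs) and
#' [simulateQcSeries()] into a single combined experiment.
#'
#' @param config a [studyConfig()].
#' @param interference inject SM M+3 interference into the raw areas
#'   (default TRUE), to be undone downstream by [correctIsotopeOverlap()].
#' @return list(\code{experiment}, \code{truth}, \code{config}) where the
#'   experiment holds study and QC injections.
#' @export
simulateDataset <- function(config, interference = TRUE) {
  sim <- simulateStudy(config)
  study <- sim$experiment
  qc <- simulateQcSeries(config, sim$truth)
  if (interference) {
    study <- injectIsotopeInterference(study)
    qc <- injectIsotopeInterference(qc)
  }
  combined <- cbind(study, qc)
  S4Vectors::metadata(combined)$istd_areas <-
    cbind(istdAreas(study), istdAreas(qc))
  list(experiment = methods::new("LipidomicsExperiment", combined),
       truth = sim$truth, config = config)
}
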