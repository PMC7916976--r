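#' Pipeline configuration
#'
#' Validated bundle of everything one end-to-end run needs: either a
#' [studyConfig()] to simulate from, or paths to an areas CSV, a sample
#' metadata CSV and an internal-standard areas CSV; plus QC thresholds,
#' the imputation seed and model options.  Unknown options are rejected.
#'
#' @param study a [studyConfig()] (simulated input), or \code{NULL} to
#'   read files.
#' @param areas_path,samples_path,istd_areas_path input CSVs when
#'   \code{study} is \code{NULL}.
#' @param istd_map class-to-standard map, see [defaultIstdMap()].
#' @param out_dir output directory for all artifacts.
#' @param cv_max,snr_min,r2_min QC thresholds (all positive), see
#'   [applyQcFilters()].
#' @param impute_seed seed for [qrilcImpute()].
#' @param interference when simulating, inject SM M+3 interference (to be
#'   removed by the correction stage).
#' @param paired_fold fold-change convention, see [medianFoldChange()].
#' @param df_method denominator df convention, see [fixedEffectFTest()].
#' @param k_rank size of the most/least variable rankings.
#' @return list of class \code{"milkvar_pipeline_config"}.
#' @export
pipelineConfig <- function(study = NULL, areas_path = NULL,
                           samples_path = NULL, istd_areas_path = NULL,
                           istd_map = defaultIstdMap(), out_dir = tempdir(),
                           cv_max = 20, snr_min = 10, r2_min = 0.85,
                           impute_seed = 17L, interference = TRUE,
                           paired_fold = TRUE,
                           df_method = "containment", k_rank = 20L) {
  if (is.null(study) &&
      (is.null(areas_path) || is.null(samples_path) ||
       is.null(istd_areas_path)))
    stop("either a studyConfig or all three input paths are required")
  if (!is.null(study)) stopifnot(inherits(study, "milkvar_study_config"))
  stopifnot(cv_max > 0, snr_min > 0, r2_min > 0)
  structure(list(study = study, areas_path = areas_path,
                 samples_path = samples_path,
                 istd_areas_path = istd_areas_path, istd_map = istd_map,
                 out_dir = out_dir, cv_max = cv_max, snr_min = snr_min,
                 r2_min = r2_min, impute_seed = as.integer(impute_seed),
                 interference = interference, paired_fold = paired_fold,
                 df_method = df_method, k_rank = as.integer(k_rank)),
            class = "milkvar_pipeline_config")
}

.fileDigest <- function(path) {
  # content digest without external dependencies: size + sum of bytes
  b <- readBin(path, "raw", n = file.size(path))
  sprintf("size=%d;sum=%.0f", length(b), sum(as.integer(b)))
}

#' Run the full post-processing pipeline
#'
#' Orchestrates the stages in study order: simulate (or load) raw areas,
#' correct isotopologue overlap, normalize to internal standards, compute
#' and apply QC filters, impute left-censored missing values, fit the
#' per-lipid and per-class variance-components models, and summarise
#' biological variability and fold changes.  Every stage writes its CSV
#' artifact under \code{out_dir}; a JSON run report records inputs,
#' content digests, seeds, thresholds and the package version so a run
#' can be reproduced exactly.  Identical config and seed give
#' byte-identical outputs.
#'
#' @param config a [pipelineConfig()].
#' @param verbose print a line per stage.
#' @return invisibly, a list with the in-memory results (\code{experiment},
#'   \code{kept}, \code{variance_species}, \code{variance_class},
#'   \code{summary}, \code{report}).
#' @export
runPipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "milkvar_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  say <- function(...) if (verbose) message("[milkvar] ", ...)
  stage <- "input"
  res <- tryCatch({
    if (!is.null(config$study)) {
      say("simulate")
      sim <- simulateDataset(config$study, interference = config$interference)
      exp <- sim$experiment
      writeAbundanceTable(SummarizedExperiment::assay(exp, "areas"),
                          out("areas.csv"), samplesAsRows = FALSE)
      write.csv(data.frame(SummarizedExperiment::colData(exp)),
                out("samples.csv"), row.names = FALSE)
      writeIstdAreas(istdAreas(exp), out("istd_areas.csv"))
      truth <- sim$truth$lipids
      jsonlite::write_json(truth, out("truth.json"), digits = NA)
      inputs <- character(0)
    } else {
      say("load")
      areas <- readAbundanceTable(config$areas_path)
      md <- readSampleMetadata(config$samples_path)
      ist <- readIstdAreas(config$istd_areas_path)
      exp <- LipidomicsExperiment(areas, md, istdAreas = ist)
      inputs <- c(config$areas_path, config$samples_path,
                  config$istd_areas_path)
    }
    stage <- "quantify"
    say(stage)
    exp <- correctIsotopeOverlap(exp)
    exp <- normalizeToIstd(exp, istdMap = config$istd_map)
    writeAbundanceTable(SummarizedExperiment::assay(exp, "concentrations"),
                        out("concentrations.csv"), samplesAsRows = FALSE)
    stage <- "qc_filter"
    say(stage)
    qcm <- computeQcMetrics(exp, istdMap = config$istd_map)
    filt <- applyQcFilters(qcm, cv_max = config$cv_max,
                           snr_min = config$snr_min, r2_min = config$r2_min)
    write.csv(qcm, out("qc_metrics.csv"), row.names = FALSE)
    write.csv(filt$audit, out("qc_audit.csv"), row.names = FALSE)
    writeLines(filt$kept, out("kept_lipids.txt"))
    exp <- exp[filt$kept, ]
    stage <- "impute"
    say(stage)
    exp <- qrilcImpute(exp, seed = config$impute_seed)
    writeAbundanceTable(
      SummarizedExperiment::assay(studySamples(exp), "concentrations"),
      out("completed.csv"), samplesAsRows = FALSE)
    stage <- "variance_model"
    say(stage)
    vs <- fitVariancePanel(exp, level = "species")
    vc <- fitVariancePanel(exp, level = "class")
    write.csv(vs, out("variance_species.csv"), row.names = FALSE)
    write.csv(vc, out("variance_class.csv"), row.names = FALSE)
    stage <- "summarize"
    say(stage)
    sm <- variabilitySummary(exp, qcMetrics = qcm,
                             paired = config$paired_fold)
    write.csv(sm, out("biological_cv.csv"), row.names = FALSE)
    write.csv(sm[, c("lipid", "fold_change")], out("fold_changes.csv"),
              row.names = FALSE)
    k <- min(config$k_rank, nrow(sm))
    write.csv(rankVariability(sm, k, "most"), out("top_most_variable.csv"),
              row.names = FALSE)
    write.csv(rankVariability(sm, k, "least"), out("top_least_variable.csv"),
              row.names = FALSE)
    list(experiment = exp, qc_metrics = qcm, kept = filt$kept,
         variance_species = vs, variance_class = vc, summary = sm,
         inputs = inputs)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  arts <- list.files(config$out_dir, pattern = "\\.(csv|txt|json)$",
                     full.names = TRUE)
  arts <- arts[basename(arts) != "run_report.json"]
  report <- list(
    package_version = as.character(utils::packageVersion("milkvar")),
    simulated = !is.null(config$study),
    seed = if (!is.null(config$study)) config$study$seed else NULL,
    impute_seed = config$impute_seed,
    thresholds = list(cv_max = config$cv_max, snr_min = config$snr_min,
                      r2_min = config$r2_min),
    df_method = config$df_method,
    inputs = if (length(res$inputs)) res$inputs else NULL,
    n_kept = length(res$kept),
    artifacts = setNames(lapply(arts, .fileDigest), basename(arts)))
  jsonlite::write_json(report, out("run_report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  res$report <- report
  invisible(res)
}
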