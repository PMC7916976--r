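#' Replicate coefficient of variation (%)
#'
#' \code{100 * sd / mean} over replicate injections of the same material.
#' Scale-invariant; the CV of a constant series is 0.
#'
#' @param values numeric vector of >= 2 finite positive-mean replicates.
#' @return CV in percent.
#' @export
technicalCV <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need >= 2 finite replicate values")
  m <- mean(values)
  if (m <= 0) stop("replicate mean must be positive")
  100 * sd(values) / m
}

#' Dilution-series linearity
#'
#' Ordinary least-squares regression of instrument response on the volume
#' fraction of the extracted sample.  Duplicate injections at a volume
#' enter as individual points.  Returns the coefficient of determination,
#' slope and intercept.
#'
#' @param volume_fractions numeric, >= 3 distinct levels.
#' @param responses numeric responses, same length.
#' @return list(\code{r2}, \code{slope}, \code{intercept});
#'   \code{r2} is clamped to \[0, 1\] and is \code{NA} if fewer than 3
#'   finite points remain.
#' @export
linearityFit <- function(volume_fractions, responses) {
  stopifnot(length(volume_fractions) == length(responses))
  ok <- is.finite(volume_fractions) & is.finite(responses)
  x <- volume_fractions[ok]; y <- responses[ok]
  if (length(unique(x)) < 2L)
    stop("all volume fractions identical: no regression possible")
  if (length(unique(x)) < 3L)
    stop("need >= 3 distinct volume levels")
  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(r2 = min(max(r2, 0), 1),
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
}

#' Signal-to-noise against blank injections
#'
#' Estimated as \code{mean(analyte) / (mean(blank) + 3 * sd(blank))}, the
#' analyte response relative to the blank background plus three standard
#' deviations of it; the denominator is floored at \code{epsilon}.  The
#' estimator is deliberately pluggable (vendor software defines S/N on the
#' chromatographic peak, which is out of scope here).
#'
#' @param analyte_values analyte responses (>= 1), typically batch-QC
#'   injections.
#' @param blank_values blank responses (>= 2).
#' @param epsilon denominator floor, default 1.
#' @return the S/N ratio.
#' @export
signalToNoise <- function(analyte_values, blank_values, epsilon = 1) {
  analyte_values <- analyte_values[is.finite(analyte_values)]
  blank_values <- blank_values[is.finite(blank_values)]
  if (length(analyte_values) < 1L) stop("need >= 1 analyte value")
  if (length(blank_values) < 2L) stop("need >= 2 blank values")
  mean(analyte_values) /
    max(mean(blank_values) + 3 * sd(blank_values), epsilon)
}

#' Per-lipid QC metrics from a run's QC injections
#'
#' Computes, for every panel lipid: TQC and BQC replicate CVs (on
#' internal-standard normalized concentrations when available, so that
#' extraction efficiency cancels), S/N of the BQC response against blanks
#' (on raw areas), and dilution-series linearity of raw areas on volume
#' fraction.
#'
#' @param x a \linkS4class{LipidomicsExperiment} containing injections
#'   with roles \code{tqc}, \code{bqc}, \code{blank} and \code{dilution}.
#' @param istdMap map used to normalize QC injections if the
#'   \code{"concentrations"} assay is absent.
#' @param epsilon S/N denominator floor, see [signalToNoise()].
#' @return data.frame, one row per lipid: \code{name}, \code{tqc_cv_pct},
#'   \code{bqc_cv_pct}, \code{snr}, \code{linearity_r2},
#'   \code{linearity_slope}.
#' @export
computeQcMetrics <- function(x, istdMap = defaultIstdMap(), epsilon = 1) {
  stopifnot(methods::is(x, "SummarizedExperiment"))
  roles <- sampleRoles(x)
  areas <- SummarizedExperiment::assay(x, "areas")
  conc <- if ("concentrations" %in% SummarizedExperiment::assayNames(x)) {
    SummarizedExperiment::assay(x, "concentrations")
  } else if (!is.null(istdAreas(x))) {
    normalizeToIstd(areas, istdMap = istdMap, istdAreas = istdAreas(x))
  } else areas
  need <- c("tqc", "bqc", "blank", "dilution")
  absent <- setdiff(need, roles)
  if (length(absent))
    stop("QC role(s) missing from the experiment: ",
         paste(absent, collapse = ", "))
  vf <- SummarizedExperiment::colData(x)$volume_fraction[roles == "dilution"]
  dil <- areas[, roles == "dilution", drop = FALSE]
  blk <- areas[, roles == "blank", drop = FALSE]
  bqc_a <- areas[, roles == "bqc", drop = FALSE]
  res <- lapply(seq_len(nrow(x)), function(k) {
    lin <- tryCatch(linearityFit(vf, dil[k, ]),
                    error = function(e) list(r2 = NA_real_, slope = NA_real_))
    data.frame(
      name = rownames(x)[k],
      tqc_cv_pct = tryCatch(technicalCV(conc[k, roles == "tqc"]),
                            error = function(e) NA_real_),
      bqc_cv_pct = tryCatch(technicalCV(conc[k, roles == "bqc"]),
                            error = function(e) NA_real_),
      snr = tryCatch(signalToNoise(bqc_a[k, ], blk[k, ], epsilon = epsilon),
                     error = function(e) NA_real_),
      linearity_r2 = lin$r2, linearity_slope = lin$slope,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Apply the panel inclusion criteria
#'
#' A lipid is kept only if all criteria hold with strict inequalities:
#' TQC CV and BQC CV both \code{< cv_max}, S/N \code{> snr_min} and
#' dilution linearity R-squared \code{> r2_min}.  A lipid sitting exactly
#' on a boundary is excluded, and a missing metric fails its criterion.
#' Relaxing any threshold can only grow the kept set.
#'
#' @param metrics data.frame from [computeQcMetrics()].
#' @param cv_max,snr_min,r2_min thresholds; defaults 20 (%), 10, 0.85.
#' @return list with \code{kept} (character vector of kept lipid names)
#'   and \code{audit} (data.frame: per-lipid pass flags
#'   \code{pass_cv}, \code{pass_snr}, \code{pass_r2}, overall \code{keep},
#'   and \code{failed_criteria} naming every violated criterion).
#' @export
applyQcFilters <- function(metrics, cv_max = 20, snr_min = 10,
                           r2_min = 0.85) {
  stopifnot(all(c("name", "tqc_cv_pct", "bqc_cv_pct", "snr",
                  "linearity_r2") %in% colnames(metrics)))
  stopifnot(cv_max > 0, snr_min > 0, r2_min > 0)
  ok <- function(x) !is.na(x)
  pass_cv <- ok(metrics$tqc_cv_pct) & ok(metrics$bqc_cv_pct) &
    metrics$tqc_cv_pct < cv_max & metrics$bqc_cv_pct < cv_max
  pass_snr <- ok(metrics$snr) & metrics$snr > snr_min
  pass_r2 <- ok(metrics$linearity_r2) & metrics$linearity_r2 > r2_min
  keep <- pass_cv & pass_snr & pass_r2
  failed <- mapply(function(a, b, c) {
    paste(c(if (!a) "cv", if (!b) "snr", if (!c) "r2"), collapse = ";")
  }, pass_cv, pass_snr, pass_r2)
  audit <- data.frame(name = metrics$name, pass_cv = pass_cv,
                      pass_snr = pass_snr, pass_r2 = pass_r2,
                      keep = keep, failed_criteria = failed,
                      stringsAsFactors = FALSE)
  list(kept = metrics$name[keep], audit = audit)
}
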