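#' Biological coefficient of variation (%)
#'
#' \code{100 * sd / mean} of a lipid's concentration across participants
#' at one time point: the between-donor spread at that collection time,
#' on the concentration scale, unit-free.
#'
#' @param values per-subject concentrations at one time point (>= 2).
#' @return CV in percent.
#' @export
biologicalCV <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need >= 2 subjects")
  m <- mean(values)
  if (m <= 0) stop("mean concentration must be positive")
  100 * sd(values) / m
}

#' Median evening/morning fold change
#'
#' Pairs each subject's evening and morning concentrations and returns
#' the median of the per-subject ratios (\code{paired = TRUE}, the
#' default, which respects the within-subject design), or the ratio of
#' the cohort medians (\code{paired = FALSE}).
#'
#' @param evening,morning per-subject concentrations, aligned by subject
#'   (same order); pairs with a missing or non-positive member are
#'   dropped.
#' @param paired median of ratios (TRUE) vs ratio of medians (FALSE).
#' @return the fold change (positive scalar).
#' @export
medianFoldChange <- function(evening, morning, paired = TRUE) {
  stopifnot(length(evening) == length(morning))
  ok <- is.finite(evening) & is.finite(morning) & evening > 0 & morning > 0
  if (!any(ok)) stop("no complete positive evening/morning pairs")
  if (paired) median(evening[ok] / morning[ok])
  else median(evening[ok]) / median(morning[ok])
}

#' Per-lipid variability summary of a study
#'
#' Computes, for every lipid, the biological %CV across subjects
#' separately at each time point and the median evening/morning fold
#' change; technical CVs from a QC metrics table can be attached for
#' side-by-side comparison.
#'
#' @param x a \linkS4class{LipidomicsExperiment} (study samples of the
#'   chosen assay are used) or a samples x lipids matrix.
#' @param metadata for the matrix method: data.frame with
#'   \code{sample_id}, \code{subject_id}, \code{timepoint}.
#' @param qcMetrics optional output of [computeQcMetrics()]; its TQC CV is
#'   attached as \code{tech_cv_pct}.
#' @param assay assay name for the experiment method.
#' @param paired fold-change convention, see [medianFoldChange()].
#' @return data.frame: \code{lipid}, \code{cv_morning}, \code{cv_evening},
#'   \code{fold_change}, and \code{tech_cv_pct} when QC metrics are given.
#' @export
setGeneric("variabilitySummary",
           function(x, metadata = NULL, qcMetrics = NULL,
                    assay = "concentrations", paired = TRUE)
             standardGeneric("variabilitySummary"))

#' @rdname variabilitySummary
setMethod("variabilitySummary", "matrix",
          function(x, metadata = NULL, qcMetrics = NULL,
                   assay = "concentrations", paired = TRUE) {
  stopifnot(!is.null(metadata),
            all(c("sample_id", "subject_id", "timepoint") %in%
                  colnames(metadata)))
  md <- as.data.frame(metadata)
  md <- md[match(rownames(x), md$sample_id), , drop = FALSE]
  tps <- unique(md$timepoint)
  stopifnot(length(tps) == 2L)
  morning <- x[md$timepoint == tps[1], , drop = FALSE]
  evening <- x[md$timepoint == tps[2], , drop = FALSE]
  subj_m <- md$subject_id[md$timepoint == tps[1]]
  subj_e <- md$subject_id[md$timepoint == tps[2]]
  evening <- evening[match(subj_m, subj_e), , drop = FALSE]
  out <- data.frame(
    lipid = colnames(x),
    cv_morning = apply(morning, 2, function(v)
      tryCatch(biologicalCV(v), error = function(e) NA_real_)),
    cv_evening = apply(evening, 2, function(v)
      tryCatch(biologicalCV(v), error = function(e) NA_real_)),
    fold_change = vapply(seq_len(ncol(x)), function(j)
      tryCatch(medianFoldChange(evening[, j], morning[, j], paired = paired),
               error = function(e) NA_real_), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(qcMetrics))
    out$tech_cv_pct <- qcMetrics$tqc_cv_pct[match(out$lipid, qcMetrics$name)]
  out
})

#' @rdname variabilitySummary
setMethod("variabilitySummary", "LipidomicsExperiment",
          function(x, metadata = NULL, qcMetrics = NULL,
                   assay = "concentrations", paired = TRUE) {
  st <- studySamples(x)
  variabilitySummary(t(SummarizedExperiment::assay(st, assay)),
                     metadata = data.frame(SummarizedExperiment::colData(st)),
                     qcMetrics = qcMetrics, paired = paired)
})

#' Most / least variable lipids
#'
#' Ranks lipids by biological %CV at one time point and returns the top
#' (\code{direction = "most"}) or bottom (\code{"least"}) \code{k}, each
#' row carrying its technical CV for comparison when available.  Ties are
#' broken lexicographically by lipid name, so rankings are deterministic.
#'
#' @param summary output of [variabilitySummary()].
#' @param k number of lipids to return (<= panel size).
#' @param direction \code{"most"} or \code{"least"} variable.
#' @param timepoint \code{"morning"} or \code{"evening"} CV column.
#' @return data.frame of \code{k} rows: \code{rank}, \code{lipid},
#'   \code{cv_pct}, and \code{tech_cv_pct} when present.
#' @export
rankVariability <- function(summary, k = 20, direction = c("most", "least"),
                            timepoint = c("morning", "evening")) {
  direction <- match.arg(direction)
  timepoint <- match.arg(timepoint)
  cvcol <- paste0("cv_", timepoint)
  stopifnot(cvcol %in% colnames(summary), k <= nrow(summary))
  cv <- summary[[cvcol]]
  ord <- order(if (direction == "most") -cv else cv, summary$lipid,
               na.last = TRUE)
  sel <- head(ord, k)
  out <- data.frame(rank = seq_len(k), lipid = summary$lipid[sel],
                    cv_pct = cv[sel], stringsAsFactors = FALSE)
  if ("tech_cv_pct" %in% colnames(summary))
    out$tech_cv_pct <- summary$tech_cv_pct[sel]
  out
}
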