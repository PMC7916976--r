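#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importMethodsFrom SummarizedExperiment assay "assay<-" assayNames
#'   rowData colData cbind
#' @importFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors metadata "metadata<-" DataFrame
#' @importFrom stats coef dbinom lm median optimize pf pnorm qnorm quantile
#'   rnorm runif sd setNames uniroot var
#' @importFrom utils head read.csv write.csv
NULL

#' LipidomicsExperiment: container for a milk lipidomics run
#'
#' A \linkS4class{SummarizedExperiment} with lipid species as rows and
#' injections as columns.  \code{rowData} carries the parsed species
#' identity (\code{lipid_class}, \code{carbons}, \code{double_bonds});
#' \code{colData} carries the study design (\code{subject_id},
#' \code{timepoint}, \code{order}) and the injection \code{role}
#' (\code{study}, \code{tqc}, \code{bqc}, \code{blank}, \code{dilution})
#' plus \code{volume_fraction} for dilution-series injections.  Internal
#' standard areas, when present, live in
#' \code{metadata(x)$istd_areas} (standards x samples matrix).
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @aliases LipidomicsExperiment-class
#' @exportClass LipidomicsExperiment
setClass("LipidomicsExperiment",
         contains = "SummarizedExperiment")

.VALID_ROLES <- c("study", "tqc", "bqc", "blank", "dilution")

setValidity("LipidomicsExperiment", function(object) {
  msg <- character(0)
  rd <- SummarizedExperiment::rowData(object)
  need_rd <- c("lipid_class", "carbons", "double_bonds")
  if (!all(need_rd %in% colnames(rd)))
    msg <- c(msg, paste("rowData must contain:", paste(need_rd, collapse = ", ")))
  cd <- SummarizedExperiment::colData(object)
  if (!"role" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'role' column")
  } else if (!all(cd$role %in% .VALID_ROLES)) {
    msg <- c(msg, paste("role must be one of:", paste(.VALID_ROLES, collapse = ", ")))
  }
  if (all(c("role", "subject_id", "timepoint") %in% colnames(cd))) {
    st <- cd[cd$role == "study", , drop = FALSE]
    if (nrow(st) && anyDuplicated(paste(st$subject_id, st$timepoint)))
      msg <- c(msg, "a subject may have at most one study sample per timepoint")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LipidomicsExperiment
#'
#' @param areas numeric matrix, samples in rows and lipids in columns (the
#'   orientation of a wide abundance CSV), or lipids x samples if
#'   \code{samplesAsRows = FALSE}.  \code{NA} encodes a missing
#'   (censored or unintegrated) peak.
#' @param sampleInfo \code{data.frame} with one row per sample:
#'   \code{sample_id}, \code{role}, and for study samples
#'   \code{subject_id}, \code{timepoint}, \code{order};
#'   \code{volume_fraction} for dilution injections.
#' @param istdAreas optional matrix of internal-standard areas
#'   (standards x samples).
#' @param assayName name of the stored assay, default \code{"areas"}.
#' @param samplesAsRows orientation flag for \code{areas}.
#' @return A \linkS4class{LipidomicsExperiment}.
#' @examples
#' sim <- simulateStudy(studyConfig(n_subjects = 4, seed = 1))
#' sim$experiment
#' @export
LipidomicsExperiment <- function(areas, sampleInfo, istdAreas = NULL,
                                 assayName = "areas", samplesAsRows = TRUE) {
  if (samplesAsRows) areas <- t(as.matrix(areas)) else areas <- as.matrix(areas)
  if (is.null(rownames(areas)))
    stop("lipid names are required as dimnames of 'areas'")
  sampleInfo <- as.data.frame(sampleInfo)
  if (!"sample_id" %in% colnames(sampleInfo))
    stop("sampleInfo must have a sample_id column")
  if (anyDuplicated(sampleInfo$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sampleInfo$sample_id[duplicated(sampleInfo$sample_id)]),
               collapse = ", "))
  if (ncol(areas) != nrow(sampleInfo))
    stop("areas and sampleInfo disagree on the number of samples")
  colnames(areas) <- sampleInfo$sample_id
  rd <- parseLipidNames(rownames(areas))
  md <- list()
  if (!is.null(istdAreas)) {
    istdAreas <- as.matrix(istdAreas)
    if (ncol(istdAreas) != ncol(areas))
      stop("istdAreas must have one column per sample")
    colnames(istdAreas) <- colnames(areas)
    md$istd_areas <- istdAreas
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = setNames(list(areas), assayName),
    rowData = S4Vectors::DataFrame(rd[, c("lipid_class", "carbons",
                                          "double_bonds", "isotope_label")]),
    colData = S4Vectors::DataFrame(sampleInfo, row.names = sampleInfo$sample_id),
    metadata = md)
  methods::new("LipidomicsExperiment", se)
}

#' @describeIn LipidomicsExperiment parsed species table (name, class,
#'   carbons, double bonds) as a base data.frame.
#' @param x a \code{LipidomicsExperiment}.
#' @export
lipidPanel <- function(x) {
  stopifnot(methods::is(x, "SummarizedExperiment"))
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  data.frame(name = rownames(x), rd, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @describeIn LipidomicsExperiment injection roles, named by sample.
#' @export
sampleRoles <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  setNames(as.character(cd$role), rownames(cd))
}

#' @describeIn LipidomicsExperiment subset to biological study samples.
#' @export
studySamples <- function(x) x[, sampleRoles(x) == "study"]

#' @describeIn LipidomicsExperiment internal-standard area matrix
#'   (standards x samples), or NULL.
#' @export
istdAreas <- function(x) S4Vectors::metadata(x)$istd_areas

setMethod("show", "LipidomicsExperiment", function(object) {
  callNextMethod()
  role <- table(SummarizedExperiment::colData(object)$role)
  cat("roles:", paste(names(role), role, sep = "=", collapse = " "), "\n")
  cls <- table(SummarizedExperiment::rowData(object)$lipid_class)
  cat("classes:", paste(names(cls), cls, sep = "=", collapse = " "), "\n")
})

#' VarianceComponentsFit: REML fit of the random-intercept model
#'
#' Result of [fitRandomIntercept()]: between-participant variance
#' \code{sigma2_bs}, within-participant (residual) variance
#' \code{sigma2_ws}, the standard error of \code{sigma2_bs} from the
#' observed information of the restricted likelihood, fixed-effect
#' estimates with their GLS standard errors, the restricted log-likelihood
#' at the optimum, and bookkeeping (boundary flag, convergence, counts).
#'
#' @aliases VarianceComponentsFit-class
#' @exportClass VarianceComponentsFit
setClass("VarianceComponentsFit",
         representation(sigma2_bs = "numeric", sigma2_ws = "numeric",
                        se_sigma2_bs = "numeric",
                        beta = "numeric", se_beta = "numeric",
                        reml_loglik = "numeric",
                        n_obs = "integer", n_subjects = "integer",
                        terms = "character",
                        boundary = "logical", degenerate = "logical",
                        convergence = "list"))

setValidity("VarianceComponentsFit", function(object) {
  msg <- character(0)
  if (length(object@sigma2_bs) != 1L || object@sigma2_bs < 0)
    msg <- c(msg, "sigma2_bs must be a single value >= 0")
  if (length(object@sigma2_ws) != 1L || object@sigma2_ws < 0)
    msg <- c(msg, "sigma2_ws must be a single value >= 0")
  if (!object@degenerate && !is.finite(object@reml_loglik))
    msg <- c(msg, "reml_loglik must be finite for a non-degenerate fit")
  if (length(object@beta) != length(object@se_beta))
    msg <- c(msg, "beta and se_beta lengths differ")
  if (length(msg)) msg else TRUE
})

setMethod("show", "VarianceComponentsFit", function(object) {
  cat("VarianceComponentsFit (", object@n_obs, " obs, ",
      object@n_subjects, " subjects)\n", sep = "")
  cat(sprintf("  sigma2_bs = %.6g (se %.4g)%s\n", object@sigma2_bs,
              object@se_sigma2_bs,
              if (object@boundary) " [boundary]" else ""))
  cat(sprintf("  sigma2_ws = %.6g\n", object@sigma2_ws))
  cat(sprintf("  ICC       = %.4f\n",
              object@sigma2_bs / (object@sigma2_bs + object@sigma2_ws)))
  cat("  fixed effects:\n")
  print(round(rbind(estimate = object@beta, se = object@se_beta), 5))
})

#' @describeIn VarianceComponentsFit between-participant variance.
#' @param fit a \code{VarianceComponentsFit}.
#' @export
sigma2Between <- function(fit) fit@sigma2_bs

#' @describeIn VarianceComponentsFit within-participant variance.
#' @export
sigma2Within <- function(fit) fit@sigma2_ws

#' @describeIn VarianceComponentsFit named fixed-effect estimates.
#' @export
fixedEffects <- function(fit) fit@beta
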