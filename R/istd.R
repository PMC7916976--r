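#' Default internal-standard map
#'
#' One spiked, class-specific synthetic or isotope-labeled standard per
#' lipid class.  Two cross-class assignments are used deliberately:
#' DAGs are normalized to the d5-labeled TAG 48:0 standard and
#' dihexosylceramides to the glucosyl C8 ceramide (a Hex1Cer) standard,
#' because no well-behaved in-class standard is available for those
#' classes.  Spike amounts are in arbitrary relative-concentration units
#' per sample; resulting concentrations inherit these units.
#'
#' @return \code{data.frame} with columns \code{lipid_class},
#'   \code{standard_name}, \code{spike_amount}, \code{units}.
#' @export
defaultIstdMap <- function() {
  data.frame(
    lipid_class = c("TAG", "DAG", "PC", "PE", "PI", "PS", "LPC", "LPE",
                    "SM", "Cer", "Hex1Cer", "Hex2Cer", "GM3"),
    standard_name = c("TAG 17:0_17:0_17:0", "TAG 48:0 d5",
                      "PC 13:0_13:0", "PE 14:0_14:0", "PI 12:0_13:0",
                      "PS 14:0_14:0", "LPC 13:0", "LPE 14:0",
                      "SM d18:1/6:0", "Cer d18:1/17:0",
                      "Hex1Cer d18:1/8:0", "Hex1Cer d18:1/8:0",
                      "GM3 d18:1/18:0 d3"),
    spike_amount = c(100, 20, 10, 10, 5, 5, 2, 2, 10, 2, 1, 1, 1),
    units = "rel.units",
    stringsAsFactors = FALSE)
}

.checkIstdMap <- function(istdMap, classes) {
  istdMap <- as.data.frame(istdMap)
  need <- c("lipid_class", "standard_name", "spike_amount")
  if (!all(need %in% colnames(istdMap)))
    stop("istdMap needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(istdMap$lipid_class))
    stop("istdMap maps a class more than once")
  unmapped <- setdiff(classes, istdMap$lipid_class)
  if (length(unmapped))
    stop("no internal standard mapped for class(es): ",
         paste(unmapped, collapse = ", "))
  if (any(!is.finite(istdMap$spike_amount) | istdMap$spike_amount <= 0))
    stop("spike amounts must be positive")
  istdMap
}

#' Internal-standard normalization to relative concentrations
#'
#' Converts peak areas to relative concentrations:
#' \deqn{c_{ls} = \frac{A_{ls}}{A_{\mathrm{ISTD}(class(l)),s}} \times
#'   \mathrm{spike}(class(l))}
#' i.e. each endogenous lipid is divided by the area of its class's
#' internal standard in the same sample and scaled by the spiked amount.
#' Missing input areas stay missing.  Normalization is scale-equivariant:
#' multiplying all areas of a sample (endogenous and standards) by any
#' positive factor leaves concentrations unchanged.
#'
#' @param x a \linkS4class{LipidomicsExperiment} carrying
#'   internal-standard areas, or a lipids x samples area matrix.
#' @param istdMap class-to-standard map, see [defaultIstdMap()].
#' @param istdAreas standards x samples matrix (required for the matrix
#'   method; taken from the object otherwise).
#' @return Same type as \code{x}; the experiment method adds a
#'   \code{"concentrations"} assay.
#' @export
setGeneric("normalizeToIstd",
           function(x, istdMap = defaultIstdMap(), istdAreas = NULL)
             standardGeneric("normalizeToIstd"))

#' @rdname normalizeToIstd
setMethod("normalizeToIstd", "matrix",
          function(x, istdMap = defaultIstdMap(), istdAreas = NULL) {
  if (is.null(istdAreas)) stop("istdAreas is required")
  panel <- parseLipidNames(rownames(x))
  istdMap <- .checkIstdMap(istdMap, unique(panel$lipid_class))
  istdAreas <- as.matrix(istdAreas)
  stds <- unique(istdMap$standard_name[istdMap$lipid_class %in% panel$lipid_class])
  absent <- setdiff(stds, rownames(istdAreas))
  if (length(absent))
    stop("internal standard area(s) missing: ", paste(absent, collapse = ", "))
  bad <- apply(istdAreas[stds, , drop = FALSE], 2,
               function(a) any(!is.finite(a) | a <= 0))
  if (any(bad))
    stop("non-positive internal standard area in sample(s): ",
         paste(colnames(istdAreas)[bad], collapse = ", "))
  idx <- match(panel$lipid_class, istdMap$lipid_class)
  std_of <- istdMap$standard_name[idx]
  spike <- istdMap$spike_amount[idx]
  x / istdAreas[std_of, colnames(x), drop = FALSE] * spike
})

#' @rdname normalizeToIstd
setMethod("normalizeToIstd", "LipidomicsExperiment",
          function(x, istdMap = defaultIstdMap(), istdAreas = NULL) {
  if (is.null(istdAreas)) istdAreas <- S4Vectors::metadata(x)$istd_areas
  if (is.null(istdAreas))
    stop("the experiment carries no internal-standard areas")
  conc <- normalizeToIstd(SummarizedExperiment::assay(x, "areas"),
                          istdMap = istdMap, istdAreas = istdAreas)
  SummarizedExperiment::assay(x, "concentrations") <- conc
  x
})

#' Spike-recovery of lipid standards
#'
#' Standard spike-recovery arithmetic for an extraction method: for each
#' standard, \code{recovery_pct = 100 * (mean(spiked) - mean(unspiked)) /
#' mean(neat)}, where \emph{spiked} is matrix spiked with the standard
#' before extraction, \emph{unspiked} is the same matrix extracted without
#' the spike (endogenous background), and \emph{neat} is the standard in
#' neat solvent (no matrix, no extraction loss).  Replicate precision is
#' \code{cv_pct = 100 * sd / mean} over the spiked replicates.
#'
#' @param spiked,unspiked,neat numeric matrices, standards x replicates
#'   (>= 2 replicates each), with standard names as rownames.
#' @return list with \code{per_standard} (data.frame: standard,
#'   recovery_pct, cv_pct, n_replicates) and \code{mean_recovery_pct}.
#' @export
computeRecovery <- function(spiked, unspiked, neat) {
  spiked <- as.matrix(spiked); unspiked <- as.matrix(unspiked)
  neat <- as.matrix(neat)
  if (min(ncol(spiked), ncol(unspiked), ncol(neat)) < 2L)
    stop("at least 2 replicates per condition are required")
  stds <- rownames(spiked)
  if (is.null(stds)) stop("standard names required as rownames")
  stopifnot(identical(stds, rownames(unspiked)),
            identical(stds, rownames(neat)))
  m_neat <- rowMeans(neat)
  if (any(m_neat <= 0))
    stop("non-positive neat response for: ",
         paste(stds[m_neat <= 0], collapse = ", "))
  m_spk <- rowMeans(spiked)
  rec <- 100 * (m_spk - rowMeans(unspiked)) / m_neat
  cv <- 100 * apply(spiked, 1, sd) / m_spk
  per <- data.frame(standard = stds, recovery_pct = as.numeric(rec),
                    cv_pct = as.numeric(cv), n_replicates = ncol(spiked),
                    row.names = NULL, stringsAsFactors = FALSE)
  list(per_standard = per, mean_recovery_pct = mean(per$recovery_pct))
}
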