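#' Isotopologue abundance relative to the monoisotopic peak
#'
#' Fraction of a lipid's M+\code{shift} isotopologue area relative to its
#' monoisotopic (M+0) area under a carbon-only binomial model: each of the
#' \code{carbons} carbon atoms is independently \eqn{^{13}}C with
#' probability \code{p13c}, so the ratio is
#' \eqn{\mathrm{Binom}(k; n, p) / \mathrm{Binom}(0; n, p)}.
#' Contributions of \eqn{^{2}}H, \eqn{^{15}}N and \eqn{^{18}}O are ignored:
#' for M+3 overlap arithmetic the three-heavy-carbon term dominates and is
#' fully determined by the carbon count.
#'
#' @param carbons non-negative integer carbon count (vectorised).
#' @param shift non-negative integer isotopologue shift; must not exceed
#'   \code{carbons}.
#' @param p13c natural \eqn{^{13}}C abundance, default 0.0107.
#' @return numeric in \[0, 1\]: the M+shift : M+0 area ratio.
#' @examples
#' isotopologueFraction(34, 3)   # M+3 of SM 34:1
#' @export
isotopologueFraction <- function(carbons, shift, p13c = 0.0107) {
  stopifnot(is.numeric(carbons), is.numeric(shift),
            all(carbons >= 0), all(shift >= 0),
            p13c > 0, p13c < 0.5)
  if (any(shift > carbons))
    stop("shift exceeds the carbon count")
  dbinom(shift, size = carbons, prob = p13c) /
    dbinom(0, size = carbons, prob = p13c)
}

.resolvePairs <- function(lipids, pairs) {
  if (is.null(pairs)) pairs <- smPcPairs(lipids)
  pairs <- as.data.frame(pairs)
  missing <- setdiff(c(pairs$sm, pairs$pc), lipids)
  if (length(missing))
    stop("species not in panel: ", paste(missing, collapse = ", "))
  parsed <- parseLipidNames(pairs$sm)
  pc <- parseLipidNames(pairs$pc)
  bad <- pc$carbons != parsed$carbons - 4L | pc$double_bonds != parsed$double_bonds - 1L
  if (any(bad))
    stop("pair(s) violate the X-4 : Y-1 relation: ",
         paste(pairs$sm[bad], "->", pairs$pc[bad], collapse = ", "))
  pairs$sm_carbons <- parsed$carbons
  pairs
}

#' Subtract M+3 interference from overlapped PC peaks
#'
#' For every SM X:Y in the panel whose M+3 isotopologue is isobaric with a
#' panel PC (X-4):(Y-1), the PC area is corrected as
#' \code{area(PC) - r3 * area(SM)} with \code{r3 =}
#' [isotopologueFraction()]\code{(carbons(SM), 3)}, floored at zero.  When
#' the object carries internal-standard areas and the panel contains
#' \code{"GM3 d18:1/18:0"} whose M+3 overlaps the d3-labeled GM3 standard,
#' the standard's area is corrected identically.  All other species are
#' untouched.  Single-pass: already-corrected tables are corrected again
#' only if interferent areas are non-zero.
#'
#' @param x a \linkS4class{LipidomicsExperiment} (assay \code{"areas"}) or
#'   a lipids x samples numeric matrix.
#' @param pairs optional \code{data.frame(sm, pc)} overriding the
#'   structurally derived pairing ([smPcPairs()]).
#' @param p13c carbon-13 abundance passed to [isotopologueFraction()].
#' @param r3 optional numeric vector overriding the theoretical M+3
#'   fraction, one value per pair (recycled).
#' @param verbose log skipped SM species and floored corrections.
#' @return An object of the same type with corrected areas; the input is
#'   not modified.
#' @export
setGeneric("correctIsotopeOverlap",
           function(x, pairs = NULL, p13c = 0.0107, r3 = NULL,
                    verbose = FALSE)
             standardGeneric("correctIsotopeOverlap"))

#' @rdname correctIsotopeOverlap
setMethod("correctIsotopeOverlap", "matrix",
          function(x, pairs = NULL, p13c = 0.0107, r3 = NULL,
                   verbose = FALSE) {
  pr <- .resolvePairs(rownames(x), pairs)
  if (!nrow(pr)) return(x)
  frac <- if (is.null(r3)) isotopologueFraction(pr$sm_carbons, 3L, p13c)
          else rep_len(r3, nrow(pr))
  out <- x
  for (j in seq_len(nrow(pr))) {
    sub <- frac[j] * x[pr$sm[j], ]
    corr <- x[pr$pc[j], ] - ifelse(is.na(sub), 0, sub)
    floored <- !is.na(corr) & corr < 0
    if (any(floored) && verbose)
      message("correctIsotopeOverlap: ", pr$pc[j], " floored at 0 in ",
              sum(floored), " sample(s)")
    corr[floored] <- 0
    out[pr$pc[j], ] <- corr
  }
  out
})

#' @rdname correctIsotopeOverlap
setMethod("correctIsotopeOverlap", "LipidomicsExperiment",
          function(x, pairs = NULL, p13c = 0.0107, r3 = NULL,
                   verbose = FALSE) {
  a <- SummarizedExperiment::assay(x, "areas")
  SummarizedExperiment::assay(x, "areas") <-
    correctIsotopeOverlap(a, pairs = pairs, p13c = p13c, r3 = r3,
                          verbose = verbose)
  ist <- istdAreas(x)
  if (!is.null(ist) && "GM3 d18:1/18:0" %in% rownames(a) &&
      "GM3 d18:1/18:0 d3" %in% rownames(ist)) {
    carb <- parseLipidNames("GM3 d18:1/18:0")$carbons
    f <- isotopologueFraction(carb, 3L, p13c)
    gm3 <- a["GM3 d18:1/18:0", ]
    gm3[is.na(gm3)] <- 0   # censored endogenous peak contributes nothing
    corr <- ist["GM3 d18:1/18:0 d3", ] - f * gm3
    ist["GM3 d18:1/18:0 d3", ] <- pmax(corr, 0)
    S4Vectors::metadata(x)$istd_areas <- ist
  }
  methods::validObject(x)
  x
})

#' Inject M+3 interference into a clean area table
#'
#' Inverse of [correctIsotopeOverlap()], used by the synthetic study
#' generator: each paired PC area is incremented by
#' \code{r3(SM) * area(SM)}.  Round-tripping injection then correction
#' restores the original areas to numerical precision.
#'
#' @inheritParams correctIsotopeOverlap
#' @return Object of the same type with interference added; the input is
#'   not modified.
#' @export
setGeneric("injectIsotopeInterference",
           function(x, pairs = NULL, p13c = 0.0107)
             standardGeneric("injectIsotopeInterference"))

#' @rdname injectIsotopeInterference
setMethod("injectIsotopeInterference", "matrix",
          function(x, pairs = NULL, p13c = 0.0107) {
  pr <- .resolvePairs(rownames(x), pairs)
  if (!nrow(pr)) return(x)
  frac <- isotopologueFraction(pr$sm_carbons, 3L, p13c)
  out <- x
  for (j in seq_len(nrow(pr))) {
    add <- frac[j] * x[pr$sm[j], ]
    out[pr$pc[j], ] <- x[pr$pc[j], ] + ifelse(is.na(add), 0, add)
  }
  out
})

#' @rdname injectIsotopeInterference
setMethod("injectIsotopeInterference", "LipidomicsExperiment",
          function(x, pairs = NULL, p13c = 0.0107) {
  a <- SummarizedExperiment::assay(x, "areas")
  SummarizedExperiment::assay(x, "areas") <-
    injectIsotopeInterference(a, pairs = pairs, p13c = p13c)
  x
})
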