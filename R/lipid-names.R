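#' Lipid classes covered by the panel
#'
#' The thirteen lipid classes quantifiable by the workflow: the neutral
#' glycerolipids (TAG, DAG) and the phospholipid / sphingolipid classes
#' (PC, PE, PI, PS, LPC, LPE, SM, Cer, Hex1Cer, Hex2Cer, GM3).
#'
#' @return Character vector of class labels.
#' @export
lipidClasses <- function() {
  c("TAG", "DAG", "PC", "PE", "PI", "PS", "LPC", "LPE",
    "SM", "Cer", "Hex1Cer", "Hex2Cer", "GM3")
}

#' Parse canonical lipid species names
#'
#' Accepts the shorthand used in targeted lipidomics panels:
#' sum-composition names (\code{"PC 34:1"}, \code{"TAG 48:0"}),
#' sphingoid-resolved names (\code{"Hex2Cer d18:1/16:0"},
#' \code{"GM3 d18:1/22:0"}), underscore-separated acyl chains used for
#' synthetic standards (\code{"PC 13:0_13:0"}, \code{"TAG 17:0_17:0_17:0"})
#' and a trailing isotope label (\code{"TAG 48:0 d5"}).  Carbon and
#' double-bond counts are summed over chains; they feed the isotopologue
#' arithmetic and the structural SM/PC pairing.
#'
#' @param x character vector of lipid names.
#' @param strict if \code{TRUE} (default) an unknown class or unparseable
#'   name is an error listing the offenders; otherwise such rows carry
#'   \code{NA}.
#' @return A \code{data.frame} with columns \code{name}, \code{lipid_class},
#'   \code{carbons}, \code{double_bonds}, \code{isotope_label} (0 when
#'   unlabeled).
#' @examples
#' parseLipidNames(c("PC 34:1", "SM 34:1", "Hex2Cer d18:1/16:0", "TAG 48:0 d5"))
#' @export
parseLipidNames <- function(x, strict = TRUE) {
  stopifnot(is.character(x))
  n <- length(x)
  cls <- character(n); carb <- integer(n); db <- integer(n); lab <- integer(n)
  known <- lipidClasses()
  bad <- character(0)
  chain_re <- "^d?([0-9]+):([0-9]+)$"
  for (i in seq_len(n)) {
    nm <- trimws(x[i])
    toks <- strsplit(nm, " +")[[1]]
    ok <- length(toks) >= 2L
    label <- 0L
    if (ok && length(toks) >= 3L && grepl("^d[0-9]+$", toks[length(toks)])) {
      label <- as.integer(sub("^d", "", toks[length(toks)]))
      toks <- toks[-length(toks)]
    }
    ok <- ok && length(toks) == 2L
    if (ok) {
      cls_i <- toks[1]
      chains <- strsplit(toks[2], "[/_]")[[1]]
      ok <- all(grepl(chain_re, chains)) && cls_i %in% known
      if (ok) {
        cs <- as.integer(sub(chain_re, "\\1", chains))
        ds <- as.integer(sub(chain_re, "\\2", chains))
        cls[i] <- cls_i; carb[i] <- sum(cs); db[i] <- sum(ds); lab[i] <- label
        ok <- carb[i] > 0L
      }
    }
    if (!ok) {
      bad <- c(bad, x[i])
      cls[i] <- NA_character_; carb[i] <- NA_integer_; db[i] <- NA_integer_
    }
  }
  if (strict && length(bad))
    stop("unparseable lipid name(s): ", paste(unique(bad), collapse = ", "))
  data.frame(name = x, lipid_class = cls, carbons = carb,
             double_bonds = db, isotope_label = lab,
             stringsAsFactors = FALSE)
}

#' Derive SM -> PC isotopologue interference pairs
#'
#' In positive-mode MRM panels the M+3 isotopologue of SM X:Y overlaps the
#' monoisotopic peak of PC (X-4):(Y-1).  Pairs are derived structurally
#' from the panel names rather than hard-coded, so synthetic panels work.
#'
#' @param panel a \code{data.frame} as returned by [parseLipidNames()] (or a
#'   character vector of names, which is parsed first).
#' @return \code{data.frame} with columns \code{sm} and \code{pc}; zero rows
#'   when the panel contains no matching pair.
#' @export
smPcPairs <- function(panel) {
  if (is.character(panel)) panel <- parseLipidNames(panel)
  sm <- panel[panel$lipid_class == "SM" & panel$isotope_label == 0L, , drop = FALSE]
  pc <- panel[panel$lipid_class == "PC" & panel$isotope_label == 0L, , drop = FALSE]
  if (!nrow(sm) || !nrow(pc))
    return(data.frame(sm = character(0), pc = character(0)))
  key_pc <- paste(pc$carbons, pc$double_bonds)
  key_tg <- paste(sm$carbons - 4L, sm$double_bonds - 1L)
  hit <- match(key_tg, key_pc)
  keep <- !is.na(hit)
  data.frame(sm = sm$name[keep], pc = pc$name[hit[keep]],
             stringsAsFactors = FALSE)
}
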