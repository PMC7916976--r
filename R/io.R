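#' Read a wide abundance table
#'
#' Delimited text, first column \code{sample_id}, remaining columns lipid
#' species (names must parse, see [parseLipidNames()]).  Empty cells and
#' sentinel tokens become missing values.
#'
#' @param path CSV file path.
#' @param sentinels tokens read as missing, default \code{c("NA", "")}.
#' @return numeric samples x lipids matrix with sample ids as rownames
#'   and an \code{NA} entry per missing cell.
#' @export
readAbundanceTable <- function(path, sentinels = c("NA", "")) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character",
                 na.strings = sentinels)
  if (ncol(df) < 2L) stop("expected sample_id plus lipid columns")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate sample_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  parseLipidNames(colnames(df)[-1])   # errors listing offenders
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a wide abundance table
#'
#' Inverse of [readAbundanceTable()]: samples as rows, first column
#' \code{sample_id}, UTF-8, \code{"."} decimal, RFC-4180 quoting.
#' Missing entries are written as empty cells.  The write/read round trip
#' is lossless for finite values and the missingness mask.
#'
#' @param x samples x lipids matrix (or lipids x samples with
#'   \code{samplesAsRows = FALSE}).
#' @param path output CSV path.
#' @param samplesAsRows orientation of \code{x}.
#' @export
writeAbundanceTable <- function(x, path, samplesAsRows = TRUE) {
  if (!samplesAsRows) x <- t(x)
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read sample metadata
#'
#' @param path CSV with columns \code{sample_id}, \code{role} and, for
#'   study samples, \code{subject_id}, \code{timepoint}, \code{order};
#'   \code{volume_fraction} for dilution injections.
#' @return data.frame.
#' @export
readSampleMetadata <- function(path) {
  md <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "role")
  if (!all(need %in% colnames(md)))
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  md
}

#' Read an internal-standard area table
#'
#' @param path CSV, first column \code{standard}, remaining columns one
#'   per sample.
#' @return standards x samples numeric matrix.
#' @export
readIstdAreas <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' @rdname readIstdAreas
#' @param x standards x samples matrix.
#' @export
writeIstdAreas <- function(x, path) {
  df <- data.frame(standard = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
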