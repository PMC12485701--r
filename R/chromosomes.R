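#' Closed chromosome vocabulary
#'
#' Chromosome labels used throughout the package: autosomes "1".."22", "X",
#' "Y", "MT", and "other" for anything that does not normalize into those.
#'
#' @return Character vector of valid labels.
#' @export
chromosomeLevels <- function() c(as.character(1:22), "X", "Y", "MT", "other")

#' Normalize chromosome labels to the closed vocabulary
#'
#' Strips a leading "chr" prefix (any case), upper-cases sex/mito labels, and
#' maps "M"/"MT" to "MT".  Labels that do not resolve to an autosome, X, Y or
#' MT become "other"; missing values also become "other".
#'
#' @param x character vector of raw chromosome labels.
#' @return character vector drawn from [chromosomeLevels()].
#' @examples
#' normalizeChromosome(c("chrX", "X", "x", "chr1", "M", "HG1832"))
#' @export
normalizeChromosome <- function(x) {
  x <- as.character(x)
  x <- sub("^[Cc][Hh][Rr]", "", x)
  x <- toupper(trimws(x))
  x[x == "M"] <- "MT"
  x[is.na(x) | !(x %in% c(as.character(1:22), "X", "Y", "MT"))] <- "other"
  x
}

# Strip Ensembl-style trailing version suffixes ("ENSG00000229807.12" ->
# "ENSG00000229807").  Only ids that look Ensembl-like are touched so that
# plain symbols containing dots survive untouched.
stripGeneVersion <- function(ids) {
  ifelse(grepl("^ENS[A-Z0-9]+\\.[0-9]+$", ids), sub("\\.[0-9]+$", "", ids), ids)
}
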