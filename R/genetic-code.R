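#' The standard genetic code and its synonym families
#'
#' Returns the standard genetic code (translation table 1) as a list of
#' lookup structures used throughout the package: the 64 codon-to-amino-acid
#' assignments, the 61 sense codons, the synonym families \eqn{C_a} grouping
#' the codons of each amino acid \eqn{a}, the family sizes \eqn{k_a}, and the
#' fixed 59-codon feature order used for RSCU vectors.
#'
#' The RSCU feature order is alphabetical by one-letter amino-acid code, then
#' alphabetical by codon within each family, with the two single-codon
#' families (Met/ATG and Trp/TGG) dropped: 61 sense codons minus 2 gives the
#' 59 features. Every consumer of RSCU vectors (the Bayes model, the PCA
#' gate, the DHEG distance) uses this one ordering.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{codonToAa}{named character(64): codon (DNA alphabet) to
#'       one-letter amino acid, with \code{"*"} for the three stop codons.}
#'     \item{senseCodons}{character(61): the sense codons in RSCU order with
#'       ATG and TGG appended at the end.}
#'     \item{families}{named list: amino acid to character vector of its
#'       synonymous codons (alphabetical).}
#'     \item{familySize}{named integer: \eqn{k_a} per amino acid.}
#'     \item{rscuCodons}{character(59): the RSCU feature order.}
#'     \item{rscuAa}{character(59): amino acid of each RSCU feature.}
#'     \item{stopCodons}{character(3).}
#'   }
#' @examples
#' gc <- geneticCode()
#' length(gc$senseCodons)  # 61
#' length(gc$rscuCodons)   # 59
#' gc$familySize[["L"]]    # leucine has 6 synonymous codons
#' @export
geneticCode <- function() {
  .geneticCodeCache()
}

.geneticCodeEnv <- new.env(parent = emptyenv())

.geneticCodeCache <- function() {
  if (!is.null(.geneticCodeEnv$code)) {
    return(.geneticCodeEnv$code)
  }
  codonToAa <- Biostrings::GENETIC_CODE
  stopifnot(length(codonToAa) == 64L)
  sense <- codonToAa[codonToAa != "*"]
  stops <- names(codonToAa)[codonToAa == "*"]
  aaLevels <- sort(unique(unname(sense)))
  families <- lapply(aaLevels, function(a) sort(names(sense)[sense == a]))
  names(families) <- aaLevels
  familySize <- vapply(families, length, integer(1))
  singletons <- names(familySize)[familySize == 1L]  # M and W
  rscuAaOrder <- setdiff(aaLevels, singletons)
  rscuCodons <- unlist(families[rscuAaOrder], use.names = FALSE)
  rscuAa <- rep(rscuAaOrder, familySize[rscuAaOrder])
  senseOrdered <- c(rscuCodons, unlist(families[singletons], use.names = FALSE))
  code <- list(
    codonToAa = codonToAa,
    senseCodons = senseOrdered,
    families = families,
    familySize = familySize,
    rscuCodons = rscuCodons,
    rscuAa = rscuAa,
    stopCodons = stops
  )
  .geneticCodeEnv$code <- code
  code
}

#' @rdname geneticCode
#' @export
rscuCodonOrder <- function() {
  geneticCode()$rscuCodons
}

# one-letter amino-acid alphabet (20 letters)
.aaAlphabet <- function() names(geneticCode()$families)
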