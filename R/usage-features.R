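#' @import methods
#' @importFrom stats prcomp rnorm runif sd quantile shapiro.test wilcox.test
#'   lm coef cor predict dnorm plogis setNames median
#' @importFrom utils write.table read.delim head tail modifyList
#'   packageVersion
NULL

#' UsageReference: codon-usage reference derived from highly expressed genes
#'
#' Holds everything derived from a reference set of highly expressed genes
#' (HEG): pooled sense-codon counts \eqn{o_{ac}}, relative adaptiveness
#' \eqn{w_{ac} = o_{ac} / \max_{c' \in C_a} o_{ac'}} (so the most-used codon
#' of each synonym family has \eqn{w = 1}), and the per-feature mean and
#' standard deviation of the per-gene RSCU vectors.
#'
#' @slot counts named numeric(61): pseudo-counted codon counts pooled over
#'   the reference genes.
#' @slot w named numeric(61): relative adaptiveness, in (0, 1].
#' @slot rscuMean,rscuSd numeric(59): per-feature RSCU mean and (floored)
#'   standard deviation across the reference genes.
#' @slot nGenes number of reference sequences.
#' @slot pseudoCount,sdFloor the regularization constants used.
#' @seealso [buildReference()], [cai()]
#' @export
setClass("UsageReference",
  representation(
    counts = "numeric", w = "numeric",
    rscuMean = "numeric", rscuSd = "numeric",
    nGenes = "integer", pseudoCount = "numeric", sdFloor = "numeric"
  )
)

setValidity("UsageReference", function(object) {
  code <- geneticCode()
  if (length(object@w) != 61L) return("w must have 61 entries")
  fam <- code$codonToAa[names(object@w)]
  mx <- tapply(object@w, fam, max)
  if (any(abs(mx - 1) > 1e-12)) {
    return("max relative adaptiveness within each synonym family must be 1")
  }
  if (any(object@rscuSd < object@sdFloor - 1e-15)) {
    return("rscuSd below the configured floor")
  }
  TRUE
})

setMethod("show", "UsageReference", function(object) {
  cat("UsageReference built from", object@nGenes, "genes\n")
  cat("  pseudo-count:", object@pseudoCount, " sd floor:", object@sdFloor, "\n")
  top <- sort(object@w, decreasing = TRUE)
  cat("  preferred codons (w = 1):",
      sum(abs(object@w - 1) < 1e-12), "of 61\n")
})

#' Accessors for UsageReference
#' @param x a [UsageReference-class].
#' @name UsageReference-accessors
#' @return `relAdaptiveness`: named numeric(61) of \eqn{w_{ac}};
#'   `codonCountsRef`: named numeric(61) of pooled pseudo-counted counts;
#'   `rscuMean`/`rscuSd`: numeric(59).
NULL

#' @rdname UsageReference-accessors
#' @export
relAdaptiveness <- function(x) x@w

#' @rdname UsageReference-accessors
#' @export
codonCountsRef <- function(x) x@counts

#' @rdname UsageReference-accessors
#' @export
rscuMean <- function(x) x@rscuMean

#' @rdname UsageReference-accessors
#' @export
rscuSd <- function(x) x@rscuSd

#' Count sense codons of a gene
#'
#' @param g a [CodingSequence-class].
#' @return Named integer(61) in the package codon order (trailing stop
#'   excluded).
#' @export
codonCounts <- function(g) {
  code <- geneticCode()
  tab <- tabulate(factor(codons(g), levels = code$senseCodons),
                  nbins = 61L)
  names(tab) <- code$senseCodons
  tab
}

#' Build a codon-usage reference from a set of highly expressed genes
#'
#' Codon counts are pooled over all reference sequences and a pseudo-count
#' is added to every sense codon so every \eqn{w_{ac}} is strictly positive
#' (CAI then never hits an exact zero factor). Relative adaptiveness divides
#' each count by the maximum count within its synonym family. The
#' per-feature RSCU mean and standard deviation over the member genes are
#' retained for the Bayes model; standard deviations are floored at
#' `sdFloor` so Gaussian densities stay finite when a small reference set
#' has zero empirical variance on a feature.
#'
#' @param heg list of [CodingSequence-class] (at least 2).
#' @param pseudoCount added to every sense-codon count (default 0.5).
#' @param sdFloor lower bound on the RSCU standard deviations (default 1e-6).
#' @return A [UsageReference-class].
#' @examples
#' set.seed(1)
#' heg <- makeHegSet(synthUsageProfile(skew = 20, seed = 1), nGenes = 20,
#'                   lengthRange = c(50, 80), seed = 2)
#' ref <- buildReference(heg)
#' cai(heg[[1]], ref)
#' @export
buildReference <- function(heg, pseudoCount = 0.5, sdFloor = 1e-6) {
  if (!is.list(heg) || length(heg) < 2L) {
    stop("need at least 2 reference sequences")
  }
  code <- geneticCode()
  countMat <- vapply(heg, codonCounts, numeric(61L))
  counts <- rowSums(countMat) + pseudoCount
  fam <- code$codonToAa[names(counts)]
  famMax <- tapply(counts, fam, max)
  w <- setNames(as.numeric(counts / famMax[fam]), names(counts))
  rs <- rscuMatrix(heg)
  mu <- colMeans(rs)
  sdv <- pmax(apply(rs, 2L, sd), sdFloor)
  new("UsageReference",
      counts = counts, w = w, rscuMean = mu, rscuSd = sdv,
      nGenes = length(heg), pseudoCount = pseudoCount, sdFloor = sdFloor)
}

#' Codon adaptation index
#'
#' \deqn{CAI(g) = \left(\prod_{i=1}^{L(g)} w_{a g_i}\right)^{1/L(g)}}
#' the geometric mean of relative adaptiveness values over all sense codons
#' of the gene (the trailing stop is excluded; Met and Trp codons enter with
#' \eqn{w = 1}). Evaluated in log space so long genes do not underflow.
#' The relative adaptiveness normalizes each codon count by the maximum
#' count within its own synonym family.
#'
#' @param g a [CodingSequence-class].
#' @param ref a [UsageReference-class].
#' @return CAI in (0, 1].
#' @export
cai <- function(g, ref) {
  stopifnot(is(g, "CodingSequence"), is(ref, "UsageReference"))
  lw <- log(ref@w[codons(g)])
  exp(mean(lw))
}

#' Relative synonymous codon usage vector
#'
#' \deqn{r_{ac}(g) = o_{ac}(g) / \left(\frac{1}{k_a}\sum_{c' \in C_a}
#' o_{ac'}(g)\right)}
#' the observed count of each codon divided by its expected count under
#' uniform synonymous usage. Genes map to a 59-dimensional feature vector:
#' the 61 sense codons minus the single-codon families Met and Trp, in a
#' fixed order (alphabetical by amino acid, then codon; see
#' [rscuCodonOrder()]). Features of amino acids absent from the gene are 0
#' (0/0 defined as 0) so vectors stay comparable across genes.
#'
#' @param g a [CodingSequence-class].
#' @return Named numeric(59).
#' @examples
#' r <- rscu(codingSequence("TTTTTTTTTTTC"))  # Phe 3:1
#' r[c("TTC", "TTT")]                         # 0.5, 1.5
#' @export
rscu <- function(g) {
  code <- geneticCode()
  cnt <- codonCounts(g)[code$rscuCodons]
  famTot <- tapply(cnt, code$rscuAa, sum)[code$rscuAa]
  k <- code$familySize[code$rscuAa]
  r <- ifelse(famTot > 0, cnt * k / famTot, 0)
  names(r) <- code$rscuCodons
  r
}

#' RSCU matrix for a set of genes
#'
#' @param genes list of [CodingSequence-class].
#' @return Numeric matrix, one row per gene, 59 columns in the package RSCU
#'   feature order.
#' @export
rscuMatrix <- function(genes) {
  m <- t(vapply(genes, rscu, numeric(59L)))
  colnames(m) <- geneticCode()$rscuCodons
  if (!is.null(names(genes))) rownames(m) <- names(genes)
  m
}

#' GC content of a gene
#'
#' Count of G and C nucleotides divided by the nucleotide length.
#'
#' @param g a [CodingSequence-class] (or a plain nucleotide string).
#' @return Fraction in [0, 1].
#' @export
gcContent <- function(g) {
  s <- if (is(g, "CodingSequence")) ntSequence(g) else canonicalizeNucleotides(g)
  n <- nchar(s)
  gc <- n - nchar(gsub("[GC]", "", s))
  gc / n
}

#' Per-gene feature table
#'
#' @param genes named list of [CodingSequence-class].
#' @param ref a [UsageReference-class].
#' @param rscuCols include the 59 RSCU columns.
#' @return data.frame with columns id, cai, gc (and optionally the RSCU
#'   features).
#' @export
featureTable <- function(genes, ref, rscuCols = FALSE) {
  ids <- names(genes)
  if (is.null(ids)) ids <- sprintf("gene_%03d", seq_along(genes))
  out <- data.frame(
    id = ids,
    cai = vapply(genes, cai, numeric(1), ref = ref),
    gc = vapply(genes, gcContent, numeric(1)),
    row.names = NULL
  )
  if (rscuCols) out <- cbind(out, as.data.frame(rscuMatrix(genes), row.names = NULL))
  out
}
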