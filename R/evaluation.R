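#' MatchCounts: aligned maximal-run match statistics between two redesigns
#'
#' Counts of maximal runs of consecutive identical aligned nucleotides
#' between two equal-length sequences, binned by run length: exactly 6,
#' exactly 7, exactly 8, and 9 or more. Runs shorter than 6 are ignored;
#' the total is the sum of the four bins by construction.
#'
#' @slot n6,n7,n8,n9plus run counts per bin.
#' @seealso [patternMatch()]
#' @export
setClass("MatchCounts",
  representation(n6 = "integer", n7 = "integer", n8 = "integer",
                 n9plus = "integer")
)

setValidity("MatchCounts", function(object) {
  v <- c(object@n6, object@n7, object@n8, object@n9plus)
  if (any(v < 0L)) return("counts must be non-negative")
  TRUE
})

setMethod("show", "MatchCounts", function(object) {
  cat("MatchCounts: 6nt =", object@n6, " 7nt =", object@n7,
      " 8nt =", object@n8, " >=9nt =", object@n9plus,
      " total =", totalMatches(object), "\n")
})

#' @rdname MatchCounts-class
#' @param x a MatchCounts.
#' @return `totalMatches`: the bin sum; `matchBins`: named integer(4).
#' @export
totalMatches <- function(x) x@n6 + x@n7 + x@n8 + x@n9plus

#' @rdname MatchCounts-class
#' @export
matchBins <- function(x) {
  c(n6 = x@n6, n7 = x@n7, n8 = x@n8, n9plus = x@n9plus)
}

#' Pattern matching between two redesigns of the same protein
#'
#' Scans the two equal-length sequences position by position, finds maximal
#' runs of consecutive identical nucleotides, and bins the run lengths
#' (6 / 7 / 8 / >= 9; shorter runs ignored). Symmetric in its arguments.
#'
#' @param a,b [CodingSequence-class] objects (or plain nucleotide strings)
#'   of equal length.
#' @return A [MatchCounts-class].
#' @examples
#' g1 <- "ATGATGATGATG"
#' patternMatch(g1, g1)  # one maximal run of 12 -> the >=9 bin
#' @export
patternMatch <- function(a, b) {
  sa <- if (is(a, "CodingSequence")) ntSequence(a) else canonicalizeNucleotides(a)
  sb <- if (is(b, "CodingSequence")) ntSequence(b) else canonicalizeNucleotides(b)
  if (nchar(sa) != nchar(sb)) {
    stop("sequences must have equal length (", nchar(sa), " vs ", nchar(sb), ")")
  }
  eq <- strsplit(sa, "")[[1L]] == strsplit(sb, "")[[1L]]
  r <- rle(eq)
  runs <- r$lengths[r$values]
  new("MatchCounts",
      n6 = sum(runs == 6L), n7 = sum(runs == 7L),
      n8 = sum(runs == 8L), n9plus = sum(runs >= 9L))
}

#' Wilcoxon signed-rank test with zero-difference removal
#'
#' Paired signed-rank test on `x - y`. Zero differences are dropped (the
#' standard convention); if every difference is zero the p-value is 1. The
#' exact null distribution is used for n <= 25 when the absolute
#' differences are untied, otherwise the normal approximation with
#' continuity correction.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return list(p.value, statistic, n) where n counts the nonzero
#'   differences.
#' @export
wilcoxonSignedRank <- function(x, y) {
  if (length(x) != length(y)) stop("unpaired samples: lengths differ")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(p.value = 1, statistic = NA_real_, n = 0L))
  exact <- n <= 25L && !any(duplicated(abs(d)))
  wt <- suppressWarnings(wilcox.test(d, mu = 0, exact = exact, correct = TRUE))
  list(p.value = wt$p.value, statistic = unname(wt$statistic), n = n)
}

.describe <- function(v) {
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  c(mean = mean(v), sd = sd(v), q1 = q[1], median = q[2], q3 = q[3])
}

#' Compare optimized gene sets against a reference design
#'
#' Computes CAI and GC per gene for each method's redesigns and for the
#' reference set, then reports: descriptive statistics (mean, sd,
#' quartiles) with a within-5\%-of-reference flag on each value,
#' Shapiro-Wilk normality p-values per sample, and the paired Wilcoxon
#' signed-rank p-value of each method's CAI (and GC) against the reference
#' (pairing by position: gene i of each set must redesign the same
#' protein).
#'
#' @param geneSets named list; each element a list of
#'   [CodingSequence-class] redesigns (>= 3 genes, all sets the same
#'   length, paired with `referenceSet`).
#' @param referenceSet list of [CodingSequence-class]: the designs compared
#'   against.
#' @param ref a [UsageReference-class] for CAI.
#' @return A list of class `ComparisonReport`: `descriptives` (long
#'   data.frame with a `within5pct` flag), `normality`, `wilcoxon`,
#'   `features` (per-gene feature table).
#' @export
compareMethods <- function(geneSets, referenceSet, ref) {
  if (is.null(names(geneSets)) || any(!nzchar(names(geneSets)))) {
    stop("geneSets must be a named list")
  }
  nRef <- length(referenceSet)
  for (nm in names(geneSets)) {
    if (length(geneSets[[nm]]) < 3L) stop("set '", nm, "' has fewer than 3 genes")
    if (length(geneSets[[nm]]) != nRef) {
      stop("set '", nm, "' is not paired with the reference (",
           length(geneSets[[nm]]), " vs ", nRef, " genes)")
    }
  }
  allSets <- c(list(reference = referenceSet), geneSets)
  feats <- lapply(allSets, function(gs) {
    data.frame(cai = vapply(gs, cai, numeric(1), ref = ref),
               gc = vapply(gs, gcContent, numeric(1)))
  })
  refStats <- lapply(c("cai", "gc"), function(fe) .describe(feats$reference[[fe]]))
  names(refStats) <- c("cai", "gc")
  desc <- do.call(rbind, lapply(names(allSets), function(nm) {
    do.call(rbind, lapply(c("cai", "gc"), function(fe) {
      st <- .describe(feats[[nm]][[fe]])
      data.frame(method = nm, feature = fe, statistic = names(st),
                 value = unname(st),
                 within5pct = abs(st - refStats[[fe]]) <=
                   0.05 * abs(refStats[[fe]]),
                 row.names = NULL)
    }))
  }))
  normality <- do.call(rbind, lapply(names(allSets), function(nm) {
    do.call(rbind, lapply(c("cai", "gc"), function(fe) {
      v <- feats[[nm]][[fe]]
      p <- if (length(unique(v)) < 3L) NA_real_ else shapiro.test(v)$p.value
      data.frame(method = nm, feature = fe, p.value = p, row.names = NULL)
    }))
  }))
  wilcoxon <- do.call(rbind, lapply(names(geneSets), function(nm) {
    do.call(rbind, lapply(c("cai", "gc"), function(fe) {
      wt <- wilcoxonSignedRank(feats[[nm]][[fe]], feats$reference[[fe]])
      data.frame(method = nm, feature = fe, p.value = wt$p.value,
                 n = wt$n, row.names = NULL)
    }))
  }))
  structure(list(descriptives = desc, normality = normality,
                 wilcoxon = wilcoxon, features = feats),
            class = "ComparisonReport")
}

#' @export
print.ComparisonReport <- function(x, ...) {
  cat("ComparisonReport over", length(x$features) - 1L, "method(s)\n\n")
  cat("Descriptive statistics (within5pct = within 5% of reference):\n")
  print(x$descriptives, row.names = FALSE)
  cat("\nShapiro-Wilk normality p-values:\n")
  print(x$normality, row.names = FALSE)
  cat("\nWilcoxon signed-rank vs reference:\n")
  print(x$wilcoxon, row.names = FALSE)
  invisible(x)
}
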