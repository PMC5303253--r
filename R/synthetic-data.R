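#' Synthetic codon-usage profile
#'
#' Per-family codon sampling probabilities controlled by a single skew
#' scalar: each synonym family gets one preferred codon (chosen at random
#' under `seed`) whose sampling weight is `skew` while the others keep
#' weight 1, so `skew = 1` gives uniform synonymous usage and large values
#' approach one codon per family. An optional GC tilt multiplies the weight
#' of codons ending in G or C by `exp(gcBias)`. Weights are normalized to
#' probabilities within each family.
#'
#' Profiles built with the same `seed` but different `skew` share the same
#' preferred codons, so gene sets generated along a skew gradient stay
#' mutually consistent (CAI under a high-skew reference increases smoothly
#' with skew).
#'
#' @param skew preferred-codon weight, >= 1 (1 = uniform usage).
#' @param gcBias log-scale tilt toward G/C-ending codons (0 = none).
#' @param seed integer seed for the choice of preferred codons.
#' @return A list of class `SynthUsageProfile`: per-amino-acid probability
#'   vectors (named by codon) plus the parameters.
#' @export
synthUsageProfile <- function(skew = 1, gcBias = 0, seed = 1L) {
  if (skew < 1) stop("skew must be >= 1")
  fams <- geneticCode()$families
  set.seed(seed)
  probs <- lapply(fams, function(f) {
    wts <- rep(1, length(f))
    wts[sample.int(length(f), 1L)] <- skew
    wts <- wts * exp(gcBias * (substr(f, 3L, 3L) %in% c("G", "C")))
    p <- wts / sum(wts)
    names(p) <- f
    p
  })
  structure(list(probs = probs, skew = skew, gcBias = gcBias, seed = seed),
            class = "SynthUsageProfile")
}

#' Generate a synthetic gene set with controlled codon-usage skew
#'
#' Draws random proteins and back-translates each by sampling codons from
#' the profile's per-family probabilities. With a high-skew profile this
#' emulates a set of highly expressed genes whose synonymous usage is
#' strongly biased; with `skew = 1` it emulates a background set with
#' near-uniform usage.
#'
#' @param profile a [synthUsageProfile()].
#' @param nGenes number of genes (>= 2).
#' @param lengthRange protein length range in codons.
#' @param seed integer seed.
#' @param prefix id prefix for the generated genes.
#' @return Named list of [CodingSequence-class].
#' @export
makeHegSet <- function(profile, nGenes, lengthRange = c(100L, 300L),
                       seed = 1L, prefix = "synth") {
  stopifnot(inherits(profile, "SynthUsageProfile"))
  if (nGenes < 2L) stop("nGenes must be >= 2")
  set.seed(seed)
  aa <- .aaAlphabet()
  genes <- lapply(seq_len(nGenes), function(i) {
    len <- sample(seq.int(lengthRange[1L], lengthRange[2L]), 1L)
    res <- sample(aa, len, replace = TRUE)
    cod <- vapply(res, function(a) {
      p <- profile$probs[[a]]
      names(p)[sample.int(length(p), 1L, prob = p)]
    }, character(1))
    .cdsFromCodons(unname(cod))
  })
  names(genes) <- sprintf("%s_%03d", prefix, seq_len(nGenes))
  genes
}

#' Background gene set with near-uniform codon usage
#'
#' Convenience wrapper: [makeHegSet()] with a skew-1 profile.
#'
#' @inheritParams makeHegSet
#' @param gcBias optional GC tilt.
#' @return Named list of [CodingSequence-class].
#' @export
makeBackgroundSet <- function(nGenes, lengthRange = c(100L, 300L),
                              seed = 1L, gcBias = 0) {
  makeHegSet(synthUsageProfile(skew = 1, gcBias = gcBias, seed = seed),
             nGenes, lengthRange, seed = seed, prefix = "bg")
}

#' Synthetic yield surface over (CAI, GC)
#'
#' Known ground-truth mapping from the two codon-usage features to an
#' expression yield in mg/L, used to generate expression tables whose
#' generating function is retained for parameter-recovery tests. Forms:
#' \describe{
#'   \item{linear}{`w1*CAI + w2*GC + intercept`.}
#'   \item{gaussian-bump}{`baseline + amplitude * exp(-(CAI-caiCenter)^2 /
#'     (2*caiWidth^2) - (GC-gcCenter)^2 / (2*gcWidth^2))`: yield peaks at an
#'     intermediate CAI (default 0.72, the empirical optimum reported for
#'     prochymosin expression in E. coli) rather than at CAI = 1, the
#'     regime where a nonlinear fitness model is needed.}
#'   \item{saturating}{Hill curve in CAI: `ymax * CAI^h / (K^h + CAI^h)`.}
#' }
#'
#' @param form one of "linear", "gaussian-bump", "saturating".
#' @param params named list overriding the form's defaults (see Details).
#' @param noiseSd Gaussian noise standard deviation in mg/L (default 10,
#'   i.e. 10\% of the default 100 mg/L amplitude).
#' @return A list of class `SynthYieldSurface` with elements `f(cai, gc)`,
#'   `form`, `params`, `noiseSd`.
#' @export
synthYieldSurface <- function(form = c("gaussian-bump", "linear", "saturating"),
                              params = list(), noiseSd = 10) {
  form <- match.arg(form)
  defaults <- switch(form,
    "linear" = list(w1 = 100, w2 = 20, intercept = 5),
    "gaussian-bump" = list(amplitude = 100, baseline = 5, caiCenter = 0.72,
                           caiWidth = 0.10, gcCenter = 0.50, gcWidth = 0.08),
    "saturating" = list(ymax = 120, K = 0.6, h = 4)
  )
  p <- modifyList(defaults, params)
  f <- switch(form,
    "linear" = function(cai, gc) p$w1 * cai + p$w2 * gc + p$intercept,
    "gaussian-bump" = function(cai, gc) {
      p$baseline + p$amplitude *
        exp(-((cai - p$caiCenter)^2 / (2 * p$caiWidth^2) +
                (gc - p$gcCenter)^2 / (2 * p$gcWidth^2)))
    },
    "saturating" = function(cai, gc) p$ymax * cai^p$h / (p$K^p$h + cai^p$h)
  )
  structure(list(f = f, form = form, params = p, noiseSd = noiseSd),
            class = "SynthYieldSurface")
}

#' Synthetic expression table with a known yield surface
#'
#' Scores each gene against the reference, evaluates the surface, adds
#' Gaussian noise and clips at zero. The generating surface is attached as
#' attribute `"truth"` for recovery tests.
#'
#' @param surface a [synthYieldSurface()].
#' @param genes named list of [CodingSequence-class].
#' @param ref a [UsageReference-class].
#' @param seed integer seed for the noise.
#' @return data.frame(id, sequence, cai, gc, yield_mgL) with attribute
#'   `truth`.
#' @export
makeExpressionTable <- function(surface, genes, ref, seed = 1L) {
  stopifnot(inherits(surface, "SynthYieldSurface"))
  ft <- featureTable(genes, ref)
  set.seed(seed)
  y <- surface$f(ft$cai, ft$gc)
  if (surface$noiseSd > 0) y <- y + rnorm(length(y), 0, surface$noiseSd)
  out <- data.frame(id = ft$id,
                    sequence = vapply(genes, ntSequence, character(1)),
                    cai = ft$cai, gc = ft$gc,
                    yield_mgL = pmax(y, 0), row.names = NULL)
  attr(out, "truth") <- surface
  out
}

#' Gene set spanning a codon-usage skew gradient
#'
#' Generates genes at several skew levels sharing one preferred-codon
#' assignment, so their CAI against a high-skew reference spreads over a
#' wide range. Used to populate synthetic expression experiments.
#'
#' @param skews numeric vector of skew levels.
#' @param genesPerSkew genes per level.
#' @param lengthRange protein length range in codons.
#' @param seed integer seed for gene generation.
#' @param gcBias optional GC tilt applied at every level.
#' @param profileSeed seed fixing the shared preferred codons; pass the
#'   seed of the HEG profile the reference was built from so CAI against
#'   that reference rises with skew.
#' @return Named list of [CodingSequence-class].
#' @export
makeSkewGradientSet <- function(skews = c(1, 2, 4, 8, 16, 40),
                                genesPerSkew = 25L,
                                lengthRange = c(100L, 300L), seed = 1L,
                                gcBias = 0, profileSeed = seed) {
  sets <- lapply(seq_along(skews), function(i) {
    makeHegSet(synthUsageProfile(skew = skews[i], gcBias = gcBias,
                                 seed = profileSeed),
               genesPerSkew, lengthRange, seed = seed + i,
               prefix = sprintf("sk%02d", i))
  })
  do.call(c, sets)
}
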