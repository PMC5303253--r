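#' BayesHegModel: Gaussian class models for HEG membership with a PCA gate
#'
#' Per-feature Gaussian models of the RSCU vector under the HEG class and
#' under the background (non-HEG) class, plus class priors and a
#' two-component PCA bounding box fitted on the HEG members only. The HEG
#' probability of a gene ([hegp()]) is the naive-Bayes posterior
#' \eqn{q_H / (q_H + q_B)}, where \eqn{q_H} and \eqn{q_B} are the
#' prior-weighted products of the per-feature Gaussian densities, forced to
#' 0 whenever either of the gene's first two principal-component scores
#' falls outside the range observed on the HEG members. The gate keeps the
#' posterior from rewarding genes that are far from both classes but
#' relatively closer to HEG.
#'
#' @slot hegMean,hegSd numeric(59): HEG-class Gaussian parameters.
#' @slot bgMean,bgSd numeric(59): background-class Gaussian parameters.
#' @slot priorHeg,priorBg class priors, summing to 1.
#' @slot pcaCenter numeric(59): HEG RSCU mean used for centering.
#' @slot pcaRotation 59 x 2 matrix of the first two principal directions of
#'   the centered HEG RSCU matrix (orthonormal columns).
#' @slot pcaBounds 2 x 2 matrix: rows = components, columns = (min, max) of
#'   the HEG members' scores.
#' @slot sdFloor the standard-deviation floor applied to both classes.
#' @seealso [fitBayesHeg()], [hegp()]
#' @export
setClass("BayesHegModel",
  representation(
    hegMean = "numeric", hegSd = "numeric",
    bgMean = "numeric", bgSd = "numeric",
    priorHeg = "numeric", priorBg = "numeric",
    pcaCenter = "numeric", pcaRotation = "matrix", pcaBounds = "matrix",
    sdFloor = "numeric"
  )
)

setValidity("BayesHegModel", function(object) {
  if (abs(object@priorHeg + object@priorBg - 1) > 1e-12) {
    return("class priors must sum to 1")
  }
  if (any(object@hegSd < object@sdFloor - 1e-15) ||
      any(object@bgSd < object@sdFloor - 1e-15)) {
    return("standard deviations below the configured floor")
  }
  xtx <- crossprod(object@pcaRotation)
  if (max(abs(xtx - diag(2))) > 1e-8) {
    return("principal directions must be orthonormal")
  }
  if (any(object@pcaBounds[, 1] > object@pcaBounds[, 2])) {
    return("PCA bounds must satisfy min <= max")
  }
  TRUE
})

setMethod("show", "BayesHegModel", function(object) {
  cat("BayesHegModel (59 RSCU features)\n")
  cat("  priors: P(HEG) =", object@priorHeg, ", P(~HEG) =", object@priorBg, "\n")
  cat("  PCA gate: PC1 in [", signif(object@pcaBounds[1, 1], 4), ",",
      signif(object@pcaBounds[1, 2], 4), "], PC2 in [",
      signif(object@pcaBounds[2, 1], 4), ",",
      signif(object@pcaBounds[2, 2], 4), "]\n")
})

#' Fit the Gaussian HEG-membership model
#'
#' @param hegRscu RSCU matrix of the HEG set (rows = genes; see
#'   [rscuMatrix()]) or a list of [CodingSequence-class]. At least 3 HEG
#'   members are required for a stable two-component PCA.
#' @param bgRscu RSCU matrix (or gene list) of the background class;
#'   non-empty.
#' @param priorHeg prior probability of the HEG class (default 0.5).
#' @param sdFloor floor on per-feature standard deviations (default 1e-6).
#' @return A [BayesHegModel-class].
#' @export
fitBayesHeg <- function(hegRscu, bgRscu, priorHeg = 0.5, sdFloor = 1e-6) {
  hegRscu <- .asRscuMatrix(hegRscu)
  bgRscu <- .asRscuMatrix(bgRscu)
  if (nrow(hegRscu) < 3L) {
    stop("need at least 3 HEG members to fit the two-component PCA gate")
  }
  if (nrow(bgRscu) < 1L) stop("background set is empty")
  if (priorHeg <= 0 || priorHeg >= 1) stop("priorHeg must be in (0, 1)")
  pc <- prcomp(hegRscu, center = TRUE, scale. = FALSE, rank. = 2L)
  rot <- unname(pc$rotation[, 1:2, drop = FALSE])
  ctr <- unname(pc$center)
  # bounds use the exact arithmetic later applied to query genes, so every
  # training member re-projects inside its own gate bit-for-bit
  scores <- t(apply(hegRscu, 1L, function(r) drop((r - ctr) %*% rot)))
  bounds <- t(apply(scores, 2L, range))
  colnames(bounds) <- c("min", "max")
  new("BayesHegModel",
      hegMean = colMeans(hegRscu),
      hegSd = pmax(apply(hegRscu, 2L, sd), sdFloor),
      bgMean = colMeans(bgRscu),
      bgSd = pmax(apply(bgRscu, 2L, sd), sdFloor),
      priorHeg = priorHeg, priorBg = 1 - priorHeg,
      pcaCenter = ctr,
      pcaRotation = rot,
      pcaBounds = unname(bounds),
      sdFloor = sdFloor)
}

.asRscuMatrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 59L)
    return(x)
  }
  if (is.list(x)) return(rscuMatrix(x))
  stop("expected an RSCU matrix or a list of CodingSequence objects")
}

.asRscuVector <- function(g) {
  if (is(g, "CodingSequence")) return(rscu(g))
  if (is.numeric(g) && length(g) == 59L) return(g)
  stop("expected a CodingSequence or a numeric(59) RSCU vector")
}

#' Principal-component scores of a gene under a model's PCA gate
#'
#' @param g a [CodingSequence-class] or numeric(59) RSCU vector.
#' @param model a [BayesHegModel-class].
#' @return numeric(2): scores on the first two HEG principal directions.
#' @export
pcaScores <- function(g, model) {
  r <- .asRscuVector(g)
  drop((r - model@pcaCenter) %*% model@pcaRotation)
}

#' HEG probability of a gene (HEGP)
#'
#' Posterior probability that the gene belongs to the highly-expressed-gene
#' class, gated by the two-component PCA bounding box: if either
#' principal-component score of the gene's RSCU vector falls outside the
#' range observed over the HEG members, the score is exactly 0 regardless of
#' the likelihoods. The class likelihood products are evaluated in log space
#' over the 59 features, so the score never over- or underflows.
#'
#' @inheritParams pcaScores
#' @return HEGP in [0, 1].
#' @export
hegp <- function(g, model) {
  stopifnot(is(model, "BayesHegModel"))
  r <- .asRscuVector(g)
  p <- drop((r - model@pcaCenter) %*% model@pcaRotation)
  if (p[1] < model@pcaBounds[1, 1] || p[1] > model@pcaBounds[1, 2] ||
      p[2] < model@pcaBounds[2, 1] || p[2] > model@pcaBounds[2, 2]) {
    return(0)
  }
  logqH <- log(model@priorHeg) +
    sum(dnorm(r, model@hegMean, model@hegSd, log = TRUE))
  logqB <- log(model@priorBg) +
    sum(dnorm(r, model@bgMean, model@bgSd, log = TRUE))
  plogis(logqH - logqB)
}

#' DhegCalibration: extremes used to normalize the raw HEG distance
#'
#' The raw distance-to-HEG ([dhegRaw()]) is an unbounded mean Euclidean
#' distance in RSCU space; the calibration records the minimum and maximum
#' raw distance observed over a calibration sample so the score can be
#' rescaled to [0, 1].
#'
#' @slot dMin,dMax calibration extremes, `dMin < dMax`.
#' @slot source free-text description of the calibration sample.
#' @seealso [calibrateDheg()], [dheg()]
#' @export
setClass("DhegCalibration",
  representation(dMin = "numeric", dMax = "numeric", source = "character")
)

setValidity("DhegCalibration", function(object) {
  if (!(object@dMin < object@dMax)) return("dMin must be strictly below dMax")
  TRUE
})

#' @rdname DhegCalibration-class
#' @param dMin,dMax calibration extremes of the raw distance.
#' @param source description of where the extremes came from.
#' @return A [DhegCalibration-class].
#' @export
dhegCalibration <- function(dMin, dMax, source = "manual") {
  new("DhegCalibration", dMin = dMin, dMax = dMax, source = source)
}

setMethod("show", "DhegCalibration", function(object) {
  cat("DhegCalibration: raw distance in [", object@dMin, ",", object@dMax,
      "] (", object@source, ")\n")
})

#' Raw distance to the HEG set
#'
#' Mean, over the HEG members, of the Euclidean distance between the gene's
#' RSCU vector and each member's RSCU vector. The HEG set is used as given
#' (no deduplication).
#'
#' @param g a [CodingSequence-class] or numeric(59) RSCU vector.
#' @param hegRscu RSCU matrix of the HEG members (or a list of genes).
#' @return Non-negative real.
#' @export
dhegRaw <- function(g, hegRscu) {
  r <- .asRscuVector(g)
  m <- .asRscuMatrix(hegRscu)
  d <- sqrt(rowSums(sweep(m, 2L, r)^2))
  mean(d)
}

#' Normalized similarity to the HEG set (DHEG)
#'
#' Rescales the raw mean distance with the calibration extremes and flips
#' direction so that 1 means the gene highly resembles the HEG set and 0
#' means it is totally different:
#' \deqn{DHEG = 1 - (D_{raw} - d_{min}) / (d_{max} - d_{min})}
#' clipped to [0, 1]. The flip makes DHEG directly usable as a fitness to
#' maximize.
#'
#' @inheritParams dhegRaw
#' @param cal a [DhegCalibration-class].
#' @return DHEG in [0, 1].
#' @export
dheg <- function(g, hegRscu, cal) {
  stopifnot(is(cal, "DhegCalibration"))
  raw <- dhegRaw(g, hegRscu)
  s <- 1 - (raw - cal@dMin) / (cal@dMax - cal@dMin)
  min(max(s, 0), 1)
}

#' Calibrate the DHEG normalization range by seeded sampling
#'
#' Draws random proteins, back-translates each with uniform synonymous codon
#' choices, and records the raw distance-to-HEG of every sampled gene and of
#' every HEG member itself; the calibration extremes are the running min and
#' max. Deterministic for a fixed seed, and generated sample-by-sample so
#' enlarging `nSamples` under the same seed only extends the stream (the
#' bracket can only widen).
#'
#' @param heg list of [CodingSequence-class]: the HEG members.
#' @param nSamples number of random genes to draw (at least 2).
#' @param seed integer seed.
#' @param lengthRange protein length range (codons) for the random genes.
#' @return A [DhegCalibration-class].
#' @export
calibrateDheg <- function(heg, nSamples = 200L, seed = 1L,
                          lengthRange = c(100L, 300L)) {
  if (nSamples < 2L) stop("nSamples must be at least 2")
  m <- rscuMatrix(heg)
  dHeg <- vapply(seq_len(nrow(m)), function(i) dhegRaw(m[i, ], m), numeric(1))
  set.seed(seed)
  dSamp <- vapply(seq_len(nSamples), function(i) {
    len <- sample(seq.int(lengthRange[1L], lengthRange[2L]), 1L)
    prot <- paste(sample(.aaAlphabet(), len, replace = TRUE), collapse = "")
    dhegRaw(randomSynonymousGene(prot), m)
  }, numeric(1))
  all <- c(dHeg, dSamp)
  dhegCalibration(min(all), max(all),
                  source = sprintf("sampled (n = %d, seed = %d) + %d HEG members",
                                   nSamples, seed, length(heg)))
}

#' Uniform random synonymous gene for a protein
#'
#' Back-translates a protein choosing each codon uniformly at random within
#' its synonym family. Uses the current RNG state (seed it with `set.seed`
#' upstream when reproducibility matters).
#'
#' @param protein protein string (validated with [proteinSequence()]).
#' @return A [CodingSequence-class] encoding `protein`.
#' @export
randomSynonymousGene <- function(protein) {
  protein <- proteinSequence(protein)
  fam <- geneticCode()$families
  res <- strsplit(protein, "")[[1L]]
  cod <- vapply(res, function(a) {
    f <- fam[[a]]
    f[sample.int(length(f), 1L)]
  }, character(1))
  .cdsFromCodons(unname(cod))
}
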