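# Shared fixtures: a small skewed HEG set, its usage reference, a uniform
# background set, and the fitted HEG-similarity scorers. Built once per run.

fixHegProfile <- synthUsageProfile(skew = 25, seed = 1)
fixHeg <- makeHegSet(fixHegProfile, nGenes = 20, lengthRange = c(60, 100),
                     seed = 2)
fixRef <- buildReference(fixHeg)
fixBg <- makeBackgroundSet(20, lengthRange = c(60, 100), seed = 3)
fixHegRscu <- rscuMatrix(fixHeg)
fixBayes <- fitBayesHeg(fixHeg, fixBg)
fixCal <- calibrateDheg(fixHeg, nSamples = 50, seed = 4,
                        lengthRange = c(60, 100))

# usage reference with hand-set relative adaptiveness (all 1 except where
# overridden); counts are irrelevant for CAI
manualRef <- function(wOverride) {
  ref <- fixRef
  w <- setNames(rep(1, 61), names(relAdaptiveness(ref)))
  w[names(wOverride)] <- wOverride
  ref@w <- w
  ref@counts <- w  # consistent family maxima
  validObject(ref)
  ref
}

# the all-preferred-codon gene for a protein under a reference
preferredGene <- function(protein, ref) {
  fams <- geneticCode()$families[strsplit(protein, "")[[1]]]
  w <- relAdaptiveness(ref)
  codingSequence(paste(vapply(fams, function(f) f[which.max(w[f])],
                              character(1)), collapse = ""))
}
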