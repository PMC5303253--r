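---
title: "Codon-usage models and gene redesign with hegopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-usage models and gene redesign with hegopt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hegopt)
```

## The problem

Synonymous codons are not used uniformly: every organism, and especially
its highly expressed genes (HEG), shows a characteristic codon usage bias
that reflects its tRNA pool. A heterologous gene whose codon choices fight
that bias translates poorly. `hegopt` treats gene redesign as an
optimization problem over synonymous codon choices: the protein is fixed,
the 4^3 = 64-codon genetic code defines for each residue a synonym family,
and a fitness function built from codon-usage features is maximized by a
genetic algorithm.

Replacing every codon with the single most preferred one ("one amino acid,
one codon") is known to backfire — it can exhaust the matching tRNAs — so
besides CAI the package implements two similarity scores that reward genes
for resembling the HEG set *as a distribution*, not for maximal bias, plus
learned expression models that can place their optimum at intermediate CAI.

## Features and scores

**CAI.** Geometric mean of relative adaptiveness values
$w_{ac} = o_{ac}(\mathrm{HEG})/\max_{c' \in C_a} o_{ac'}(\mathrm{HEG})$.
The denominator is the maximum *within the synonym family* — the standard
reading of relative adaptiveness. A pseudo-count (default 0.5) on every
sense-codon count keeps $w_{ac} > 0$, so CAI is computable for genes using
codons the reference never shows; the log-space evaluation makes long
genes safe from underflow. Met and Trp enter the product with $w = 1$; a
trailing stop codon is recorded but excluded from all codon features.

**RSCU.** Observed codon count over its expectation under uniform
synonymous usage. Genes map to a fixed 59-feature vector (61 sense codons
minus the Met and Trp singleton families), ordered alphabetically by
amino acid then codon; every consumer — the Bayes model, its PCA gate, the
DHEG distance — uses this one ordering. Features of amino acids absent
from a gene are set to 0 (0/0 := 0) so vectors remain comparable; for each
family present, the feature values sum to the family size by construction.

**HEGP.** Per-feature Gaussians are fitted to the RSCU vectors of the HEG
class and of a background class, and the posterior is the normalized ratio
$q_H/(q_H+q_B)$ of prior-weighted likelihood products. Two deliberate
choices here:

* *Priors applied exactly once.* The class priors are folded into
  $q_H$ and $q_B$; the posterior is then normalized by their sum. The
  default priors are 0.5/0.5 and overridable — with no information about
  class frequencies, the posterior reduces to a likelihood ratio.
* *The PCA gate.* A naive-Bayes posterior can be high for a gene that is
  far from **both** classes but relatively closer to the HEG side. To
  contain this, a two-component PCA is fitted to the centered HEG RSCU
  matrix (covariance-based, no feature scaling — the gate must reflect the
  HEG set alone), and any gene whose PC1 or PC2 score leaves the range
  spanned by the HEG members scores exactly 0. Two components keep the
  gate inspectable on a plane. The gate bounds are computed with the same
  arithmetic later applied to query genes, so every training member passes
  its own gate bit-for-bit. At least 3 HEG members are required.

Densities are evaluated in log space (59 features with standard deviations
floored at $10^{-6}$ would overflow a direct product), and the posterior
is recovered with the logistic of the log-odds.

**DHEG.** The raw score is the mean Euclidean distance between the gene's
RSCU vector and every HEG member's (no deduplication). It is rescaled with
calibration extremes $(d_{\min}, d_{\max})$ and *flipped*,
$1 - (D - d_{\min})/(d_{\max} - d_{\min})$, clipped to $[0,1]$, so that 1
means "highly resembles the HEG set" and the score can be maximized
directly. The calibration is data-dependent; the package ships a seeded
sampling procedure (random proteins, uniform synonymous back-translation,
plus the HEG members themselves; lengths 100–300 codons by default) and a
manual constructor for externally chosen extremes. The sampler draws one
complete gene per iteration, so enlarging the sample under the same seed
only extends the stream and the bracket can only widen.

## Expression models

The yield model is a two-hidden-layer network over the standardized
(CAI, GC) pair with logistic hidden activations and a linear output,
de-standardized to mg/L. Hidden sizes follow Huang's rule
$m=\sqrt{3N}+2\sqrt{N/3}$, $n=2\sqrt{N/3}$ for $N$ records. Training is
full-batch gradient descent with momentum on the squared error,
initialized uniformly in $[-0.5, 0.5]$, with validation-based early
stopping (patience 50 epochs, cap 2000); the trainer is defined by the
properties it must satisfy (least-squares fit, reproducibility, the
held-out comparisons below), not by a particular weight trajectory.
Standardizing both inputs and targets keeps the sigmoids out of
saturation.

The protocol: each of (by default) 100 repeats draws a fresh seeded split
— 30% test, then 30% of the remainder for validation, leaving 49% for
training — fits one member, and records Pearson correlations on all three
splits; the final predictor is the arithmetic mean of the members.
Averaging across resampled fits damps the overfitting a small expression
dataset invites.

The restricted variants NNP and NND return the HEGP (resp. DHEG) score
itself whenever it is below a threshold, otherwise the ensemble mean. The
threshold defaults to 0.75 for both and is configurable; the same value is
used for both variants since the restriction has one purpose in either
case — keep the optimizer inside codon-usage territory the reference set
supports, where the network interpolates rather than extrapolates. The
linear baseline is OLS of yield on (CAI, GC, 1).

## The genetic algorithm

A candidate is one synonymous-codon index per residue, so crossover and
mutation are closed over synonymy and every individual ever evaluated
encodes the target protein — asserted in the test suite. Defaults:
population 100, 500 generations, crossover 0.8, per-position mutation
1/L, tournament size 3, elitism 1 (making best-so-far fitness monotone).
Fitness values are cached by genome. When a usage reference is available,
one founder is the all-preferred-codon gene; this speeds convergence
without touching the validation oracle, which is exhaustive enumeration.

The landscape scan drives the GA to *target triples* (i, j, k) on a grid
over $[0,1]^3$ by minimizing the residual
$|CAI - i| + |GC - j| + |\mathrm{score} - k|$ — the sum of absolute
deviations is minimized, since the goal is to reach each target, and the
achieved feature combinations map out which (CAI, GC, HEGP/DHEG) values
are attainable at all.

## Synthetic data: what it emulates and what it does not

The generator is the package's stand-in for collected datasets and is
synthetic by design:

* `synthUsageProfile(skew, gcBias, seed)` gives every synonym family one
  preferred codon with weight `skew` (1 = uniform, large = near one-hot),
  optionally tilted toward G/C-ending codons. A single knob controls how
  biased the emulated HEG set is; profiles sharing a seed share preferred
  codons, so skew gradients are internally consistent.
* `makeHegSet` / `makeBackgroundSet` back-translate random proteins from a
  profile (default skew 25 for the HEG set in the shipped experiments —
  strongly but not perfectly biased — and skew 1 for the background, the
  simplest defensible choice given that the provenance of a real non-HEG
  training set is a user decision).
* `makeExpressionTable` evaluates a known yield surface on each gene's
  (CAI, GC) and adds Gaussian noise (default sd 10 mg/L, 10% of the
  default 100 mg/L amplitude). The `gaussian-bump` form peaks at CAI 0.72
  — an intermediate optimum of the kind reported for prochymosin
  expression in *E. coli* — which is exactly the regime where the linear
  baseline must fail and the network must not.

What passing tests on these data do **not** show: real HEG sets have
correlated RSCU features, non-uniform amino-acid composition, and
length/GC structure the generator ignores; real yields depend on far more
than (CAI, GC). The tests validate the machinery — estimators, scores,
optimizer, protocol — not any biological claim about a specific host.

## Numerical choices and degenerate inputs

* Pseudo-count 0.5 and RSCU-sd floor $10^{-6}$, as above.
* CAI of the all-preferred gene is exactly 1 (sum of exact zero logs).
* DHEG clips to $[0,1]$ outside the calibration bracket; a degenerate
  bracket ($d_{\min} = d_{\max}$) is an error.
* Wilcoxon signed-rank: zero differences dropped; all-zero comparisons
  give p = 1; exact null for n ≤ 25 without ties, else normal
  approximation with continuity correction. Exactness is verified against
  full enumeration of sign assignments.
* Pattern matching between two equal-length redesigns counts *maximal*
  runs of consecutive identical aligned nucleotides, binned as exactly
  6 / 7 / 8 / ≥ 9 (longer runs kept in the top bin rather than dropped);
  the total is the bin sum by construction and the statistic is symmetric.
  This aligned maximal-run reading is an interpretation — it is the one
  under which published match tables are internally consistent (each total
  equals its bin sum) — and is documented as such rather than asserted as
  the only possible definition.
* Sequence handling: RNA input is canonicalized to DNA (idempotently),
  ambiguity codes are rejected, internal stops are errors that name the
  1-based codon, and only the standard genetic code is supported.

## Problem sizes in the shipped checks

The test suite and acceptance script run at desk scale, chosen so the full
cycle stays fast while every property is still exercised meaningfully:
HEG/background sets of 20–30 genes of 60–200 codons, expression tables of
~200 genes over a six-level skew gradient, ensembles of 5–20 repeats
(the protocol is identical at 100), GA-vs-enumeration checks on 4–5
residue proteins (search spaces up to 6^5), and 10 GA seeds per fitness.
The ensemble-vs-linear comparison asserts the qualitative claim — the
network's held-out correlation beats the linear baseline on a bump-shaped
surface in at least 18 of 20 repeats and in the medians — not any
particular correlation value, which would be a property of a specific
dataset rather than of the method.

## Known limitations

* Only the standard genetic code; no GenBank/GFF input; no ambiguity
  codes.
* Fitness models see only (CAI, GC); mRNA structure, repeats and
  ribosome-binding motifs are out of scope.
* The PCA gate is axis-aligned in PC space and can admit genes outside
  the HEG cloud along the 57 unmodeled directions; it is a guard, not a
  classifier.
* DHEG calibration extremes are sample-dependent; scores from different
  calibrations are not comparable.
* The GA is stochastic; on large proteins it returns a good synonymous
  design, not a certified optimum (certification is only feasible — and
  tested — on tiny proteins).
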