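#' Genetic-algorithm configuration
#'
#' Hyperparameters of the synonymous-codon genetic algorithm. Defaults:
#' population 100, 500 generations, crossover rate 0.8, per-position
#' mutation rate 1/L (set when the protein length is known), tournament
#' size 3, elitism 1.
#'
#' @param populationSize individuals per generation (>= 2).
#' @param generations number of generations (>= 1).
#' @param crossoverRate probability of single-point crossover per pairing.
#' @param mutationRate per-position probability of resampling a codon
#'   uniformly within its synonym family; `NULL` means 1/L.
#' @param tournamentSize individuals per selection tournament.
#' @param elitismCount top individuals copied unchanged each generation
#'   (must be below `populationSize`).
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @return A list of class `GaConfig`.
#' @export
gaConfig <- function(populationSize = 100L, generations = 500L,
                     crossoverRate = 0.8, mutationRate = NULL,
                     tournamentSize = 3L, elitismCount = 1L, seed = NULL) {
  cfg <- list(populationSize = as.integer(populationSize),
              generations = as.integer(generations),
              crossoverRate = crossoverRate, mutationRate = mutationRate,
              tournamentSize = as.integer(tournamentSize),
              elitismCount = as.integer(elitismCount), seed = seed)
  if (cfg$populationSize < 2L) stop("populationSize must be >= 2")
  if (cfg$generations < 1L) stop("generations must be >= 1")
  if (cfg$crossoverRate < 0 || cfg$crossoverRate > 1) {
    stop("crossoverRate must be in [0, 1]")
  }
  if (!is.null(cfg$mutationRate) &&
      (cfg$mutationRate < 0 || cfg$mutationRate > 1)) {
    stop("mutationRate must be in [0, 1]")
  }
  if (cfg$tournamentSize < 1L) stop("tournamentSize must be >= 1")
  if (cfg$elitismCount < 0L || cfg$elitismCount >= cfg$populationSize) {
    stop("elitismCount must be in [0, populationSize)")
  }
  structure(cfg, class = "GaConfig")
}

#' OptimizationResult: outcome of a gene-redesign run
#'
#' @slot bestGene the best [CodingSequence-class] found; always a
#'   synonymous encoding of the target protein.
#' @slot bestFitness its fitness.
#' @slot trajectory data.frame(generation, best, mean) of per-generation
#'   fitness; with elitism the best column is non-decreasing.
#' @slot featureReport named numeric of features of the best gene (CAI, GC,
#'   and any similarity scores computed at report time); may be empty.
#' @seealso [optimizeGene()]
#' @export
setClass("OptimizationResult",
  representation(
    bestGene = "CodingSequence", bestFitness = "numeric",
    trajectory = "data.frame", featureReport = "numeric"
  )
)

setMethod("show", "OptimizationResult", function(object) {
  cat("OptimizationResult:", nCodons(object@bestGene), "codons, fitness",
      signif(object@bestFitness, 6), "after",
      nrow(object@trajectory), "generations\n")
  if (length(object@featureReport) > 0) {
    cat("  features:", paste(names(object@featureReport),
                             signif(object@featureReport, 4),
                             sep = " = ", collapse = ", "), "\n")
  }
})

#' @rdname OptimizationResult-class
#' @param x an OptimizationResult.
#' @export
bestGene <- function(x) x@bestGene

#' @rdname OptimizationResult-class
#' @export
bestFitness <- function(x) x@bestFitness

#' @rdname OptimizationResult-class
#' @export
trajectory <- function(x) x@trajectory

#' @rdname OptimizationResult-class
#' @export
featureReport <- function(x) x@featureReport

#' Optimize a synonymous gene for a protein by genetic algorithm
#'
#' The search space is one synonymous-codon index per residue, so every
#' individual at every generation encodes exactly the target protein
#' (crossover and mutation are closed over synonymy). Evolution uses
#' tournament selection, single-point crossover, per-position synonymous
#' mutation, and elitism; fitness values are cached by genome so duplicate
#' individuals are never re-scored. Deterministic under a fixed
#' `config$seed`.
#'
#' The initial population is uniform-random synonymous genes; when `ref` is
#' supplied, one individual is seeded with the all-preferred-codon gene
#' (each family's maximum-adaptiveness codon) to speed convergence on
#' usage-driven fitnesses.
#'
#' @param protein target protein string (validated).
#' @param fitness function mapping a [CodingSequence-class] to a single
#'   finite numeric fitness; maximized.
#' @param config a [gaConfig()] list.
#' @param ref optional [UsageReference-class] for seeding.
#' @param report optional named list of scorers used to fill the feature
#'   report of the result: `ref` ([UsageReference-class]), `bayes`
#'   ([BayesHegModel-class]), `hegRscu` + `cal` (for DHEG).
#' @return An [OptimizationResult-class].
#' @examples
#' set.seed(1)
#' heg <- makeHegSet(synthUsageProfile(skew = 25, seed = 1), nGenes = 15,
#'                   lengthRange = c(40, 60), seed = 2)
#' ref <- buildReference(heg)
#' res <- optimizeGene("MHEALKW", function(g) cai(g, ref),
#'                     gaConfig(populationSize = 30, generations = 50, seed = 3),
#'                     ref = ref)
#' bestFitness(res)  # 1 (all-preferred-codon optimum)
#' @export
optimizeGene <- function(protein, fitness, config = gaConfig(), ref = NULL,
                         report = NULL) {
  protein <- proteinSequence(protein)
  code <- geneticCode()
  res <- strsplit(protein, "")[[1L]]
  fams <- code$families[res]
  k <- lengths(fams)
  L <- length(res)
  if (!is.null(config$seed)) set.seed(config$seed)
  mutRate <- if (is.null(config$mutationRate)) 1 / L else config$mutationRate
  decode <- function(genome) {
    .cdsFromCodons(vapply(seq_len(L), function(i) fams[[i]][genome[i]],
                          character(1)))
  }
  cache <- new.env(parent = emptyenv())
  evalGenome <- function(genome) {
    key <- paste(genome, collapse = ",")
    v <- cache[[key]]
    if (is.null(v)) {
      v <- fitness(decode(genome))
      if (!is.finite(v)) stop("fitness returned a non-finite value")
      cache[[key]] <- v
    }
    v
  }
  randGenome <- function() {
    vapply(k, function(ki) sample.int(ki, 1L), integer(1))
  }
  pop <- replicate(config$populationSize, randGenome(), simplify = FALSE)
  if (!is.null(ref)) {
    w <- relAdaptiveness(ref)
    pop[[1L]] <- vapply(seq_len(L), function(i) which.max(w[fams[[i]]]),
                        integer(1L))
  }
  fit <- vapply(pop, evalGenome, numeric(1))
  traj <- data.frame(generation = seq_len(config$generations),
                     best = NA_real_, mean = NA_real_)
  tournament <- function() {
    cand <- sample.int(config$populationSize, config$tournamentSize,
                       replace = TRUE)
    cand[which.max(fit[cand])]
  }
  for (gen in seq_len(config$generations)) {
    ord <- order(fit, decreasing = TRUE)
    newPop <- pop[ord[seq_len(config$elitismCount)]]
    while (length(newPop) < config$populationSize) {
      p1 <- pop[[tournament()]]
      p2 <- pop[[tournament()]]
      if (L > 1L && runif(1) < config$crossoverRate) {
        cut <- sample.int(L - 1L, 1L)
        child <- c(p1[seq_len(cut)], p2[(cut + 1L):L])
      } else {
        child <- p1
      }
      mut <- which(runif(L) < mutRate)
      if (length(mut) > 0L) {
        child[mut] <- vapply(mut, function(i) sample.int(k[i], 1L), integer(1))
      }
      newPop[[length(newPop) + 1L]] <- child
    }
    pop <- newPop
    fit <- vapply(pop, evalGenome, numeric(1))
    traj$best[gen] <- max(fit)
    traj$mean[gen] <- mean(fit)
  }
  bi <- which.max(fit)
  best <- decode(pop[[bi]])
  fr <- .featureReportFor(best, report)
  new("OptimizationResult", bestGene = best, bestFitness = fit[bi],
      trajectory = traj, featureReport = fr)
}

.featureReportFor <- function(g, report) {
  if (is.null(report)) return(setNames(numeric(0), character(0)))
  fr <- c(gc = gcContent(g))
  if (!is.null(report$ref)) fr <- c(cai = cai(g, report$ref), fr)
  if (!is.null(report$bayes)) fr <- c(fr, hegp = hegp(g, report$bayes))
  if (!is.null(report$hegRscu) && !is.null(report$cal)) {
    fr <- c(fr, dheg = dheg(g, report$hegRscu, report$cal))
  }
  fr
}

#' Feature-landscape scan over target triples
#'
#' For every target triple (i, j, k) on the grid
#' \eqn{\{0, s, 2s, \dots, 1\}^3}, runs the genetic algorithm to minimize
#' the residual \eqn{|CAI - i| + |GC - j| + |score - k|}, where the score is
#' HEGP or DHEG, and records the feature values actually achieved. The
#' resulting table maps out which (CAI, GC, similarity) combinations are
#' attainable by synonymous redesign of the protein.
#'
#' @param protein target protein string.
#' @param mode "HEGP" or "DHEG".
#' @param ref a [UsageReference-class] (for CAI).
#' @param bayes a [BayesHegModel-class] (HEGP mode).
#' @param hegRscu,cal HEG RSCU matrix and [DhegCalibration-class] (DHEG
#'   mode).
#' @param gridStep grid spacing in (0, 1].
#' @param config a [gaConfig()]; each triple runs with seed
#'   `config$seed + triple index` when a seed is set.
#' @return data.frame with the targets (i, j, k), the achieved cai, gc and
#'   score, and the residual.
#' @export
landscapeScan <- function(protein, mode = c("HEGP", "DHEG"), ref,
                          bayes = NULL, hegRscu = NULL, cal = NULL,
                          gridStep = 0.25, config = gaConfig()) {
  mode <- match.arg(mode)
  if (gridStep <= 0 || gridStep > 1) stop("gridStep must be in (0, 1]")
  axis <- seq(0, 1, by = gridStep)
  grid <- expand.grid(i = axis, j = axis, k = axis)
  if (nrow(grid) == 0L) stop("empty target grid")
  scoreFun <- if (mode == "HEGP") {
    if (is.null(bayes)) stop("HEGP mode requires 'bayes'")
    function(g) hegp(g, bayes)
  } else {
    if (is.null(hegRscu) || is.null(cal)) stop("DHEG mode requires 'hegRscu' and 'cal'")
    hegRscu <- .asRscuMatrix(hegRscu)
    function(g) dheg(g, hegRscu, cal)
  }
  out <- grid
  out$cai <- out$gc <- out$score <- out$residual <- NA_real_
  for (t in seq_len(nrow(grid))) {
    tgt <- grid[t, ]
    fitn <- function(g) {
      -(abs(cai(g, ref) - tgt$i) + abs(gcContent(g) - tgt$j) +
          abs(scoreFun(g) - tgt$k))
    }
    cfg <- config
    if (!is.null(cfg$seed)) cfg$seed <- cfg$seed + t
    res <- optimizeGene(protein, fitn, cfg, ref = ref)
    g <- bestGene(res)
    out$cai[t] <- cai(g, ref)
    out$gc[t] <- gcContent(g)
    out$score[t] <- scoreFun(g)
    out$residual[t] <- -bestFitness(res)
  }
  out
}

#' Random protein sequence
#'
#' Residues drawn i.i.d. uniformly from the 20-letter alphabet.
#'
#' @param length number of residues (>= 1).
#' @param seed optional integer seed.
#' @return Protein string.
#' @export
randomProtein <- function(length, seed = NULL) {
  if (length < 1) stop("length must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  paste(sample(.aaAlphabet(), length, replace = TRUE), collapse = "")
}

#' Exhaustive synonymous optimum (oracle for small proteins)
#'
#' Enumerates every synonymous encoding of a short protein and returns the
#' fitness maximum. Intended for validating the genetic algorithm on
#' proteins of a handful of residues; the search space grows as the product
#' of family sizes.
#'
#' @param protein protein string (product of family sizes capped by
#'   `maxCandidates`).
#' @param fitness fitness function over [CodingSequence-class].
#' @param maxCandidates safety cap on the enumeration size.
#' @return list(gene, fitness) at the exact optimum.
#' @export
exhaustiveOptimum <- function(protein, fitness, maxCandidates = 2e5) {
  protein <- proteinSequence(protein)
  fams <- geneticCode()$families[strsplit(protein, "")[[1L]]]
  nCand <- prod(lengths(fams))
  if (nCand > maxCandidates) {
    stop("search space too large for exhaustive enumeration (", nCand, ")")
  }
  grid <- expand.grid(fams, stringsAsFactors = FALSE)
  bestV <- -Inf
  bestG <- NULL
  for (i in seq_len(nrow(grid))) {
    g <- .cdsFromCodons(unlist(grid[i, ], use.names = FALSE))
    v <- fitness(g)
    if (v > bestV) {
      bestV <- v
      bestG <- g
    }
  }
  list(gene = bestG, fitness = bestV)
}
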