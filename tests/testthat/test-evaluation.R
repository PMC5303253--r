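test_that("identical sequences give a single maximal run in the top bin", {
  s <- paste(rep("ATG", 10), collapse = "")  # 30 nt
  mc <- patternMatch(s, s)
  expect_identical(matchBins(mc), c(n6 = 0L, n7 = 0L, n8 = 0L, n9plus = 1L))
  expect_identical(totalMatches(mc), 1L)
})

test_that("mismatches every third position leave no countable run", {
  a <- paste(rep("AAT", 10), collapse = "")
  b <- paste(rep("AAC", 10), collapse = "")
  expect_identical(totalMatches(patternMatch(a, b)), 0L)
})

test_that("hand-built 6-run and 7-run are binned exactly", {
  a <- paste0("AAAAAA", "C", "GGGGGGG", "TTTT")
  b <- paste0("AAAAAA", "A", "GGGGGGG", "GGGG")
  mc <- patternMatch(a, b)
  expect_identical(matchBins(mc), c(n6 = 1L, n7 = 1L, n8 = 0L, n9plus = 0L))
  expect_identical(totalMatches(mc), 2L)
  # an exact 8-run and an 11-run
  a2 <- paste0("AAAAAAAA", "C", "GGGGGGGGGGG", "T")
  b2 <- paste0("AAAAAAAA", "G", "GGGGGGGGGGG", "A")
  expect_identical(matchBins(patternMatch(a2, b2)),
                   c(n6 = 0L, n7 = 0L, n8 = 1L, n9plus = 1L))
})

test_that("pattern matching is symmetric and requires equal lengths", {
  set.seed(41)
  for (i in 1:5) {
    ga <- randomSynonymousGene(randomProtein(30))
    gb <- randomSynonymousGene(translate(ga))
    expect_identical(matchBins(patternMatch(ga, gb)),
                     matchBins(patternMatch(gb, ga)))
  }
  expect_error(patternMatch("ATGATG", "ATG"), "equal length")
})

test_that("signed-rank test: self-comparison gives p = 1 after zero removal", {
  x <- c(0.5, 0.6, 0.7, 0.8)
  wt <- wilcoxonSignedRank(x, x)
  expect_identical(wt$p.value, 1)
  expect_identical(wt$n, 0L)
})

test_that("a constant +0.1 shift is significant at n >= 6", {
  x <- c(0.55, 0.62, 0.73, 0.81, 0.49, 0.66)
  wt <- wilcoxonSignedRank(x + 0.1, x)
  expect_lt(wt$p.value, 0.05)  # tied |d| -> continuity-corrected approximation
  # untied all-positive differences hit the exact 2/2^n tail
  wt2 <- wilcoxonSignedRank(x + seq(0.1, 0.15, length.out = 6), x)
  expect_equal(wt2$p.value, 2 / 64)
})

test_that("exact small-n p-values match full enumeration of sign assignments", {
  enumerate_p <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    v <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vall <- as.vector(signs %*% r)
    min(1, 2 * min(mean(vall <= v), mean(vall >= v)))
  }
  set.seed(42)
  for (n in c(4, 6, 8, 10)) {
    for (rep in 1:3) {
      x <- runif(n)
      y <- runif(n)
      expect_equal(wilcoxonSignedRank(x, y)$p.value, enumerate_p(x - y),
                   tolerance = 1e-12)
    }
  }
})

test_that("unpaired samples are rejected", {
  expect_error(wilcoxonSignedRank(1:4, 1:5), "unpaired")
})

test_that("method comparison reports descriptives, normality and paired tests", {
  set.seed(43)
  prots <- replicate(8, randomProtein(40))
  refSet <- lapply(prots, function(p) {
    bestGene(optimizeGene(p, function(g) cai(g, fixRef),
                          gaConfig(populationSize = 10, generations = 5,
                                   seed = 1), ref = fixRef))
  })
  methodA <- lapply(prots, randomSynonymousGene)
  methodB <- refSet  # identical to the reference
  rep <- compareMethods(list(A = methodA, B = methodB), refSet, fixRef)
  expect_s3_class(rep, "ComparisonReport")
  expect_setequal(unique(rep$descriptives$method), c("reference", "A", "B"))
  # the self-identical set: p = 1 and every descriptive within 5%
  wB <- rep$wilcoxon[rep$wilcoxon$method == "B", ]
  expect_true(all(wB$p.value == 1))
  dB <- rep$descriptives[rep$descriptives$method == "B", ]
  expect_true(all(dB$within5pct))
  # the within-5% flag is plain arithmetic on the reference value
  dRef <- rep$descriptives[rep$descriptives$method == "reference", ]
  for (i in seq_len(nrow(dB))) {
    refVal <- dRef$value[dRef$feature == dB$feature[i] &
                           dRef$statistic == dB$statistic[i]]
    expect_identical(dB$within5pct[i],
                     abs(dB$value[i] - refVal) <= 0.05 * abs(refVal))
  }
  expect_true(all(rep$normality$p.value >= 0 & rep$normality$p.value <= 1,
                  na.rm = TRUE))
})

test_that("mean CAI 0.70 against reference 0.72 is flagged within 5 percent", {
  expect_lt(abs(0.70 - 0.72) / 0.72, 0.05)
})

test_that("comparison requires paired sets of at least 3 genes", {
  g <- lapply(1:4, function(i) randomSynonymousGene(randomProtein(20)))
  expect_error(compareMethods(list(A = g[1:2]), g[1:2], fixRef), "fewer than 3")
  expect_error(compareMethods(list(A = g[1:3]), g, fixRef), "not paired")
  expect_error(compareMethods(list(g[1:4]), g, fixRef), "named")
})
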