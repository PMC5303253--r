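Package: hegopt
Title: Gene Optimization Guided by Highly Expressed Gene Codon Usage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Codon-usage featurization (codon adaptation index, relative
    synonymous codon usage, GC content) and gene redesign for heterologous
    expression in Escherichia coli. Provides two similarity scores against a
    reference set of highly expressed genes -- a Gaussian naive-Bayes
    posterior gated by a two-component PCA bounding box (HEGP) and a
    normalized mean Euclidean distance in RSCU space (DHEG) -- together with
    expression-yield fitness models (a two-hidden-layer sigmoid network
    trained as a 100-member ensemble with optional HEGP/DHEG restriction,
    and a multivariable linear baseline), a genetic algorithm over
    synonymous codon choices that maximizes any of these fitnesses,
    synthetic-data generators with controlled codon-usage skew and known
    yield surfaces, and statistical machinery for comparing optimization
    methods (descriptive statistics, Shapiro-Wilk, Wilcoxon signed-rank,
    and aligned maximal-run pattern matching).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, SequenceMatching, GenePrediction, Regression
RoxygenNote: 7.3.3
Collate:
    'genetic-code.R'
    'seqcore.R'
    'usage-features.R'
    'heg-scores.R'
    'expression-models.R'
    'ga-optimizer.R'
    'synthetic-data.R'
    'evaluation.R'
    'cli.R'
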