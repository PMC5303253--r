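#' Hidden-layer sizing rule
#'
#' Huang's (2003) sizing for a two-hidden-layer network trained on N
#' samples: \eqn{m = \sqrt{3N} + 2\sqrt{N/3}} nodes in the first hidden
#' layer and \eqn{n = 2\sqrt{N/3}} in the second, rounded to the nearest
#' integer and floored at 1.
#'
#' @param N number of training samples (>= 1).
#' @return Integer vector `c(m = ..., n = ...)`.
#' @examples
#' huangSizes(73)  # c(m = 25, n = 10)
#' @export
huangSizes <- function(N) {
  if (N < 1) stop("N must be at least 1")
  m <- max(1L, as.integer(round(sqrt(3 * N) + 2 * sqrt(N / 3))))
  n <- max(1L, as.integer(round(2 * sqrt(N / 3))))
  c(m = m, n = n)
}

#' NNModel: a two-hidden-layer sigmoid network over (CAI, GC)
#'
#' The expression-fitness network maps the two codon-usage features of a
#' gene to a predicted yield (mg/L) through
#' \deqn{o_1 = W_1 (CAI, GC, 1)^T,\; h_1 = \sigma(o_1),\;
#'       o_2 = W_2 (h_1, 1)^T,\; h_2 = \sigma(o_2),\;
#'       o = W_{out} (h_2, 1)^T}
#' with \eqn{\sigma} the logistic function. Inputs are z-scored with the
#' stored training constants and the linear output is de-standardized back
#' to mg/L; identity standardization (center 0, scale 1) makes the raw
#' composition available directly.
#'
#' @slot W1 m x 3 first-layer weights (third column multiplies the bias 1).
#' @slot W2 n x (m+1) second-layer weights.
#' @slot Wout 1 x (n+1) output weights.
#' @slot xCenter,xScale numeric(2): input standardization (CAI, GC).
#' @slot yCenter,yScale target standardization.
#' @seealso [nnModel()], [nnForward()]
#' @export
setClass("NNModel",
  representation(
    W1 = "matrix", W2 = "matrix", Wout = "matrix",
    xCenter = "numeric", xScale = "numeric",
    yCenter = "numeric", yScale = "numeric"
  )
)

setValidity("NNModel", function(object) {
  m <- nrow(object@W1)
  n <- nrow(object@W2)
  if (ncol(object@W1) != 3L) return("W1 must have 3 columns")
  if (ncol(object@W2) != m + 1L) return("W2 must have m + 1 columns")
  if (nrow(object@Wout) != 1L || ncol(object@Wout) != n + 1L) {
    return("Wout must be 1 x (n + 1)")
  }
  if (!all(is.finite(object@W1), is.finite(object@W2), is.finite(object@Wout))) {
    return("weights must be finite")
  }
  TRUE
})

#' @rdname NNModel-class
#' @param W1,W2,Wout weight matrices (see slots).
#' @param xCenter,xScale,yCenter,yScale standardization constants; the
#'   defaults give the raw network composition.
#' @return An [NNModel-class].
#' @export
nnModel <- function(W1, W2, Wout, xCenter = c(0, 0), xScale = c(1, 1),
                    yCenter = 0, yScale = 1) {
  new("NNModel", W1 = W1, W2 = W2, Wout = Wout,
      xCenter = xCenter, xScale = xScale, yCenter = yCenter, yScale = yScale)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Evaluate the expression network
#'
#' Deterministic forward pass; vectorized over genes.
#'
#' @param model an [NNModel-class].
#' @param cai,gc numeric vectors of equal length in [0, 1].
#' @return Predicted yield (mg/L), numeric of the same length.
#' @export
nnForward <- function(model, cai, gc) {
  stopifnot(length(cai) == length(gc))
  z1 <- (cai - model@xCenter[1]) / model@xScale[1]
  z2 <- (gc - model@xCenter[2]) / model@xScale[2]
  X <- rbind(z1, z2, 1)
  H1 <- .sigmoid(model@W1 %*% X)
  H2 <- .sigmoid(model@W2 %*% rbind(H1, 1))
  o <- drop(model@Wout %*% rbind(H2, 1))
  unname(o * model@yScale + model@yCenter)
}

# full-batch gradient descent with momentum and validation early stopping,
# on standardized inputs/targets; returns an NNModel in mg/L units
.trainNN <- function(xTrain, yTrain, xVal, yVal, m, n, control = list()) {
  ctl <- modifyList(list(epochs = 2000L, lr = 0.2, momentum = 0.9,
                         patience = 50L, initRange = 0.5), control)
  xc <- colMeans(xTrain)
  xs <- pmax(apply(xTrain, 2L, sd), 1e-8)
  yc <- mean(yTrain)
  ys <- max(sd(yTrain), 1e-8)
  Xt <- rbind((xTrain[, 1] - xc[1]) / xs[1], (xTrain[, 2] - xc[2]) / xs[2], 1)
  Xv <- rbind((xVal[, 1] - xc[1]) / xs[1], (xVal[, 2] - xc[2]) / xs[2], 1)
  yt <- (yTrain - yc) / ys
  yv <- (yVal - yc) / ys
  N <- length(yt)
  r <- ctl$initRange
  W1 <- matrix(runif(m * 3, -r, r), m, 3)
  W2 <- matrix(runif(n * (m + 1), -r, r), n, m + 1)
  Wo <- matrix(runif(n + 1, -r, r), 1, n + 1)
  V1 <- W1 * 0; V2 <- W2 * 0; Vo <- Wo * 0
  fwd <- function(X) {
    H1 <- .sigmoid(W1 %*% X)
    H2 <- .sigmoid(W2 %*% rbind(H1, 1))
    list(H1 = H1, H2 = H2, o = drop(Wo %*% rbind(H2, 1)))
  }
  best <- list(err = Inf, W1 = W1, W2 = W2, Wo = Wo)
  stall <- 0L
  for (ep in seq_len(ctl$epochs)) {
    f <- fwd(Xt)
    dO <- matrix(2 * (f$o - yt) / N, 1)
    H2b <- rbind(f$H2, 1)
    gWo <- dO %*% t(H2b)
    dH2 <- crossprod(Wo[, seq_len(n), drop = FALSE], dO)
    dA2 <- dH2 * f$H2 * (1 - f$H2)
    H1b <- rbind(f$H1, 1)
    gW2 <- dA2 %*% t(H1b)
    dH1 <- crossprod(W2[, seq_len(m), drop = FALSE], dA2)
    dA1 <- dH1 * f$H1 * (1 - f$H1)
    gW1 <- dA1 %*% t(Xt)
    V1 <- ctl$momentum * V1 - ctl$lr * gW1; W1 <- W1 + V1
    V2 <- ctl$momentum * V2 - ctl$lr * gW2; W2 <- W2 + V2
    Vo <- ctl$momentum * Vo - ctl$lr * gWo; Wo <- Wo + Vo
    oV <- fwd(Xv)$o
    errV <- mean((oV - yv)^2)
    if (errV < best$err - 1e-9) {
      best <- list(err = errV, W1 = W1, W2 = W2, Wo = Wo)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= ctl$patience) break
    }
  }
  nnModel(best$W1, best$W2, best$Wo,
          xCenter = unname(xc), xScale = unname(xs),
          yCenter = yc, yScale = ys)
}

#' ExpressionEnsemble: an ensemble of expression networks
#'
#' The final expression predictor is the arithmetic mean of the member
#' networks, each trained on its own random train/validation/test split of
#' the expression data (49\% / 21\% / 30\%). Optionally the prediction is
#' restricted by a HEG-similarity score: with restriction `"HEGP"`
#' (`"DHEG"`), a gene whose HEGP (DHEG) falls below the threshold receives
#' that similarity score itself as fitness instead of the network
#' prediction, pulling the optimizer back toward codon usage the reference
#' set supports.
#'
#' @slot members list of [NNModel-class].
#' @slot restriction one of "none", "HEGP", "DHEG".
#' @slot threshold restriction threshold in (0, 1) (default 0.75).
#' @slot cors data.frame with one row per repeat: Pearson correlation of
#'   prediction vs observed yield on the training, validation and test
#'   splits.
#' @slot m,n hidden-layer sizes used for every member.
#' @slot scorers list holding the attached restriction scorers (`bayes`
#'   and/or `hegRscu` + `cal`), possibly empty.
#' @seealso [trainEnsemble()], [predictFitness()]
#' @export
setClass("ExpressionEnsemble",
  representation(
    members = "list", restriction = "character", threshold = "numeric",
    cors = "data.frame", m = "integer", n = "integer", scorers = "list"
  )
)

setValidity("ExpressionEnsemble", function(object) {
  if (!object@restriction %in% c("none", "HEGP", "DHEG")) {
    return("restriction must be 'none', 'HEGP' or 'DHEG'")
  }
  if (object@threshold <= 0 || object@threshold >= 1) {
    return("threshold must be in (0, 1)")
  }
  if (nrow(object@cors) != length(object@members)) {
    return("one correlation record per member is required")
  }
  TRUE
})

setMethod("show", "ExpressionEnsemble", function(object) {
  cat("ExpressionEnsemble of", length(object@members),
      "networks (m =", object@m, ", n =", object@n, ")\n")
  cat("  restriction:", object@restriction,
      if (object@restriction != "none") paste("(threshold", object@threshold, ")")
      else "", "\n")
  cat("  median test correlation:",
      signif(median(object@cors$test), 3), "\n")
})

#' @rdname ExpressionEnsemble-class
#' @param x an ExpressionEnsemble.
#' @export
correlationRecords <- function(x) x@cors

.expressionFeatures <- function(data, ref) {
  if (all(c("cai", "gc") %in% names(data))) {
    x <- cbind(cai = data$cai, gc = data$gc)
  } else if ("sequence" %in% names(data)) {
    if (is.null(ref)) stop("a UsageReference is required to featurize sequences")
    genes <- lapply(data$sequence, codingSequence)
    x <- cbind(cai = vapply(genes, cai, numeric(1), ref = ref),
               gc = vapply(genes, gcContent, numeric(1)))
  } else {
    stop("expression data must have columns (cai, gc) or a 'sequence' column")
  }
  if (!"yield_mgL" %in% names(data)) stop("expression data must have 'yield_mgL'")
  y <- data$yield_mgL
  if (any(!is.finite(y)) || any(y < 0)) stop("yields must be finite and >= 0")
  list(x = x, y = y)
}

# 30% test; of the remainder, 30% validation; rest training
.splitIndices <- function(N) {
  idx <- sample.int(N)
  nTest <- round(0.3 * N)
  nVal <- round(0.3 * (N - nTest))
  list(test = idx[seq_len(nTest)],
       validation = idx[nTest + seq_len(nVal)],
       train = idx[-seq_len(nTest + nVal)])
}

#' Train the expression-network ensemble
#'
#' Repeats, `repeats` times: draw a seeded random split of the expression
#' records into 30\% test, 21\% validation and 49\% training; fit one
#' network (sized by [huangSizes()] on the full record count) by full-batch
#' gradient least squares with validation early stopping; record the
#' Pearson correlation between predictions and observed yields on each
#' split. The final predictor is the arithmetic mean of the members.
#' Repeat r uses seed `seed + r`, so runs are reproducible and members are
#' independent of each other's RNG draws.
#'
#' @param data data.frame of expression records with column `yield_mgL` and
#'   either precomputed `cai`/`gc` columns or a `sequence` column (then
#'   `ref` is required). At least 10 records.
#' @param ref optional [UsageReference-class] for featurizing sequences.
#' @param repeats ensemble size (default 100).
#' @param seed base integer seed.
#' @param restriction "none", "HEGP" or "DHEG" (see
#'   [ExpressionEnsemble-class]).
#' @param threshold restriction threshold (default 0.75).
#' @param control trainer options: `epochs` (2000), `lr`, `momentum`,
#'   `patience` (50), `initRange` (weights start uniform in ±0.5).
#' @return An [ExpressionEnsemble-class].
#' @export
trainEnsemble <- function(data, ref = NULL, repeats = 100L, seed = 1L,
                          restriction = c("none", "HEGP", "DHEG"),
                          threshold = 0.75, control = list()) {
  restriction <- match.arg(restriction)
  feat <- .expressionFeatures(data, ref)
  N <- length(feat$y)
  if (N < 10L) stop("need at least 10 expression records")
  if (sd(feat$y) == 0) stop("yields have zero variance; nothing to fit")
  sizes <- huangSizes(N)
  members <- vector("list", repeats)
  cors <- data.frame(repeatId = seq_len(repeats), train = NA_real_,
                     validation = NA_real_, test = NA_real_)
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    sp <- .splitIndices(N)
    mod <- .trainNN(feat$x[sp$train, , drop = FALSE], feat$y[sp$train],
                    feat$x[sp$validation, , drop = FALSE], feat$y[sp$validation],
                    m = sizes[["m"]], n = sizes[["n"]], control = control)
    members[[r]] <- mod
    for (s in c("train", "validation", "test")) {
      ii <- sp[[s]]
      pred <- nnForward(mod, feat$x[ii, 1], feat$x[ii, 2])
      cors[[s]][r] <- suppressWarnings(cor(pred, feat$y[ii]))
    }
  }
  new("ExpressionEnsemble", members = members, restriction = restriction,
      threshold = threshold, cors = cors,
      m = sizes[["m"]], n = sizes[["n"]], scorers = list())
}

#' Mean ensemble prediction (no restriction)
#'
#' @param ens an [ExpressionEnsemble-class].
#' @param cai,gc numeric vectors.
#' @return Mean of the member predictions, in mg/L.
#' @export
predictEnsemble <- function(ens, cai, gc) {
  preds <- vapply(ens@members, nnForward, numeric(length(cai)),
                  cai = cai, gc = gc)
  if (length(cai) == 1L) mean(preds) else rowMeans(matrix(preds, nrow = length(cai)))
}

#' Attach restriction scorers to an ensemble
#'
#' @param ens an [ExpressionEnsemble-class].
#' @param restriction "none", "HEGP" or "DHEG"; defaults to the ensemble's
#'   current setting.
#' @param bayes a [BayesHegModel-class] (for HEGP restriction).
#' @param hegRscu RSCU matrix of the HEG set (for DHEG restriction).
#' @param cal a [DhegCalibration-class] (for DHEG restriction).
#' @param threshold optionally override the threshold.
#' @return The updated ensemble.
#' @export
attachScorers <- function(ens, restriction = ens@restriction, bayes = NULL,
                          hegRscu = NULL, cal = NULL, threshold = NULL) {
  ens@restriction <- restriction
  if (!is.null(threshold)) ens@threshold <- threshold
  sc <- ens@scorers
  if (!is.null(bayes)) sc$bayes <- bayes
  if (!is.null(hegRscu)) sc$hegRscu <- .asRscuMatrix(hegRscu)
  if (!is.null(cal)) sc$cal <- cal
  ens@scorers <- sc
  validObject(ens)
  ens
}

#' Restricted expression fitness of a gene
#'
#' With restriction "none" this is the plain ensemble mean. With "HEGP"
#' ("DHEG"), the gene's HEGP (DHEG) score is computed first; if it falls
#' below the threshold the score itself is returned as the fitness,
#' otherwise the ensemble mean prediction is returned.
#'
#' @param ens an [ExpressionEnsemble-class] with the needed scorers attached
#'   (see [attachScorers()]).
#' @param g a [CodingSequence-class].
#' @param ref a [UsageReference-class] used to compute CAI.
#' @return A single fitness value.
#' @export
predictFitness <- function(ens, g, ref) {
  if (ens@restriction == "HEGP") {
    if (is.null(ens@scorers$bayes)) {
      stop("HEGP restriction requires an attached BayesHegModel (attachScorers)")
    }
    s <- hegp(g, ens@scorers$bayes)
    if (s < ens@threshold) return(s)
  } else if (ens@restriction == "DHEG") {
    if (is.null(ens@scorers$hegRscu) || is.null(ens@scorers$cal)) {
      stop("DHEG restriction requires attached hegRscu and DhegCalibration")
    }
    s <- dheg(g, ens@scorers$hegRscu, ens@scorers$cal)
    if (s < ens@threshold) return(s)
  }
  predictEnsemble(ens, cai(g, ref), gcContent(g))
}

#' LinearExpressionModel: the linear yield baseline
#'
#' Ordinary least squares of yield on (CAI, GC):
#' \deqn{\hat y_g = \hat w_1 CAI(g) + \hat w_2 GC(g) + \hat\epsilon}
#'
#' @slot w1,w2 coefficients on CAI and GC.
#' @slot intercept the fitted intercept.
#' @seealso [fitLinear()], [predictYield()]
#' @export
setClass("LinearExpressionModel",
  representation(w1 = "numeric", w2 = "numeric", intercept = "numeric")
)

setMethod("show", "LinearExpressionModel", function(object) {
  cat(sprintf("LinearExpressionModel: yield = %.4g*CAI + %.4g*GC + %.4g\n",
              object@w1, object@w2, object@intercept))
})

#' Fit the linear expression baseline by ordinary least squares
#'
#' @inheritParams trainEnsemble
#' @return A [LinearExpressionModel-class].
#' @export
fitLinear <- function(data, ref = NULL) {
  feat <- .expressionFeatures(data, ref)
  if (length(feat$y) < 3L) stop("need at least 3 records")
  df <- data.frame(y = feat$y, cai = feat$x[, 1], gc = feat$x[, 2])
  fit <- lm(y ~ cai + gc, data = df)
  cf <- coef(fit)
  if (any(is.na(cf))) stop("rank-deficient design (collinear CAI/GC)")
  new("LinearExpressionModel", w1 = unname(cf["cai"]), w2 = unname(cf["gc"]),
      intercept = unname(cf["(Intercept)"]))
}

#' @rdname fitLinear
#' @param model a [LinearExpressionModel-class].
#' @param cai,gc numeric vectors.
#' @export
predictYield <- function(model, cai, gc) {
  model@w1 * cai + model@w2 * gc + model@intercept
}
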