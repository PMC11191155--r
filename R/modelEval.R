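#' Random-forest hyperparameters
#'
#' The documented default profile (`nTrees = 500`, `mtry = 3`,
#' `splitrule = "extratrees"`, `minNodeSize = 1`) is the tuned optimum
#' reported for the 15-gene composite-biomarker setting; retune with
#' [tuneRandomForest()] for other feature counts.
#'
#' @param nTrees number of trees.
#' @param mtry features considered per split.
#' @param splitrule `"gini"` or `"extratrees"`.
#' @param minNodeSize minimum node size.
#' @return a validated list of class `RFHyperparams`.
#' @export
rfHyperparams <- function(nTrees = 500L, mtry = 3L,
                          splitrule = c("extratrees", "gini"),
                          minNodeSize = 1L) {
    splitrule <- match.arg(splitrule)
    hp <- list(nTrees = as.integer(nTrees), mtry = as.integer(mtry),
               splitrule = splitrule, minNodeSize = as.integer(minNodeSize))
    if (hp$nTrees < 1L || hp$mtry < 1L || hp$minNodeSize < 1L)
        stop("all hyperparameters must be positive")
    structure(hp, class = "RFHyperparams")
}

#' Train a probability random forest
#'
#' @param X samples x features matrix (balance the classes upstream, e.g.
#'   with [adasyn()]; this function does not resample).
#' @param y two-class labels (0/1).
#' @param hp a [rfHyperparams()].
#' @param seed integer seed; predictions are deterministic given it.
#' @return an object of class `rfModel`; `predict(model, X)` returns a list
#'   with `labels` (0/1, class 0 when its vote fraction is >= 0.5) and
#'   `score0` (fraction of trees voting class 0).
#' @export
trainRF <- function(X, y, hp = rfHyperparams(), seed = 1L) {
    stopifnot(inherits(hp, "RFHyperparams"))
    if (hp$mtry > ncol(X))
        stop("mtry (", hp$mtry, ") exceeds the number of features (",
             ncol(X), ")")
    fit <- ranger::ranger(x = as.data.frame(X), y = yFactor(y),
                          num.trees = hp$nTrees, mtry = hp$mtry,
                          splitrule = hp$splitrule,
                          min.node.size = hp$minNodeSize,
                          probability = TRUE, seed = seed,
                          num.threads = 1L, verbose = FALSE)
    structure(list(fit = fit, features = colnames(X), hp = hp),
              class = "rfModel")
}

#' @export
predict.rfModel <- function(object, newdata, ...) {
    miss <- setdiff(object$features, colnames(newdata))
    if (length(miss))
        stop("feature(s) missing from new data: ", paste(miss, collapse = ", "))
    nd <- as.data.frame(newdata[, object$features, drop = FALSE])
    pr <- predict(object$fit, data = nd, num.threads = 1L)$predictions
    score0 <- pr[, "0"]
    list(labels = ifelse(score0 >= 0.5, 0L, 1L), score0 = score0)
}

#' Grid-search hyperparameter tuning with balanced CV folds
#'
#' Evaluates `gridSize` combinations of (mtry, splitrule, minNodeSize) at a
#' fixed `nTrees` by stratified `nCV`-fold cross-validated accuracy, with
#' ADASYN applied to each training fold only. Ties are broken toward the
#' smallest mtry, then `gini`, then the smallest node size.
#'
#' @param X samples x features matrix (original, unbalanced data).
#' @param y two-class labels (0/1).
#' @param gridSize number of combinations (mtry values x split rules).
#' @param nCV folds of the tuning cross-validation.
#' @param nTrees fixed forest size during tuning.
#' @param seed integer seed.
#' @return the winning [rfHyperparams()]; attribute `"cvAccuracy"` carries
#'   the per-combination accuracies.
#' @export
tuneRandomForest <- function(X, y, gridSize = 10L, nCV = 5L, nTrees = 500L,
                             seed = 1L) {
    y <- as.integer(y)
    if (min(table(factor(y, c(0, 1)))) < nCV)
        stop("fewer samples than nCV in a class")
    p <- ncol(X)
    nMtry <- max(1L, ceiling(gridSize / 2))
    mtryVals <- unique(pmax(1L, floor(seq(1, p, length.out = nMtry))))
    grid <- expand.grid(mtry = mtryVals, splitrule = c("gini", "extratrees"),
                        minNodeSize = 1L, stringsAsFactors = FALSE)
    grid <- grid[order(grid$mtry, match(grid$splitrule, c("gini", "extratrees")),
                       grid$minNodeSize), , drop = FALSE]
    grid <- grid[seq_len(min(gridSize, nrow(grid))), , drop = FALSE]
    fold <- stratifiedFolds(y, nCV, deriveSeed(seed, 0L, 0L, "tune"))
    acc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
        hp <- rfHyperparams(nTrees, grid$mtry[g], grid$splitrule[g],
                            grid$minNodeSize[g])
        hits <- 0L
        for (f in seq_len(nCV)) {
            tr <- fold != f
            bal <- adasyn(X[tr, , drop = FALSE], y[tr],
                          seed = deriveSeed(seed, f, g, "adasyn"))
            fit <- trainRF(bal@X, bal@y, hp,
                           seed = deriveSeed(seed, f, g, "rf"))
            pred <- predict(fit, X[!tr, , drop = FALSE])
            hits <- hits + sum(pred$labels == y[!tr])
        }
        acc[g] <- hits / length(y)
    }
    best <- which.max(acc)     # grid pre-ordered => ties resolve as documented
    out <- rfHyperparams(nTrees, grid$mtry[best], grid$splitrule[best],
                         grid$minNodeSize[best])
    attr(out, "cvAccuracy") <- cbind(grid, accuracy = acc)
    out
}

assayFeatures <- function(x, genes, assayName = "logcpm") {
    mat <- SummarizedExperiment::assay(x, assayName)
    miss <- setdiff(genes, rownames(mat))
    if (length(miss))
        stop("gene(s) missing from the matrix: ", paste(miss, collapse = ", "))
    t(mat[genes, , drop = FALSE])
}

#' Repeated stratified train/test split evaluation
#'
#' `nRep` stratified splits at `testFrac`; per repetition the training side
#' is ADASYN-balanced, a forest trained, and the untouched test side
#' evaluated with the twelve metrics. Reports the per-metric mean and a 95
#' percent normal band (mean +/- 1.96 sd across repetitions).
#'
#' @param x a [MarkerExperiment-class] with a `"logcpm"` assay.
#' @param genes feature gene set (non-empty).
#' @param hp a [rfHyperparams()].
#' @param nRep repetitions.
#' @param testFrac held-out fraction per repetition.
#' @param role cohort role evaluated (`"train"` for the train-cohort
#'   protocol, `"validation"` for recalibration).
#' @param seed integer seed.
#' @return a [MetricReport-class] with per-repetition values and CI.
#' @export
protocolRepeatedSplit <- function(x, genes, hp = rfHyperparams(),
                                  nRep = 100L, testFrac = 0.10,
                                  role = "train", seed = 1L) {
    if (!length(genes)) stop("empty gene set")
    keep <- sampleRole(x) == role
    X <- assayFeatures(x[, keep], genes)
    y <- classLabel(x)[keep]
    perRep <- matrix(NA_real_, nRep, 12L)
    audit <- list(syntheticInTest = 0L, role = role)
    for (r in seq_len(nRep)) {
        testIdx <- NULL
        for (try in seq_len(10L)) {
            cand <- stratifiedSplit(y, testFrac,
                                    deriveSeed(seed, r, try, "protocol"))
            if (all(c(0L, 1L) %in% y[cand])) { testIdx <- cand; break }
        }
        if (is.null(testIdx))
            stop("could not draw a test split containing both classes")
        tr <- setdiff(seq_along(y), testIdx)
        bal <- adasyn(X[tr, , drop = FALSE], y[tr],
                      seed = deriveSeed(seed, r, 0L, "adasyn"))
        fit <- trainRF(bal@X, bal@y, hp, seed = deriveSeed(seed, r, 0L, "rf"))
        pred <- predict(fit, X[testIdx, , drop = FALSE])
        perRep[r, ] <- metricValues(
            computeMetrics(y[testIdx], pred$labels, pred$score0))
    }
    rep <- aggregateReports(perRep)
    attr(rep, "audit") <- audit
    rep
}

#' Cross-dataset validation
#'
#' One forest trained on the ADASYN-balanced full train cohort, evaluated
#' once on the untouched validation cohort.
#'
#' @param xTrain,xValid [MarkerExperiment-class] objects with `"logcpm"`
#'   assays (their train / validation samples are used respectively; pass
#'   the same combined object twice if roles live together).
#' @param genes feature gene set, present in both datasets.
#' @param hp a [rfHyperparams()].
#' @param seed integer seed.
#' @return a [MetricReport-class] (single evaluation, no CI).
#' @export
protocolCrossDataset <- function(xTrain, xValid, genes, hp = rfHyperparams(),
                                 seed = 1L) {
    if (!length(genes)) stop("empty gene set")
    trKeep <- sampleRole(xTrain) == "train"
    vaKeep <- sampleRole(xValid) == "validation"
    if (!any(vaKeep)) vaKeep <- rep(TRUE, ncol(xValid))
    Xtr <- assayFeatures(xTrain[, trKeep], genes)
    ytr <- classLabel(xTrain)[trKeep]
    Xva <- assayFeatures(xValid[, vaKeep], genes)
    yva <- classLabel(xValid)[vaKeep]
    bal <- adasyn(Xtr, ytr, seed = deriveSeed(seed, 0L, 0L, "adasyn"))
    fit <- trainRF(bal@X, bal@y, hp, seed = deriveSeed(seed, 0L, 0L, "rf"))
    pred <- predict(fit, Xva)
    computeMetrics(yva, pred$labels, pred$score0)
}

#' Random-gene baseline for a composite signature
#'
#' Repeats [protocolCrossDataset()] `nRep` times with `nGenes` genes drawn
#' uniformly without replacement from the train matrix, the negative
#' control against which a consensus signature's performance is judged.
#'
#' @inheritParams protocolCrossDataset
#' @param nGenes genes per random draw.
#' @param nRep repetitions.
#' @return a [MetricReport-class] with per-repetition values and CI;
#'   attribute `"draws"` lists the gene sets drawn.
#' @export
randomGeneBaseline <- function(xTrain, xValid, nGenes = 15L, nRep = 100L,
                               hp = rfHyperparams(), seed = 1L) {
    pool <- rownames(xTrain)
    if (nGenes > length(pool))
        stop("nGenes exceeds the number of available genes")
    perRep <- matrix(NA_real_, nRep, 12L)
    draws <- vector("list", nRep)
    for (r in seq_len(nRep)) {
        g <- withSeed(deriveSeed(seed, r, 0L, "baseline"),
                      sample(pool, nGenes))
        draws[[r]] <- g
        hpUse <- if (hp$mtry > nGenes)
            rfHyperparams(hp$nTrees, nGenes, hp$splitrule, hp$minNodeSize)
        else hp
        perRep[r, ] <- metricValues(
            protocolCrossDataset(xTrain, xValid, g, hpUse,
                                 seed = deriveSeed(seed, r, 1L, "baseline")))
    }
    rep <- aggregateReports(perRep)
    attr(rep, "draws") <- draws
    rep
}
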