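## Separable two-feature toy experiment with both cohort roles.
separableExperiment <- function(n = 60, seed = 2, nGenes = 8) {
    withr::with_seed(seed, {
        y <- rep(c(0L, 1L), length.out = n)
        lc <- matrix(rnorm(nGenes * n, 6), nGenes, n)
        lc[1, ] <- 6 + ifelse(y == 0L, 2, -2) + rnorm(n, sd = 0.1)
        lc[2, ] <- 6 + ifelse(y == 0L, -2, 2) + rnorm(n, sd = 0.1)
        dimnames(lc) <- list(sprintf("g%02d", seq_len(nGenes)),
                             sprintf("s%03d", seq_len(n)))
        cnt <- matrix(1L, nGenes, n, dimnames = dimnames(lc))
        cd <- S4Vectors::DataFrame(
            class_label = y,
            batch_id = rep(c("b1", "b2"), length.out = n),
            role = rep(c("train", "validation"), each = n / 2),
            row.names = colnames(lc))
        new("MarkerExperiment", SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = cnt, logcpm = lc), colData = cd))
    })
}

test_that("hyperparameters validate and forests are deterministic", {
    expect_error(rfHyperparams(mtry = 0), "positive")
    d <- signalNoiseData(n = 60, pNoise = 4, seed = 1)
    expect_error(trainRF(d$X, d$y, rfHyperparams(mtry = 50), seed = 1),
                 "exceeds the number of features")
    hp <- rfHyperparams(nTrees = 100, mtry = 2, splitrule = "gini")
    f1 <- trainRF(d$X, d$y, hp, seed = 9)
    f2 <- trainRF(d$X, d$y, hp, seed = 9)
    p1 <- predict(f1, d$X); p2 <- predict(f2, d$X)
    expect_identical(p1$labels, p2$labels)
    expect_equal(p1$score0, p2$score0)
    expect_true(all(p1$score0 >= 0 & p1$score0 <= 1))
    ## training accuracy 1 on a separable toy
    me <- separableExperiment()
    X <- t(SummarizedExperiment::assay(me, "logcpm")[1:2, ])
    fit <- trainRF(X, classLabel(me), rfHyperparams(mtry = 2), seed = 3)
    expect_identical(predict(fit, X)$labels, classLabel(me))
})

test_that("tuning returns the single grid point or breaks ties as documented", {
    d <- signalNoiseData(n = 50, pNoise = 2, seed = 5)
    one <- tuneRandomForest(d$X, d$y, gridSize = 1, nCV = 3, nTrees = 50,
                            seed = 1)
    expect_identical(one$mtry, 1L)
    expect_identical(one$splitrule, "gini")
    ## fully separable: every grid point ties at accuracy 1
    me <- separableExperiment()
    X <- t(SummarizedExperiment::assay(me, "logcpm")[1:2, ])
    hp <- tuneRandomForest(X, classLabel(me), gridSize = 4, nCV = 3,
                           nTrees = 50, seed = 1)
    acc <- attr(hp, "cvAccuracy")
    if (all(acc$accuracy == acc$accuracy[1])) {
        expect_identical(hp$mtry, as.integer(min(acc$mtry)))
        expect_identical(hp$splitrule, "gini")
    }
    expect_identical(hp$minNodeSize, 1L)
})

test_that("the documented default profile matches the tuned reference optimum", {
    hp <- rfHyperparams()
    expect_identical(hp$nTrees, 500L)
    expect_identical(hp$mtry, 3L)
    expect_identical(hp$splitrule, "extratrees")
    expect_identical(hp$minNodeSize, 1L)
})

test_that("repetition aggregation reproduces direct mean/CI arithmetic", {
    v <- withr::with_seed(1, matrix(runif(100 * 12, 0.6, 1), 100, 12))
    rep <- consensusMarkers:::aggregateReports(v)
    expect_equal(unname(metricValues(rep)), unname(colMeans(v)))
    expect_equal(unname(rep@ciLow), unname(colMeans(v) - 1.96 * apply(v, 2, sd)))
    expect_equal(unname(rep@ciHigh), unname(colMeans(v) + 1.96 * apply(v, 2, sd)))
    ## single repetition: CI collapses onto the mean
    one <- consensusMarkers:::aggregateReports(v[1, , drop = FALSE])
    expect_equal(one@ciLow, one@ciHigh)
    expect_equal(unname(one@ciLow), unname(v[1, ]))
})

test_that("repeated splits evaluate only untouched test samples", {
    me <- separableExperiment(n = 80)
    hp <- rfHyperparams(nTrees = 100, mtry = 2)
    rep <- protocolRepeatedSplit(me, c("g01", "g02"), hp, nRep = 5,
                                 role = "train", seed = 4)
    expect_identical(nrow(rep@perRepetition), 5L)
    ## separable signal: near-perfect held-out metrics
    expect_gt(metricValues(rep)["MCC"], 0.8)
    ## determinism
    rep2 <- protocolRepeatedSplit(me, c("g01", "g02"), hp, nRep = 5,
                                  role = "train", seed = 4)
    expect_equal(rep@perRepetition, rep2@perRepetition)
    expect_error(protocolRepeatedSplit(me, character(0), hp, nRep = 2,
                                       seed = 1), "empty gene set")
})

## combineCohorts() requires a counts assay only; rebuild with both assays.
combineCohorts2 <- function(a, b) {
    cnt <- cbind(SummarizedExperiment::assay(a, "counts"),
                 SummarizedExperiment::assay(b, "counts"))
    lc <- cbind(SummarizedExperiment::assay(a, "logcpm"),
                SummarizedExperiment::assay(b, "logcpm"))
    cd <- rbind(SummarizedExperiment::colData(a),
                SummarizedExperiment::colData(b))
    new("MarkerExperiment", SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = cnt, logcpm = lc), colData = cd))
}

test_that("cross-dataset validation on a train copy equals resubstitution", {
    me <- separableExperiment(n = 60)
    hp <- rfHyperparams(nTrees = 100, mtry = 2)
    ## validation cohort = bitwise copy of the train cohort
    tr <- me[, sampleRole(me) == "train"]
    copy <- tr
    SummarizedExperiment::colData(copy)$role <- "validation"
    colnames(copy) <- paste0("copy_", colnames(copy))
    joined <- combineCohorts2(tr, copy)
    cross <- protocolCrossDataset(joined, joined, c("g01", "g02"), hp,
                                  seed = 6)
    ## resubstitution with the same balanced training and seed
    Xtr <- t(SummarizedExperiment::assay(tr, "logcpm")[c("g01", "g02"), ])
    bal <- adasyn(Xtr, classLabel(tr),
                  seed = deriveSeed(6, 0L, 0L, "adasyn"))
    fit <- trainRF(bal@X, bal@y, hp, seed = deriveSeed(6, 0L, 0L, "rf"))
    pred <- predict(fit, Xtr)
    resub <- computeMetrics(classLabel(tr), pred$labels, pred$score0)
    expect_equal(metricValues(cross), metricValues(resub))
    expect_error(protocolCrossDataset(joined, joined, "absent", hp, seed = 1),
                 "missing from the matrix")
})


test_that("random signatures on pure noise hover at chance", {
    withr::with_seed(10, {
        n <- 80; nGenes <- 40
        lc <- matrix(rnorm(nGenes * n, 6), nGenes, n,
                     dimnames = list(sprintf("g%02d", 1:nGenes),
                                     sprintf("s%03d", 1:n)))
        cnt <- matrix(1L, nGenes, n, dimnames = dimnames(lc))
        cd <- S4Vectors::DataFrame(
            class_label = rep(c(0L, 1L), n / 2),
            batch_id = "b1",
            role = rep(c("train", "validation"), each = n / 2),
            row.names = colnames(lc))
        me <- new("MarkerExperiment",
                  SummarizedExperiment::SummarizedExperiment(
                      assays = list(counts = cnt, logcpm = lc), colData = cd))
    })
    hp <- rfHyperparams(nTrees = 100, mtry = 3)
    base <- randomGeneBaseline(me, me, nGenes = 5, nRep = 20, hp = hp,
                               seed = 3)
    expect_lt(abs(metricValues(base)["MCC"]), 0.25)
    ## draws are seed-reproducible
    base2 <- randomGeneBaseline(me, me, nGenes = 5, nRep = 20, hp = hp,
                                seed = 3)
    expect_identical(attr(base, "draws"), attr(base2, "draws"))
    expect_equal(base@perRepetition, base2@perRepetition)
    expect_error(randomGeneBaseline(me, me, nGenes = 100, nRep = 2, hp = hp,
                                    seed = 1), "exceeds")
})
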