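test_that("derived seeds are stable, injective and base-separated", {
    expect_identical(deriveSeed(42, 3, 17, "boruta"),
                     deriveSeed(42, 3, 17, "boruta"))
    grid <- expand.grid(fold = 1:10, model = 1:100,
                        context = c("lasso", "boruta", "varselrf"),
                        stringsAsFactors = FALSE)
    s1 <- mapply(deriveSeed, 1L, grid$fold, grid$model, grid$context)
    expect_false(anyDuplicated(s1) > 0)
    s2 <- mapply(deriveSeed, 2L, grid$fold, grid$model, grid$context)
    expect_length(intersect(s1, s2), 0)
    expect_true(all(s1 >= 0 & s1 < 2^31))
    expect_error(deriveSeed(1, 1, 1, "nope"), "unknown seed context")
})

## A small but complete consensus run shared by the blocks below.
tinyRun <- function(seed = 5) {
    pr <- preppedSim(simConfig(nGenes = 40, nBatches = 2, samplesPerBatch = 20,
                               nSignal = 4, signalLFC = 2, nbDispersion = 0.2,
                               seed = 3))
    cp <- consensusParams(nFolds = 3, nModels = 5, minFolds = 2,
                          varselrfNTreesFirst = 500L,
                          varselrfNTreesIter = 200L, seed = seed)
    list(ledger = suppressWarnings(runSelectionCV(pr$X, cp, y = pr$y)),
         truth = pr$truth, params = cp, y = pr$y)
}

test_that("the selection engine is reproducible and internally consistent", {
    a <- tinyRun(); b <- tinyRun()
    expect_identical(a$ledger@records, b$ledger@records)
    expect_identical(a$ledger@foldAssignments, b$ledger@foldAssignments)
    expect_identical(robustGenes(a$ledger), robustGenes(b$ledger))
    ## aggregate on the raw records reproduces the robust set
    agg <- aggregateLedger(a$ledger)
    expect_identical(agg$robustGenes, robustGenes(a$ledger))
    ## robust genes come from the union of fold pools
    expect_true(all(agg$robustGenes %in% unlist(a$ledger@lassoPools)))
    ## tree-selector records never leave the fold's LASSO pool
    rec <- ledgerRecords(a$ledger)
    for (f in unique(rec$fold)) {
        tree <- rec$gene[rec$fold == f & rec$selector != "lasso"]
        expect_true(all(tree %in% a$ledger@lassoPools[[f]]))
    }
})

test_that("raising thresholds never grows the robust set", {
    a <- tinyRun()
    base <- aggregateLedger(a$ledger)$robustGenes
    for (mf in c(0.8, 0.9, 1.0))
        for (minF in 2:3) {
            shr <- aggregateLedger(a$ledger, modelFreq = mf,
                                   minFolds = minF)$robustGenes
            if (mf >= a$ledger@modelFreq && minF >= a$ledger@minFolds)
                expect_true(all(shr %in% base))
        }
})

test_that("no selection record derives from samples outside the fold's training portion", {
    a <- tinyRun()
    fa <- a$ledger@foldAssignments
    for (f in seq_len(a$params$nFolds)) {
        inFold <- names(fa)[fa == f]
        expect_length(intersect(a$ledger@foldTrainIds[[f]], inFold), 0)
        expect_setequal(a$ledger@foldTrainIds[[f]], names(fa)[fa != f])
    }
})

test_that("ledgers round-trip through CSV with the robust set intact", {
    a <- tinyRun()
    path <- withr::local_tempfile(fileext = ".csv")
    writeLedger(a$ledger, path)
    back <- readLedger(path, nFolds = a$params$nFolds,
                       nModels = a$params$nModels,
                       modelFreq = a$params$modelFreq,
                       minFolds = a$params$minFolds)
    expect_identical(aggregateLedger(back)$robustGenes,
                     robustGenes(a$ledger))
    expect_identical(back@records$gene, a$ledger@records$gene)
})

test_that("fold-count aggregation honours inclusive thresholds", {
    ## hand-built ledger: nModels = 10, modelFreq = 0.8 => threshold 8 models
    mk <- function(gene, selector, folds, nPerFold) {
        do.call(rbind, lapply(seq_along(folds), function(i)
            data.frame(fold = folds[i], model = seq_len(nPerFold[i]),
                       selector = selector, gene = gene,
                       stringsAsFactors = FALSE)))
    }
    rec <- rbind(
        mk("gA", "boruta", 1:10, rep(10, 10)),     # 10 folds, every model
        mk("gA", "varselrf", 1:10, rep(10, 10)),
        mk("gB", "boruta", 1:10, rep(8, 10)),      # exactly 80% of models
        mk("gB", "varselrf", 1:5, rep(8, 5)),      # exactly minFolds folds
        mk("gC", "boruta", 1:10, rep(10, 10)),
        mk("gC", "varselrf", 1:4, rep(10, 4)),     # one fold short
        mk("gD", "boruta", 1:10, rep(7, 10)),      # below the model threshold
        mk("gD", "varselrf", 1:10, rep(10, 10)))
    led <- new("SelectionLedger", records = rec, nFolds = 10L, nModels = 10L,
               modelFreq = 0.8, minFolds = 5L, resample = "bootstrap",
               seed = 1L, foldAssignments = integer(0), foldTrainIds = list(),
               lassoPools = list())
    agg <- aggregateLedger(led)
    expect_setequal(agg$robustGenes, c("gA", "gB"))
    s <- agg$summary
    expect_identical(s$varselrf[s$gene == "gC"], 4L)
    expect_identical(s$boruta[s$gene == "gD"], 0L)
})

test_that("a class smaller than nFolds is rejected with advice", {
    d <- signalNoiseData(n = 12, pNoise = 4, seed = 1)
    expect_error(runSelectionCV(d$X, consensusParams(nFolds = 10), y = d$y),
                 "fewer than nFolds")
})
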