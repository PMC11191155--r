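## Shared fixture builders; everything is generated in code.

toyCounts <- function(nGenes = 10L, nSamples = 4L, seed = 42L) {
    withr::with_seed(seed, {
        m <- matrix(rpois(nGenes * nSamples, 50), nGenes, nSamples,
                    dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                                    sprintf("s%02d", seq_len(nSamples))))
        storage.mode(m) <- "integer"
        m
    })
}

toySampleTable <- function(ids, classes = NULL, batches = "b1",
                           roles = "train") {
    n <- length(ids)
    if (is.null(classes)) classes <- rep_len(c(0L, 1L), n)
    data.frame(sample_id = ids, class_label = rep_len(classes, n),
               batch_id = rep_len(batches, n), role = rep_len(roles, n),
               stringsAsFactors = FALSE)
}

## Small simulated experiment, preprocessed up to corrected log-CPM.
preppedSim <- function(cfg, applyFilters = TRUE, correct = TRUE) {
    sim <- simulateDataset(cfg)
    me <- sim$experiment
    cnt <- SummarizedExperiment::assay(me, "counts")
    lc <- logCPM(cnt, tmmFactors(cnt))
    st <- data.frame(sample_id = colnames(me), class_label = classLabel(me),
                     batch_id = batchId(me), role = sampleRole(me),
                     stringsAsFactors = FALSE)
    if (applyFilters) {
        mask <- combineMasks(filterGenes(lc, st), filterBatchInconsistent(lc, st))
        lc <- lc[mask$kept, , drop = FALSE]
    }
    if (correct && length(unique(st$batch_id)) > 1L)
        lc <- arsynCorrect(lc, st)$corrected
    list(X = t(lc), y = classLabel(me), st = st, truth = sim$truth,
         logcpm = lc, experiment = me)
}

## Labels with one perfectly predictive feature among noise.
signalNoiseData <- function(n = 200L, pNoise = 20L, seed = 1L,
                            informative = "f1") {
    withr::with_seed(seed, {
        y <- rep(c(0L, 1L), length.out = n)
        f1 <- y + rnorm(n, sd = 0.3)
        X <- cbind(f1, matrix(rnorm(n * pNoise), n, pNoise))
        colnames(X) <- c(informative, sprintf("noise%02d", seq_len(pNoise)))
        list(X = X, y = y)
    })
}

sampleTableOf <- function(me) {
    data.frame(sample_id = colnames(me), class_label = classLabel(me),
               batch_id = batchId(me), role = sampleRole(me),
               stringsAsFactors = FALSE)
}

## The scaled-down consensus benchmark conditions: 300-sample 3-batch train
## cohort (65/35 imbalance), 500 genes, 15 planted at lfc 1, a 150-sample
## 2-batch validation cohort sharing the signature, selection at 5 folds x
## 25 models with the half-the-folds robustness rule.
benchmarkConfig <- function(seed, randomBaseline = TRUE) {
    list(seed = seed,
         simulate = list(
             train = list(),                     # generator defaults
             validation = list(nBatches = 2, samplesPerBatch = 75)),
         consensus = list(nFolds = 5, nModels = 25, minFolds = 3),
         protocols = list(repeatedSplit = FALSE, recalibration = FALSE,
                          crossDataset = TRUE,
                          randomBaseline = randomBaseline,
                          nRep = 100, nRandomGenes = 15))
}

nullConfig <- function(seed) {
    list(seed = seed,
         simulate = list(train = list(nSignal = 0)),
         consensus = list(nFolds = 5, nModels = 25, minFolds = 3),
         protocols = list(repeatedSplit = FALSE, recalibration = FALSE,
                          crossDataset = FALSE, randomBaseline = FALSE))
}
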