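#' Parameters of the consensus selection run
#'
#' Defaults mirror the reference protocol: 10 stratified folds, 100
#' resampled models per fold, a gene must appear in at least 80 percent of a
#' fold's models to count for that fold, and in at least 5 folds for BOTH
#' tree-based selectors to enter the robust set. Thresholds are inclusive
#' ("at least").
#'
#' @param nFolds number of cross-validation folds.
#' @param nModels resampled models per fold (per selector).
#' @param modelFreq within-fold model frequency threshold in (0, 1].
#' @param minFolds minimum fold count for the robust set, in 1..nFolds.
#' @param resample per-model resampling scheme: stratified `"bootstrap"`
#'   (default) or 90 percent stratified `"subsample90"`.
#' @param seed integer base seed; every fold x model x selector cell draws
#'   from its own [deriveSeed()] stream.
#' @param lassoNCV,borutaMaxRuns,borutaNTrees,varselrfNTreesFirst,
#'   varselrfNTreesIter selector settings passed through.
#' @return a validated list of class `ConsensusParams`.
#' @export
consensusParams <- function(nFolds = 10L, nModels = 100L, modelFreq = 0.80,
                            minFolds = 5L,
                            resample = c("bootstrap", "subsample90"),
                            seed = 1L, lassoNCV = 5L, borutaMaxRuns = 100L,
                            borutaNTrees = 100L, varselrfNTreesFirst = 2000L,
                            varselrfNTreesIter = 500L) {
    resample <- match.arg(resample)
    cp <- list(nFolds = as.integer(nFolds), nModels = as.integer(nModels),
               modelFreq = modelFreq, minFolds = as.integer(minFolds),
               resample = resample, seed = as.integer(seed),
               lassoNCV = as.integer(lassoNCV),
               borutaMaxRuns = as.integer(borutaMaxRuns),
               borutaNTrees = as.integer(borutaNTrees),
               varselrfNTreesFirst = as.integer(varselrfNTreesFirst),
               varselrfNTreesIter = as.integer(varselrfNTreesIter))
    if (cp$modelFreq <= 0 || cp$modelFreq > 1)
        stop("modelFreq must lie in (0, 1]")
    if (cp$minFolds < 1L || cp$minFolds > cp$nFolds)
        stop("minFolds must lie in 1..nFolds")
    structure(cp, class = "ConsensusParams")
}

#' Consensus variable selection over folds and resampled models
#'
#' The core selection engine. Train samples are partitioned into `nFolds`
#' stratified folds; within each fold, only the other `nFolds - 1` folds'
#' samples (that fold's training portion) are ever touched. Per model index,
#' a stratified resample of the training portion is drawn, ADASYN-balanced,
#' and run through LASSO; the fold's LASSO pool is the set of genes present
#' in at least `modelFreq` of the fold's LASSO models. The same resamples
#' (paired by model index, re-balanced on the pool features) then feed the
#' Boruta-style and varSelRF-style selectors restricted to the pool. A gene
#' is fold-selected for a selector when it appears in at least
#' `modelFreq * nModels` of that selector's models in the fold; the robust
#' set contains the genes fold-selected in at least `minFolds` folds by BOTH
#' tree-based selectors.
#'
#' @param x a [MarkerExperiment-class] with a `"logcpm"` assay (train
#'   samples only are used), or a samples x genes matrix.
#' @param params a [consensusParams()].
#' @param y,sampleIds labels and ids when `x` is a plain matrix.
#' @return a [SelectionLedger-class]; [robustGenes()] extracts the robust
#'   set and [aggregateLedger()] the per-gene fold-count table.
#' @export
runSelectionCV <- function(x, params = consensusParams(), y = NULL,
                           sampleIds = NULL) {
    stopifnot(inherits(params, "ConsensusParams"))
    if (is(x, "MarkerExperiment")) {
        keep <- sampleRole(x) == "train"
        X <- t(SummarizedExperiment::assay(x, "logcpm")[, keep, drop = FALSE])
        y <- classLabel(x)[keep]
        sampleIds <- colnames(x)[keep]
    } else {
        X <- as.matrix(x)
        stopifnot(!is.null(y))
        if (is.null(sampleIds))
            sampleIds <- rownames(X)
        if (is.null(sampleIds)) sampleIds <- sprintf("s%04d", seq_len(nrow(X)))
    }
    y <- as.integer(y)
    if (min(table(factor(y, c(0, 1)))) < params$nFolds)
        stop("a class has fewer than nFolds samples; reduce nFolds")
    fold <- stratifiedFolds(y, params$nFolds,
                            deriveSeed(params$seed, 0L, 0L, "split"))
    nModelThresh <- params$modelFreq * params$nModels - 1e-9
    recs <- list()
    pools <- vector("list", params$nFolds)
    foldTrainIds <- vector("list", params$nFolds)
    for (f in seq_len(params$nFolds)) {
        trIdx <- which(fold != f)
        foldTrainIds[[f]] <- sampleIds[trIdx]
        Xf <- X[trIdx, , drop = FALSE]
        yf <- y[trIdx]
        modelGenes <- vector("list", params$nModels)
        for (m in seq_len(params$nModels)) {
            ri <- resampleIndices(yf, params$resample,
                                  deriveSeed(params$seed, f, m, "resample"))
            bal <- adasyn(Xf[ri, , drop = FALSE], yf[ri],
                          seed = deriveSeed(params$seed, f, m, "adasyn"))
            res <- lassoSelect(bal@X, bal@y, nCV = params$lassoNCV,
                               seed = deriveSeed(params$seed, f, m, "lasso"))
            modelGenes[[m]] <- res$genes
            if (length(res$genes))
                recs[[length(recs) + 1L]] <- data.frame(
                    fold = f, model = m, selector = "lasso",
                    gene = res$genes, stringsAsFactors = FALSE)
        }
        cnt <- table(unlist(modelGenes))
        pool <- sort(names(cnt)[cnt >= nModelThresh], method = "radix")
        pools[[f]] <- pool
        if (!length(pool)) {
            warning("fold ", f, ": empty LASSO pool; fold contributes no selections")
            next
        }
        for (m in seq_len(params$nModels)) {
            ri <- resampleIndices(yf, params$resample,
                                  deriveSeed(params$seed, f, m, "resample"))
            bal <- adasyn(Xf[ri, pool, drop = FALSE], yf[ri],
                          seed = deriveSeed(params$seed, f, m, "adasyn"))
            bo <- borutaSelect(bal@X, bal@y, maxRuns = params$borutaMaxRuns,
                               nTrees = params$borutaNTrees,
                               seed = deriveSeed(params$seed, f, m, "boruta"))
            vs <- varSelRFSelect(bal@X, bal@y,
                                 nTreesFirst = params$varselrfNTreesFirst,
                                 nTreesIter = params$varselrfNTreesIter,
                                 seed = deriveSeed(params$seed, f, m, "varselrf"))
            for (res in list(bo, vs))
                if (length(res$genes))
                    recs[[length(recs) + 1L]] <- data.frame(
                        fold = f, model = m, selector = res$selector,
                        gene = res$genes, stringsAsFactors = FALSE)
        }
    }
    records <- if (length(recs)) do.call(rbind, recs) else
        data.frame(fold = integer(0), model = integer(0),
                   selector = character(0), gene = character(0),
                   stringsAsFactors = FALSE)
    new("SelectionLedger", records = records, nFolds = params$nFolds,
        nModels = params$nModels, modelFreq = params$modelFreq,
        minFolds = params$minFolds, resample = params$resample,
        seed = params$seed,
        foldAssignments = setNames(as.integer(fold), sampleIds),
        foldTrainIds = foldTrainIds, lassoPools = pools)
}

#' Aggregate a selection ledger into fold counts and the robust set
#'
#' Recomputes the per-fold selection flags and the robust set from the raw
#' (fold, model, selector, gene) records: a gene counts for a fold/selector
#' when it appears in at least `modelFreq * nModels` of that fold's models
#' (inclusive); the robust set needs at least `minFolds` fold counts for
#' both `boruta` and `varselrf`.
#'
#' @param ledger a [SelectionLedger-class].
#' @param modelFreq,minFolds override the ledger's thresholds (for
#'   sensitivity analyses; raising either can only shrink the set).
#' @return list with `summary` (data.frame gene x selector fold counts,
#'   shaped like a published selection-frequency table) and `robustGenes`.
#' @export
aggregateLedger <- function(ledger, modelFreq = ledger@modelFreq,
                            minFolds = ledger@minFolds) {
    rec <- ledger@records
    genes <- sort(unique(rec$gene), method = "radix")
    selectors <- c("lasso", "boruta", "varselrf")
    foldCounts <- matrix(0L, length(genes), 3,
                         dimnames = list(genes, selectors))
    if (nrow(rec)) {
        thresh <- modelFreq * ledger@nModels - 1e-9
        ## model counts per (fold, selector, gene); \r never occurs in ids
        key <- paste(rec$fold, rec$selector, rec$gene, sep = "\r")
        cnt <- table(key)
        parts <- strsplit(names(cnt), "\r", fixed = TRUE)
        sel <- vapply(parts, `[`, "", 2L)
        gn <- vapply(parts, `[`, "", 3L)
        ok <- as.integer(cnt) >= thresh
        for (i in which(ok))
            foldCounts[gn[i], sel[i]] <- foldCounts[gn[i], sel[i]] + 1L
    }
    robust <- genes[foldCounts[, "boruta"] >= minFolds &
                    foldCounts[, "varselrf"] >= minFolds]
    summary <- data.frame(gene = genes,
                          lasso = foldCounts[, "lasso"],
                          boruta = foldCounts[, "boruta"],
                          varselrf = foldCounts[, "varselrf"],
                          robust = genes %in% robust,
                          row.names = NULL, stringsAsFactors = FALSE)
    summary <- summary[order(-summary$boruta - summary$varselrf - summary$lasso,
                             summary$gene, method = "radix"), ]
    rownames(summary) <- NULL
    list(summary = summary, robustGenes = robust)
}

#' @rdname robustGenes
setMethod("robustGenes", "SelectionLedger", function(x, ...)
    aggregateLedger(x, ...)$robustGenes)

#' Write / read a selection ledger (long-format CSV)
#'
#' Only the raw records travel; [aggregateLedger()] on a re-read ledger with
#' the same thresholds reproduces the robust set.
#'
#' @param ledger a [SelectionLedger-class].
#' @param path destination CSV.
#' @export
writeLedger <- function(ledger, path) {
    utils::write.table(ledger@records, path, sep = ",", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeLedger
#' @param nFolds,nModels,modelFreq,minFolds run parameters of the ledger
#'   being read back.
#' @export
readLedger <- function(path, nFolds, nModels, modelFreq = 0.8, minFolds = 5L) {
    rec <- utils::read.table(path, header = TRUE, sep = ",",
                             stringsAsFactors = FALSE)
    new("SelectionLedger", records = rec, nFolds = as.integer(nFolds),
        nModels = as.integer(nModels), modelFreq = modelFreq,
        minFolds = as.integer(minFolds), resample = "bootstrap",
        seed = NA_integer_, foldAssignments = integer(0),
        foldTrainIds = list(), lassoPools = list())
}
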