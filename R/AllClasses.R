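#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

REQUIRED_SAMPLE_COLS <- c("sample_id", "class_label", "batch_id", "role")
SAMPLE_ROLES <- c("train", "validation")
CLASS_LEVELS <- c(0L, 1L)

#' MarkerExperiment: expression data with biomarker-study sample annotation
#'
#' An extension of \linkS4class{SummarizedExperiment} whose column metadata
#' carries the three annotations the pipeline needs: a binary class label
#' (0 = metastasis, the majority class in the motivating disease setting;
#' 1 = non-metastasis), a batch/cohort identifier, and a cohort role
#' (\code{"train"} or \code{"validation"}). The \code{"counts"} assay holds
#' non-negative integer counts (genes x samples); normalisation adds a
#' \code{"logcpm"} assay of finite log2 counts-per-million.
#'
#' @seealso [MarkerExperiment()], [classLabel()], [batchId()], [sampleRole()]
#' @export
setClass("MarkerExperiment", contains = "SummarizedExperiment")

setValidity("MarkerExperiment", function(object) {
    msg <- character()
    cd <- SummarizedExperiment::colData(object)
    need <- c("class_label", "batch_id", "role")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        return(paste("missing colData column(s):", paste(miss, collapse = ", ")))
    if (nrow(object) < 2L || ncol(object) < 2L)
        msg <- c(msg, "need at least 2 genes and 2 samples")
    gid <- rownames(object); sid <- colnames(object)
    if (is.null(gid) || anyDuplicated(gid))
        msg <- c(msg, "gene ids must be present and unique")
    if (is.null(sid) || anyDuplicated(sid))
        msg <- c(msg, "sample ids must be present and unique")
    if (!all(cd$class_label %in% CLASS_LEVELS))
        msg <- c(msg, "class_label must be 0 (metastasis) or 1 (non-metastasis)")
    if (!all(cd$role %in% SAMPLE_ROLES))
        msg <- c(msg, sprintf("role must be one of: %s",
                              paste(SAMPLE_ROLES, collapse = ", ")))
    if (any(is.na(cd$batch_id)))
        msg <- c(msg, "batch_id must not contain NA")
    an <- SummarizedExperiment::assayNames(object)
    if ("counts" %in% an) {
        cnt <- SummarizedExperiment::assay(object, "counts")
        if (anyNA(cnt) || any(cnt < 0))
            msg <- c(msg, "counts must be non-negative and non-missing")
    }
    if ("logcpm" %in% an) {
        lc <- SummarizedExperiment::assay(object, "logcpm")
        if (!all(is.finite(lc)))
            msg <- c(msg, "logcpm entries must all be finite")
    }
    if (length(msg)) msg else TRUE
})

#' Per-(fold, model, selector) record of consensus variable selection
#'
#' The substrate of consensus aggregation: one row per gene retained by one
#' selector in one resampled model of one cross-validation fold, together
#' with the fold layout, the per-fold LASSO pools and the parameters the run
#' used. [aggregateLedger()] recomputes fold counts and the robust set from
#' the raw records.
#'
#' @slot records data.frame with columns fold, model, selector, gene.
#' @slot nFolds,nModels,modelFreq,minFolds,resample,seed run parameters.
#' @slot foldAssignments integer vector, fold index per training sample id.
#' @slot foldTrainIds list of character vectors: sample ids each fold's
#'   selection models were allowed to see (leakage audit consults this).
#' @slot lassoPools list of character vectors, the per-fold LASSO pools.
#' @export
setClass("SelectionLedger", representation(
    records = "data.frame",
    nFolds = "integer",
    nModels = "integer",
    modelFreq = "numeric",
    minFolds = "integer",
    resample = "character",
    seed = "integer",
    foldAssignments = "integer",
    foldTrainIds = "list",
    lassoPools = "list"
))

setValidity("SelectionLedger", function(object) {
    rec <- object@records
    need <- c("fold", "model", "selector", "gene")
    if (!all(need %in% colnames(rec)))
        return("records must have columns fold, model, selector, gene")
    if (nrow(rec)) {
        if (any(rec$fold < 1L | rec$fold > object@nFolds))
            return("record fold outside 1..nFolds")
        if (any(rec$model < 1L | rec$model > object@nModels))
            return("record model outside 1..nModels")
        if (!all(rec$selector %in% c("lasso", "boruta", "varselrf")))
            return("unknown selector in records")
    }
    TRUE
})

#' Fitted batch-variance model from ASCA-style correction
#'
#' @slot nComponents number of retained systematic components.
#' @slot varianceShares explained-variance share of each candidate component.
#' @slot batchEffects genes x batches matrix of reconstructed systematic
#'   batch effects (the quantity subtracted from every sample of the batch).
#' @slot batchSizes named integer vector of batch sizes used in the fit.
#' @slot beta component-selection multiplier.
#' @slot joint logical; TRUE when fit on train and validation together.
#' @export
setClass("BatchModel", representation(
    nComponents = "integer",
    varianceShares = "numeric",
    batchEffects = "matrix",
    batchSizes = "integer",
    beta = "numeric",
    joint = "logical"
))

setValidity("BatchModel", function(object) {
    if (object@nComponents < 0L) return("retained components must be >= 0")
    eff <- object@batchEffects
    if (ncol(eff) && length(object@batchSizes) == ncol(eff)) {
        w <- object@batchSizes / sum(object@batchSizes)
        resid <- max(abs(eff %*% w))
        scale <- max(abs(eff), 1)
        if (resid > 1e-6 * scale)
            return("batch effects must sum to ~0 across batches (size-weighted)")
    }
    TRUE
})

#' Twelve-metric evaluation report
#'
#' Holds the twelve metrics used throughout: precision/recall/F1 for class 0
#' (metastasis) and class 1 (non-metastasis), their macro averages, ROC-AUC,
#' PR-AUC (average precision with class 0 positive) and the Matthews
#' correlation coefficient. For repeated protocols, per-repetition values and
#' a normal-approximation 95 percent interval (mean +/- 1.96 sd) are kept.
#'
#' @slot metrics named numeric of the 12 metrics (point value or mean).
#' @slot perRepetition matrix (repetitions x metrics) or 0-row matrix.
#' @slot ciLow,ciHigh named numerics (empty for single evaluations).
#' @slot flags character; e.g. records precisions reported as 0 because no
#'   sample was predicted into that class.
#' @export
setClass("MetricReport", representation(
    metrics = "numeric",
    perRepetition = "matrix",
    ciLow = "numeric",
    ciHigh = "numeric",
    flags = "character"
))

METRIC_NAMES <- c("PC0", "RC0", "F10", "PC1", "RC1", "F11",
                  "MPC", "MRC", "MF1", "ROC_AUC", "PR_AUC", "MCC")

setValidity("MetricReport", function(object) {
    m <- object@metrics
    if (!identical(names(m), METRIC_NAMES))
        return("metrics must be named PC0,RC0,F10,PC1,RC1,F11,MPC,MRC,MF1,ROC_AUC,PR_AUC,MCC")
    ok <- m[setdiff(METRIC_NAMES, "MCC")]
    ok <- ok[!is.na(ok)]
    if (length(ok) && (any(ok < -1e-12) || any(ok > 1 + 1e-12)))
        return("metrics other than MCC must lie in [0,1]")
    if (!is.na(m["MCC"]) && (m["MCC"] < -1 - 1e-12 || m["MCC"] > 1 + 1e-12))
        return("MCC must lie in [-1,1]")
    TRUE
})

#' Planted ground truth of a simulated dataset
#'
#' @slot signalGenes ids of the planted signature genes.
#' @slot lfc log2 fold change (class 0 over class 1) per planted gene.
#' @export
setClass("SyntheticTruth", representation(
    signalGenes = "character",
    lfc = "numeric"
))

setValidity("SyntheticTruth", function(object) {
    if (length(object@signalGenes) != length(object@lfc))
        return("signalGenes and lfc must have equal length")
    if (anyDuplicated(object@signalGenes))
        return("signalGenes must be unique")
    TRUE
})

#' Class-balanced training set produced by ADASYN
#'
#' @slot X samples x features matrix; original rows first, bit-identical to
#'   the input, followed by synthetic minority rows.
#' @slot y class labels aligned to rows of X.
#' @slot origin factor with levels original/synthetic.
#' @export
setClass("BalancedSet", representation(
    X = "matrix",
    y = "integer",
    origin = "factor"
))

setValidity("BalancedSet", function(object) {
    if (nrow(object@X) != length(object@y) ||
        nrow(object@X) != length(object@origin))
        return("X rows, y and origin must align")
    if (!all(levels(object@origin) %in% c("original", "synthetic")))
        return("origin levels must be original/synthetic")
    TRUE
})
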