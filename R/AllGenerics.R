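#' @include AllClasses.R
NULL

#' Accessors for MarkerExperiment annotation
#'
#' `classLabel()` returns the binary class per sample (0 = metastasis,
#' 1 = non-metastasis), `batchId()` the batch/cohort identifier and
#' `sampleRole()` the cohort role (`train`/`validation`).
#'
#' @param x a [MarkerExperiment-class].
#' @return an atomic vector of length `ncol(x)`.
#' @examples
#' me <- simulateDataset(simConfig(nGenes = 20, nBatches = 2,
#'     samplesPerBatch = 10, seed = 1))$experiment
#' table(classLabel(me), batchId(me))
#' @aliases classLabel batchId sampleRole
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))

#' @rdname classLabel
#' @export
setGeneric("batchId", function(x) standardGeneric("batchId"))

#' @rdname classLabel
#' @export
setGeneric("sampleRole", function(x) standardGeneric("sampleRole"))

#' @rdname classLabel
setMethod("classLabel", "MarkerExperiment", function(x)
    as.integer(SummarizedExperiment::colData(x)$class_label))

#' @rdname classLabel
setMethod("batchId", "MarkerExperiment", function(x)
    as.character(SummarizedExperiment::colData(x)$batch_id))

#' @rdname classLabel
setMethod("sampleRole", "MarkerExperiment", function(x)
    as.character(SummarizedExperiment::colData(x)$role))

#' Extract the robust consensus gene set
#'
#' @param x a [SelectionLedger-class] (or an object carrying one).
#' @param ... passed to methods.
#' @return character vector of gene ids.
#' @export
setGeneric("robustGenes", function(x, ...) standardGeneric("robustGenes"))

#' Extract metric values
#'
#' @param x a [MetricReport-class].
#' @return named numeric vector of the 12 metrics.
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

#' @rdname metricValues
setMethod("metricValues", "MetricReport", function(x) x@metrics)

#' Ledger record accessor
#'
#' @param x a [SelectionLedger-class].
#' @return the long-format data.frame of (fold, model, selector, gene) rows.
#' @export
setGeneric("ledgerRecords", function(x) standardGeneric("ledgerRecords"))

#' @rdname ledgerRecords
setMethod("ledgerRecords", "SelectionLedger", function(x) x@records)

setMethod("show", "MarkerExperiment", function(object) {
    callNextMethod()
    cl <- classLabel(object)
    cat(sprintf("class balance: %d metastasis (0) / %d non-metastasis (1)\n",
                sum(cl == 0L), sum(cl == 1L)))
    cat(sprintf("batches: %s\n",
                paste(unique(batchId(object)), collapse = ", ")))
    cat(sprintf("roles: %s\n",
                paste(sprintf("%s=%d", names(table(sampleRole(object))),
                              table(sampleRole(object))), collapse = ", ")))
})

setMethod("show", "SelectionLedger", function(object) {
    cat(sprintf("SelectionLedger: %d folds x %d models, %d records\n",
                object@nFolds, object@nModels, nrow(object@records)))
    cat(sprintf("thresholds: >=%g%% of models per fold, >=%d folds (both tree selectors)\n",
                100 * object@modelFreq, object@minFolds))
    rb <- robustGenes(object)
    cat(sprintf("robust set: %d gene(s)%s\n", length(rb),
                if (length(rb)) paste0(" [", paste(utils::head(rb, 8), collapse = ", "),
                                       if (length(rb) > 8) ", ..." else "", "]") else ""))
})

setMethod("show", "MetricReport", function(object) {
    cat("MetricReport (class 0 = metastasis is the positive class)\n")
    m <- object@metrics
    if (length(object@ciLow)) {
        for (k in names(m))
            cat(sprintf("  %-8s %.3f [%.3f; %.3f]\n", k, m[k],
                        object@ciLow[k], object@ciHigh[k]))
        cat(sprintf("  (mean and 95%% CI over %d repetitions)\n",
                    nrow(object@perRepetition)))
    } else {
        for (k in names(m)) cat(sprintf("  %-8s %.3f\n", k, m[k]))
    }
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "BatchModel", function(object) {
    cat(sprintf("BatchModel: %d retained component(s), beta = %g, %s fit\n",
                object@nComponents, object@beta,
                if (object@joint) "joint train+validation" else "train-only (strict)"))
    cat(sprintf("batches: %s\n",
                paste(sprintf("%s(n=%d)", names(object@batchSizes),
                              object@batchSizes), collapse = ", ")))
})

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf("SyntheticTruth: %d planted signature gene(s)\n",
                length(object@signalGenes)))
    if (length(object@signalGenes))
        cat(sprintf("log2 fold changes (class 0 vs 1): %s\n",
                    paste(unique(object@lfc), collapse = ", ")))
})

setMethod("show", "BalancedSet", function(object) {
    tb <- table(object@origin)
    cat(sprintf("BalancedSet: %d original + %d synthetic rows, %d features\n",
                tb[["original"]], if ("synthetic" %in% names(tb)) tb[["synthetic"]] else 0L,
                ncol(object@X)))
    print(table(class = object@y, origin = object@origin))
})
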