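#' ASCA-style removal of systematic batch variance
#'
#' Decomposes the batch submodel of the log-expression matrix (each sample
#' replaced by its batch's gene-wise mean, after gene centering) by singular
#' value decomposition, retains the leading components whose explained
#' variance share exceeds `beta` times the average share of the full
#' sample-space decomposition, reconstructs each batch's systematic effect
#' from the retained components and subtracts it from every sample of that
#' batch. Biological class structure is protected only insofar as each batch
#' contains both classes, which is therefore enforced.
#'
#' The default fits the correction on all samples jointly (train and
#' validation together), accepting the train/validation dependence this
#' creates; [leakageAudit()] flags it. `strict = TRUE` fits on train samples
#' only: train batches are corrected from the train fit, and batches with no
#' train samples are aligned to the train grand mean via their own batch
#' means (no validation sample influences the train-side correction).
#'
#' @param logcpm genes x samples matrix of log expression.
#' @param sampleData aligned sample table (columns class_label, batch_id,
#'   role).
#' @param beta component-selection multiplier (default 2).
#' @param strict logical; fit on train samples only (see Details).
#' @return list with `corrected` (matrix, same shape) and `model`
#'   ([BatchModel-class]).
#' @export
arsynCorrect <- function(logcpm, sampleData, beta = 2, strict = FALSE) {
    stopifnot(ncol(logcpm) == nrow(sampleData))
    b <- as.character(sampleData$batch_id)
    y <- sampleData$class_label
    role <- sampleData$role
    fitIdx <- if (strict) which(role == "train") else seq_len(ncol(logcpm))
    fitBatches <- unique(b[fitIdx])
    if (length(fitBatches) < 2L) {
        warning("single batch in the fit: nothing to correct")
        model <- new("BatchModel", nComponents = 0L, varianceShares = numeric(0),
                     batchEffects = matrix(0, nrow(logcpm), 0),
                     batchSizes = integer(0), beta = beta, joint = !strict)
        return(list(corrected = logcpm, model = model))
    }
    for (bb in fitBatches) {
        inb <- b == bb & seq_len(ncol(logcpm)) %in% fitIdx
        if (!any(y[inb] == 0L) || !any(y[inb] == 1L))
            stop("batch '", bb, "' lacks one of the two classes; ",
                 "batch correction requires both classes in every batch")
    }
    center <- rowMeans(logcpm[, fitIdx, drop = FALSE])
    nb <- vapply(fitBatches, function(bb) sum(b[fitIdx] == bb), integer(1))
    M <- vapply(fitBatches, function(bb)
        rowMeans(logcpm[, intersect(which(b == bb), fitIdx), drop = FALSE]) - center,
        numeric(nrow(logcpm)))
    ## size-weighted centering of the batch means (exact 0 for a joint fit)
    w <- nb / sum(nb)
    M <- M - as.vector(M %*% w)
    Bw <- t(M) * sqrt(nb)                       # batches x genes, size-weighted
    sv <- svd(Bw)
    tot <- sum(sv$d^2)
    if (tot < 1e-24) {
        retain <- logical(length(sv$d))
    } else {
        shares <- sv$d^2 / tot
        ## average share taken over the full sample-space decomposition of
        ## the batch submodel, as in ASCA practice (the batch-mean matrix has
        ## at most nBatches - 1 nonzero components, each compared against
        ## beta / K with K = min(n_fit, n_genes))
        K <- min(length(fitIdx), nrow(logcpm))
        retain <- shares >= beta / K & sv$d^2 > 1e-12 * tot
    }
    nComp <- sum(retain)
    if (nComp > 0L) {
        Vr <- sv$v[, retain, drop = FALSE]
        effects <- Vr %*% (t(Vr) %*% M)
    } else {
        effects <- matrix(0, nrow(logcpm), length(fitBatches))
    }
    colnames(effects) <- fitBatches
    rownames(effects) <- rownames(logcpm)
    corrected <- logcpm
    for (i in seq_along(fitBatches)) {
        inb <- which(b == fitBatches[i])
        corrected[, inb] <- corrected[, inb] - effects[, i]
    }
    if (strict) {
        unseen <- setdiff(unique(b), fitBatches)
        for (bb in unseen) {
            inb <- which(b == bb)
            dev <- rowMeans(logcpm[, inb, drop = FALSE]) - center
            corrected[, inb] <- corrected[, inb] - dev
            effects <- cbind(effects, dev)
            colnames(effects)[ncol(effects)] <- bb
        }
    }
    shares <- if (tot < 1e-24) numeric(0) else sv$d^2 / tot
    model <- new("BatchModel", nComponents = as.integer(nComp),
                 varianceShares = shares[shares > 1e-15],
                 batchEffects = effects[, fitBatches, drop = FALSE],
                 batchSizes = setNames(nb, fitBatches),
                 beta = beta, joint = !strict)
    list(corrected = corrected, model = model)
}

#' Per-gene batch-variance diagnostic
#'
#' One-way variance decomposition of each gene on the batch factor:
#' R^2 = between-batch sum of squares / total sum of squares (0 for
#' zero-variance genes), plus the across-gene mean. Useful before/after
#' [arsynCorrect()].
#'
#' @inheritParams arsynCorrect
#' @return list with `perGene` (named numeric) and `mean`.
#' @export
batchVarianceDiag <- function(logcpm, sampleData) {
    b <- as.character(sampleData$batch_id)
    batches <- unique(b)
    if (length(batches) < 2L) stop("need >= 2 batches for the diagnostic")
    gm <- rowMeans(logcpm)
    sst <- rowSums((logcpm - gm)^2)
    ssb <- numeric(nrow(logcpm))
    for (bb in batches) {
        inb <- b == bb
        mb <- rowMeans(logcpm[, inb, drop = FALSE])
        ssb <- ssb + sum(inb) * (mb - gm)^2
    }
    r2 <- ifelse(sst > 0, ssb / sst, 0)
    names(r2) <- rownames(logcpm)
    list(perGene = r2, mean = mean(r2))
}

#' Serialize a BatchModel to JSON
#' @param model a [BatchModel-class].
#' @param path destination file.
#' @export
writeBatchModel <- function(model, path) {
    jsonlite::write_json(list(
        n_components = model@nComponents,
        beta = model@beta,
        joint = model@joint,
        variance_shares = model@varianceShares,
        batch_sizes = as.list(model@batchSizes),
        batch_effects = apply(model@batchEffects, 2, identity, simplify = FALSE)
    ), path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
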