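#' Twelve-metric evaluation of a binary classifier
#'
#' Class 0 (metastasis) is the positive class throughout. Per-class
#' precision, recall and F1 are computed from the confusion matrix, macro
#' metrics as unweighted means over the two classes; macro-F1 is the mean of
#' the class F1s (not the F1 of the macro precision/recall). ROC-AUC is the
#' normalised Mann-Whitney statistic of `score0` for class 0 against class 1
#' (ties count one half); PR-AUC is the average precision (step-wise sum of
#' precision times recall increments). MCC uses the convention that a zero
#' factor in the denominator yields 0. A precision whose denominator is
#' empty (no sample predicted into that class) is reported as 0 and flagged.
#'
#' @param yTrue true labels (0/1), both classes present.
#' @param yPred predicted labels (0/1).
#' @param score0 class-0 scores aligned to the samples (probability or any
#'   monotone score); `NULL` leaves ROC_AUC/PR_AUC as `NA`.
#' @return a [MetricReport-class].
#' @examples
#' computeMetrics(c(0, 0, 0, 1, 1), c(0, 0, 1, 1, 0),
#'                c(0.9, 0.8, 0.3, 0.2, 0.6))
#' @export
computeMetrics <- function(yTrue, yPred, score0 = NULL) {
    yTrue <- as.integer(yTrue); yPred <- as.integer(yPred)
    if (length(yTrue) != length(yPred))
        stop("yTrue and yPred differ in length")
    if (!all(c(0L, 1L) %in% yTrue))
        stop("yTrue must contain both classes")
    if (!is.null(score0) && length(score0) != length(yTrue))
        stop("score0 misaligned with the samples")
    TP <- sum(yTrue == 0L & yPred == 0L)
    FP <- sum(yTrue == 1L & yPred == 0L)
    FN <- sum(yTrue == 0L & yPred == 1L)
    TN <- sum(yTrue == 1L & yPred == 1L)
    flags <- character(0)
    safeDiv <- function(num, den) if (den == 0) 0 else num / den
    PC0 <- safeDiv(TP, TP + FP)
    if (TP + FP == 0) flags <- c(flags, "PC0 undefined (no predicted class 0); reported as 0")
    RC0 <- safeDiv(TP, TP + FN)
    PC1 <- safeDiv(TN, TN + FN)
    if (TN + FN == 0) flags <- c(flags, "PC1 undefined (no predicted class 1); reported as 0")
    RC1 <- safeDiv(TN, TN + FP)
    f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
    F10 <- f1(PC0, RC0); F11 <- f1(PC1, RC1)
    den <- prod(sqrt(c(TP + FP, TP + FN, TN + FP, TN + FN)))
    MCC <- if (den == 0) 0 else (TP * TN - FP * FN) / den
    if (is.null(score0)) {
        ROC <- NA_real_; PR <- NA_real_
    } else {
        ROC <- rocAUC(yTrue, score0)
        PR <- averagePrecision(yTrue, score0)
    }
    m <- c(PC0 = PC0, RC0 = RC0, F10 = F10, PC1 = PC1, RC1 = RC1, F11 = F11,
           MPC = (PC0 + PC1) / 2, MRC = (RC0 + RC1) / 2,
           MF1 = (F10 + F11) / 2, ROC_AUC = ROC, PR_AUC = PR, MCC = MCC)
    new("MetricReport", metrics = m,
        perRepetition = matrix(numeric(0), 0, 12,
                               dimnames = list(NULL, METRIC_NAMES)),
        ciLow = numeric(0), ciHigh = numeric(0), flags = flags)
}

## Normalised Mann-Whitney U of score0 for class 0 against class 1; ties
## count one half.
rocAUC <- function(yTrue, score0) {
    n0 <- sum(yTrue == 0L); n1 <- sum(yTrue == 1L)
    r <- rank(score0, ties.method = "average")
    (sum(r[yTrue == 0L]) - n0 * (n0 + 1) / 2) / (n0 * n1)
}

## Average precision with class 0 positive: precision at each positive hit
## in the score-descending ordering, times the 1/n0 recall increment.
## Score ties are broken deterministically by sample position.
averagePrecision <- function(yTrue, score0) {
    ord <- order(-score0, seq_along(score0), method = "radix")
    pos <- yTrue[ord] == 0L
    n0 <- sum(pos)
    cumPos <- cumsum(pos)
    prec <- cumPos / seq_along(pos)
    sum(prec[pos]) / n0
}

## Mean and normal 95% band over repetitions of the 12 metrics.
aggregateReports <- function(perRep, flags = character(0)) {
    stopifnot(ncol(perRep) == 12L)
    colnames(perRep) <- METRIC_NAMES
    mu <- colMeans(perRep)
    s <- apply(perRep, 2, function(v) if (length(v) > 1L) sd(v) else 0)
    s[is.na(s)] <- 0
    new("MetricReport", metrics = mu, perRepetition = perRep,
        ciLow = mu - 1.96 * s, ciHigh = mu + 1.96 * s, flags = flags)
}

#' Serialize a MetricReport to JSON
#'
#' Writes the twelve metric keys (PC0, RC0, F10, PC1, RC1, F11, MPC, MRC,
#' MF1, ROC_AUC, PR_AUC, MCC), plus `ci_low`/`ci_high` blocks for repeated
#' protocols.
#'
#' @param report a [MetricReport-class].
#' @param path destination file.
#' @export
writeMetricReport <- function(report, path) {
    out <- as.list(report@metrics)
    if (length(report@ciLow)) {
        out <- list(mean = as.list(report@metrics),
                    ci_low = as.list(report@ciLow),
                    ci_high = as.list(report@ciHigh),
                    n_repetitions = nrow(report@perRepetition))
    }
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
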