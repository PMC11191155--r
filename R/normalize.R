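#' TMM library scale factors
#'
#' Trimmed mean of M-values scale factors (edgeR's TMM): the reference
#' sample is the one whose 75th-percentile count fraction is closest to the
#' across-sample mean of that statistic; per sample, log ratios (M) and
#' average log abundances (A) against the reference are doubly trimmed
#' (`trimM` on M, `trimA` on A) over genes with positive counts in both
#' samples, and the factor is the precision-weighted mean of the surviving M
#' values. Factors are rescaled to geometric mean 1.
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @param trimM,trimA two-sided trim fractions for M and A.
#' @return named numeric vector of positive per-sample factors with
#'   geometric mean 1. Samples for which fewer than 10 genes survive
#'   trimming fall back to factor 1 with a warning.
#' @export
tmmFactors <- function(counts, trimM = 0.30, trimA = 0.05) {
    libSize <- colSums(counts)
    if (any(libSize == 0))
        stop("sample(s) with all-zero counts: ",
             paste(colnames(counts)[libSize == 0], collapse = ", "))
    f <- edgeR::calcNormFactors(counts, method = "TMM",
                                logratioTrim = trimM, sumTrim = trimA)
    ## Guard: samples sharing too few usable genes with the reference are
    ## unreliable; fall back to 1 (edgeR does not flag this itself).
    q75 <- apply(counts, 2, function(x) quantile(x, 0.75)) / libSize
    ref <- which.min(abs(q75 - mean(q75)))
    usable <- vapply(seq_len(ncol(counts)), function(j) {
        ok <- counts[, j] > 0 & counts[, ref] > 0
        nOk <- sum(ok)
        as.integer(max(0, nOk - 2 * (floor(nOk * trimM) + floor(nOk * trimA))))
    }, integer(1))
    low <- usable < 10L & seq_len(ncol(counts)) != ref
    if (any(low)) {
        warning("fewer than 10 usable genes after trimming for sample(s) ",
                paste(colnames(counts)[low], collapse = ", "),
                "; factor set to 1")
        f[low] <- 1
        f <- f / geometricMean(f)
    }
    names(f) <- colnames(counts)
    f
}

#' Log2 counts-per-million with TMM-effective library sizes
#'
#' `log2((y + prior) / (N * f + 2 * prior) * 1e6)` for count `y`, library
#' size `N`, scale factor `f`; finite for all inputs.
#'
#' @param counts genes x samples count matrix.
#' @param normFactors factors from [tmmFactors()], aligned to the samples.
#' @param priorCount pseudo-count (default 0.5).
#' @return numeric matrix of the same shape, all entries finite.
#' @export
logCPM <- function(counts, normFactors, priorCount = 0.5) {
    if (length(normFactors) != ncol(counts))
        stop("normFactors misaligned: ", length(normFactors), " factors for ",
             ncol(counts), " samples")
    if (!is.null(names(normFactors)) && !is.null(colnames(counts)) &&
        !identical(names(normFactors), colnames(counts)))
        stop("normFactors names do not match sample ids")
    effLib <- colSums(counts) * normFactors
    lc <- log2(sweep(counts + priorCount, 2, effLib + 2 * priorCount, "/") * 1e6)
    dimnames(lc) <- dimnames(counts)
    lc
}

#' Train-derived low-expression / low-fold-change gene filter
#'
#' A gene is removed when its mean log-CPM over train samples falls below
#' the `exprQuantile` quantile of all train gene means (strict less-than),
#' or when the absolute difference of its class-0 and class-1 train means is
#' below `minAbsLFC` log2 units (strict less-than). The two rules act as
#' independent filter-out rules (union removed).
#'
#' @param logcpm genes x samples log-expression matrix.
#' @param sampleData sample table (data.frame with class_label and role)
#'   aligned to the columns.
#' @param exprQuantile quantile defining "low expression" (default 0.05).
#' @param minAbsLFC minimum absolute class difference in log2 units
#'   (default 0.1).
#' @return data.frame gene mask: gene_id, kept (logical), reason
#'   ("", "low_expr", "low_fc" or "low_expr;low_fc").
#' @export
filterGenes <- function(logcpm, sampleData, exprQuantile = 0.05,
                        minAbsLFC = 0.1) {
    stopifnot(exprQuantile >= 0, exprQuantile < 1, minAbsLFC >= 0)
    tr <- sampleData$role == "train"
    y <- sampleData$class_label[tr]
    if (!any(y == 0L) || !any(y == 1L))
        stop("both classes must be present among train samples")
    x <- logcpm[, tr, drop = FALSE]
    gm <- rowMeans(x)
    lowExpr <- gm < quantile(gm, exprQuantile)
    lfc <- abs(rowMeans(x[, y == 0L, drop = FALSE]) -
               rowMeans(x[, y == 1L, drop = FALSE]))
    ## strict "<" with a guard so a difference of exactly the threshold,
    ## computed in floating point, is kept
    lowFC <- lfc < minAbsLFC - 1e-9
    reason <- rep("", nrow(logcpm))
    reason[lowExpr] <- "low_expr"
    reason[lowFC] <- ifelse(lowExpr[lowFC], "low_expr;low_fc", "low_fc")
    data.frame(gene_id = rownames(logcpm), kept = !(lowExpr | lowFC),
               reason = reason, stringsAsFactors = FALSE)
}

#' Cross-batch consistency gene filter
#'
#' A gene is kept only if the sign of its class-0 minus class-1 mean
#' log-expression, computed within each train batch, is identical (and
#' nonzero) across all train batches. With a single train batch every gene
#' is kept (vacuous consistency).
#'
#' @inheritParams filterGenes
#' @return data.frame gene mask: gene_id, kept, reason ("" or
#'   "batch_inconsistent").
#' @export
filterBatchInconsistent <- function(logcpm, sampleData) {
    tr <- sampleData$role == "train"
    y <- sampleData$class_label[tr]
    b <- sampleData$batch_id[tr]
    x <- logcpm[, tr, drop = FALSE]
    batches <- unique(b)
    if (length(batches) < 2L) {
        return(data.frame(gene_id = rownames(logcpm), kept = TRUE,
                          reason = "", stringsAsFactors = FALSE))
    }
    diffs <- vapply(batches, function(bb) {
        in0 <- b == bb & y == 0L; in1 <- b == bb & y == 1L
        if (!any(in0) || !any(in1))
            stop("train batch '", bb, "' lacks one class")
        rowMeans(x[, in0, drop = FALSE]) - rowMeans(x[, in1, drop = FALSE])
    }, numeric(nrow(logcpm)))
    sgn <- sign(diffs)
    consistent <- apply(sgn, 1, function(s) all(s == s[1]) && s[1] != 0)
    data.frame(gene_id = rownames(logcpm), kept = consistent,
               reason = ifelse(consistent, "", "batch_inconsistent"),
               stringsAsFactors = FALSE)
}

#' Combine gene masks (intersection of kept sets)
#'
#' @param ... gene-mask data.frames as returned by the filters.
#' @return combined mask with reasons joined by ";".
#' @export
combineMasks <- function(...) {
    masks <- list(...)
    stopifnot(length(masks) >= 1L)
    out <- masks[[1L]]
    for (m in masks[-1L]) {
        stopifnot(identical(m$gene_id, out$gene_id))
        both <- paste(out$reason, m$reason, sep = ";")
        both <- gsub("^;|;$", "", both)
        out$kept <- out$kept & m$kept
        out$reason <- both
    }
    out
}

#' Serialize a gene mask as TSV (gene_id, kept 0/1, reason)
#' @param mask gene-mask data.frame.
#' @param path destination file.
#' @export
writeGeneMask <- function(mask, path) {
    utils::write.table(
        data.frame(gene_id = mask$gene_id, kept = as.integer(mask$kept),
                   reason = mask$reason),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
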