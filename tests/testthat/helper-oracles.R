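## Independent brute-force TMM: trimmed, precision-weighted mean of M
## values against the 75th-percentile reference, coded directly from the
## definition (used only as an oracle here).
bruteTMM <- function(counts, trimM = 0.30, trimA = 0.05) {
    N <- colSums(counts)
    q75 <- apply(counts, 2, function(x) quantile(x, 0.75)) / N
    ref <- which.min(abs(q75 - mean(q75)))
    f <- vapply(seq_len(ncol(counts)), function(j) {
        if (j == ref) return(1)
        ok <- counts[, j] > 0 & counts[, ref] > 0
        yj <- counts[ok, j]; yr <- counts[ok, ref]
        M <- log2((yj / N[j]) / (yr / N[ref]))
        A <- 0.5 * log2((yj / N[j]) * (yr / N[ref]))
        if (max(abs(M)) < 1e-6) return(1)
        n <- length(M)
        loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
        loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
        keep <- rank(M) >= loM & rank(M) <= hiM &
                rank(A) >= loA & rank(A) <= hiA
        w <- 1 / ((N[j] - yj) / (N[j] * yj) + (N[ref] - yr) / (N[ref] * yr))
        2^(sum(w[keep] * M[keep]) / sum(w[keep]))
    }, numeric(1))
    f / exp(mean(log(f)))
}

## Independent oracle: metrics computed directly from confusion-matrix
## counts with plain integer arithmetic.
oracleFromCounts <- function(TP, FP, FN, TN) {
    prec <- function(a, b) if (a + b == 0) 0 else a / (a + b)
    f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
    PC0 <- prec(TP, FP); RC0 <- prec(TP, FN)
    PC1 <- prec(TN, FN); RC1 <- prec(TN, FP)
    den2 <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
    c(PC0 = PC0, RC0 = RC0, F10 = f1(PC0, RC0),
      PC1 = PC1, RC1 = RC1, F11 = f1(PC1, RC1),
      MPC = (PC0 + PC1) / 2, MRC = (RC0 + RC1) / 2,
      MF1 = (f1(PC0, RC0) + f1(PC1, RC1)) / 2,
      MCC = if (den2 == 0) 0 else (TP * TN - FP * FN) / sqrt(den2))
}
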