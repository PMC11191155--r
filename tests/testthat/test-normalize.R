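
test_that("TMM factors are 1 for identical columns and pure depth changes", {
    cm <- toyCounts(30, 4, seed = 3)
    same <- cm; same[] <- rep(cm[, 1], 4)
    expect_equal(unname(tmmFactors(same)), rep(1, 4), tolerance = 1e-12)
    depth <- cbind(A = cm[, 1], B = 2L * cm[, 1])
    expect_equal(unname(tmmFactors(depth)), c(1, 1), tolerance = 1e-12)
})

test_that("TMM matches a brute-force trimmed weighted mean on a toy", {
    ## 40 genes so that the doubly trimmed set keeps >= 10 usable genes
    set.seed(7)
    cm <- matrix(rpois(80, 200) + 1L, 40, 2,
                 dimnames = list(sprintf("g%02d", 1:40), c("A", "B")))
    cm[1:8, 2] <- cm[1:8, 2] * 2L        # composition change in genes 1-8
    expect_equal(unname(tmmFactors(cm)), unname(bruteTMM(cm)),
                 tolerance = 1e-8)
    ## larger random case
    cm2 <- matrix(rpois(300, 100) + 1L, 50, 6,
                  dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:6)))
    cm2[1:8, 3] <- cm2[1:8, 3] * 4L
    expect_equal(unname(tmmFactors(cm2)), unname(bruteTMM(cm2)),
                 tolerance = 1e-8)
})

test_that("TMM factors have geometric mean 1 and guard degenerate samples", {
    cm <- toyCounts(60, 5, seed = 11)
    f <- tmmFactors(cm)
    expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
    bad <- cm; bad[, 2] <- 0L
    expect_error(tmmFactors(bad), "all-zero")
    ## nearly disjoint support => < 10 usable genes => fallback with warning
    sp <- matrix(0L, 20, 3, dimnames = list(sprintf("g%02d", 1:20),
                                            c("A", "B", "C")))
    sp[1:12, 1] <- 100L; sp[1:12, 2] <- 120L
    sp[c(1, 13:20), 3] <- 90L
    expect_warning(f2 <- tmmFactors(sp), "fewer than 10 usable genes")
    expect_equal(exp(mean(log(f2))), 1, tolerance = 1e-9)
})

test_that("log-CPM follows the stated closed form", {
    cm <- matrix(c(0L, 1000L, 999000L, 0L, 1000L, 999000L), 3, 2,
                 dimnames = list(c("g1", "g2", "g3"), c("A", "B")))
    ## library size is exactly 1e6 per sample; use unit factors
    nf <- setNames(c(1, 1), c("A", "B"))
    lc <- logCPM(cm, nf, priorCount = 0.5)
    expect_equal(lc["g1", "A"], log2(0.5 / (1e6 + 1) * 1e6),
                 tolerance = 1e-12)
    expect_equal(lc["g1", "A"], -1.0000014, tolerance = 1e-6)
    expect_equal(lc["g2", "A"], log2(1000.5 / (1e6 + 1) * 1e6),
                 tolerance = 1e-12)
    expect_equal(lc["g2", "A"], 9.966, tolerance = 1e-3)
    expect_true(all(is.finite(lc)))
    ## doubling counts and depth leaves large-count values ~unchanged
    lc2 <- logCPM(2L * cm, nf)
    expect_lt(max(abs(lc2[2:3, ] - lc[2:3, ])), 0.01)
    expect_error(logCPM(cm, c(1, 1, 1)), "misaligned")
})

test_that("low-expression and low-FC filters remove by the stated rules", {
    set.seed(21)
    n <- 40
    lc <- matrix(rnorm(100 * n, mean = 6), 100, n,
                 dimnames = list(sprintf("g%03d", 1:100),
                                 sprintf("s%02d", 1:n)))
    st <- toySampleTable(colnames(lc))
    y <- st$class_label
    ## plant exact class differences on two genes
    lc["g001", y == 0] <- 6 + 0.025; lc["g001", y == 1] <- 6 - 0.025
    lc["g003", y == 0] <- 6 + 1; lc["g003", y == 1] <- 6 - 1
    mask <- filterGenes(lc, st)
    expect_false(mask$kept[mask$gene_id == "g001"])   # |diff| = 0.05 < 0.1
    expect_match(mask$reason[mask$gene_id == "g001"], "low_fc")
    expect_true(mask$kept[mask$gene_id == "g003"])    # |diff| = 2
    ## expression rule alone removes at most 5% of genes (strict quantile)
    lowOnly <- filterGenes(lc, st, minAbsLFC = 0)
    expect_lte(sum(grepl("low_expr", lowOnly$reason)), 5)
    ## one class absent is fatal
    st1 <- st; st1$class_label <- 0L
    expect_error(filterGenes(lc, st1), "both classes")
})

test_that("boundary fold change of exactly the threshold is kept", {
    lc <- matrix(5, 4, 10, dimnames = list(paste0("g", 1:4),
                                           paste0("s", 1:10)))
    st <- toySampleTable(colnames(lc))
    y <- st$class_label
    lc[1, y == 0] <- 5 + 0.1; lc[1, y == 1] <- 5      # diff exactly 0.1
    lc[2, y == 0] <- 5 + 0.099; lc[2, y == 1] <- 5    # just below
    lc[3, ] <- rnorm(10, 20); lc[4, ] <- rnorm(10, 20)
    mask <- filterGenes(lc, st, exprQuantile = 0)
    expect_true(mask$kept[1])
    expect_false(mask$kept[2])
})

test_that("cross-batch consistency keeps same-sign differences only", {
    ids <- sprintf("s%02d", 1:12)
    st <- toySampleTable(ids, batches = rep(c("b1", "b2", "b3"), each = 4))
    y <- st$class_label; b <- st$batch_id
    lc <- matrix(0, 3, 12, dimnames = list(c("gA", "gB", "gC"), ids))
    setDiff <- function(g, diffs) {
        for (i in seq_along(unique(b))) {
            bb <- unique(b)[i]
            lc[g, b == bb & y == 0] <<- diffs[i]
            lc[g, b == bb & y == 1] <<- 0
        }
    }
    setDiff("gA", c(0.4, 0.2, 0.3))
    setDiff("gB", c(0.4, -0.2, 0.3))
    setDiff("gC", c(-0.1, -0.5, -0.2))
    mask <- filterBatchInconsistent(lc, st)
    expect_identical(mask$kept, c(TRUE, FALSE, TRUE))
    expect_identical(mask$reason[2], "batch_inconsistent")
    ## single batch: vacuous consistency
    st1 <- toySampleTable(ids)
    expect_true(all(filterBatchInconsistent(lc, st1)$kept))
    ## batch lacking a class is fatal
    st2 <- st; st2$class_label[st2$batch_id == "b2"] <- 0L
    expect_error(filterBatchInconsistent(lc, st2), "lacks one class")
})

test_that("filter composition is order-independent", {
    pr <- preppedSim(simConfig(nGenes = 80, nBatches = 2, samplesPerBatch = 15,
                               nSignal = 5, seed = 13),
                     applyFilters = FALSE, correct = FALSE)
    a <- combineMasks(filterGenes(pr$logcpm, pr$st),
                      filterBatchInconsistent(pr$logcpm, pr$st))
    b <- combineMasks(filterBatchInconsistent(pr$logcpm, pr$st),
                      filterGenes(pr$logcpm, pr$st))
    expect_identical(a$kept, b$kept)
})

test_that("a clear planted signal survives both filters", {
    ## no batch effects, strong fold change: planted genes must be kept
    hits <- vapply(1:5, function(s) {
        pr <- preppedSim(simConfig(nGenes = 120, nBatches = 2,
                                   samplesPerBatch = 25, nSignal = 6,
                                   signalLFC = 2, batchLogFCSd = 0, seed = s),
                         applyFilters = FALSE, correct = FALSE)
        mask <- combineMasks(filterGenes(pr$logcpm, pr$st),
                             filterBatchInconsistent(pr$logcpm, pr$st))
        all(pr$truth@signalGenes %in% mask$gene_id[mask$kept])
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})
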