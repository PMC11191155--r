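test_that("TSV/CSV count matrices parse with ids and exact values", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("gene_id\tA\tB", "g1\t1\t2", "g2\t0\t5", "g3\t7\t7"), path)
    cm <- readCounts(path)
    expect_identical(dim(cm), c(3L, 2L))
    expect_identical(as.vector(cm), c(1L, 0L, 7L, 2L, 5L, 7L))
    expect_identical(rownames(cm), c("g1", "g2", "g3"))
    expect_identical(colnames(cm), c("A", "B"))
})

test_that("count reader rejects duplicates, negatives and empty matrices", {
    dup <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("gene_id\tA\tB", "A1\t1\t2", "A1\t3\t4"), dup)
    expect_error(readCounts(dup), "duplicate gene id.*A1")
    neg <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("gene_id,A,B", "g1,1,2", "g2,-3,4"), neg)
    expect_error(readCounts(neg), "negative count.*g2.*A")
    bad <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("gene_id,A,B", "g1,1,2", "g2,x,4"), bad)
    expect_error(readCounts(bad), "non-numeric")
    empty <- withr::local_tempfile(fileext = ".tsv")
    writeLines("gene_id\tA\tB", empty)
    expect_error(readCounts(empty), "empty")
})

test_that("MatrixMarket triplets densify with explicit zeros", {
    path <- withr::local_tempfile(fileext = ".mtx")
    writeLines(c("%%MatrixMarket matrix coordinate integer general",
                 "3 3 4", "1 1 5", "2 2 3", "3 1 2", "3 3 1"), path)
    writeLines(c("g1", "g2", "g3"), paste0(path, ".genes.txt"))
    writeLines(c("s1", "s2", "s3"), paste0(path, ".samples.txt"))
    cm <- readCounts(path, fmt = "mtx")
    expect_identical(sum(cm == 0L), 5L)
    expect_identical(cm["g1", "s1"], 5L)
    expect_identical(cm["g3", "s3"], 1L)
})

test_that("write-then-read round-trips values and id order exactly", {
    cm <- toyCounts(8, 5)
    for (fmt in c("tsv", "csv")) {
        path <- withr::local_tempfile(fileext = paste0(".", fmt))
        writeCounts(cm, path, fmt)
        expect_identical(readCounts(path), cm)
    }
})

test_that("sample tables validate class labels and roles", {
    ok <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("sample_id,class_label,batch_id,role",
                 "s1,0,b1,train", "s2,0,b1,train",
                 "s3,1,b1,train", "s4,1,b1,validation"), ok)
    st <- readSampleTable(ok)
    expect_identical(st$class_label, c(0L, 0L, 1L, 1L))
    bad <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("sample_id,class_label,batch_id,role", "s1,2,b1,train",
                 "s2,1,b1,train"), bad)
    expect_error(readSampleTable(bad), "unknown class label.*2")
    badRole <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("sample_id,class_label,batch_id,role", "s1,0,b1,test",
                 "s2,1,b1,train"), badRole)
    expect_error(readSampleTable(badRole), "train, validation")
    noCol <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("sample_id,class_label,role", "s1,0,train"), noCol)
    expect_error(readSampleTable(noCol), "missing column.*batch_id")
})

test_that("experiment construction aligns, subsets and validates samples", {
    cm <- toyCounts(6, 3)                       # columns s01 s02 s03
    st <- toySampleTable(c("s02", "s01"))
    ## reorder to table order (the unused third column drops with a warning)
    expect_warning(me <- MarkerExperiment(cm, st), "s03")
    expect_identical(colnames(me), c("s02", "s01"))
    expect_identical(SummarizedExperiment::assay(me, "counts")[, "s01"],
                     cm[, "s01"])
    ## extra matrix column dropped with a warning, never silently kept
    expect_warning(me2 <- MarkerExperiment(cm, toySampleTable(c("s01", "s03"))),
                   "s02")
    expect_identical(colnames(me2), c("s01", "s03"))
    ## table id absent from the matrix is fatal
    expect_error(MarkerExperiment(cm, toySampleTable(c("s01", "sX"))),
                 "absent from count matrix.*sX")
    ## construction is idempotent: aligned input passes through unchanged
    me3 <- MarkerExperiment(SummarizedExperiment::assay(me, "counts"),
                            sampleTableOf(me))
    expect_identical(colnames(me3), colnames(me))
    expect_identical(SummarizedExperiment::assay(me3, "counts"),
                     SummarizedExperiment::assay(me, "counts"))
})

test_that("class-balance summary reports counts, percentages and totals", {
    st <- toySampleTable(sprintf("s%02d", 1:10),
                         classes = c(rep(0L, 7), rep(1L, 3)))
    ## classes arg is recycled positionally by the builder; force exact
    st$class_label <- c(rep(0L, 7), rep(1L, 3))
    cb <- classBalanceSummary(st)
    expect_identical(cb$n, c(7L, 3L))
    expect_equal(cb$pct, c(70, 30))
    expect_identical(unique(cb$total), 10L)
})

test_that("accessors expose annotation and show() summarises", {
    cm <- toyCounts(6, 4)
    me <- MarkerExperiment(cm, toySampleTable(colnames(cm),
                                              batches = c("b1", "b1", "b2", "b2")))
    expect_identical(classLabel(me), rep(c(0L, 1L), 2))
    expect_identical(batchId(me), c("b1", "b1", "b2", "b2"))
    expect_identical(sampleRole(me), rep("train", 4))
    expect_output(show(me), "class balance")
})
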