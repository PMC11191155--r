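#' @include AllClasses.R
NULL

#' Construct a MarkerExperiment from counts and a sample table
#'
#' Columns of `counts` are subset and reordered to the order of
#' `sampleData$sample_id`. Matrix columns absent from the sample table are
#' dropped with a warning (never silently retained); a sample table id
#' missing from the matrix is an error.
#'
#' @param counts genes x samples matrix of non-negative integer counts, with
#'   unique row (gene) and column (sample) names.
#' @param sampleData data.frame or DataFrame with columns `sample_id`,
#'   `class_label` (0 = metastasis, 1 = non-metastasis), `batch_id`, `role`
#'   (`train` or `validation`).
#' @return a [MarkerExperiment-class] with a `"counts"` assay.
#' @examples
#' cnt <- matrix(rpois(40, 10), 10, 4,
#'               dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' st <- data.frame(sample_id = paste0("s", 1:4),
#'                  class_label = c(0, 0, 1, 1),
#'                  batch_id = "b1", role = "train")
#' MarkerExperiment(cnt, st)
#' @export
MarkerExperiment <- function(counts, sampleData) {
    sampleData <- as.data.frame(sampleData)
    miss <- setdiff(REQUIRED_SAMPLE_COLS, colnames(sampleData))
    if (length(miss))
        stop("sample table is missing column(s): ", paste(miss, collapse = ", "))
    ids <- as.character(sampleData$sample_id)
    if (anyDuplicated(ids))
        stop("duplicate sample id in sample table: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    checkCountMatrix(counts)
    absent <- setdiff(ids, colnames(counts))
    if (length(absent))
        stop("sample id(s) absent from count matrix: ",
             paste(absent, collapse = ", "))
    extra <- setdiff(colnames(counts), ids)
    if (length(extra)) {
        warning("dropping ", length(extra),
                " matrix column(s) absent from the sample table: ",
                paste(utils::head(extra, 5), collapse = ", "),
                if (length(extra) > 5) ", ..." else "")
        counts <- counts[, ids, drop = FALSE]
    } else {
        counts <- counts[, ids, drop = FALSE]
    }
    cd <- S4Vectors::DataFrame(
        class_label = validateClassLabels(sampleData$class_label),
        batch_id = as.character(sampleData$batch_id),
        role = validateRoles(sampleData$role),
        row.names = ids)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    new("MarkerExperiment", se)
}

checkCountMatrix <- function(counts) {
    if (is.null(dim(counts)) || nrow(counts) < 2L || ncol(counts) < 2L)
        stop("count matrix must have at least 2 genes and 2 samples")
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("count matrix must carry gene and sample ids as dimnames")
    dupg <- rownames(counts)[duplicated(rownames(counts))]
    if (length(dupg))
        stop("duplicate gene id: ", paste(unique(dupg), collapse = ", "))
    dups <- colnames(counts)[duplicated(colnames(counts))]
    if (length(dups))
        stop("duplicate sample id: ", paste(unique(dups), collapse = ", "))
    if (anyNA(counts))
        stop("count matrix contains missing values")
    if (any(counts < 0)) {
        bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
        stop(sprintf("negative count at gene '%s', sample '%s'",
                     rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
    }
    invisible(TRUE)
}

validateClassLabels <- function(x) {
    v <- suppressWarnings(as.integer(as.character(x)))
    bad <- is.na(v) | !(v %in% CLASS_LEVELS)
    if (any(bad))
        stop("unknown class label(s): ",
             paste(unique(as.character(x)[bad]), collapse = ", "),
             " (allowed: 0 = metastasis, 1 = non-metastasis)")
    v
}

validateRoles <- function(x) {
    v <- as.character(x)
    bad <- !(v %in% SAMPLE_ROLES)
    if (any(bad))
        stop("unknown role(s): ", paste(unique(v[bad]), collapse = ", "),
             " (allowed roles: ", paste(SAMPLE_ROLES, collapse = ", "), ")")
    v
}

#' Read a gene-level count matrix
#'
#' Tabular formats carry gene ids in the first column and sample ids in the
#' header row; the MatrixMarket triplet format needs sidecar one-id-per-line
#' files for genes (rows) and samples (columns).
#'
#' @param path file path.
#' @param fmt `"tsv"`, `"csv"` or `"mtx"`; guessed from the extension when
#'   omitted.
#' @param genesPath,samplesPath sidecar id files for `fmt = "mtx"`; default
#'   `<path>.genes.txt` / `<path>.samples.txt`.
#' @return integer matrix (genes x samples) with dimnames.
#' @export
readCounts <- function(path, fmt = c("auto", "tsv", "csv", "mtx"),
                       genesPath = NULL, samplesPath = NULL) {
    fmt <- match.arg(fmt)
    if (!file.exists(path)) stop("file not found: ", path)
    if (fmt == "auto") {
        ext <- tolower(tools::file_ext(path))
        fmt <- switch(ext, tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                      stop("cannot guess count format from extension '.", ext, "'"))
    }
    if (fmt == "mtx") {
        if (is.null(genesPath)) genesPath <- paste0(path, ".genes.txt")
        if (is.null(samplesPath)) samplesPath <- paste0(path, ".samples.txt")
        if (!file.exists(genesPath) || !file.exists(samplesPath))
            stop("mtx format needs sidecar id files: ", genesPath, ", ", samplesPath)
        m <- as.matrix(Matrix::readMM(path))
        gid <- readLines(genesPath); sid <- readLines(samplesPath)
        if (length(gid) != nrow(m) || length(sid) != ncol(m))
            stop("sidecar id files do not match matrix dimensions")
        dimnames(m) <- list(gid, sid)
        tab <- m
    } else {
        raw <- utils::read.table(path, header = TRUE,
                                 sep = if (fmt == "tsv") "\t" else ",",
                                 check.names = FALSE, stringsAsFactors = FALSE,
                                 colClasses = "character")
        if (!nrow(raw) || ncol(raw) < 2L) stop("empty count matrix in ", path)
        gid <- raw[[1L]]
        num <- as.matrix(raw[, -1L, drop = FALSE])
        suppressWarnings(storage.mode(num) <- "numeric")
        if (anyNA(num)) {
            bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
            stop(sprintf("non-numeric count at row '%s', column '%s'",
                         gid[bad[1L]], colnames(num)[bad[2L]]))
        }
        rownames(num) <- gid
        tab <- num
    }
    if (any(tab != round(tab)))
        warning("non-integer counts rounded to the nearest integer")
    storage.mode(tab) <- "integer"
    checkCountMatrix(tab)
    tab
}

#' Write a count matrix (TSV/CSV round-trip companion of [readCounts()])
#'
#' @param counts genes x samples matrix with dimnames.
#' @param path destination file.
#' @param fmt `"tsv"` or `"csv"`.
#' @export
writeCounts <- function(counts, path, fmt = c("tsv", "csv")) {
    fmt <- match.arg(fmt)
    df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
    utils::write.table(df, path, sep = if (fmt == "tsv") "\t" else ",",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a sample metadata table
#'
#' Expects columns `sample_id`, `class_label`, `batch_id`, `role` (CSV or
#' TSV by extension). Class labels are validated to \{0, 1\} and roles to
#' \{train, validation\}.
#'
#' @param path file path.
#' @return data.frame with validated columns.
#' @export
readSampleTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
    st <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
    miss <- setdiff(REQUIRED_SAMPLE_COLS, colnames(st))
    if (length(miss))
        stop("sample table is missing column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(st$sample_id))
        stop("duplicate sample id: ",
             paste(unique(st$sample_id[duplicated(st$sample_id)]), collapse = ", "))
    st$class_label <- validateClassLabels(st$class_label)
    st$role <- validateRoles(st$role)
    st$sample_id <- as.character(st$sample_id)
    st$batch_id <- as.character(st$batch_id)
    st[, REQUIRED_SAMPLE_COLS]
}

#' Class balance per cohort role
#'
#' Tabulates sample counts per (role, class) with within-role percentages and
#' totals -- the stratification arithmetic used to describe imbalanced
#' two-class cohorts.
#'
#' @param x a [MarkerExperiment-class] or a sample table data.frame with
#'   columns `class_label` and `role`.
#' @return data.frame with columns role, class_label, n, pct (percent of the
#'   role's total), total (role total).
#' @examples
#' st <- data.frame(sample_id = 1:6, class_label = c(0,0,0,0,1,1),
#'                  batch_id = "b", role = "train")
#' classBalanceSummary(st)
#' @export
classBalanceSummary <- function(x) {
    if (is(x, "MarkerExperiment")) {
        cl <- classLabel(x); role <- sampleRole(x)
    } else {
        cl <- validateClassLabels(x$class_label)
        role <- validateRoles(x$role)
    }
    out <- do.call(rbind, lapply(unique(role), function(r) {
        n0 <- sum(cl == 0L & role == r); n1 <- sum(cl == 1L & role == r)
        tot <- n0 + n1
        data.frame(role = r, class_label = c(0L, 1L), n = c(n0, n1),
                   pct = round(100 * c(n0, n1) / tot, 2), total = tot)
    }))
    rownames(out) <- NULL
    out
}

sampleTable <- function(x) {
    stopifnot(is(x, "MarkerExperiment"))
    data.frame(sample_id = colnames(x), class_label = classLabel(x),
               batch_id = batchId(x), role = sampleRole(x),
               stringsAsFactors = FALSE)
}
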