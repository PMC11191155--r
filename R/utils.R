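#' @importFrom stats quantile rnorm runif rnbinom rpois sd median coef
#'   predict setNames var dist pbinom
#' @importFrom utils head write.table read.table modifyList packageVersion
#' @importFrom tools file_ext
NULL

## Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
## global RNG stream is untouched.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
    expr
}

SEED_CONTEXTS <- c("split", "resample", "adasyn", "lasso", "boruta",
                   "varselrf", "tune", "rf", "baseline", "protocol")

#' Derive a reproducible sub-seed for one (fold, model, context) cell
#'
#' Maps a base seed and a grid position to a 32-bit-safe integer seed.
#' The map is injective over any (fold <= 40008, model <= 100002) grid for a
#' fixed base seed and stable across platforms, so every stochastic stage of
#' a run draws from its own deterministic stream.
#'
#' @param baseSeed integer base seed of the run.
#' @param fold,model grid coordinates (use 0 for stages outside the grid).
#' @param context one of `r paste(SEED_CONTEXTS, collapse = ", ")`.
#' @return integer seed in `[0, 2^31)`.
#' @export
deriveSeed <- function(baseSeed, fold = 0L, model = 0L, context = "split") {
    idx <- match(context, SEED_CONTEXTS)
    if (is.na(idx)) stop("unknown seed context: ", context)
    if (fold < 0 || fold > 40008 || model < 0 || model > 100002)
        stop("fold/model outside the supported seed grid")
    b <- as.numeric(baseSeed) %% 50021
    s <- ((b * 40009 + fold) * 100003 + model) * 16 + (idx - 1)
    as.integer(s %% 2147483647)
}

## Integer allocation of `total` among weights by largest remainder
## (deterministic; ties broken by position). sum(result) == total exactly.
largestRemainder <- function(weights, total) {
    if (total <= 0 || sum(weights) <= 0)
        return(integer(length(weights)))
    share <- weights / sum(weights) * total
    base <- floor(share)
    rem <- as.integer(total - sum(base))
    if (rem > 0) {
        ord <- order(share - base, seq_along(share), decreasing = c(TRUE, FALSE),
                     method = "radix")
        base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
    }
    as.integer(base)
}

## Stratified fold assignment: samples of each class spread evenly over
## nFolds folds, order randomized under the local seed.
stratifiedFolds <- function(y, nFolds, seed) {
    withSeed(seed, {
        fold <- integer(length(y))
        for (cl in unique(y)) {
            idx <- which(y == cl)
            idx <- idx[sample.int(length(idx))]
            fold[idx] <- rep_len(seq_len(nFolds), length(idx))
        }
        fold
    })
}

## Stratified train/test split indices at a given test fraction.
stratifiedSplit <- function(y, testFrac, seed) {
    withSeed(seed, {
        testIdx <- integer(0)
        for (cl in unique(y)) {
            idx <- which(y == cl)
            nTest <- max(1L, round(length(idx) * testFrac))
            testIdx <- c(testIdx, idx[sample.int(length(idx), nTest)])
        }
        sort(testIdx)
    })
}

## Stratified bootstrap (with replacement, class sizes preserved) or 90%
## stratified subsample, as used for the per-model resamples.
resampleIndices <- function(y, method = c("bootstrap", "subsample90"), seed) {
    method <- match.arg(method)
    withSeed(seed, {
        out <- integer(0)
        for (cl in unique(y)) {
            idx <- which(y == cl)
            out <- c(out, if (method == "bootstrap")
                idx[sample.int(length(idx), length(idx), replace = TRUE)]
                else idx[sample.int(length(idx), max(2L, round(0.9 * length(idx))))])
        }
        sort(out)
    })
}

geometricMean <- function(x) exp(mean(log(x)))
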