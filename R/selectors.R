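## The three single-run variable selectors applied inside each
## fold x model resample. Each returns a list (class "SelectorResult") with
## $selector, $genes (subset of colnames(X)) and $diagnostics.

selectorResult <- function(selector, genes, diagnostics = list()) {
    structure(list(selector = selector, genes = as.character(genes),
                   diagnostics = diagnostics), class = "SelectorResult")
}

#' @export
print.SelectorResult <- function(x, ...) {
    cat(sprintf("<SelectorResult %s: %d gene(s)>\n", x$selector,
                length(x$genes)))
    invisible(x)
}

yFactor <- function(y) factor(as.integer(y), levels = c(0L, 1L))

rangerForest <- function(X, y, seed, numTrees = 500L,
                         importance = "permutation", probability = FALSE,
                         mtry = NULL, splitrule = "gini", minNodeSize = NULL) {
    ranger::ranger(x = as.data.frame(X), y = yFactor(y),
                   num.trees = numTrees, importance = importance,
                   probability = probability, mtry = mtry,
                   splitrule = splitrule, min.node.size = minNodeSize,
                   seed = seed, num.threads = 1L, verbose = FALSE)
}

#' L1-penalised logistic regression selector
#'
#' Fits a LASSO logistic regression over a descending lambda path
#' (features standardised internally), picks lambda by stratified
#' `nCV`-fold cross-validated deviance (`rule = "min"`, the permissive
#' choice producing the larger pre-selection pools) or by the
#' one-standard-error rule, and returns the genes with nonzero coefficients
#' at the chosen lambda.
#'
#' @param X samples x genes numeric matrix.
#' @param y two-class labels (0/1).
#' @param nCV number of cross-validation folds for the lambda choice.
#' @param rule `"min"` or `"1se"`.
#' @param seed integer seed (controls the CV fold assignment).
#' @return a `SelectorResult` (selector, genes, diagnostics with the chosen
#'   lambda).
#' @export
lassoSelect <- function(X, y, nCV = 5L, rule = c("min", "1se"), seed = 1L) {
    rule <- match.arg(rule)
    y <- as.integer(y)
    if (length(unique(y)) < 2L) stop("single-class y: cannot fit LASSO")
    sds <- apply(X, 2, sd)
    if (any(sds == 0)) {
        warning("dropping ", sum(sds == 0), " constant feature(s) before LASSO")
        X <- X[, sds > 0, drop = FALSE]
    }
    if (ncol(X) < 2L) {
        ## glmnet needs >= 2 columns; a single candidate cannot be shrunk
        ## against alternatives, keep it
        return(selectorResult("lasso", colnames(X),
                              list(lambda = NA_real_, rule = rule)))
    }
    foldid <- stratifiedFolds(y, nCV, seed)
    cv <- glmnet::cv.glmnet(X, y, family = "binomial", foldid = foldid,
                            standardize = TRUE)
    lam <- if (rule == "min") cv$lambda.min else cv$lambda.1se
    cf <- coef(cv, s = lam)[-1L, 1L]
    selectorResult("lasso", colnames(X)[cf != 0],
                   list(lambda = lam, rule = rule))
}

#' Boruta-style all-relevant selection with shadow features
#'
#' Iteratively appends one shuffled (shadow) copy of every undecided
#' feature, fits a random forest with permutation importance, and scores a
#' "hit" for each undecided feature whose importance exceeds the maximum
#' shadow importance. After each iteration a two-sided binomial test
#' (p = 0.5) on the accumulated hits at level `alpha` confirms features
#' (significantly more hits than chance) or rejects them (significantly
#' fewer). Runs until every feature is decided or `maxRuns` iterations.
#'
#' @param X samples x genes matrix.
#' @param y two-class labels (0/1).
#' @param maxRuns maximum number of shadow iterations (>= 10).
#' @param alpha significance level of the binomial decision test.
#' @param nTrees trees per iteration forest.
#' @param tentative what to do with features still undecided at `maxRuns`:
#'   `"reject"` (conservative default) or `"median"` (accept those whose
#'   median importance across iterations beats the median of the iteration
#'   shadow maxima).
#' @param seed integer seed.
#' @return a `SelectorResult`; diagnostics carry hit counts and decisions.
#' @export
borutaSelect <- function(X, y, maxRuns = 100L, alpha = 0.01, nTrees = 100L,
                         tentative = c("reject", "median"), seed = 1L) {
    tentative <- match.arg(tentative)
    if (maxRuns < 10L) stop("maxRuns < 10: decision test underpowered")
    y <- as.integer(y)
    if (min(table(y)) < 5L) stop("need >= 5 samples per class for Boruta")
    p <- ncol(X)
    genes <- colnames(X)
    status <- rep(0L, p)          # 0 undecided, 1 confirmed, -1 rejected
    hits <- integer(p)
    trials <- integer(p)
    impHist <- matrix(NA_real_, p, 0)
    shadowMaxHist <- numeric(0)
    for (iter in seq_len(maxRuns)) {
        und <- which(status == 0L)
        if (!length(und)) break
        inModel <- which(status >= 0L)     # undecided + confirmed
        ## one shuffled copy of every remaining attribute, topped up to at
        ## least 5 shadows so the reference bar stays meaningful
        shadowOf <- inModel
        while (length(shadowOf) < 5L)
            shadowOf <- c(shadowOf, inModel[seq_len(
                min(length(inModel), 5L - length(shadowOf)))])
        shadows <- withSeed(deriveSeed(seed, 0L, iter, "boruta"), {
            apply(X[, shadowOf, drop = FALSE], 2, sample)
        })
        colnames(shadows) <- sprintf("shadow_%03d", seq_along(shadowOf))
        Xa <- cbind(X[, inModel, drop = FALSE], shadows)
        fit <- rangerForest(Xa, y, seed = deriveSeed(seed, 1L, iter, "boruta"),
                            numTrees = nTrees)
        imp <- fit$variable.importance
        shadowMax <- max(imp[(length(inModel) + 1):length(imp)])
        shadowMaxHist <- c(shadowMaxHist, shadowMax)
        impIter <- rep(NA_real_, p)
        impIter[inModel] <- imp[seq_along(inModel)]
        impHist <- cbind(impHist, impIter)
        hit <- imp[match(und, inModel)] > shadowMax
        hits[und] <- hits[und] + as.integer(hit)
        trials[und] <- trials[und] + 1L
        ## two-sided binomial decisions, Bonferroni-adjusted over all
        ## attributes as in the reference shadow-search algorithm
        pG <- stats::pbinom(hits[und] - 1L, trials[und], 0.5,
                            lower.tail = FALSE)
        pL <- stats::pbinom(hits[und], trials[und], 0.5)
        adj <- p
        conf <- 2 * pG * adj < alpha
        rej <- !conf & 2 * pL * adj < alpha
        status[und[conf]] <- 1L
        status[und[rej]] <- -1L
    }
    if (tentative == "median" && any(status == 0L)) {
        medShadow <- median(shadowMaxHist)
        for (j in which(status == 0L)) {
            mj <- median(impHist[j, ], na.rm = TRUE)
            status[j] <- if (!is.na(mj) && mj > medShadow) 1L else -1L
        }
    }
    selectorResult("boruta", genes[status == 1L],
                   list(hits = setNames(hits, genes),
                        trials = setNames(trials, genes),
                        status = setNames(status, genes)))
}

#' Backward-elimination random-forest selector (varSelRF style)
#'
#' Ranks features once by permutation importance from an initial forest,
#' then iteratively drops the least-important `dropFrac` fraction (at least
#' one feature), refitting and recording the out-of-bag error at every set
#' size. The selected set is the smallest whose OOB error is within
#' `cSd` standard errors of the minimum
#' (`SE = sqrt(err * (1 - err) / n)`); `cSd = 0` degenerates to the
#' smallest OOB minimiser.
#'
#' @param X samples x genes matrix.
#' @param y two-class labels (0/1).
#' @param dropFrac fraction dropped per elimination step, in (0, 1).
#' @param cSd standard-error multiplier of the selection rule.
#' @param nTreesFirst trees of the initial (ranking) forest.
#' @param nTreesIter trees of each elimination-path forest.
#' @param seed integer seed.
#' @return a `SelectorResult`; diagnostics carry the OOB error path.
#' @export
varSelRFSelect <- function(X, y, dropFrac = 0.2, cSd = 1.0,
                           nTreesFirst = 2000L, nTreesIter = 500L, seed = 1L) {
    if (dropFrac <= 0 || dropFrac >= 1) stop("dropFrac must lie in (0, 1)")
    y <- as.integer(y)
    if (min(table(y)) < 5L) stop("need >= 5 samples per class")
    genes <- colnames(X)
    n <- nrow(X)
    first <- rangerForest(X, y, seed = deriveSeed(seed, 0L, 0L, "varselrf"),
                          numTrees = nTreesFirst)
    imp <- first$variable.importance
    ranked <- genes[order(-imp, seq_along(imp), method = "radix")]
    sizes <- integer(0); errs <- numeric(0)
    cur <- length(ranked)
    step <- 0L
    while (TRUE) {
        step <- step + 1L
        feats <- ranked[seq_len(cur)]
        fit <- if (cur == length(ranked)) first else
            rangerForest(X[, feats, drop = FALSE], y,
                         seed = deriveSeed(seed, 0L, step, "varselrf"),
                         numTrees = nTreesIter, importance = "none")
        sizes <- c(sizes, cur)
        errs <- c(errs, fit$prediction.error)
        if (cur == 1L) break
        cur <- cur - max(1L, as.integer(floor(dropFrac * cur)))
    }
    minErr <- min(errs)
    se <- sqrt(minErr * (1 - minErr) / n)
    ok <- errs <= minErr + cSd * se + 1e-12
    sel <- min(sizes[ok])
    selectorResult("varselrf", ranked[seq_len(sel)],
                   list(sizes = sizes, oobErrors = errs,
                        importance = setNames(imp, genes)))
}

#' Serialize a SelectorResult to JSON
#' @param res a `SelectorResult`.
#' @param path destination file.
#' @export
writeSelectorResult <- function(res, path) {
    jsonlite::write_json(list(selector = res$selector, genes = res$genes,
                              diagnostics = res$diagnostics),
                         path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
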