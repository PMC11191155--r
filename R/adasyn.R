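#' ADASYN adaptive synthetic oversampling of the minority class
#'
#' Generates `G = round(beta * (m_majority - m_minority))` synthetic minority
#' samples, allocated preferentially to minority points whose k-nearest
#' neighbourhood (Euclidean, over the full set) contains many majority
#' points: point i receives a share proportional to
#' `r_i = (majority neighbours among its k nearest) / k` (uniform shares
#' when every `r_i` is 0). Integer allocation uses largest-remainder
#' rounding so the synthetic total is exactly G, making the post-balance
#' class counts exact at `beta = 1`. Each synthetic point is
#' `x_i + lambda * (x_z - x_i)` with `lambda ~ U(0, 1)` and `x_z` drawn
#' uniformly from the (up to) k nearest minority neighbours of `x_i`.
#'
#' @param X samples x features numeric matrix.
#' @param y two-class labels aligned to rows.
#' @param k neighbour count (default 5).
#' @param beta balance level in `[0, 1]`; 1 equalises the classes, 0 is the
#'   identity.
#' @param seed integer seed; output is deterministic given inputs and seed.
#' @return a [BalancedSet-class]; original rows first (bit-identical),
#'   synthetic rows carry the minority label.
#' @examples
#' X <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(2, 1),
#'            c(0, 2), c(1, 2), c(2, 2))
#' y <- c(1, 1, 0, 0, 0, 0, 0, 0)
#' adasyn(X, y, k = 3, seed = 1)
#' @export
adasyn <- function(X, y, k = 5L, beta = 1.0, seed = 1L) {
    X <- as.matrix(X)
    y <- as.integer(y)
    stopifnot(nrow(X) == length(y), k >= 1L, beta >= 0)
    tab <- table(y)
    if (length(tab) < 2L)
        stop("ADASYN needs two classes; got a single class")
    minLab <- as.integer(names(tab)[which.min(tab)])
    majLab <- as.integer(names(tab)[which.max(tab)])
    mMin <- min(tab); mMaj <- max(tab)
    if (mMin < 2L)
        stop("minority class has fewer than 2 samples; cannot interpolate")
    G <- round(beta * (mMaj - mMin))
    mkBalanced <- function(Xs, ys) {
        n0 <- nrow(X); ns <- nrow(Xs)
        out <- rbind(X, Xs)
        rownames(out) <- if (is.null(rownames(X))) NULL else
            c(rownames(X), rownames(Xs))
        new("BalancedSet", X = out, y = c(y, ys),
            origin = factor(rep(c("original", "synthetic"), c(n0, ns)),
                            levels = c("original", "synthetic")))
    }
    if (G <= 0)
        return(mkBalanced(X[0, , drop = FALSE], integer(0)))
    minIdx <- which(y == minLab)
    ## full-set k-NN of each minority point (self excluded); deterministic
    ## distance ties broken by sample index
    d2 <- as.matrix(stats::dist(X))^2
    r <- vapply(minIdx, function(i) {
        ord <- order(d2[i, -i], seq_len(nrow(X) - 1L), method = "radix")
        nn <- (seq_len(nrow(X))[-i])[ord[seq_len(min(k, nrow(X) - 1L))]]
        sum(y[nn] == majLab) / k
    }, numeric(1))
    rhat <- if (sum(r) > 0) r / sum(r) else rep(1 / mMin, mMin)
    g <- largestRemainder(rhat, G)
    ## per-minority-point nearest minority neighbours (up to k)
    minNN <- lapply(minIdx, function(i) {
        others <- setdiff(minIdx, i)
        ord <- order(d2[i, others], seq_along(others), method = "radix")
        others[ord[seq_len(min(k, length(others)))]]
    })
    synth <- withSeed(seed, {
        rows <- vector("list", sum(g))
        pos <- 1L
        for (ii in seq_along(minIdx)) {
            if (g[ii] == 0L) next
            i <- minIdx[ii]
            nbrs <- minNN[[ii]]
            for (rep_ in seq_len(g[ii])) {
                z <- nbrs[sample.int(length(nbrs), 1L)]
                lambda <- runif(1)
                rows[[pos]] <- X[i, ] + lambda * (X[z, ] - X[i, ])
                pos <- pos + 1L
            }
        }
        if (length(rows)) do.call(rbind, rows) else X[0, , drop = FALSE]
    })
    colnames(synth) <- colnames(X)
    rownames(synth) <- if (nrow(synth))
        sprintf("synthetic_%04d", seq_len(nrow(synth))) else character(0)
    mkBalanced(synth, rep(minLab, nrow(synth)))
}

#' Matrix/label view of a BalancedSet
#' @param bs a [BalancedSet-class].
#' @return list with `X`, `y`, `origin`.
#' @export
balancedData <- function(bs) {
    stopifnot(is(bs, "BalancedSet"))
    list(X = bs@X, y = bs@y, origin = bs@origin)
}
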