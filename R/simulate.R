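#' Simulation configuration for multi-batch imbalanced RNA-seq counts
#'
#' Defaults describe the benchmark conditions the package is exercised
#' under: a three-batch cohort of 300 samples with a 65/35 class imbalance,
#' 500 genes of which 15 carry a modest planted signal (log2 fold change 1,
#' up in class 0), negative-binomial counts with inter-patient dispersion
#' 0.4, gene-and-batch-specific systematic shifts, and 4-fold library-size
#' variation.
#'
#' @param nGenes number of genes.
#' @param nBatches number of batches (cohorts).
#' @param samplesPerBatch samples per batch.
#' @param propClass0 fraction of class-0 (metastasis) samples per batch.
#' @param baselineLogMeanMu,baselineLogMeanSd natural-log mean and sd of the
#'   per-gene baseline abundance distribution.
#' @param nbDispersion negative-binomial dispersion phi
#'   (variance = mu + phi * mu^2); 0 gives Poisson counts.
#' @param batchLogFCSd sd (log2 units) of the per-(gene, batch) systematic
#'   shift.
#' @param libsizeRange min/max multiplicative library-size factors (drawn
#'   log-uniformly).
#' @param nSignal number of planted signature genes (the first `nSignal`
#'   gene ids, so independently simulated cohorts share the signature).
#' @param signalLFC log2 fold change of planted genes, class 0 vs class 1.
#' @param seed integer seed; same config and seed give bit-identical output.
#' @return a validated list of class `SimConfig`.
#' @export
simConfig <- function(nGenes = 500L, nBatches = 3L, samplesPerBatch = 100L,
                      propClass0 = 0.65, baselineLogMeanMu = 4,
                      baselineLogMeanSd = 1.5, nbDispersion = 0.4,
                      batchLogFCSd = 0.5, libsizeRange = c(0.5, 2),
                      nSignal = 15L, signalLFC = 1.0, seed = 1L) {
    cfg <- list(nGenes = as.integer(nGenes), nBatches = as.integer(nBatches),
                samplesPerBatch = as.integer(samplesPerBatch),
                propClass0 = propClass0,
                baselineLogMeanMu = baselineLogMeanMu,
                baselineLogMeanSd = baselineLogMeanSd,
                nbDispersion = nbDispersion, batchLogFCSd = batchLogFCSd,
                libsizeRange = as.numeric(libsizeRange),
                nSignal = as.integer(nSignal), signalLFC = signalLFC,
                seed = as.integer(seed))
    with(cfg, {
        if (nGenes < 2L || nBatches < 1L || samplesPerBatch < 2L)
            stop("nGenes, nBatches and samplesPerBatch must be positive (>=2 genes/samples)")
        if (propClass0 <= 0 || propClass0 >= 1)
            stop("propClass0 must lie in (0, 1)")
        if (nbDispersion < 0) stop("nbDispersion must be >= 0")
        if (length(libsizeRange) != 2L || libsizeRange[1] > libsizeRange[2] ||
            libsizeRange[1] <= 0)
            stop("libsizeRange must be positive with min <= max")
        if (nSignal > nGenes) stop("nSignal exceeds nGenes")
        if (baselineLogMeanSd < 0 || batchLogFCSd < 0)
            stop("scale parameters must be >= 0")
    })
    structure(cfg, class = "SimConfig")
}

#' Simulate a multi-batch, class-imbalanced count dataset with planted signal
#'
#' Counts for gene g in sample j are negative binomial with mean
#' `baseline_g * 2^shift(g, batch(j)) * 2^(signalLFC * planted(g) * I(class(j) == 0)) * libsize_j`.
#' Batch shifts are drawn once per (gene, batch); library sizes are
#' log-uniform over `libsizeRange`; each batch's class split matches
#' `propClass0` up to rounding. All draws flow from the single seed in the
#' config.
#'
#' @param cfg a [simConfig()].
#' @param role cohort role recorded for every sample (`train` or
#'   `validation`); simulate twice with different seeds for a two-cohort
#'   study sharing the planted signature.
#' @param prefix prefix for sample and batch ids, so cohorts can be combined.
#' @return list with `experiment` ([MarkerExperiment-class]) and `truth`
#'   ([SyntheticTruth-class]).
#' @examples
#' sim <- simulateDataset(simConfig(nGenes = 50, nBatches = 2,
#'     samplesPerBatch = 20, nSignal = 5, seed = 11))
#' sim$truth
#' @export
simulateDataset <- function(cfg, role = "train", prefix = "b") {
    stopifnot(inherits(cfg, "SimConfig"))
    role <- match.arg(role, SAMPLE_ROLES)
    n <- cfg$nBatches * cfg$samplesPerBatch
    geneIds <- sprintf("gene_%04d", seq_len(cfg$nGenes))
    batch <- rep(sprintf("%s%d", prefix, seq_len(cfg$nBatches)),
                 each = cfg$samplesPerBatch)
    n0 <- round(cfg$samplesPerBatch * cfg$propClass0)
    classPerBatch <- c(rep(0L, n0), rep(1L, cfg$samplesPerBatch - n0))
    cl <- rep(classPerBatch, cfg$nBatches)
    sampleIds <- sprintf("%s_s%03d", batch, sequence(rep(cfg$samplesPerBatch,
                                                         cfg$nBatches)))
    planted <- seq_len(cfg$nSignal)
    counts <- withSeed(cfg$seed, {
        baseline <- exp(rnorm(cfg$nGenes, cfg$baselineLogMeanMu,
                              cfg$baselineLogMeanSd))
        shift <- matrix(rnorm(cfg$nGenes * cfg$nBatches, 0, cfg$batchLogFCSd),
                        cfg$nGenes, cfg$nBatches)
        lib <- exp(runif(n, log(cfg$libsizeRange[1]), log(cfg$libsizeRange[2])))
        bIdx <- rep(seq_len(cfg$nBatches), each = cfg$samplesPerBatch)
        mu <- baseline * 2^shift[, bIdx, drop = FALSE]
        if (cfg$nSignal > 0) {
            isClass0 <- cl == 0L
            mu[planted, isClass0] <- mu[planted, isClass0] * 2^cfg$signalLFC
        }
        mu <- sweep(mu, 2, lib, "*")
        m <- if (cfg$nbDispersion > 0)
            matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nbDispersion),
                   nrow = cfg$nGenes)
        else matrix(rpois(length(mu), lambda = mu), nrow = cfg$nGenes)
        dimnames(m) <- list(geneIds, sampleIds)
        m
    })
    st <- data.frame(sample_id = sampleIds, class_label = cl,
                     batch_id = batch, role = role, stringsAsFactors = FALSE)
    truth <- new("SyntheticTruth",
                 signalGenes = geneIds[planted],
                 lfc = rep(cfg$signalLFC, cfg$nSignal))
    list(experiment = MarkerExperiment(counts, st), truth = truth)
}

#' Score recovery of the planted signature by a selected gene set
#'
#' @param selected character vector of selected gene ids.
#' @param truth a [SyntheticTruth-class].
#' @return list with `sensitivity` (fraction of planted genes recovered;
#'   1 when nothing was planted), `falsePositives` (selected genes outside
#'   the planted set) and `truePositives`.
#' @export
scoreRecovery <- function(selected, truth) {
    stopifnot(is(truth, "SyntheticTruth"))
    selected <- unique(as.character(selected))
    sig <- truth@signalGenes
    tp <- length(intersect(selected, sig))
    list(sensitivity = if (length(sig)) tp / length(sig) else 1.0,
         truePositives = tp,
         falsePositives = length(setdiff(selected, sig)))
}

#' Write the planted truth as a two-column TSV (gene_id, lfc)
#' @param truth a [SyntheticTruth-class].
#' @param path destination file.
#' @export
writeTruth <- function(truth, path) {
    utils::write.table(
        data.frame(gene_id = truth@signalGenes, lfc = truth@lfc),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
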