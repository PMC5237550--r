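#' The eight benchmark scenarios
#'
#' Gene numbers 100 and 300 crossed with sample sizes 50, 100, 200 and 300,
#' all other settings at the \code{\link{simScenario}} defaults.
#'
#' @param ... passed on to \code{\link{simScenario}} (e.g. \code{coupling}).
#' @return list of eight \code{SimScenario} objects, named
#'   \code{g<genes>_n<samples>}.
#' @export
defaultScenarios <- function(...) {
    grid <- expand.grid(nGenes = c(100L, 300L),
                        nSamples = c(50L, 100L, 200L, 300L))
    grid <- grid[order(grid$nGenes, grid$nSamples), ]
    out <- lapply(seq_len(nrow(grid)), function(i)
        simScenario(nGenes = grid$nGenes[i], nSamples = grid$nSamples[i],
                    ...))
    names(out) <- sprintf("g%d_n%d", grid$nGenes, grid$nSamples)
    out
}

#' Run the simulation benchmark
#'
#' For each scenario, runs \code{nReps} replicates of simulate -> CNA call
#' -> \code{\link{runCnaDE}} -> \code{\link{evaluateDetection}} and
#' aggregates sensitivity and specificity across replicates. Replicate seeds
#' are derived deterministically from \code{seed}, the scenario index and
#' the replicate index, so the whole benchmark is a pure function of
#' \code{(scenarios, seed)}.
#'
#' @param scenarios a \code{\link{simScenario}} or list thereof (see
#'   \code{\link{defaultScenarios}}).
#' @param nReps replicates per scenario.
#' @param seed integer base seed.
#' @param alpha,useFdr detection rule, see \code{\link{evaluateDetection}}.
#' @param gainThreshold,lossThreshold CNA call thresholds
#'   (\code{\link{callCNA}}).
#' @param minProp proportion filter passed to \code{\link{runCnaDE}}.
#' @param collectPvalues additionally pool per-condition p-value quartiles
#'   across replicates (\code{\link{pvalueByCondition}}).
#' @param verbose print one line per finished scenario.
#' @return list of class \code{"cnaBenchmark"} with elements
#'   \code{summary} (one row per scenario: mean and sd of sensitivity and
#'   specificity), \code{replicates} (per-replicate values) and, when
#'   requested, \code{pvalues} (per scenario x condition quartiles).
#' @examples
#' bench <- runBenchmark(simScenario(nGenes = 16, nSamples = 30),
#'                       nReps = 3, seed = 1)
#' bench$summary
#' @export
runBenchmark <- function(scenarios, nReps = 200L, seed = 1L, alpha = 0.05,
                         useFdr = FALSE, gainThreshold = 2.5,
                         lossThreshold = 1.5, minProp = 0.2,
                         collectPvalues = FALSE, verbose = FALSE) {
    if (is(scenarios, "SimScenario"))
        scenarios <- list(scenarios)
    stopifnot(length(scenarios) > 0L,
              all(vapply(scenarios, is, logical(1), "SimScenario")),
              nReps >= 1L)
    if (is.null(names(scenarios)))
        names(scenarios) <- vapply(scenarios, function(sc)
            sprintf("g%d_n%d", sc@nGenes, sc@nSamples), character(1))
    reps <- list()
    pvals <- list()
    for (si in seq_along(scenarios)) {
        sc <- scenarios[[si]]
        sens <- spec <- numeric(nReps)
        pAcc <- if (collectPvalues) vector("list", nReps) else NULL
        for (r in seq_len(nReps)) {
            repSeed <- replicateSeed(seed, si, r)
            sim <- simulateScenario(sc, repSeed)
            calls <- callCNA(sim$cn, gainThreshold, lossThreshold)
            res <- runCnaDE(sim$ge, calls, minProp = minProp)
            m <- evaluateDetection(res, sim$truth, alpha = alpha,
                                   useFdr = useFdr)
            sens[r] <- m[["sensitivity"]]
            spec[r] <- m[["specificity"]]
            if (collectPvalues)
                pAcc[[r]] <- DataFrame(
                    gene = res$gene, p_value = res$p_value,
                    condition = sim$truth$condition[
                        match(res$gene, sim$truth$gene)])
        }
        reps[[names(scenarios)[si]]] <- data.frame(
            scenario = names(scenarios)[si], nGenes = sc@nGenes,
            nSamples = sc@nSamples, rep = seq_len(nReps),
            sensitivity = sens, specificity = spec)
        if (collectPvalues) {
            pooled <- do.call(rbind, pAcc)
            pq <- pvalueByCondition(
                pooled, DataFrame(gene = pooled$gene,
                                  condition = pooled$condition))
            pq$scenario <- names(scenarios)[si]
            pvals[[names(scenarios)[si]]] <- pq
        }
        if (verbose)
            message(sprintf(
                "%s: sensitivity %.4f +/- %.4f, specificity %.4f +/- %.4f",
                names(scenarios)[si], mean(sens), sdOrZero(sens),
                mean(spec), sdOrZero(spec)))
    }
    repdf <- do.call(rbind, reps)
    rownames(repdf) <- NULL
    summary <- do.call(rbind, lapply(split(repdf, repdf$scenario), function(d)
        data.frame(scenario = d$scenario[1L], nGenes = d$nGenes[1L],
                   nSamples = d$nSamples[1L], nReps = nrow(d),
                   sensitivityMean = mean(d$sensitivity),
                   sensitivitySd = sdOrZero(d$sensitivity),
                   specificityMean = mean(d$specificity),
                   specificitySd = sdOrZero(d$specificity))))
    summary <- summary[match(names(scenarios), summary$scenario), ]
    rownames(summary) <- NULL
    out <- list(summary = summary, replicates = repdf)
    if (collectPvalues)
        out$pvalues <- do.call(rbind, unname(pvals))
    class(out) <- "cnaBenchmark"
    out
}

## deterministic per-replicate seed, kept inside the 32-bit integer range
replicateSeed <- function(seed, scenarioIdx, repIdx) {
    as.integer((as.numeric(seed) + 999983 * scenarioIdx + repIdx) %%
               2147483647)
}

sdOrZero <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

#' @export
print.cnaBenchmark <- function(x, ...) {
    cat("Simulation benchmark,", nrow(x$summary), "scenario(s)\n")
    df <- x$summary
    df$sensitivity <- sprintf("%.4f +/- %.4f", df$sensitivityMean,
                              df$sensitivitySd)
    df$specificity <- sprintf("%.4f +/- %.4f", df$specificityMean,
                              df$specificitySd)
    print(df[, c("scenario", "nGenes", "nSamples", "nReps", "sensitivity",
                 "specificity")], row.names = FALSE)
    invisible(x)
}

#' Write the benchmark summary as a TSV
#'
#' One row per scenario: gene number, sample size, replicate count, and the
#' mean and standard deviation of detection sensitivity and specificity.
#'
#' @param bench result of \code{\link{runBenchmark}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBenchmarkTable <- function(bench, path) {
    stopifnot(inherits(bench, "cnaBenchmark"))
    write.table(bench$summary, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
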