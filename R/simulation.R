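#' Simulate one coupled copy-number / expression dataset
#'
#' Generates the matrices for one benchmark replicate under a
#' \code{\link{simScenario}}. Genes are split evenly across the four
#' correlation conditions; each gene draws a target correlation uniformly
#' from its condition interval and couples its copy-number and expression
#' values through the scenario's coupling mechanism (see
#' \code{\link{simScenario}}). Each sample carries the gene's CNA
#' independently with probability \code{cnaFrequency}; absolute copy number
#' is clamped at zero. The output is a pure function of
#' \code{(scenario, seed)}: the same pair reproduces the matrices exactly.
#'
#' @param scenario a \code{\link{simScenario}} object.
#' @param seed integer seed for this replicate (the function calls
#'   \code{set.seed}).
#' @return list with elements \code{cn} (absolute copy-number matrix),
#'   \code{ge} (expression matrix) and \code{truth} (\code{DataFrame} with
#'   \code{gene}, \code{condition}, \code{rho} -- the per-gene target
#'   correlation -- and \code{isTruePositive}, \code{TRUE} for the
#'   \code{"r0.7-1"} condition).
#' @examples
#' sim <- simulateScenario(simScenario(nGenes = 8, nSamples = 20), seed = 1)
#' dim(sim$cn)
#' @export
simulateScenario <- function(scenario, seed) {
    stopifnot(is(scenario, "SimScenario"))
    validObject(scenario)
    set.seed(as.integer(seed))
    G <- scenario@nGenes
    S <- scenario@nSamples
    p <- scenario@cnaFrequency
    sdv <- if (scenario@dispersionUnit == "variance")
        sqrt(scenario@dispersion) else scenario@dispersion
    perCond <- G %/% 4L
    labels <- rep(simConditionLabels(), each = perCond)
    intervals <- simConditionIntervals()
    rho <- unlist(lapply(simConditionLabels(), function(lab) {
        iv <- intervals[[lab]]
        if (iv[1] == iv[2]) rep(iv[1], perCond)
        else runif(perCond, iv[1], iv[2])
    }), use.names = FALSE)
    geneIds <- sprintf("gene%03d", seq_len(G))
    sampleIds <- sprintf("S%03d", seq_len(S))
    dcn <- scenario@cnMeanCna - scenario@cnMeanNeutral
    dge <- scenario@geMeanCna - scenario@geMeanNeutral

    if (scenario@coupling == "correlation") {
        B <- matrix(runif(G * S) < p, G, S)
        D <- matrix(runif(G * S) < p, G, S)
        U <- matrix(rnorm(G * S, 0, sdv), G, S)
        E <- matrix(rnorm(G * S, 0, sdv), G, S)
        V <- rho * U + sqrt(1 - rho^2) * E   # per-gene (row) correlation
        cn <- scenario@cnMeanNeutral + dcn * B + U
        ge <- scenario@geMeanNeutral + dge * D + V
    } else {
        ## shuffle coupling: expression carrier labels copy the CN carrier
        ## labels for a calibrated fraction of samples, and the gene is
        ## redrawn until the realized Pearson correlation falls inside its
        ## condition interval (truth by construction); "r0" draws labels
        ## independently and is never rejected.
        rmax <- maxMixtureCorrelation(p, dcn, dge, sdv^2)
        cn <- matrix(NA_real_, G, S)
        ge <- matrix(NA_real_, G, S)
        for (i in seq_len(G)) {
            iv <- intervals[[labels[i]]]
            m <- min(1, rho[i] / rmax)
            for (try in seq_len(scenario@rejectionCap)) {
                b <- runif(S) < p
                keep <- runif(S) < m
                d <- ifelse(keep, b, runif(S) < p)
                x <- scenario@cnMeanNeutral + dcn * b + rnorm(S, 0, sdv)
                y <- scenario@geMeanNeutral + dge * d + rnorm(S, 0, sdv)
                if (iv[1] == iv[2])
                    break
                r <- suppressWarnings(cor(x, y))
                if (!is.na(r) && r >= iv[1] &&
                    (r < iv[2] || (iv[2] == 1 && r <= 1)))
                    break
                if (try == scenario@rejectionCap)
                    stop(sprintf(paste0("gene %s: no draw realized a ",
                                        "correlation in [%g,%g] within %d ",
                                        "tries"), geneIds[i], iv[1], iv[2],
                                 scenario@rejectionCap))
            }
            cn[i, ] <- x
            ge[i, ] <- y
        }
    }
    cn <- pmax(cn, 0)
    dimnames(cn) <- list(geneIds, sampleIds)
    dimnames(ge) <- list(geneIds, sampleIds)
    truth <- DataFrame(gene = geneIds, condition = labels, rho = rho,
                       isTruePositive = labels == "r0.7-1")
    list(cn = cn, ge = ge, truth = truth)
}

## largest Pearson correlation attainable between the two two-component
## mixtures when carrier labels coincide and noise is independent; used to
## calibrate the label-match fraction of the shuffle coupling
maxMixtureCorrelation <- function(p, dcn, dge, noiseVar) {
    v <- p * (1 - p)
    v * dcn * dge / sqrt((v * dcn^2 + noiseVar) * (v * dge^2 + noiseVar))
}

#' Score detection against simulation truth
#'
#' A gene counts as detected when it appears in the result table with
#' \code{p_value < alpha} in either direction (or \code{fdr < alpha} with
#' \code{useFdr = TRUE}). Sensitivity is the detected fraction of true
#' positives (condition \code{"r0.7-1"}); specificity is the non-detected
#' fraction of true negatives (the other three conditions). Genes filtered
#' out before testing are necessarily non-detected.
#'
#' @param results \code{DataFrame} from \code{\link{runCnaDE}}.
#' @param truth truth table from \code{\link{simulateScenario}}.
#' @param alpha detection threshold (default 0.05).
#' @param useFdr threshold the BH-adjusted values instead of raw p-values.
#' @return named numeric vector: \code{sensitivity}, \code{specificity}.
#' @examples
#' truth <- S4Vectors::DataFrame(gene = c("a", "b"),
#'                               condition = c("r0.7-1", "r0"),
#'                               rho = c(0.9, 0),
#'                               isTruePositive = c(TRUE, FALSE))
#' res <- S4Vectors::DataFrame(gene = "a", p_value = 0.001, fdr = 0.002)
#' evaluateDetection(res, truth)
#' @export
evaluateDetection <- function(results, truth, alpha = 0.05,
                              useFdr = FALSE) {
    stopifnot(alpha > 0, alpha <= 1)
    score <- if (useFdr) results$fdr else results$p_value
    detected <- unique(results$gene[!is.na(score) & score < alpha])
    tp <- truth$gene[truth$isTruePositive]
    tn <- truth$gene[!truth$isTruePositive]
    c(sensitivity = if (length(tp)) mean(tp %in% detected) else NA_real_,
      specificity = if (length(tn)) mean(!(tn %in% detected)) else NA_real_)
}

#' Pooled p-value quartiles per correlation condition
#'
#' Summarizes the p-values of all emitted tests, pooled across replicates,
#' by the true correlation condition of the tested gene. Under a
#' correlation-driven generator the p-values shrink as the condition's
#' correlation grows, so the medians decrease from \code{"r0"} to
#' \code{"r0.7-1"}.
#'
#' @param results a result \code{DataFrame} (rows from one or many
#'   replicates concatenated).
#' @param truth a truth table covering the tested genes (gene -> condition;
#'   concatenations across replicates are fine as long as the mapping is
#'   consistent).
#' @return \code{DataFrame} with one row per condition: \code{condition},
#'   \code{nTests}, \code{q25}, \code{median}, \code{q75} (\code{NA} when a
#'   condition has no tests).
#' @export
pvalueByCondition <- function(results, truth) {
    cond <- truth$condition[match(results$gene, truth$gene)]
    p <- results$p_value
    out <- lapply(simConditionLabels(), function(lab) {
        pv <- p[!is.na(cond) & cond == lab & !is.na(p)]
        if (length(pv) == 0L)
            return(DataFrame(condition = lab, nTests = 0L, q25 = NA_real_,
                             median = NA_real_, q75 = NA_real_))
        q <- quantile(pv, c(0.25, 0.5, 0.75), names = FALSE)
        DataFrame(condition = lab, nTests = length(pv), q25 = q[1],
                  median = q[2], q75 = q[3])
    })
    do.call(rbind, out)
}
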