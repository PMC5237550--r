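#' Paired copy-number / expression container
#'
#' \code{CNAExperiment} extends
#' \link[SummarizedExperiment]{SummarizedExperiment} and holds, for a common
#' set of genes (rows) and samples (columns), a normalized expression matrix
#' (assay \code{"expression"}), a per-gene absolute copy-number matrix (assay
#' \code{"copyNumber"}), and -- after \code{\link{callCNA}} -- a categorical
#' CNA call matrix (assay \code{"cnaCall"}, values \code{"G"}, \code{"L"},
#' \code{"N"} or \code{NA} where no segment covered the gene).
#'
#' The constructor intersects the row (gene) and column (sample) names of the
#' two matrices, preserving the order of the expression matrix, so the two
#' inputs may come from files with different gene universes.
#'
#' @param expression numeric matrix of normalized expression, genes x samples,
#'   with row and column names.
#' @param copyNumber numeric matrix of per-gene absolute copy number
#'   (\code{NA} = no overlapping segment), genes x samples, with dimnames.
#' @return A \code{CNAExperiment} object.
#' @examples
#' ge <- matrix(rnorm(6), 2, 3,
#'              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' cn <- matrix(2, 2, 3, dimnames = dimnames(ge))
#' CNAExperiment(ge, cn)
#' @seealso \code{\link{callCNA}}, \code{\link{runCnaDE}}
#' @aliases CNAExperiment-class
#' @export
CNAExperiment <- function(expression, copyNumber) {
    if (!is.matrix(expression) || !is.numeric(expression))
        stop("'expression' must be a numeric matrix")
    if (!is.matrix(copyNumber) || !is.numeric(copyNumber))
        stop("'copyNumber' must be a numeric matrix")
    if (is.null(rownames(expression)) || is.null(colnames(expression)) ||
        is.null(rownames(copyNumber)) || is.null(colnames(copyNumber)))
        stop("both matrices need row (gene) and column (sample) names")
    genes <- intersect(rownames(expression), rownames(copyNumber))
    samples <- intersect(colnames(expression), colnames(copyNumber))
    if (length(samples) == 0L)
        stop("no samples in common between expression and copy-number data")
    if (length(genes) == 0L)
        stop("no genes in common between expression and copy-number data")
    se <- SummarizedExperiment(
        assays = list(expression = expression[genes, samples, drop = FALSE],
                      copyNumber = copyNumber[genes, samples, drop = FALSE]))
    new("CNAExperiment", se)
}

setClass("CNAExperiment", contains = "SummarizedExperiment")

setValidity("CNAExperiment", function(object) {
    an <- assayNames(object)
    if (!all(c("expression", "copyNumber") %in% an))
        return("assays 'expression' and 'copyNumber' are required")
    cn <- assay(object, "copyNumber")
    if (any(cn < 0, na.rm = TRUE))
        return("copy-number values must be >= 0 (absolute scale)")
    if ("cnaCall" %in% an) {
        calls <- assay(object, "cnaCall")
        bad <- !(calls %in% c("G", "L", "N") | is.na(calls))
        if (any(bad))
            return("cnaCall values must be 'G', 'L', 'N' or NA")
    }
    TRUE
})

#' Accessors for CNAExperiment
#'
#' \code{geValues} and \code{cnValues} return the expression and absolute
#' copy-number matrices; \code{cnaCalls} returns the G/L/N call matrix (or
#' \code{NULL} before \code{\link{callCNA}} has been run);
#' \code{callThresholds} returns the gain/loss thresholds used for calling.
#'
#' @param x a \code{\link{CNAExperiment}}.
#' @return A matrix (or \code{NULL}/numeric vector, see above).
#' @name CNAExperiment-accessors
NULL

#' @rdname CNAExperiment-accessors
#' @export
setMethod("geValues", "CNAExperiment", function(x) assay(x, "expression"))

#' @rdname CNAExperiment-accessors
#' @export
setMethod("cnValues", "CNAExperiment", function(x) assay(x, "copyNumber"))

#' @rdname CNAExperiment-accessors
#' @export
setMethod("cnaCalls", "CNAExperiment", function(x) {
    if ("cnaCall" %in% assayNames(x)) assay(x, "cnaCall") else NULL
})

#' @rdname CNAExperiment-accessors
#' @export
setMethod("callThresholds", "CNAExperiment", function(x)
    metadata(x)$callThresholds)

setMethod("show", "CNAExperiment", function(object) {
    cat("CNAExperiment with", nrow(object), "genes and", ncol(object),
        "samples\n")
    cat("assays:", paste(assayNames(object), collapse = ", "), "\n")
    th <- callThresholds(object)
    if (!is.null(th))
        cat(sprintf("CNA calls at gain >= %g, loss <= %g\n",
                    th[["gain"]], th[["loss"]]))
    calls <- cnaCalls(object)
    if (!is.null(calls)) {
        tab <- table(factor(calls, levels = c("G", "L", "N")),
                     useNA = "ifany")
        cat("call counts:", paste(names(tab), tab, sep = "=",
                                  collapse = " "), "\n")
    }
})

## ---------------------------------------------------------------------------

#' Simulation scenario for the benchmark
#'
#' A \code{SimScenario} bundles the generator settings for one benchmark
#' scenario: coupled per-gene copy-number and expression profiles in which
#' each sample carries a CNA independently with probability
#' \code{cnaFrequency}, carrier copy number is Normal(\code{cnMeanCna},
#' \code{dispersion}) and non-carrier Normal(\code{cnMeanNeutral},
#' \code{dispersion}); expression carriers are Normal(\code{geMeanCna},
#' \code{dispersion}) against Normal(\code{geMeanNeutral},
#' \code{dispersion}). \code{dispersion} is interpreted as a variance by
#' default (\code{dispersionUnit = "variance"}), matching the covariance
#' parameterization of multivariate-normal generators; set
#' \code{dispersionUnit = "sd"} for a standard-deviation reading.
#'
#' Genes are split evenly over four Pearson-correlation conditions
#' (\code{"r0"}, \code{"r0-0.3"}, \code{"r0.3-0.7"}, \code{"r0.7-1"}); each
#' gene draws a target correlation uniformly from its condition interval.
#' Two coupling mechanisms are available (see the package vignette):
#' \describe{
#'   \item{\code{"correlation"} (default)}{the target value is the
#'     correlation parameter of the bivariate normal noise shared by the
#'     copy-number and expression values of each sample, with CNA-carrier
#'     indicators drawn independently for the two layers. The condition label
#'     is exactly the simulated correlation parameter.}
#'   \item{\code{"shuffle"}}{expression carrier labels copy the copy-number
#'     carrier labels for a calibrated fraction of samples, and the gene is
#'     re-drawn (up to \code{rejectionCap} times) until the realized Pearson
#'     correlation between the two vectors falls inside the condition
#'     interval, so truth labels hold for the realized correlation by
#'     construction. The \code{"r0"} condition draws labels independently and
#'     is never rejected.}
#' }
#'
#' @param nGenes number of genes; must be divisible by 4 (equal-sized
#'   correlation conditions). Study sizes are 100 and 300.
#' @param nSamples number of samples (50, 100, 200 or 300 in the benchmark).
#' @param cnaFrequency per-sample probability of carrying the CNA
#'   (default 0.30).
#' @param cnMeanCna,cnMeanNeutral mean absolute copy number of carrier /
#'   non-carrier samples (3 and 2).
#' @param geMeanCna,geMeanNeutral mean expression of expression-carrier /
#'   non-carrier samples (5 and 2.5).
#' @param dispersion spread of all four normals (default 0.2).
#' @param dispersionUnit \code{"variance"} (default) or \code{"sd"}.
#' @param coupling \code{"correlation"} or \code{"shuffle"} (see Details).
#' @param rejectionCap maximum redraws per gene under \code{"shuffle"}
#'   coupling before an error is raised.
#' @return A \code{SimScenario} object.
#' @examples
#' simScenario(nGenes = 100, nSamples = 50)
#' @seealso \code{\link{simulateScenario}}, \code{\link{runBenchmark}}
#' @aliases SimScenario-class
#' @export
simScenario <- function(nGenes = 100L, nSamples = 50L, cnaFrequency = 0.30,
                        cnMeanCna = 3, cnMeanNeutral = 2, geMeanCna = 5,
                        geMeanNeutral = 2.5, dispersion = 0.2,
                        dispersionUnit = c("variance", "sd"),
                        coupling = c("correlation", "shuffle"),
                        rejectionCap = 1000L) {
    new("SimScenario",
        nGenes = as.integer(nGenes), nSamples = as.integer(nSamples),
        cnaFrequency = cnaFrequency, cnMeanCna = cnMeanCna,
        cnMeanNeutral = cnMeanNeutral, geMeanCna = geMeanCna,
        geMeanNeutral = geMeanNeutral, dispersion = dispersion,
        dispersionUnit = match.arg(dispersionUnit),
        coupling = match.arg(coupling),
        rejectionCap = as.integer(rejectionCap))
}

setClass("SimScenario",
    representation(nGenes = "integer", nSamples = "integer",
                   cnaFrequency = "numeric", cnMeanCna = "numeric",
                   cnMeanNeutral = "numeric", geMeanCna = "numeric",
                   geMeanNeutral = "numeric", dispersion = "numeric",
                   dispersionUnit = "character", coupling = "character",
                   rejectionCap = "integer"))

setValidity("SimScenario", function(object) {
    if (object@nGenes < 4L || object@nGenes %% 4L != 0L)
        return("nGenes must be a positive multiple of 4")
    if (object@nSamples < 4L)
        return("nSamples must be at least 4")
    if (object@cnaFrequency <= 0 || object@cnaFrequency >= 1)
        return("cnaFrequency must lie in (0, 1)")
    if (object@dispersion <= 0)
        return("dispersion must be positive")
    if (!object@dispersionUnit %in% c("variance", "sd"))
        return("dispersionUnit must be 'variance' or 'sd'")
    if (!object@coupling %in% c("correlation", "shuffle"))
        return("coupling must be 'correlation' or 'shuffle'")
    if (object@rejectionCap < 1L)
        return("rejectionCap must be >= 1")
    TRUE
})

setMethod("show", "SimScenario", function(object) {
    cat(sprintf("SimScenario: %d genes x %d samples\n",
                object@nGenes, object@nSamples))
    cat(sprintf("  CNA frequency %.2f; CN %g/%g, GE %g/%g (%s %g)\n",
                object@cnaFrequency, object@cnMeanCna, object@cnMeanNeutral,
                object@geMeanCna, object@geMeanNeutral,
                object@dispersionUnit, object@dispersion))
    cat(sprintf("  coupling: %s; conditions: %s\n", object@coupling,
                paste(simConditionLabels(), collapse = ", ")))
})

## condition labels and intervals are fixed by the study design
simConditionLabels <- function()
    c("r0", "r0-0.3", "r0.3-0.7", "r0.7-1")

simConditionIntervals <- function()
    list("r0" = c(0, 0), "r0-0.3" = c(0, 0.3),
         "r0.3-0.7" = c(0.3, 0.7), "r0.7-1" = c(0.7, 1))
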