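#' Welch's unequal-variance t-test
#'
#' The two-sample t-test without the equal-variance assumption:
#' \deqn{t = (\bar x - \bar y) / \sqrt{s_x^2/n_x + s_y^2/n_y}}
#' with Welch-Satterthwaite degrees of freedom and a two-sided p-value from
#' the t distribution. This is the per-gene test applied by
#' \code{\link{runCnaDE}} to the expression of the CNA group versus its
#' complement; it is exposed directly for transparency and testing.
#'
#' Degenerate inputs follow fixed rules: a group with fewer than two finite
#' values yields \code{NA} statistics; zero variance in both groups yields
#' \code{p = 1} when the means are equal and \code{p = 0} (infinite
#' \code{t}) when they differ.
#'
#' @param x,y numeric vectors; \code{NA}s are dropped.
#' @return list with elements \code{t}, \code{df} and \code{p}.
#' @examples
#' welchTest(c(1, 2, 3), c(4, 5, 6))
#' @export
welchTest <- function(x, y) {
    x <- x[is.finite(x)]
    y <- y[is.finite(y)]
    nx <- length(x); ny <- length(y)
    if (nx < 2L || ny < 2L)
        return(list(t = NA_real_, df = NA_real_, p = NA_real_))
    res <- welchStats(nx, mean(x), stats::var(x), ny, mean(y), stats::var(y))
    list(t = res$t, df = res$df, p = res$p)
}

## vectorized Welch statistics from sufficient statistics; the NA/zero-variance
## conventions of welchTest() apply elementwise
welchStats <- function(n1, m1, v1, n2, m2, v2) {
    se2 <- v1 / n1 + v2 / n2
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * pt(-abs(t), df)
    zero <- !is.na(se2) & se2 == 0
    if (any(zero)) {
        eq <- zero & (m1 == m2)
        t[eq] <- 0; df[eq] <- n1[eq] + n2[eq] - 2; p[eq] <- 1
        ne <- zero & (m1 != m2)
        t[ne] <- sign(m1[ne] - m2[ne]) * Inf
        df[ne] <- n1[ne] + n2[ne] - 2; p[ne] <- 0
    }
    small <- !is.na(n1) & (n1 < 2L | n2 < 2L)
    t[small] <- NA_real_; df[small] <- NA_real_; p[small] <- NA_real_
    list(t = t, df = df, p = p)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted p-values (via \code{\link[stats]{p.adjust}} with
#' \code{method = "BH"}): monotone non-decreasing in rank, capped at 1 and
#' elementwise no smaller than the input. \code{NA} p-values are excluded
#' from the pool and returned as \code{NA}.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of adjusted values, same length as \code{p}.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))   # all 0.04
#' @export
bhAdjust <- function(p) {
    stopifnot(is.numeric(p))
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    out <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    out[ok] <- p.adjust(p[ok], method = "BH")
    out
}

#' Per-gene CNA proportions
#'
#' For each gene, the fraction of samples called CNA-gain and CNA-loss over
#' the samples with a non-missing call (samples without an overlapping
#' copy-number segment do not enter the denominator).
#'
#' @param calls character matrix of \code{"G"}/\code{"L"}/\code{"N"} calls
#'   (genes x samples), as produced by \code{\link{callCNA}}, or a
#'   \code{\link{CNAExperiment}} carrying a \code{"cnaCall"} assay.
#' @return \code{DataFrame} with columns \code{gene}, \code{nGain},
#'   \code{nLoss}, \code{nNeutral}, \code{nCalled}, \code{propGain},
#'   \code{propLoss}; genes with no called sample have \code{NA} proportions.
#' @export
cnaProportions <- function(calls) {
    if (is(calls, "CNAExperiment")) {
        calls <- cnaCalls(calls)
        if (is.null(calls))
            stop("run callCNA() first: no 'cnaCall' assay present")
    }
    stopifnot(is.matrix(calls))
    nG <- rowSums(calls == "G", na.rm = TRUE)
    nL <- rowSums(calls == "L", na.rm = TRUE)
    nN <- rowSums(calls == "N", na.rm = TRUE)
    nTot <- nG + nL + nN
    DataFrame(gene = if (is.null(rownames(calls)))
                  as.character(seq_len(nrow(calls))) else rownames(calls),
              nGain = unname(nG), nLoss = unname(nL),
              nNeutral = unname(nN), nCalled = unname(nTot),
              propGain = unname(ifelse(nTot > 0, nG / nTot, NA_real_)),
              propLoss = unname(ifelse(nTot > 0, nL / nTot, NA_real_)))
}

#' Select testable gene-direction pairs
#'
#' A gene is testable in the gain direction when its CNA-gain proportion is
#' at least \code{minProp} (inclusive, "at least 20 percent of the samples"
#' by default), and likewise for loss; a gene may be testable in both
#' directions and both are then reported.
#'
#' @param props result of \code{\link{cnaProportions}}.
#' @param minProp minimum CNA proportion, in (0, 1); default 0.20.
#' @return \code{DataFrame} with columns \code{gene} and \code{direction}
#'   (\code{"gain"}/\code{"loss"}).
#' @export
selectTestable <- function(props, minProp = 0.2) {
    stopifnot(minProp > 0, minProp < 1)
    gain <- !is.na(props$propGain) & props$propGain >= minProp
    loss <- !is.na(props$propLoss) & props$propLoss >= minProp
    DataFrame(gene = c(props$gene[gain], props$gene[loss]),
              direction = rep(c("gain", "loss"),
                              c(sum(gain), sum(loss))))
}

#' Reconstruct the group mean difference from summary statistics
#'
#' The reported \code{GE_mean_diff} statistic is the mean expression of the
#' CNA group minus the mean of the pooled complement (loss plus neutral
#' samples for the gain direction; gain plus neutral for loss). Given only
#' per-group means and CNA proportions -- as printed in a summary table --
#' the pooled complement mean is the proportion-weighted average of the
#' complement subgroup means, skipping subgroups with proportion zero (whose
#' means are undefined, printed \code{NA}).
#'
#' @param meanGain,meanLoss,meanNeutral numeric vectors of group means
#'   (\code{NA} allowed for empty groups).
#' @param propGain,propLoss numeric vectors of CNA proportions; the neutral
#'   proportion is \code{1 - propGain - propLoss}.
#' @param direction character vector, \code{"gain"} or \code{"loss"}.
#' @return numeric vector of reconstructed mean differences.
#' @examples
#' ## gain-direction gene: test group G against pooled L+N
#' reconstructGroupDiff(0.372, -1.048, -0.200, 0.558, 0.015, "gain")
#' @export
reconstructGroupDiff <- function(meanGain, meanLoss, meanNeutral,
                                 propGain, propLoss, direction) {
    n <- length(direction)
    stopifnot(all(direction %in% c("gain", "loss")))
    propNeutral <- 1 - propGain - propLoss
    testMean <- ifelse(direction == "gain", meanGain, meanLoss)
    w1 <- ifelse(direction == "gain", propLoss, propGain)
    m1 <- ifelse(direction == "gain", meanLoss, meanGain)
    w1 <- ifelse(w1 > 0, w1, 0)
    m1z <- ifelse(w1 > 0, m1, 0)
    w2 <- ifelse(propNeutral > 0, propNeutral, 0)
    m2z <- ifelse(w2 > 0, meanNeutral, 0)
    comp <- (w1 * m1z + w2 * m2z) / (w1 + w2)
    testMean - comp
}

#' Identify CNA-driven differentially expressed genes
#'
#' The core per-gene procedure: for every gene with a CNA (gain or loss)
#' proportion of at least \code{minProp}, the expression of the CNA group is
#' compared against the pooled complement (G versus L+N, or L versus G+N)
#' with Welch's t-test; Benjamini-Hochberg FDR is computed jointly across
#' all emitted gene-direction tests and results are ordered by ascending
#' FDR. Genes whose complement group is empty (CNA in 100 percent of the
#' called samples) cannot be tested -- no control group exists -- and are
#' omitted. Tests where either side has fewer than \code{minGroupSize}
#' finite expression values are reported with \code{NA} statistics (set
#' \code{dropNA = TRUE} to drop them).
#'
#' @param x expression matrix (genes x samples, dimnames required) or a
#'   \code{\link{CNAExperiment}} that has been through \code{\link{callCNA}}.
#' @param calls character call matrix from \code{\link{callCNA}} (ignored
#'   when \code{x} is a \code{CNAExperiment}). Genes and samples are matched
#'   by name; the intersection must be non-empty.
#' @param minProp minimum CNA proportion for a gene-direction to be tested
#'   (default 0.20, inclusive).
#' @param minGroupSize minimum finite expression values per side for the
#'   t-test (default 2; variance must exist).
#' @param dropNA drop rows whose test could not be computed.
#' @return \code{DataFrame} with one row per tested (gene, direction):
#'   \code{gene}, \code{direction}, \code{GE_mean_gain}, \code{GE_mean_loss},
#'   \code{GE_mean_neutral} (\code{NA} for empty subgroups),
#'   \code{GE_mean_diff} (test group minus pooled complement),
#'   \code{CNA_prop_gain}, \code{CNA_prop_loss}, \code{t_statistic},
#'   \code{df}, \code{p_value}, \code{fdr}; sorted by FDR. Filter-stage
#'   counts are kept in \code{metadata()}.
#' @examples
#' set.seed(1)
#' ge <- matrix(rnorm(60, 5), 3, 20,
#'              dimnames = list(paste0("g", 1:3), paste0("s", 1:20)))
#' cn <- matrix(2, 3, 20, dimnames = dimnames(ge))
#' cn[1, 1:8] <- 3.2          # gene g1 gained in 40% of samples
#' ge[1, 1:8] <- ge[1, 1:8] + 3
#' runCnaDE(ge, callCNA(cn))
#' @rdname runCnaDE
#' @export
setMethod("runCnaDE", signature(x = "matrix", calls = "matrix"),
    function(x, calls, minProp = 0.2, minGroupSize = 2L, dropNA = FALSE) {
        if (is.null(rownames(x)) || is.null(rownames(calls)))
            stop("expression and call matrices must have gene rownames")
        genes <- intersect(rownames(x), rownames(calls))
        samples <- intersect(colnames(x), colnames(calls))
        if (length(samples) == 0L)
            stop("no samples in common between expression and CNA calls")
        if (length(genes) == 0L)
            stop("no genes in common between expression and CNA calls")
        cnaDECore(x[genes, samples, drop = FALSE],
                  calls[genes, samples, drop = FALSE],
                  minProp = minProp, minGroupSize = minGroupSize,
                  dropNA = dropNA)
    })

#' @rdname runCnaDE
#' @export
setMethod("runCnaDE", signature(x = "CNAExperiment", calls = "missing"),
    function(x, calls, minProp = 0.2, minGroupSize = 2L, dropNA = FALSE) {
        cl <- cnaCalls(x)
        if (is.null(cl))
            stop("run callCNA() first: no 'cnaCall' assay present")
        cnaDECore(geValues(x), cl, minProp = minProp,
                  minGroupSize = minGroupSize, dropNA = dropNA)
    })

## Vectorized implementation shared by both methods; expr and calls are
## conformable matrices with identical dimnames.
cnaDECore <- function(expr, calls, minProp = 0.2, minGroupSize = 2L,
                      dropNA = FALSE) {
    stopifnot(minProp > 0, minProp < 1, minGroupSize >= 1L)
    genes <- rownames(expr)
    eOK <- is.finite(expr)
    ez <- ifelse(eOK, expr, 0)
    ez2 <- ez * ez
    stats <- lapply(c(G = "G", L = "L", N = "N"), function(lab) {
        m <- !is.na(calls) & calls == lab
        nCall <- rowSums(m)
        me <- m & eOK
        n <- rowSums(me)
        s <- rowSums(ez * me)
        q <- rowSums(ez2 * me)
        mean <- ifelse(n > 0, s / n, NA_real_)
        var <- ifelse(n > 1, (q - n * mean^2) / (n - 1), NA_real_)
        var <- pmax(var, 0)    # guard tiny negative from rounding
        list(nCall = nCall, n = n, s = s, q = q, mean = mean, var = var)
    })
    nCalled <- stats$G$nCall + stats$L$nCall + stats$N$nCall
    propG <- ifelse(nCalled > 0, stats$G$nCall / nCalled, NA_real_)
    propL <- ifelse(nCalled > 0, stats$L$nCall / nCalled, NA_real_)

    oneDirection <- function(direction) {
        test <- if (direction == "gain") stats$G else stats$L
        o1 <- if (direction == "gain") stats$L else stats$G
        o2 <- stats$N
        prop <- if (direction == "gain") propG else propL
        compCalled <- o1$nCall + o2$nCall
        sel <- which(!is.na(prop) & prop >= minProp & compCalled > 0)
        if (length(sel) == 0L)
            return(NULL)
        nT <- test$n[sel]; sT <- test$s[sel]; qT <- test$q[sel]
        nC <- o1$n[sel] + o2$n[sel]
        sC <- o1$s[sel] + o2$s[sel]
        qC <- o1$q[sel] + o2$q[sel]
        mT <- ifelse(nT > 0, sT / nT, NA_real_)
        mC <- ifelse(nC > 0, sC / nC, NA_real_)
        vT <- ifelse(nT > 1, pmax((qT - nT * mT^2) / (nT - 1), 0), NA_real_)
        vC <- ifelse(nC > 1, pmax((qC - nC * mC^2) / (nC - 1), 0), NA_real_)
        testable <- nT >= minGroupSize & nC >= minGroupSize
        w <- welchStats(nT, mT, vT, nC, mC, vC)
        w$t[!testable] <- NA_real_
        w$df[!testable] <- NA_real_
        w$p[!testable] <- NA_real_
        DataFrame(gene = genes[sel], direction = direction,
                  GE_mean_gain = unname(stats$G$mean[sel]),
                  GE_mean_loss = unname(stats$L$mean[sel]),
                  GE_mean_neutral = unname(stats$N$mean[sel]),
                  GE_mean_diff = unname(mT - mC),
                  CNA_prop_gain = unname(propG[sel]),
                  CNA_prop_loss = unname(propL[sel]),
                  t_statistic = unname(w$t), df = unname(w$df),
                  p_value = unname(w$p))
    }
    parts <- Filter(Negate(is.null),
                    list(oneDirection("gain"), oneDirection("loss")))
    res <- if (length(parts)) do.call(rbind, parts) else NULL
    if (is.null(res))
        res <- DataFrame(gene = character(0), direction = character(0),
                         GE_mean_gain = numeric(0),
                         GE_mean_loss = numeric(0),
                         GE_mean_neutral = numeric(0),
                         GE_mean_diff = numeric(0),
                         CNA_prop_gain = numeric(0),
                         CNA_prop_loss = numeric(0),
                         t_statistic = numeric(0), df = numeric(0),
                         p_value = numeric(0))
    res$fdr <- bhAdjust(res$p_value)
    if (dropNA)
        res <- res[!is.na(res$p_value), , drop = FALSE]
    ord <- order(res$fdr, res$p_value, res$gene, na.last = TRUE)
    res <- res[ord, , drop = FALSE]
    rownames(res) <- NULL
    metadata(res) <- list(minProp = minProp, minGroupSize = minGroupSize,
                          nGenes = length(genes),
                          nSamples = ncol(expr),
                          nTestableGenes = length(unique(res$gene)),
                          nTests = nrow(res))
    res
}

#' Subtract a baseline from an expression matrix
#'
#' Centers tumor expression on a set of baseline (e.g. adjacent-normal)
#' samples: per gene, the mean expression over the baseline samples is
#' subtracted from every non-baseline sample, and the baseline columns are
#' removed from the output.
#'
#' @param expr numeric expression matrix (genes x samples).
#' @param baselineSamples character vector of baseline column names (must be
#'   present, and must not cover all samples).
#' @return expression matrix restricted to non-baseline samples.
#' @export
subtractBaseline <- function(expr, baselineSamples) {
    stopifnot(is.matrix(expr))
    if (length(baselineSamples) == 0L)
        stop("no baseline samples given")
    missing <- setdiff(baselineSamples, colnames(expr))
    if (length(missing))
        stop("baseline sample(s) absent from matrix: ",
             paste(missing, collapse = ", "))
    rest <- setdiff(colnames(expr), baselineSamples)
    if (length(rest) == 0L)
        stop("baseline covers all samples; nothing left to center")
    base <- rowMeans(expr[, baselineSamples, drop = FALSE], na.rm = TRUE)
    expr[, rest, drop = FALSE] - base
}
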