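#' Per-gene Pearson correlation between expression and copy number
#'
#' For each gene shared between the two matrices, the Pearson correlation of
#' its expression and absolute copy-number values over the shared samples,
#' using pairwise-complete observations. Continuous copy-number values are
#' used, not the categorical G/L/N calls. Genes with fewer than three
#' complete pairs or zero variance in either vector get \code{r = NA} and
#' are flagged.
#'
#' @param expr numeric expression matrix (genes x samples) or a
#'   \code{\link{CNAExperiment}} (in which case \code{cn} is ignored).
#' @param cn numeric absolute copy-number matrix.
#' @param groupLabel optional evaluation-condition tag recorded on every row
#'   (e.g. \code{"whole-set"}, \code{"cna-region"}, \code{"venn"},
#'   \code{"cna-driven"}, \code{"cna-driven-positive"},
#'   \code{"cna-driven-negative"}).
#' @return \code{DataFrame} with columns \code{gene}, \code{r}, \code{n}
#'   (complete pairs), \code{flagged} (undefined correlation) and, when
#'   given, \code{group}.
#' @export
cnGeCorrelation <- function(expr, cn, groupLabel = NULL) {
    if (is(expr, "CNAExperiment")) {
        cn <- cnValues(expr)
        expr <- geValues(expr)
    }
    stopifnot(is.matrix(expr), is.matrix(cn))
    genes <- intersect(rownames(expr), rownames(cn))
    samples <- intersect(colnames(expr), colnames(cn))
    if (length(genes) == 0L || length(samples) == 0L)
        stop("no shared genes/samples between expression and copy number")
    e <- expr[genes, samples, drop = FALSE]
    c2 <- cn[genes, samples, drop = FALSE]
    r <- numeric(length(genes))
    n <- integer(length(genes))
    for (i in seq_along(genes)) {
        ok <- is.finite(e[i, ]) & is.finite(c2[i, ])
        n[i] <- sum(ok)
        r[i] <- if (n[i] >= 3L) suppressWarnings(cor(e[i, ok], c2[i, ok]))
                else NA_real_
    }
    out <- DataFrame(gene = genes, r = r, n = n, flagged = is.na(r))
    if (!is.null(groupLabel))
        out$group <- groupLabel
    out
}

#' Split gene correlations by sign
#'
#' Partitions a correlation table into positively and negatively correlated
#' genes. A correlation of exactly zero (a measure-zero event on continuous
#' data, but possible on degenerate integer input) is assigned to neither
#' set; undefined correlations are dropped.
#'
#' @param correlations result of \code{\link{cnGeCorrelation}}.
#' @return list with elements \code{positive} and \code{negative}, each a
#'   \code{DataFrame} subset of the input.
#' @export
splitBySign <- function(correlations) {
    r <- correlations$r
    list(positive = correlations[!is.na(r) & r > 0, , drop = FALSE],
         negative = correlations[!is.na(r) & r < 0, , drop = FALSE])
}

#' Venn-style gene set intersection
#'
#' The baseline integration protocol against which within-patient testing is
#' compared: genes significant for differential expression and genes
#' significant for CNA are intersected as plain sets, without regard to
#' whether the two events co-occur in the same samples.
#'
#' @param deGenes,cnaGenes character vectors of gene identifiers.
#' @return list with \code{intersection} (character vector) and \code{sizes}
#'   (named integer vector: \code{de}, \code{cna}, \code{common}).
#' @examples
#' vennIntersect(c("a", "b", "c"), c("b", "c", "d"))
#' @export
vennIntersect <- function(deGenes, cnaGenes) {
    deGenes <- unique(as.character(deGenes))
    cnaGenes <- unique(as.character(cnaGenes))
    common <- intersect(deGenes, cnaGenes)
    list(intersection = common,
         sizes = c(de = length(deGenes), cna = length(cnaGenes),
                   common = length(common)))
}
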