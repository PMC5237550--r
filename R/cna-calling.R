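#' Convert segment values to absolute copy number
#'
#' Segment means from array/sequencing pipelines are usually log2 ratios of
#' observed to expected (diploid) copy number; the gain/loss thresholds of
#' \code{\link{callCNA}} live on the absolute scale, where diploid = 2.
#' \code{"absolute"} values pass through unchanged; \code{"log2ratio"} values
#' are transformed as \eqn{2 \cdot 2^{v}} (so 0 maps to 2, 1 to 4, -1 to 1).
#'
#' @param value numeric vector of segment values.
#' @param scale \code{"absolute"} or \code{"log2ratio"}.
#' @return numeric vector of absolute copy numbers.
#' @examples
#' toAbsoluteCN(c(0, 1, -1), "log2ratio")   # 2 4 1
#' @export
toAbsoluteCN <- function(value, scale = c("absolute", "log2ratio")) {
    scale <- match.arg(scale)
    stopifnot(is.numeric(value))
    if (scale == "absolute") value else 2 * 2^value
}

#' Map copy-number segments onto genes
#'
#' Builds the per-gene absolute copy-number matrix used for CNA calling. For
#' every (gene, sample) pair the value is taken from the overlapping segment
#' of that sample with the largest overlap length; ties are broken first by
#' the segment whose copy number is farthest from the diploid value 2 (the
#' most extreme event), then by genomic order. Cells with no overlapping
#' segment are \code{NA} and stay missing downstream -- such samples are
#' excluded from the gene's proportion denominator and test groups.
#'
#' @param segments \code{GRanges} from \code{\link{readCnSegments}} (metadata
#'   columns \code{sample}, \code{value}; declared scale in
#'   \code{metadata(segments)$scale}, defaulting to \code{"absolute"}).
#' @param genes named \code{GRanges} from \code{\link{readGeneAnnotation}}.
#' @param samples optional character vector fixing the column set/order;
#'   defaults to the samples present in \code{segments}, in order of first
#'   appearance.
#' @return numeric matrix of absolute copy number, genes x samples, with
#'   \code{NA} where no segment overlaps.
#' @examples
#' genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' names(genes) <- "G1"
#' segs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000),
#'                                sample = "S1", value = 3.1)
#' mapSegmentsToGenes(segs, genes)
#' @export
mapSegmentsToGenes <- function(segments, genes, samples = NULL) {
    stopifnot(is(segments, "GRanges"), is(genes, "GRanges"))
    if (is.null(names(genes)))
        stop("'genes' must be named by gene identifier")
    scale <- metadata(segments)$scale
    if (is.null(scale)) scale <- "absolute"
    if (is.null(samples)) samples <- unique(mcols(segments)$sample)
    cn <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                 dimnames = list(names(genes), samples))
    if (length(segments) == 0L || length(genes) == 0L)
        return(cn)
    hits <- findOverlaps(genes, segments, ignore.strand = TRUE)
    if (length(hits) == 0L)
        return(cn)
    ov <- width(pintersect(granges(genes)[S4Vectors::queryHits(hits)],
                           granges(segments)[S4Vectors::subjectHits(hits)],
                           ignore.strand = TRUE))
    sj <- S4Vectors::subjectHits(hits)
    dt <- data.table(
        gene = S4Vectors::queryHits(hits),
        sample = mcols(segments)$sample[sj],
        overlap = ov,
        cn = toAbsoluteCN(mcols(segments)$value[sj], scale),
        segStart = start(segments)[sj])
    ## largest overlap wins; ties: most extreme copy number, then position
    dt[, extremity := abs(cn - 2)]
    setorder(dt, gene, sample, -overlap, -extremity, segStart)
    best <- dt[, .SD[1L], by = c("gene", "sample")]
    cn[cbind(best$gene, match(best$sample, samples))] <- best$cn
    cn
}

#' Call per-gene CNA status
#'
#' Classifies each (gene, sample) cell of an absolute copy-number matrix into
#' CNA-gain (\code{"G"}, copy number >= \code{gainThreshold}), CNA-loss
#' (\code{"L"}, copy number <= \code{lossThreshold}) or neutral (\code{"N"}).
#' Thresholds are inclusive and live on the absolute scale; the defaults
#' (2.5 gain, 1.5 loss) are half a copy away from diploid. Missing copy
#' number stays missing. For a \code{\link{CNAExperiment}} the call matrix is
#' stored as assay \code{"cnaCall"} and the thresholds are recorded in the
#' object metadata.
#'
#' @param x numeric matrix of absolute copy number, or a
#'   \code{\link{CNAExperiment}}.
#' @param gainThreshold,lossThreshold absolute-copy-number thresholds;
#'   \code{lossThreshold < 2 < gainThreshold} is enforced.
#' @return A character matrix of calls, or the updated
#'   \code{CNAExperiment}.
#' @examples
#' callCNA(matrix(c(2.6, 2.0, 1.2), 1, 3,
#'                dimnames = list("g", c("a", "b", "c"))))
#' @rdname callCNA
#' @export
setMethod("callCNA", "matrix",
    function(x, gainThreshold = 2.5, lossThreshold = 1.5) {
        checkThresholds(gainThreshold, lossThreshold)
        calls <- matrix(NA_character_, nrow(x), ncol(x),
                        dimnames = dimnames(x))
        calls[!is.na(x)] <- "N"
        calls[!is.na(x) & x >= gainThreshold] <- "G"
        calls[!is.na(x) & x <= lossThreshold] <- "L"
        calls
    })

#' @rdname callCNA
#' @export
setMethod("callCNA", "CNAExperiment",
    function(x, gainThreshold = 2.5, lossThreshold = 1.5) {
        calls <- callCNA(cnValues(x), gainThreshold, lossThreshold)
        assay(x, "cnaCall") <- calls
        metadata(x)$callThresholds <- c(gain = gainThreshold,
                                        loss = lossThreshold)
        validObject(x)
        x
    })

checkThresholds <- function(gainThreshold, lossThreshold) {
    stopifnot(is.numeric(gainThreshold), is.numeric(lossThreshold))
    if (!(lossThreshold < 2 && 2 < gainThreshold))
        stop("thresholds must satisfy lossThreshold < 2 < gainThreshold ",
             "(absolute copy number, diploid = 2)")
    invisible(TRUE)
}
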