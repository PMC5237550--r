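#' Read gene annotation from a BED file
#'
#' Reads a BED file (chrom, start, end, name[, score, strand]) into a
#' \link[GenomicRanges]{GRanges} named by gene identifier. BED coordinates are
#' 0-based half-open; the returned ranges follow the usual 1-based closed
#' GRanges convention (the conversion is handled by
#' \code{\link[rtracklayer]{import}}), so a BED line \code{chr1 100 200 G}
#' becomes the range \code{chr1:101-200}. Strand is retained but ignored by
#' segment mapping: copy number is strand-agnostic.
#'
#' @param path path to a BED file with at least 4 columns.
#' @return \code{GRanges} with one range per gene, \code{names} set to the
#'   gene identifiers.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tGSTM1\t0\t+", bed)
#' readGeneAnnotation(bed)
#' @export
readGeneAnnotation <- function(path) {
    if (!file.exists(path))
        stop("annotation file not found: ", path)
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
    nf <- lengths(strsplit(lines[keep], "[ \t]+"))
    if (any(nf < 4L))
        stop("malformed BED line ", which(keep)[nf < 4L][1L],
             ": need at least 4 fields (chrom, start, end, name)")
    if (!any(keep))
        return(GRanges())
    gr <- rtracklayer::import(path, format = "BED")
    if (any(width(gr) < 1L))
        stop("BED record with start >= end for gene(s): ",
             paste(mcols(gr)$name[width(gr) < 1L], collapse = ", "))
    ids <- mcols(gr)$name
    if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
        stop("every BED record must carry a gene identifier in column 4")
    if (anyDuplicated(ids))
        stop("duplicate gene identifier(s) in annotation: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    names(gr) <- ids
    gr
}

segHeaderAliases <- list(
    sample = c("sample", "id", "sample_id", "sampleid"),
    chrom = c("chromosome", "chrom", "chr"),
    start = c("start", "loc.start", "start.pos"),
    end = c("end", "loc.end", "end.pos"),
    value = c("segment_mean", "seg.mean", "segmean", "value"))

#' Read copy-number segments
#'
#' Reads per-sample copy-number segments either from a SEG-style TSV (header
#' with Sample, Chromosome, Start, End, [Num_Probes,] Segment_Mean; 1-based
#' inclusive coordinates) or through a user-supplied \code{reader} function,
#' supporting arbitrary input formats. Segment values are kept on the
#' declared scale; conversion to absolute copy number happens when segments
#' are mapped onto genes (\code{\link{mapSegmentsToGenes}}).
#'
#' @param path path to the segment file.
#' @param scale scale of the segment values: \code{"absolute"} copy number or
#'   \code{"log2ratio"} (log2 of observed/expected copy ratio, the SEG
#'   convention).
#' @param reader optional custom reader: a function taking \code{path} and
#'   returning a data.frame with columns \code{sample}, \code{chrom},
#'   \code{start}, \code{end}, \code{value} (1-based inclusive coordinates).
#'   When supplied, it replaces the SEG dialect parser but all validation
#'   still applies.
#' @return \code{GRanges} with metadata columns \code{sample} and
#'   \code{value}, and the declared scale stored in
#'   \code{metadata(x)$scale}.
#' @examples
#' seg <- tempfile(fileext = ".seg")
#' writeLines(c("Sample\tChromosome\tStart\tEnd\tSegment_Mean",
#'              "S1\tchr1\t101\t200\t0.0"), seg)
#' readCnSegments(seg, scale = "log2ratio")
#' @export
readCnSegments <- function(path, scale = c("absolute", "log2ratio"),
                           reader = NULL) {
    scale <- match.arg(scale)
    if (!is.null(reader)) {
        stopifnot(is.function(reader))
        df <- reader(path)
        need <- c("sample", "chrom", "start", "end", "value")
        if (!all(need %in% names(df)))
            stop("custom reader must return columns: ",
                 paste(need, collapse = ", "))
        df <- df[, need]
    } else {
        if (!file.exists(path))
            stop("segment file not found: ", path)
        raw <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
        lower <- tolower(names(raw))
        idx <- vapply(segHeaderAliases, function(al) {
            m <- which(lower %in% al)
            if (length(m) == 0L) NA_integer_ else m[1L]
        }, integer(1))
        if (anyNA(idx))
            stop("not a SEG header (missing ",
                 paste(names(idx)[is.na(idx)], collapse = ", "),
                 "); columns found: ", paste(names(raw), collapse = ", "))
        df <- data.frame(sample = as.character(raw[[idx["sample"]]]),
                         chrom = as.character(raw[[idx["chrom"]]]),
                         start = raw[[idx["start"]]],
                         end = raw[[idx["end"]]],
                         value = raw[[idx["value"]]],
                         stringsAsFactors = FALSE)
    }
    for (col in c("start", "end", "value")) {
        v <- suppressWarnings(as.numeric(df[[col]]))
        if (anyNA(v))
            stop("missing or non-numeric '", col, "' value in segment file")
        df[[col]] <- v
    }
    if (any(df$start > df$end))
        stop("segment with Start > End at row ",
             which(df$start > df$end)[1L])
    if (any(!is.finite(df$value)))
        stop("non-finite segment value at row ",
             which(!is.finite(df$value))[1L])
    gr <- GRanges(df$chrom, IRanges(df$start, df$end),
                  sample = df$sample, value = df$value)
    metadata(gr)$scale <- scale
    gr
}

#' Read a normalized expression matrix
#'
#' Reads a TSV whose first column holds gene identifiers and whose header row
#' holds sample identifiers. Cells equal to \code{NA} (or empty) are treated
#' as missing and are excluded pairwise from all downstream group means and
#' tests; they are never imputed.
#'
#' @param path path to the expression TSV.
#' @return numeric matrix, genes x samples.
#' @export
readExpressionMatrix <- function(path) {
    if (!file.exists(path))
        stop("expression file not found: ", path)
    nf <- count.fields(path, sep = "\t", quote = "")
    if (length(unique(nf)) > 1L)
        stop("ragged expression table: line ",
             which(nf != nf[1L])[1L], " has ", nf[nf != nf[1L]][1L],
             " fields, expected ", nf[1L])
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                     check.names = FALSE)
    if (ncol(df) < 2L)
        stop("expression table needs a gene column plus >= 1 sample column")
    genes <- as.character(df[[1L]])
    if (anyDuplicated(genes))
        stop("duplicated gene row(s) in expression table: ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes
    m
}

resultColumns <- c("gene", "direction", "GE_mean_gain", "GE_mean_loss",
                   "GE_mean_neutral", "GE_mean_diff", "CNA_prop_gain",
                   "CNA_prop_loss", "t_statistic", "p_value", "fdr")

#' Write / read a result table
#'
#' \code{writeResultTable} serializes the result of \code{\link{runCnaDE}} as
#' a TSV with the fixed column set \code{gene, direction, GE_mean_gain,
#' GE_mean_loss, GE_mean_neutral, GE_mean_diff, CNA_prop_gain, CNA_prop_loss,
#' t_statistic, p_value, fdr}; empty-group means appear as the literal
#' \code{NA}. \code{readResultTable} reads such a file back.
#'
#' @param results a \code{DataFrame}/data.frame with at least the columns
#'   above (extra columns such as \code{df} are dropped on write).
#' @param path output (input) file path.
#' @return \code{writeResultTable} returns \code{path} invisibly;
#'   \code{readResultTable} returns a \code{DataFrame}.
#' @export
writeResultTable <- function(results, path) {
    results <- as.data.frame(results)
    missing <- setdiff(resultColumns, names(results))
    if (length(missing))
        stop("result table is missing column(s): ",
             paste(missing, collapse = ", "))
    out <- results[, resultColumns, drop = FALSE]
    status <- try(write.table(out, path, sep = "\t", quote = FALSE,
                              row.names = FALSE, na = "NA"), silent = TRUE)
    if (inherits(status, "try-error"))
        stop("cannot write result table to ", path)
    invisible(path)
}

#' @rdname writeResultTable
#' @export
readResultTable <- function(path) {
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    missing <- setdiff(resultColumns, names(df))
    if (length(missing))
        stop("not a result table (missing ",
             paste(missing, collapse = ", "), "): ", path)
    DataFrame(df)
}
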