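#' Write a toy end-to-end fixture set
#'
#' Emits a small, fully deterministic dataset exercising every reader and
#' the whole pipeline: a BED annotation (6 genes on 2 chromosomes), SEG
#' segment tables on both value scales (absolute copy number and log2
#' ratio), an expression TSV, and a README describing the planted truth:
#'
#' \itemize{
#'   \item \code{GAIN1} is gained (CN 3.3) in 8/20 samples whose expression
#'     is shifted up by 3 -- the planted CNA-driven gene, expected to be the
#'     top hit by FDR;
#'   \item \code{LOSS1} is lost (CN 1.2) in 5/20 samples with a moderate
#'     expression drop -- a weaker, second hit;
#'   \item \code{ALLG1} is gained in all samples: no control group exists,
#'     so it must yield no test row;
#'   \item \code{SPLIT1} is covered by two overlapping segments per sample
#'     (largest overlap wins); \code{FLAT1}/\code{FLAT2} are neutral, and
#'     \code{FLAT2} has no segment in sample S20 (a missing cell).
#' }
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed for the expression noise; a fixed seed
#'   reproduces the files byte for byte.
#' @return named character vector of the written file paths, invisibly.
#' @examples
#' paths <- makeFixtures(tempfile("fx"), seed = 7)
#' basename(paths)
#' @export
makeFixtures <- function(outDir, seed = 7L) {
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create fixture directory ", outDir)
    set.seed(as.integer(seed))
    samples <- sprintf("S%02d", 1:20)
    gainCarriers <- samples[1:8]
    lossCarriers <- samples[9:13]

    bed <- c("chr1\t999\t2000\tGAIN1\t0\t+",
             "chr1\t4999\t6000\tALLG1\t0\t-",
             "chr1\t8999\t10000\tFLAT1\t0\t+",
             "chr2\t999\t2000\tFLAT2\t0\t+",
             "chr2\t8999\t11000\tSPLIT1\t0\t-",
             "chr2\t14999\t16000\tLOSS1\t0\t+")
    bedPath <- file.path(outDir, "genes.bed")
    writeLines(bed, bedPath)

    segRow <- function(s, chrom, start, end, cn)
        data.frame(Sample = s, Chromosome = chrom, Start = start, End = end,
                   Segment_Mean = cn)
    segs <- do.call(rbind, lapply(samples, function(s) rbind(
        segRow(s, "chr1", 900, 2100,
               if (s %in% gainCarriers) 3.3 else 2.0),
        segRow(s, "chr1", 4900, 6100, 3.4),
        segRow(s, "chr1", 8900, 10100, 2.0),
        if (s != "S20") segRow(s, "chr2", 900, 2100, 2.0),
        segRow(s, "chr2", 8000, 9800, 2.1),
        segRow(s, "chr2", 9801, 12000, 2.0),
        segRow(s, "chr2", 14900, 16100,
               if (s %in% lossCarriers) 1.2 else 2.0))))
    segs <- rbind(segs, segRow("S01", "chr2", 30000, 31000, 2.0))
    absPath <- file.path(outDir, "segments_absolute.seg")
    write.table(segs, absPath, sep = "\t", quote = FALSE, row.names = FALSE)
    logSegs <- segs
    logSegs$Segment_Mean <- round(log2(segs$Segment_Mean / 2), 6)
    logPath <- file.path(outDir, "segments_log2ratio.seg")
    write.table(logSegs, logPath, sep = "\t", quote = FALSE,
                row.names = FALSE)

    genes <- c("GAIN1", "ALLG1", "FLAT1", "FLAT2", "SPLIT1", "LOSS1")
    expr <- matrix(round(rnorm(length(genes) * length(samples), 5, 0.5), 4),
                   nrow = length(genes),
                   dimnames = list(genes, samples))
    expr["GAIN1", gainCarriers] <- expr["GAIN1", gainCarriers] + 3
    expr["LOSS1", lossCarriers] <- expr["LOSS1", lossCarriers] - 1.2
    expr["ALLG1", ] <- expr["ALLG1", ] + 1
    exprPath <- file.path(outDir, "expression.tsv")
    write.table(data.frame(gene = rownames(expr), expr,
                           check.names = FALSE),
                exprPath, sep = "\t", quote = FALSE, row.names = FALSE)

    readmePath <- file.path(outDir, "README.txt")
    writeLines(c(
        "Toy fixture set (deterministic; regenerate with makeFixtures()).",
        "",
        "Planted truth:",
        "  GAIN1  gained (CN 3.3) in S01-S08 (8/20 = 40%); expression +3",
        "         in carriers -> expected top hit by FDR, direction gain.",
        "  LOSS1  lost (CN 1.2) in S09-S13 (5/20 = 25%); expression -1.2",
        "         in carriers -> weaker hit, direction loss.",
        "  ALLG1  gained (CN 3.4) in 20/20 samples -> untestable (no",
        "         control group), must be absent from results.",
        "  SPLIT1 covered by two segments (2.1 over 800 bp, 2.0 over",
        "         1200 bp); largest overlap wins -> CN 2.0, neutral.",
        "  FLAT1/FLAT2 neutral; FLAT2 has no segment in S20 (missing).",
        "",
        "segments_absolute.seg carries absolute copy numbers;",
        "segments_log2ratio.seg the same segments as log2(CN/2)."),
        readmePath)

    invisible(c(genes = bedPath, segAbsolute = absPath, segLog2 = logPath,
                expression = exprPath, readme = readmePath))
}
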