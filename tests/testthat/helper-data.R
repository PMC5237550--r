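## Small in-code builders shared across test files.

writeTempLines <- function(lines, ext = ".txt") {
    path <- tempfile(fileext = ext)
    writeLines(lines, path)
    path
}

## genes x samples matrix pair with a planted gain-driven gene: 'hit' is
## gained (CN 3.2, expression +shift) in the first nGain of nSamples.
plantedMatrices <- function(nSamples = 20L, nGain = 8L, shift = 3,
                            seed = 42L) {
    set.seed(seed)
    genes <- c("hit", "flat", "noisy")
    samples <- sprintf("s%02d", seq_len(nSamples))
    ge <- matrix(rnorm(3 * nSamples, 5, 0.5), 3, nSamples,
                 dimnames = list(genes, samples))
    cn <- matrix(2, 3, nSamples, dimnames = list(genes, samples))
    cn["hit", seq_len(nGain)] <- 3.2
    ge["hit", seq_len(nGain)] <- ge["hit", seq_len(nGain)] + shift
    list(ge = ge, cn = cn)
}

## independent oracle for BH step-up: for each p_i the minimum over
## candidate thresholds t >= p_i of m * t / #{p <= t}, capped at 1
bhOracle <- function(p) {
    m <- length(p)
    vapply(p, function(pi) {
        cand <- p[p >= pi]
        min(1, min(m * cand / vapply(cand, function(t) sum(p <= t),
                                     numeric(1))))
    }, numeric(1))
}

## independent oracle for segment->gene assignment: scan every
## (gene, segment) pair on closed 1-based intervals and apply the
## largest-overlap / most-extreme / leftmost tie-break by explicit ranking
mapOracle <- function(segDf, geneDf, samples) {
    cn <- matrix(NA_real_, nrow(geneDf), length(samples),
                 dimnames = list(geneDf$gene, samples))
    for (gi in seq_len(nrow(geneDf))) {
        for (s in samples) {
            rows <- segDf[segDf$sample == s &
                          segDf$chrom == geneDf$chrom[gi], , drop = FALSE]
            if (nrow(rows) == 0L) next
            ov <- pmax(0, pmin(rows$end, geneDf$end[gi]) -
                          pmax(rows$start, geneDf$start[gi]) + 1)
            rows <- rows[ov > 0, , drop = FALSE]
            ov <- ov[ov > 0]
            if (length(ov) == 0L) next
            rank <- order(-ov, -abs(rows$cn - 2), rows$start)
            cn[geneDf$gene[gi], s] <- rows$cn[rank[1L]]
        }
    }
    cn
}

## all permutations of 1..n, one per column
combinat_perms <- function(n) {
    if (n == 1L) return(matrix(1L))
    sub <- combinat_perms(n - 1L)
    do.call(cbind, lapply(seq_len(n), function(i) {
        rest <- setdiff(seq_len(n), i)
        rbind(i, matrix(rest[sub], nrow = n - 1L))
    }))
}

reportedRowsPath <- function(which = c("brca", "luad")) {
    which <- match.arg(which)
    system.file("extdata", paste0(which, "_reported_genes.tsv"),
                package = "cnadrive")
}
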