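Package: cnadrive
Title: Identification of Copy-Number-Driven Differentially Expressed Genes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates paired copy-number and gene-expression profiles from
    the same individuals to identify genes whose expression changes are driven
    by copy number alterations (CNAs). For each gene, samples are partitioned
    into CNA-gain, CNA-loss and neutral groups from segmented copy-number
    calls mapped onto gene annotation; genes altered in a minimum fraction of
    samples are tested for differential expression between the altered group
    and its complement with Welch's unequal-variance t-test, with
    Benjamini-Hochberg false discovery rate control across all tests. The
    package also ships a simulation benchmark that generates coupled
    copy-number/expression data under controlled Pearson-correlation
    conditions and scores detection sensitivity and specificity, per-gene
    expression/copy-number correlation utilities, and readers and writers for
    BED gene annotation, SEG segment and expression/result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: CopyNumberVariation, DifferentialExpression, GeneExpression,
    Transcriptomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'cnadrive-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'io.R'
    'cna-calling.R'
    'de-test.R'
    'correlation.R'
    'simulation.R'
    'benchmark.R'
    'fixtures.R'
    'cli.R'
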