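test_that("scenario validation enforces the study design", {
    expect_error(simScenario(nGenes = 10), "multiple of 4")
    expect_error(simScenario(cnaFrequency = 0), "cnaFrequency")
    expect_error(simScenario(cnaFrequency = 1.2), "cnaFrequency")
    expect_error(simScenario(dispersion = -1), "dispersion")
    sc <- simScenario()
    expect_s4_class(sc, "SimScenario")
    expect_output(show(sc), "100 genes x 50 samples")
})

test_that("simulated datasets are a pure function of (scenario, seed)", {
    for (coupling in c("correlation", "shuffle")) {
        sc <- simScenario(nGenes = 20, nSamples = 30, coupling = coupling)
        a <- simulateScenario(sc, seed = 77)
        b <- simulateScenario(sc, seed = 77)
        expect_identical(a$cn, b$cn)
        expect_identical(a$ge, b$ge)
        expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
        c2 <- simulateScenario(sc, seed = 78)
        expect_false(identical(a$cn, c2$cn))
    }
})

test_that("truth tables have equal-sized conditions and correct TP flags", {
    sim <- simulateScenario(simScenario(nGenes = 100, nSamples = 50),
                            seed = 5)
    expect_equal(as.vector(table(sim$truth$condition)[
        c("r0", "r0-0.3", "r0.3-0.7", "r0.7-1")]), rep(25L, 4))
    expect_equal(sim$truth$isTruePositive,
                 sim$truth$condition == "r0.7-1")
    expect_true(all(sim$truth$rho[sim$truth$condition == "r0"] == 0))
    expect_true(all(sim$truth$rho[sim$truth$condition == "r0.7-1"] >= 0.7))
    expect_equal(dim(sim$cn), c(100L, 50L))
    expect_equal(dimnames(sim$cn), dimnames(sim$ge))
    expect_true(all(sim$cn >= 0))
})

test_that("the carrier fraction matches the CNA frequency binomially", {
    sc <- simScenario(nGenes = 100, nSamples = 200)
    sim <- simulateScenario(sc, seed = 9)
    ## carriers are the high-CN component; 2.5 splits the two modes
    frac <- mean(sim$cn >= 2.5)
    n <- length(sim$cn)
    ## 2.5 misclassifies ~13% of each component symmetrically around 0.30;
    ## expected called fraction = 0.3*0.868 + 0.7*0.132
    expected <- 0.3 * (1 - pnorm(2.5, 3, sqrt(0.2))) +
        0.7 * (1 - pnorm(2.5, 2, sqrt(0.2)))
    se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(frac - expected), 3 * se + 1e-3)
})

test_that("detection scoring counts hits against the truth table", {
    truth <- S4Vectors::DataFrame(
        gene = paste0("g", 1:16),
        condition = rep(c("r0", "r0-0.3", "r0.3-0.7", "r0.7-1"), each = 4),
        rho = 0, isTruePositive = rep(c(FALSE, TRUE), c(12, 4)))
    res <- S4Vectors::DataFrame(
        gene = c("g13", "g14", "g15", "g16", "g1", "g2"),
        p_value = c(0.001, 0.004, 0.8, NA, 0.01, 0.9),
        fdr = c(0.01, 0.02, 0.9, NA, 0.06, 0.95))
    m <- evaluateDetection(res, truth, alpha = 0.05)
    expect_equal(unname(m["sensitivity"]), 2 / 4)
    expect_equal(unname(m["specificity"]), 11 / 12)
    mf <- evaluateDetection(res, truth, alpha = 0.05, useFdr = TRUE)
    expect_equal(unname(mf["sensitivity"]), 0.5)
    expect_equal(unname(mf["specificity"]), 1)
    none <- evaluateDetection(res[0, ], truth)
    expect_equal(unname(none), c(0, 1))
    all4 <- evaluateDetection(
        S4Vectors::DataFrame(gene = paste0("g", 13:16),
                             p_value = rep(1e-6, 4),
                             fdr = rep(1e-5, 4)), truth)
    expect_equal(unname(all4), c(1, 1))
})

test_that("p-value summaries by condition behave under the null", {
    set.seed(31)
    truth <- S4Vectors::DataFrame(
        gene = paste0("g", 1:400),
        condition = rep(c("r0", "r0-0.3", "r0.3-0.7", "r0.7-1"),
                        each = 100))
    res <- S4Vectors::DataFrame(gene = truth$gene, p_value = runif(400))
    pq <- pvalueByCondition(res, truth)
    expect_equal(pq$condition, c("r0", "r0-0.3", "r0.3-0.7", "r0.7-1"))
    expect_true(all(abs(pq$median - 0.5) < 0.15))
    ## a condition whose genes were all filtered out is reported NA
    pq2 <- pvalueByCondition(res[1:100, ], truth)
    expect_true(is.na(pq2$median[pq2$condition == "r0.7-1"]))
    expect_equal(pq2$nTests[pq2$condition == "r0"], 100L)
})

test_that("shuffle rejection gives up with a named error when impossible", {
    sc <- simScenario(nGenes = 4, nSamples = 100, dispersion = 25,
                      coupling = "shuffle", rejectionCap = 20)
    expect_error(simulateScenario(sc, seed = 2), "gene00.*20 tries")
})

test_that("the benchmark is deterministic and aggregates correctly", {
    sc <- simScenario(nGenes = 16, nSamples = 30)
    b1 <- runBenchmark(sc, nReps = 4, seed = 123)
    b2 <- runBenchmark(sc, nReps = 4, seed = 123)
    expect_identical(b1$summary, b2$summary)
    expect_identical(b1$replicates, b2$replicates)
    expect_equal(nrow(b1$replicates), 4L)
    expect_equal(b1$summary$sensitivityMean,
                 mean(b1$replicates$sensitivity))
    single <- runBenchmark(sc, nReps = 1, seed = 5)
    expect_equal(single$summary$sensitivitySd, 0)
    expect_equal(single$summary$specificitySd, 0)
    path <- tempfile(fileext = ".tsv")
    writeBenchmarkTable(b1, path)
    back <- read.delim(path)
    expect_equal(back$specificityMean, b1$summary$specificityMean)
})

test_that("vanishing dispersion drives shuffle-coupled sensitivity to 1", {
    ## n large enough that the 20% proportion filter essentially never
    ## removes a 30%-frequency CNA gene by binomial chance
    sc <- simScenario(nGenes = 16, nSamples = 200, dispersion = 1e-6,
                      coupling = "shuffle")
    b <- runBenchmark(sc, nReps = 5, seed = 11)
    expect_equal(b$summary$sensitivityMean, 1)
})
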