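test_that("Welch statistic matches the closed form and its symmetries", {
    res <- welchTest(c(1, 2, 3), c(4, 5, 6))
    expect_equal(res$t, -3.6742346142, tolerance = 1e-9)
    expect_equal(res$df, 4, tolerance = 1e-9)
    expect_equal(res$p, 0.0213116411, tolerance = 1e-8)
    x <- c(0.3, 1.7, 2.2, -0.4)
    same <- welchTest(x, x)
    expect_equal(same$t, 0)
    expect_equal(same$p, 1)
    ab <- welchTest(x, x + 1.5)
    ba <- welchTest(x + 1.5, x)
    expect_equal(ab$t, -ba$t)
    expect_equal(ab$p, ba$p)
})

test_that("Welch degenerate inputs follow the documented rules", {
    expect_true(is.na(welchTest(1, c(2, 3, 4))$p))
    expect_true(is.na(welchTest(numeric(0), c(2, 3))$p))
    expect_equal(welchTest(c(2, 2, 2), c(2, 2))$p, 1)
    zv <- welchTest(c(2, 2, 2), c(5, 5))
    expect_equal(zv$p, 0)
    expect_equal(zv$t, -Inf)
    expect_true(is.na(welchTest(c(1, NA), c(2, 3))$p))
})

test_that("Welch agrees with the reference implementation to 1e-10", {
    set.seed(99)
    for (i in 1:200) {
        x <- rnorm(sample(3:30, 1), sd = runif(1, 0.2, 3))
        y <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2),
                   sd = runif(1, 0.2, 3))
        ref <- t.test(x, y, var.equal = FALSE)
        got <- welchTest(x, y)
        expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
        expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
        expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    }
})

test_that("BH adjustment equals brute-force step-up on all permutations", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.037), 0.037)
    sets <- list(c(0.001, 0.01, 0.02, 0.5, 0.8, 1),
                 c(0.04, 0.04, 0.2, 0.25, 0.9),
                 c(0.3, 0.31, 0.32, 0.9))
    for (p in sets) {
        perms <- combinat_perms(length(p))
        for (k in seq_len(ncol(perms))) {
            pp <- p[perms[, k]]
            expect_equal(bhAdjust(pp), bhOracle(pp))
        }
    }
    set.seed(5)
    for (i in 1:25) {
        p <- runif(sample(1:6, 1))
        expect_equal(bhAdjust(p), bhOracle(p))
        expect_true(all(bhAdjust(p) >= p))
    }
    expect_equal(bhAdjust(c(0.2, NA, 0.01)), c(0.2, NA, 0.02))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("CNA proportions count over non-missing samples only", {
    calls <- matrix("N", 3, 10,
                    dimnames = list(c("a", "b", "c"), paste0("s", 1:10)))
    calls["a", 1:3] <- "G"
    calls["a", 9:10] <- NA
    calls["c", ] <- NA
    pr <- cnaProportions(calls)
    expect_equal(pr$propGain[pr$gene == "a"], 3 / 8)
    expect_equal(pr$nCalled[pr$gene == "a"], 8)
    expect_equal(pr$propGain[pr$gene == "b"], 0)
    expect_equal(pr$propLoss[pr$gene == "b"], 0)
    expect_true(is.na(pr$propGain[pr$gene == "c"]))
    big <- matrix(c(rep("G", 31), rep("N", 69)), 1, 100,
                  dimnames = list("g", paste0("s", 1:100)))
    expect_equal(cnaProportions(big)$propGain, 0.31)
})

test_that("the 20% filter is inclusive and direction-aware", {
    pr <- S4Vectors::DataFrame(gene = c("a", "b", "c", "d"),
                               propGain = c(0.20, 0.19, 0.31, 0.05),
                               propLoss = c(0.0, 0.0, 0.41, 0.10))
    sel <- selectTestable(pr, minProp = 0.2)
    expect_equal(sel$gene[sel$direction == "gain"], c("a", "c"))
    expect_equal(sel$gene[sel$direction == "loss"], "c")
    expect_false("b" %in% sel$gene)
    expect_false("d" %in% sel$gene)
})

test_that("pooled-complement mean difference matches reported rows", {
    for (cohort in c("brca", "luad")) {
        tab <- read.delim(reportedRowsPath(cohort))
        got <- reconstructGroupDiff(tab$GE_mean_gain, tab$GE_mean_loss,
                                    tab$GE_mean_neutral, tab$CNA_prop_gain,
                                    tab$CNA_prop_loss, tab$direction)
        expect_equal(got, tab$GE_mean_diff, tolerance = 0.002)
    }
})

test_that("runCnaDE recovers a planted CNA-driven gene", {
    d <- plantedMatrices()
    res <- runCnaDE(d$ge, callCNA(d$cn))
    expect_equal(nrow(res), 1L)
    expect_equal(res$gene, "hit")
    expect_equal(res$direction, "gain")
    expect_lt(res$p_value, 0.01)
    expect_equal(res$CNA_prop_gain, 0.4)
    ## direct Welch cross-check on the same split
    ref <- welchTest(d$ge["hit", 1:8], d$ge["hit", 9:20])
    expect_equal(res$t_statistic, ref$t)
    expect_equal(res$p_value, ref$p)
    expect_equal(res$GE_mean_diff,
                 mean(d$ge["hit", 1:8]) - mean(d$ge["hit", 9:20]))
})

test_that("genes below the proportion filter or without controls drop out", {
    d <- plantedMatrices()
    d$cn["noisy", 1:2] <- 3.2   # 10% gain
    d$cn["noisy", 3:4] <- 1.2   # 10% loss
    d$cn["flat", ] <- 3.5       # CNA in 100% of samples: no control group
    res <- runCnaDE(d$ge, callCNA(d$cn))
    expect_false("noisy" %in% res$gene)
    expect_false("flat" %in% res$gene)
})

test_that("both directions are reported when both proportions pass", {
    set.seed(7)
    ge <- matrix(rnorm(40, 5), 1, 40,
                 dimnames = list("dual", paste0("s", 1:40)))
    cn <- matrix(2, 1, 40, dimnames = dimnames(ge))
    cn[1, 1:12] <- 3.1
    cn[1, 13:28] <- 1.3
    res <- runCnaDE(ge, callCNA(cn))
    expect_setequal(res$direction, c("gain", "loss"))
    expect_equal(res$CNA_prop_gain, rep(0.3, 2))
    expect_equal(res$CNA_prop_loss, rep(0.4, 2))
})

test_that("results are FDR-ordered and p <= fdr always holds", {
    set.seed(21)
    n <- 30
    ge <- matrix(rnorm(8 * n, 5), 8, n,
                 dimnames = list(paste0("g", 1:8), paste0("s", 1:n)))
    cn <- matrix(2, 8, n, dimnames = dimnames(ge))
    for (i in 1:8) cn[i, sample(n, 10)] <- 3.2
    ge[1, cn[1, ] > 3] <- ge[1, cn[1, ] > 3] + 4
    res <- runCnaDE(ge, callCNA(cn))
    expect_equal(res$gene[1], "g1")
    expect_false(is.unsorted(res$fdr))
    expect_true(all(res$fdr >= res$p_value))
    expect_equal(res$fdr, bhAdjust(res$p_value), tolerance = 1e-12)
})

test_that("runCnaDE is invariant to row and column order", {
    d <- plantedMatrices(nSamples = 24, nGain = 9)
    res <- runCnaDE(d$ge, callCNA(d$cn))
    perm <- runCnaDE(d$ge[c(3, 1, 2), sample(24)],
                     callCNA(d$cn)[c(2, 3, 1), sample(24)])
    expect_equal(as.data.frame(res), as.data.frame(perm))
})

test_that("missing expression is excluded pairwise and small groups go NA", {
    d <- plantedMatrices()
    d$ge["hit", 1:7] <- NA    # one finite value left in the gain group
    res <- runCnaDE(d$ge, callCNA(d$cn))
    expect_true(is.na(res$p_value[res$gene == "hit"]))
    expect_equal(nrow(runCnaDE(d$ge, callCNA(d$cn), dropNA = TRUE)), 0L)
    ## NA cells change nothing else: complement mean uses remaining values
    expect_equal(res$GE_mean_gain[res$gene == "hit"],
                 d$ge["hit", 8])
})

test_that("shared-sample contract is enforced", {
    d <- plantedMatrices()
    ge2 <- d$ge
    colnames(ge2) <- paste0("other", seq_len(ncol(ge2)))
    expect_error(runCnaDE(ge2, callCNA(d$cn)), "no samples in common")
})

test_that("baseline subtraction centers per gene and drops the baseline", {
    expr <- matrix(c(5, 2, 1, 7, 3, 3), 2, 3,
                   dimnames = list(c("g1", "g2"), c("t1", "t2", "n1")))
    out <- subtractBaseline(expr, "n1")
    expect_equal(colnames(out), c("t1", "t2"))
    expect_equal(out["g1", ], c(t1 = 2, t2 = -2))
    expect_equal(out["g2", ], c(t1 = -1, t2 = 4))
    zero <- matrix(0, 2, 1, dimnames = list(c("g1", "g2"), "n1"))
    expect_equal(subtractBaseline(cbind(expr[, 1:2], zero), "n1"),
                 expr[, 1:2])
    expect_error(subtractBaseline(expr, c("t1", "t2", "n1")),
                 "all samples")
    expect_error(subtractBaseline(expr, "nope"), "absent")
})
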