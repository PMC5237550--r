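## The full-scale benchmark (8 scenarios x 200 replicates) is computed once
## per test run and shared by the acceptance blocks that need it.
acceptanceBenchmark <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- runBenchmark(defaultScenarios(), nReps = 200,
                                   seed = 20240601, alpha = 0.05,
                                   collectPvalues = TRUE)
        cache
    }
})

benchRow <- function(bench, scenario)
    bench$summary[bench$summary$scenario == scenario, ]
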