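# Shared fixtures: all test inputs are generated in code, deterministically.

# a small random image in [0,1] under a fixed seed
randomImage <- function(n = 16, seed = 1, bg = 0.5) {
    set.seed(seed)
    stimulusImage(matrix(runif(n * n), n, n), backgroundLevel = bg)
}

# reference kernel small enough for the direct spatial path
smallKernel <- function(sigmaF = 1.5, K = 5) {
    dogKernel(rfProfile(0, sigmaPx = sigmaF, K = K))
}

# run each shipped experiment at most once per test session
.runCache <- new.env(parent = emptyenv())
cachedRun <- function(id) {
    if (is.null(.runCache[[id]]))
        .runCache[[id]] <- runExperiment(experimentConfig(id))
    .runCache[[id]]
}
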