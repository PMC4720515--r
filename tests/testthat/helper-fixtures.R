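# fixtures are built in code; nothing is read from disk except files the
# tests themselves write into tempdir()

tinyCounts <- function() {
    matrix(c(10, 30, 60,
             20, 20, 160), nrow = 3,
           dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
}

randomCountsMatrix <- function(nGenes, nSamples, seed = 1, lambda = 50) {
    set.seed(seed)
    matrix(rpois(nGenes * nSamples, lambda), nGenes, nSamples,
           dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                           sprintf("s%02d", seq_len(nSamples))))
}

# a cpm ExpressionMatrix with given columns (each rescaled to sum 1e6)
cpmMatrix <- function(values, ages, treatment = NULL) {
    values <- sweep(values, 2, colSums(values), "/") * 1e6
    ann <- data.frame(sample_id = colnames(values), age = ages,
                      age_unit = "days",
                      treatment = if (is.null(treatment)) "water" else treatment,
                      replicate = seq_len(ncol(values)))
    ExpressionMatrix(values, unit = "cpm", annotations = ann)
}

# build a DriftMatrix directly from a td matrix (for rule-level tests of
# the attenuation classifier etc.)
makeDriftMatrix <- function(td, ages, treatment = "water") {
    ref <- new("YoungReference",
               refExpression = setNames(rep(100, nrow(td)), rownames(td)),
               method = "holdout", refAge = 0,
               sourceSamples = character(0), holdoutExcluded = TRUE,
               minSourceExpression = setNames(rep(100, nrow(td)),
                                              rownames(td)))
    cd <- S4Vectors::DataFrame(
        age = ages, treatment = rep(treatment, length.out = ncol(td)),
        selfReferential = rep(FALSE, ncol(td)), row.names = colnames(td))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(td = td), colData = cd,
        metadata = list(logBase = 2, pseudocount = 0.5, reference = ref))
    new("DriftMatrix", se)
}

# small synthetic bundle reused across drift/stats tests
smallSim <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            sim <- generateTranscriptome(syntheticConfig(nGenes = 400,
                                                         seed = 11))
            cpm <- cpmNormalize(sim$expression)
            ref <- buildYoungReference(cpm, 1)
            cache <<- list(sim = sim, cpm = cpm, ref = ref,
                           drift = computeDrift(cpm, ref))
        }
        cache
    }
})
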