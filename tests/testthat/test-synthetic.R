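test_that("generator is deterministic by seed and validates its config", {
    cfg <- syntheticConfig(nGenes = 100, seed = 5)
    a <- generateTranscriptome(cfg)
    b <- generateTranscriptome(cfg)
    expect_identical(exprsValues(a$expression), exprsValues(b$expression))
    expect_identical(a$truth$rate, b$truth$rate)
    c2 <- generateTranscriptome(syntheticConfig(nGenes = 100, seed = 6))
    expect_false(identical(exprsValues(a$expression),
                           exprsValues(c2$expression)))

    expect_error(syntheticConfig(attenuation = 1.5), "\\[0, 1\\]")
    expect_error(syntheticConfig(ages = c(3, 1)), "sorted")
    expect_error(syntheticConfig(refAge = 99), "one of the ages")
})

test_that("full attenuation freezes the treated arm at the young state", {
    cfg <- syntheticConfig(nGenes = 300, attenuation = 1, noiseSd = 0,
                           nbDispersion = 0, seed = 8)
    sim <- generateTranscriptome(cfg)
    cpm <- cpmNormalize(sim$expression)
    d <- computeDrift(cpm, buildYoungReference(cpm, 1))
    dv <- driftVariance(d, c("age", "treatment"))
    treated <- dv[grepl("treated", dv$group), ]
    water10 <- dv$variance[dv$group == "10_water"]
    expect_true(all(treated$variance < 0.05 * water10))
    exp10 <- sim$truth$expected_dv
    expect_true(all(exp10$expected_dv[exp10$treatment == "treated"] == 0))
})

test_that("noise-free drift-variance matches the closed-form truth within 2%", {
    # noise-free limit: Poisson counts at very deep libraries, so count
    # sampling noise and pseudocount shrinkage are both negligible
    cfg <- syntheticConfig(nGenes = 5000, noiseSd = 0, nbDispersion = 0,
                           ageExponent = 1, libSizeMeanLog = log(2.5e9),
                           seed = 13)
    sim <- generateTranscriptome(cfg)
    cpm <- cpmNormalize(sim$expression)
    d <- computeDrift(cpm, buildYoungReference(cpm, 1), pseudocount = 0.01)
    dv <- driftVariance(d, c("age", "treatment"))
    truth <- sim$truth$expected_dv
    for (grp in c("10_water", "10_treated", "5_water")) {
        age <- as.numeric(sub("_.*", "", grp))
        trt <- sub(".*_", "", grp)
        expected <- truth$expected_dv[truth$age == age &
                                      truth$treatment == trt]
        got <- dv$variance[dv$group == grp]
        expect_lt(abs(got - expected) / expected, 0.02)
    }
})

test_that("drift-variance grows monotonically with age in expectation", {
    dvs <- sapply(1:20, function(i) {
        sim <- generateTranscriptome(syntheticConfig(nGenes = 250,
                                                     seed = 1000 + i))
        cpm <- cpmNormalize(sim$expression)
        d <- computeDrift(cpm, buildYoungReference(cpm, 1))
        dv <- driftVariance(d, c("age", "treatment"))
        dv$variance[match(c("3_water", "5_water", "10_water"), dv$group)]
    })
    means <- rowMeans(dvs)
    expect_true(all(diff(means) > 0))
})

test_that("disjoint gene subsamples share one drift-variance trajectory", {
    sim <- generateTranscriptome(syntheticConfig(nGenes = 5000, seed = 23))
    cpm <- cpmNormalize(sim$expression)
    d <- computeDrift(cpm, buildYoungReference(cpm, 1))
    sets <- subsampleGenes(rownames(d), nSets = 5, setSize = 900, seed = 3)
    traj <- sapply(sets, function(s) {
        dv <- driftVariance(d, c("age", "treatment"), geneSet = s)
        dv$variance[match(c("3_water", "5_water", "10_water"), dv$group)]
    })
    ratio <- apply(traj, 1, function(v) max(v) / min(v))
    expect_true(all(ratio < 1.35))
})

test_that("designed gene sets contrast coherent vs opposing drift", {
    sim <- generateTranscriptome(syntheticConfig(nGenes = 2000, seed = 29))
    sets <- generateGeneSets(sim$truth, nSets = 3, setSize = 300, seed = 4)
    expect_true(all(c("coherent", "opposing") %in% names(sets)))
    expect_true(all(unlist(lapply(sets, geneIds)) %in% sim$truth$gene_ids))
    expect_length(geneIds(sets$opposing), 300)
    dir <- sim$truth$direction
    expect_true(all(dir[geneIds(sets$coherent)] == 1))
    expect_equal(sum(dir[geneIds(sets$opposing)] == 1), 150)

    cpm <- cpmNormalize(sim$expression)
    d <- computeDrift(cpm, buildYoungReference(cpm, 1))
    for (grp in c("3_water", "5_water", "10_water")) {
        dvC <- driftVariance(d, c("age", "treatment"), geneSet = sets$coherent)
        dvO <- driftVariance(d, c("age", "treatment"), geneSet = sets$opposing)
        expect_gt(dvO$variance[dvO$group == grp],
                  dvC$variance[dvC$group == grp])
    }
    # random sets track the transcriptome-wide variance
    dvAll <- driftVariance(d, c("age", "treatment"))
    v10 <- dvAll$variance[dvAll$group == "10_water"]
    dvR <- driftVariance(d, c("age", "treatment"),
                         geneSet = sets$subsample_01)
    expect_lt(abs(dvR$variance[dvR$group == "10_water"] - v10) / v10, 0.25)
})

test_that("attenuation factor is recovered through the full pipeline", {
    # transparent measurement (Poisson, deep libraries) so the td-level
    # oracle below is the generator's true expectation
    cfg <- syntheticConfig(nGenes = 2000, attenuation = 0.8,
                           nbDispersion = 0, libSizeMeanLog = log(2.5e9),
                           seed = 37)
    sim <- generateTranscriptome(cfg)
    cpm <- cpmNormalize(sim$expression)
    d <- computeDrift(cpm, buildYoungReference(cpm, 1), pseudocount = 0.05)
    cd <- SummarizedExperiment::colData(d)
    res <- classifyAttenuation(d[, cd$treatment == "water"],
                               d[, cd$treatment == "treated"])
    # independent oracle: expected attenuated fraction from the td-level
    # model itself (rates/noise known, no counts involved)
    set.seed(1)
    ages <- c(3, 5, 10); nrep <- cfg$nReplicates
    r <- sim$truth$rate
    simFrac <- mean(vapply(seq_along(r), function(g) {
        # shared per-gene reference error from pooling 3 noisy replicates
        ref <- rnorm(1, 0, cfg$noiseSd / sqrt(nrep))
        mc <- sapply(ages, function(t) mean(abs(
            r[g] * (t - 1) + rnorm(nrep, 0, cfg$noiseSd) - ref)))
        mt <- sapply(ages, function(t) mean(abs(
            0.2 * r[g] * (t - 1) + rnorm(nrep, 0, cfg$noiseSd) - ref)))
        mean(mt) < mean(mc)
    }, logical(1)))
    half <- 1.96 * sqrt(simFrac * (1 - simFrac) / res$n)
    expect_gt(res$k / res$n, simFrac - half - 0.03)
    expect_lt(res$k / res$n, simFrac + half + 0.03)
    expect_lt(res$p.value, 1e-20)

    # a = 0: no systematic difference, calls hover at the coin-flip rate
    cfg0 <- syntheticConfig(nGenes = 2000, attenuation = 0, seed = 38)
    sim0 <- generateTranscriptome(cfg0)
    cpm0 <- cpmNormalize(sim0$expression)
    d0 <- computeDrift(cpm0, buildYoungReference(cpm0, 1))
    cd0 <- SummarizedExperiment::colData(d0)
    res0 <- classifyAttenuation(d0[, cd0$treatment == "water"],
                                d0[, cd0$treatment == "treated"])
    expect_lt(abs(res0$k / res0$n - 0.5), 0.04)
})

test_that("treated-arm dispersion difference is detected with high power", {
    sim <- generateTranscriptome(syntheticConfig(nGenes = 5000, seed = 41))
    cpm <- cpmNormalize(sim$expression)
    d <- computeDrift(cpm, buildYoungReference(cpm, 1))
    vals <- driftValues(d, c("age", "treatment"))
    lev <- robustLevene(vals[c("10_water", "10_treated")])
    expect_lt(lev$p.value, 1e-12)
})

test_that("stronger attenuation strictly lowers day-5 treated drift-variance", {
    day5 <- sapply(c(0, 0.3, 0.6, 0.9), function(a) {
        sim <- generateTranscriptome(
            syntheticConfig(nGenes = 800, attenuation = a, seed = 47))
        cpm <- cpmNormalize(sim$expression)
        d <- computeDrift(cpm, buildYoungReference(cpm, 1))
        dv <- driftVariance(d, c("age", "treatment"))
        dv$variance[dv$group == "5_treated"]
    })
    expect_true(all(diff(day5) < 0))
})

test_that("delayed treatment yields intermediate drift-variance", {
    dvAt <- function(start) {
        sim <- generateTranscriptome(syntheticConfig(
            nGenes = 800, attenuation = 0.8, attenuationStart = start,
            seed = 53))
        cpm <- cpmNormalize(sim$expression)
        d <- computeDrift(cpm, buildYoungReference(cpm, 1))
        dv <- driftVariance(d, c("age", "treatment"))
        dv$variance[dv$group == "10_treated"]
    }
    always <- dvAt(1); late <- dvAt(5)
    sim <- generateTranscriptome(syntheticConfig(nGenes = 800,
                                                 attenuation = 0.8,
                                                 seed = 53))
    cpm <- cpmNormalize(sim$expression)
    d <- computeDrift(cpm, buildYoungReference(cpm, 1))
    never <- driftVariance(d, c("age", "treatment"))
    never <- never$variance[never$group == "10_water"]
    expect_lt(always, late)
    expect_lt(late, never)
})

test_that("random-walk drift mode still produces growing dispersion", {
    sim <- generateTranscriptome(syntheticConfig(
        nGenes = 400, driftMode = "random_walk", seed = 59))
    cpm <- cpmNormalize(sim$expression)
    d <- computeDrift(cpm, buildYoungReference(cpm, 1))
    dv <- driftVariance(d, c("age", "treatment"))
    expect_gt(dv$variance[dv$group == "10_water"],
              dv$variance[dv$group == "3_water"])
})

test_that("synthetic lifespan arms are shifted, exchangeable and reproducible", {
    m <- gompertzFromMeanLifespan(19.8, 0.35)
    ls <- generateLifespans(m, nPerArm = 1500, effectDays = 7.5, seed = 61)
    expect_equal(mean(deathDays(ls$treated)) - mean(deathDays(ls$control)),
                 7.5, tolerance = 0.1)
    expect_identical(
        deathDays(generateLifespans(m, 1500, 7.5, seed = 61)$control),
        deathDays(ls$control))
    null <- generateLifespans(m, 800, 0, seed = 62)
    expect_gt(logrankTest(null$control, null$treated)$p.value, 0.01)
})
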