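test_that("young reference pooling and holdout behave as specified", {
    v <- matrix(c(10, 100, 20, 100, 30, 100), 2, 3,
                dimnames = list(c("g", "h"), c("r1", "r2", "r3")))
    cpm <- cpmMatrix(v, ages = c(1, 1, 1))
    ref <- buildYoungReference(cpm, 1, "pooled_mean")
    # pooled mean over the cpm-rescaled replicates, gene by gene
    expect_equal(refExpression(ref),
                 rowMeans(exprsValues(cpm)), tolerance = 1e-12)
    expect_false(ref@holdoutExcluded)

    expect_error(buildYoungReference(cpm, 5), "no sample at reference age")
    expect_error(buildYoungReference(cpm, 1, "holdout", "nope"),
                 "not at reference age")

    # a single reference replicate: pooled_mean and holdout coincide
    one <- cpmMatrix(v[, 1, drop = FALSE], ages = 1)
    expect_equal(refExpression(buildYoungReference(one, 1, "pooled_mean")),
                 refExpression(buildYoungReference(one, 1, "holdout")))
})

test_that("held-out reference samples never reach downstream groups", {
    s <- smallSim()
    hold <- sourceSamples(buildYoungReference(s$cpm, 1, "holdout"))
    ref <- buildYoungReference(s$cpm, 1, "holdout", hold)
    d <- computeDrift(s$cpm, ref)
    expect_false(any(hold %in% colnames(d)))
    dv <- driftVariance(d, c("age", "treatment"))
    expect_false(any(dv$self_referential))
    # the remaining reference-age replicates show a real (positive) variance
    expect_gt(dv$variance[dv$group == "1_water"], 0)
})

test_that("drift is the log fold-change against the reference", {
    v <- matrix(c(50, 10, 400, 200, 40, 100), 3, 2,
                dimnames = list(c("g1", "g2", "g3"), c("young", "old")))
    ann <- data.frame(sample_id = c("young", "old"), age = c(1, 5),
                      age_unit = "days", treatment = "water",
                      replicate = 1)
    em <- ExpressionMatrix(v * (1e6 / colSums(v))[col(v)], unit = "cpm",
                           annotations = ann)
    # self-reference: a sample identical to its reference has td = 0
    ref <- buildYoungReference(em, 1, "pooled_mean")
    d0 <- computeDrift(em, ref, pseudocount = 0.5)
    expect_equal(unname(tdMatrix(d0)[, "young"]), rep(0, 3))
    expect_true(SummarizedExperiment::colData(d0)["young",
                                                  "selfReferential"])

    # cpm 200 vs reference 50, pseudocount 0, log2 -> td = 2; the whole
    # column is checked element by element against the written-out formula
    k <- 1e6 / 340   # depth scale putting the hand numbers on the cpm scale
    refv <- c(g1 = 50, g2 = 10, g3 = 400) * k
    refManual <- new("YoungReference", refExpression = refv,
                     method = "holdout", refAge = 1,
                     sourceSamples = character(0), holdoutExcluded = FALSE,
                     minSourceExpression = refv)
    em200 <- ExpressionMatrix(
        matrix(c(200, 40, 100) * k, 3, 1,
               dimnames = list(c("g1", "g2", "g3"), "old")), unit = "cpm")
    dm <- computeDrift(em200, refManual, pseudocount = 0)
    expect_equal(tdMatrix(dm)["g1", "old"], 2, tolerance = 1e-12)
    expect_equal(tdMatrix(dm),
                 log2(exprsValues(em200) / refv), tolerance = 1e-12)
})

test_that("genes undetected in the reference are dropped, not imputed", {
    v <- matrix(c(100, 0, 50, 80, 5, 60), 3, 2,
                dimnames = list(c("ok", "zero", "ok2"), c("y", "o")))
    cpm <- cpmMatrix(v, ages = c(1, 5))
    ref <- buildYoungReference(cpm, 1)
    d <- computeDrift(cpm, ref)
    expect_setequal(rownames(d), c("ok", "ok2"))
    expect_equal(S4Vectors::metadata(d)$nGenesDropped, 1)
    allzero <- cpmMatrix(matrix(c(0, 100, 3, 97), 2, 2,
                         dimnames = list(c("a", "b"), c("y", "o"))),
                         ages = c(1, 5))
    refz <- buildYoungReference(allzero, 1)
    expect_error(computeDrift(allzero[ "a", ], refz), "no genes")
})

test_that("pooled-mean reference gives near-zero mean drift across its replicates", {
    set.seed(4)
    base <- rexp(200, 1 / 100)
    v <- sapply(1:3, function(i) base * exp(rnorm(200, 0, 0.02)))
    dimnames(v) <- list(sprintf("g%03d", 1:200), c("r1", "r2", "r3"))
    cpm <- cpmMatrix(v, ages = c(1, 1, 1))
    d <- computeDrift(cpm, buildYoungReference(cpm, 1), pseudocount = 0)
    expect_lt(max(abs(rowMeans(tdMatrix(d)))), 0.01)
})

test_that("drift-variance matches Eq-style brute force and hand examples", {
    twoPass <- function(x) {     # independent two-pass oracle
        m <- 0; for (v in x) m <- m + v; m <- m / length(x)
        s <- 0; for (v in x) s <- s + (v - m)^2
        s / (length(x) - 1)
    }
    d <- makeDriftMatrix(matrix(c(0, 2), 1, 2,
                         dimnames = list("g", c("a", "b"))), ages = c(5, 5))
    dv <- driftVariance(d, groups = c(a = "g1", b = "g1"))
    expect_equal(dv$variance, 2)
    expect_equal(dv$median, 1)

    d4 <- makeDriftMatrix(matrix(1:4, 1, 4,
                          dimnames = list("g", letters[1:4])),
                          ages = rep(5, 4))
    dv4 <- driftVariance(d4, groups = setNames(rep("g1", 4), letters[1:4]))
    expect_equal(dv4$variance, 5 / 3, tolerance = 1e-12)

    dc <- makeDriftMatrix(matrix(3.7, 4, 2, dimnames = list(
        paste0("g", 1:4), c("a", "b"))), ages = c(1, 1))
    expect_equal(driftVariance(dc, c(a = "x", b = "x"))$variance, 0)

    set.seed(12)
    for (i in 1:20) {
        x <- rnorm(sample(10:200, 1), sd = runif(1, 0.1, 3))
        m <- makeDriftMatrix(matrix(x, length(x), 1,
             dimnames = list(sprintf("g%03d", seq_along(x)), "s")), ages = 5)
        expect_equal(driftVariance(m, c(s = "grp"))$variance, twoPass(x),
                     tolerance = 1e-12)
    }
})

test_that("outliers are excluded from whiskers but never from the variance", {
    x <- c(seq(-1, 1, length.out = 50), 25)   # one extreme outlier
    m <- makeDriftMatrix(matrix(x, length(x), 1,
         dimnames = list(sprintf("g%02d", seq_along(x)), "s")), ages = 5)
    dv <- driftVariance(m, c(s = "grp"))
    expect_equal(dv$n_outliers, 1)
    expect_lt(dv$whisker_hi, 25)
    expect_equal(dv$variance, var(x), tolerance = 1e-12)  # outlier included
})

test_that("changing the log base rescales td but leaves Levene p invariant", {
    s <- smallSim()
    d2 <- s$drift
    de <- computeDrift(s$cpm, s$ref, logBase = exp(1))
    ratio <- tdMatrix(de) / tdMatrix(d2)
    ratio <- ratio[is.finite(ratio)]
    expect_equal(unname(ratio), rep(log(2), length(ratio)),
                 tolerance = 1e-9)
    g2 <- driftValues(d2, c("age", "treatment"))
    ge <- driftValues(de, c("age", "treatment"))
    cmp <- c("10_water", "10_treated")
    expect_equal(driftVariance(de, c("age", "treatment"))$variance,
                 driftVariance(d2, c("age", "treatment"))$variance * log(2)^2,
                 tolerance = 1e-9)
    expect_equal(robustLevene(ge[cmp])$p.value,
                 robustLevene(g2[cmp])$p.value, tolerance = 1e-10)
})

test_that("gene-set restricted drift-variance requires overlap", {
    s <- smallSim()
    good <- GeneSet("present", rownames(s$drift)[1:20])
    dv <- driftVariance(s$drift, c("age", "treatment"), geneSet = good)
    expect_true(all(dv$n <= 20 * 3))
    bad <- GeneSet("absent", c("nope1", "nope2"))
    expect_error(driftVariance(s$drift, c("age", "treatment"),
                               geneSet = bad), "absent")
})

test_that("age binning is half-open with an overflow bin", {
    expect_equal(unname(binSamples(c(a = 13, b = 26), c(0, 30, 60))),
                 rep("[0,30)", 2))
    # an age exactly on an edge belongs to the right (upper) bin
    expect_equal(unname(binSamples(c(x = 30), c(0, 30, 60))), "[30,60)")
    expect_equal(unname(binSamples(c(x = 75), c(0, 30, 60))), "[60,Inf)")
    expect_error(binSamples(c(x = 5), c(10, 20)), "below the first")
    expect_error(binSamples(c(x = 5), c(10, 10)), "strictly increasing")

    # hour-scale ages group into the day 0/1/2/4/6 design
    hrs <- c(8, 24, 28, 40, 52, 72, 96, 144, 196)
    names(hrs) <- sprintf("s%d", seq_along(hrs))
    bins <- binSamples(hrs, c(8, 24, 28, 72, 144))
    expect_equal(as.integer(table(bins)[unique(bins)]),
                 c(1L, 1L, 3L, 2L, 2L))
    expect_length(unique(bins), 5)
})

test_that("gene subsampling is disjoint, exact and reproducible", {
    genes <- sprintf("g%05d", 1:19196)
    sets <- subsampleGenes(genes, 10, 1000, seed = 77)
    ids <- lapply(sets, geneIds)
    expect_true(all(lengths(ids) == 1000))
    expect_length(unique(unlist(ids)), 10000)   # pairwise disjoint
    again <- subsampleGenes(genes, 10, 1000, seed = 77)
    expect_identical(lapply(again, geneIds), ids)
    expect_error(subsampleGenes(genes[1:50], 10, 1000, seed = 1),
                 "only 50 available")
})

test_that("leading-logFC distances match hand computation and are metric", {
    v <- matrix(c(100, 200, 50, 400, 10, 30,
                  100, 200, 50, 400, 10, 30,
                  800, 25, 50, 400, 10, 30), 6, 3,
                dimnames = list(paste0("g", 1:6), c("a", "b", "c")))
    emc <- cpmMatrix(v, ages = c(1, 1, 1))
    res <- leadingLogFCMDS(emc, topN = 2, nDims = 2, pseudocount = 0.5)
    expect_equal(res$distances["a", "b"], 0)       # duplicated samples
    lg <- log2(exprsValues(emc) + 0.5)
    fc <- sort(abs(lg[, "a"] - lg[, "c"]), decreasing = TRUE)[1:2]
    expect_equal(res$distances["a", "c"], sqrt(mean(fc^2)),
                 tolerance = 1e-12)
    expect_equal(res$distances, t(res$distances))
    expect_equal(unname(diag(res$distances)), rep(0, 3))
    expect_warning(leadingLogFCMDS(emc, topN = 500), "using all genes")
})

test_that("drift-plot tables are tidy and round-trip through TSV", {
    s <- smallSim()
    dv <- driftVariance(s$drift, c("age", "treatment"))
    path <- withr::local_tempfile(fileext = ".tsv")
    tab <- driftPlotTable(dv, path)
    back <- read.delim(path)
    expect_equal(nrow(back), nrow(tab))
    expect_equal(back$variance, tab$variance, tolerance = 1e-15)
    expect_identical(back$group, tab$group)
})
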