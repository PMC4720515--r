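#' Configuration for the synthetic aging-transcriptome generator
#'
#' The generator emulates the statistical structure transcriptional-drift
#' analysis assumes: per-gene log-fold drift trajectories moving in opposing
#' directions with age around a young-adult baseline, a treated arm whose
#' drift accrual is attenuated by a factor, replicate-level noise, and
#' negative-binomial count noise at realistic sequencing depth. Defaults
#' mirror a C. elegans time-course design: ~19k genes, ages day 1 (young
#' reference, control only), 3, 5 and 10, three biological replicates,
#' 20-30 million reads per sample.
#'
#' @param nGenes number of genes (default 19196)
#' @param ages sorted ages in days (default \code{c(1, 3, 5, 10)})
#' @param nReplicates replicates per age and arm (default 3)
#' @param refAge young-reference age (default \code{min(ages)}); the treated
#'   arm exists only at later ages
#' @param baselineLogCpmMean,baselineLogCpmSd mean/sd of per-gene baseline
#'   log2 cpm (defaults 3 and 2)
#' @param pUp probability a gene drifts upward (default 0.5: balanced
#'   opposing directions)
#' @param rateMean,rateSd mean/sd of the per-gene drift rate, in log2 units
#'   per day (gamma-distributed; defaults 0.10 and 0.07, giving a
#'   transcriptome drift-variance near 1.2 log2^2 by day 10)
#' @param ageExponent gamma: systematic drift grows as
#'   (elapsed time)^gamma (default 1, near-linear growth)
#' @param attenuation a in [0, 1]: the treated arm's drift clock runs at
#'   (1 - a) of the control rate (default 0.7; a = 1 freezes drift at the
#'   young state, a = 0 is no treatment effect)
#' @param attenuationStart age at which treatment begins (default
#'   \code{refAge}); drift accrued before it is not undone
#' @param noiseSd replicate-level sd of td noise in log2 units
#'   (default 0.2)
#' @param nbDispersion negative-binomial dispersion of count noise
#'   (default 0.05; 0 gives Poisson counts)
#' @param libSizeMeanLog,libSizeSdLog log-normal library-size parameters
#'   (defaults \code{log(2.5e7)} and 0.15, i.e. 20-30 million reads)
#' @param driftMode \code{"trend"} (deterministic trend plus replicate
#'   noise, the default) or \code{"random_walk"} (per-arm cumulative
#'   increments across ages; the underlying mechanism of drift is not
#'   settled, so both are offered)
#' @param seed integer master seed; all randomness derives from it through
#'   fixed sub-streams, so any sub-result is independently reproducible
#' @return list of class \code{"syntheticConfig"}
#' @export
syntheticConfig <- function(nGenes = 19196, ages = c(1, 3, 5, 10),
                            nReplicates = 3, refAge = min(ages),
                            baselineLogCpmMean = 3, baselineLogCpmSd = 2,
                            pUp = 0.5, rateMean = 0.10, rateSd = 0.07,
                            ageExponent = 1, attenuation = 0.7,
                            attenuationStart = refAge, noiseSd = 0.2,
                            nbDispersion = 0.05,
                            libSizeMeanLog = log(2.5e7), libSizeSdLog = 0.15,
                            driftMode = c("trend", "random_walk"), seed = 1) {
    driftMode <- match.arg(driftMode)
    if (is.unsorted(ages, strictly = TRUE)) stop("ages must be sorted, unique")
    if (attenuation < 0 || attenuation > 1) stop("attenuation must be in [0, 1]")
    if (pUp < 0 || pUp > 1) stop("pUp must be in [0, 1]")
    if (noiseSd < 0 || nbDispersion < 0 || rateMean < 0 || rateSd < 0)
        stop("noiseSd, nbDispersion and rate parameters must be nonnegative")
    if (!refAge %in% ages) stop("refAge must be one of the ages")
    structure(as.list(environment()), class = "syntheticConfig")
}

# attenuated drift clock: elapsed drift time for a sample of age t
driftClock <- function(t, refAge, treated, a, t0) {
    elapsed <- pmax(t - refAge, 0)
    if (!treated) return(elapsed)
    pre <- pmax(pmin(t, t0) - refAge, 0)
    pre + (1 - a) * pmax(t - pmax(t0, refAge), 0)
}

#' Generate a synthetic aging transcriptome with ground truth
#'
#' Per gene g and sample of age t, the systematic drift is
#' \code{td = s_g * r_g * clock(t)^gamma} with direction s, rate r and an
#' attenuated drift clock in the treated arm; replicate noise
#' N(0, noiseSd) is added, expected cpm is \code{baseline * 2^td}, and raw
#' counts are drawn negative-binomially at the configured dispersion and a
#' log-normal library size. The control arm covers every age; the treated
#' arm starts after the reference age (the reference age is sequenced
#' untreated, as in a time-course whose day-1 samples precede treatment).
#'
#' @param cfg a \code{\link{syntheticConfig}}
#' @return list: \code{expression} (an \linkS4class{ExpressionMatrix} of
#'   raw counts with annotations), \code{truth} (class
#'   \code{"syntheticTruth"}: per-gene \code{direction} and \code{rate},
#'   \code{expected_dv} per arm and age from the closed form
#'   Var(s r) clock^(2 gamma) + noiseSd^2, and the generating parameters)
#' @export
generateTranscriptome <- function(cfg) {
    stopifnot(inherits(cfg, "syntheticConfig"))
    genePar <- withSeed(subSeed(cfg$seed, 1L), {
        baseLog <- stats::rnorm(cfg$nGenes, cfg$baselineLogCpmMean,
                                cfg$baselineLogCpmSd)
        s <- ifelse(stats::runif(cfg$nGenes) < cfg$pUp, 1, -1)
        r <- if (cfg$rateSd == 0) rep(cfg$rateMean, cfg$nGenes)
             else stats::rgamma(cfg$nGenes,
                                shape = (cfg$rateMean / cfg$rateSd)^2,
                                scale = cfg$rateSd^2 / cfg$rateMean)
        list(baseProp = 2^baseLog / sum(2^baseLog), s = s, r = r)
    })
    genes <- sprintf("gene_%05d", seq_len(cfg$nGenes))
    arms <- data.frame(
        treatment = c(rep("water", length(cfg$ages)),
                      rep("treated", sum(cfg$ages > cfg$refAge))),
        age = c(cfg$ages, cfg$ages[cfg$ages > cfg$refAge]))
    samples <- do.call(rbind, lapply(seq_len(cfg$nReplicates), function(rep) {
        cbind(arms, replicate = rep)
    }))
    samples$sample_id <- sprintf("%s_d%g_r%d", samples$treatment,
                                 samples$age, samples$replicate)
    samples <- samples[order(samples$treatment != "water", samples$age,
                             samples$replicate), ]

    # systematic drift per arm/age; random_walk accumulates increments
    sr <- genePar$s * genePar$r
    sysDrift <- function(treatment, age) {
        clock <- driftClock(age, cfg$refAge, treatment == "treated",
                            cfg$attenuation, cfg$attenuationStart)
        sr * clock^cfg$ageExponent
    }
    if (cfg$driftMode == "random_walk") {
        walk <- withSeed(subSeed(cfg$seed, 2L), {
            out <- list()
            for (trt in unique(arms$treatment)) {
                agesArm <- sort(unique(arms$age[arms$treatment == trt]))
                acc <- rep(0, cfg$nGenes); prevClock <- 0
                for (a in agesArm) {
                    clock <- driftClock(a, cfg$refAge, trt == "treated",
                                        cfg$attenuation, cfg$attenuationStart)
                    dt <- clock - prevClock
                    if (dt > 0)
                        acc <- acc + stats::rnorm(cfg$nGenes, sr * dt,
                                                  genePar$r * sqrt(dt))
                    prevClock <- clock
                    out[[paste(trt, a)]] <- acc
                }
            }
            out
        })
        sysDrift <- function(treatment, age) walk[[paste(treatment, age)]]
    }

    counts <- withSeed(subSeed(cfg$seed, 3L), {
        vapply(seq_len(nrow(samples)), function(i) {
            td <- sysDrift(samples$treatment[i], samples$age[i]) +
                stats::rnorm(cfg$nGenes, 0, cfg$noiseSd)
            p <- genePar$baseProp * 2^td
            mu <- p / sum(p) *
                stats::rlnorm(1, cfg$libSizeMeanLog, cfg$libSizeSdLog)
            if (cfg$nbDispersion == 0) stats::rpois(cfg$nGenes, mu)
            else stats::rnbinom(cfg$nGenes, mu = mu,
                                size = 1 / cfg$nbDispersion)
        }, numeric(cfg$nGenes))
    })
    dimnames(counts) <- list(genes, samples$sample_id)
    ann <- data.frame(sample_id = samples$sample_id, age = samples$age,
                      age_unit = "days", treatment = samples$treatment,
                      replicate = samples$replicate)
    expected <- do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
        clock <- driftClock(arms$age[i], cfg$refAge,
                            arms$treatment[i] == "treated",
                            cfg$attenuation, cfg$attenuationStart)
        data.frame(treatment = arms$treatment[i], age = arms$age[i],
                   drift_clock = clock,
                   expected_dv = stats::var(sr) * clock^(2 * cfg$ageExponent) +
                       cfg$noiseSd^2)
    }))
    truth <- structure(list(
        gene_ids = genes, direction = stats::setNames(genePar$s, genes),
        rate = stats::setNames(genePar$r, genes),
        attenuation = cfg$attenuation, ageExponent = cfg$ageExponent,
        refAge = cfg$refAge, noiseSd = cfg$noiseSd,
        expected_dv = expected, config = cfg), class = "syntheticTruth")
    list(expression = ExpressionMatrix(counts, unit = "raw_count",
                                       annotations = ann),
         truth = truth)
}

#' Generate gene-set fixtures from synthetic truth
#'
#' Draws \code{nSets} disjoint random sets plus two designed contrast sets:
#' \code{"coherent"} (members all drift in the same direction; low
#' drift-variance despite strong drift) and \code{"opposing"} (balanced
#' up/down members of comparable rate; high drift-variance). The contrast
#' pair demonstrates that drift-variance measures divergence within a set,
#' not net up/down regulation.
#'
#' @param truth a \code{"syntheticTruth"} object
#' @param nSets number of random sets (default 5)
#' @param setSize genes per set (default 200)
#' @param seed integer seed
#' @return named list of \linkS4class{GeneSet}
#' @export
generateGeneSets <- function(truth, nSets = 5, setSize = 200, seed = 1) {
    stopifnot(inherits(truth, "syntheticTruth"))
    genes <- truth$gene_ids
    if (setSize > length(genes)) stop("setSize exceeds the gene universe")
    sets <- subsampleGenes(genes, nSets, setSize, seed = subSeed(seed, 1L))
    names(sets) <- vapply(sets, setName, "")
    up <- genes[truth$direction > 0]; dn <- genes[truth$direction < 0]
    half <- setSize %/% 2
    designed <- withSeed(subSeed(seed, 2L), list(
        coherent = GeneSet("coherent", sample(up, min(setSize, length(up))),
                           source = "synthetic: all same direction"),
        opposing = GeneSet("opposing",
                           c(sample(up, min(half, length(up))),
                             sample(dn, min(setSize - half, length(dn)))),
                           source = "synthetic: balanced directions")))
    c(sets, designed)
}

#' Generate a two-arm synthetic lifespan experiment
#'
#' Control arm drawn from the Gompertz model; treated arm identically
#' drawn, then day-shifted by \code{effectDays} (a parallel displacement of
#' the mortality curve).
#'
#' @param model a \linkS4class{GompertzModel}
#' @param nPerArm animals per arm
#' @param effectDays additive lifespan extension of the treated arm
#' @param seed integer seed
#' @return list: \code{control}, \code{treated} (\linkS4class{LifeTable}),
#'   \code{truth} (generating parameters)
#' @export
generateLifespans <- function(model, nPerArm, effectDays, seed = 1) {
    control <- simulateCohort(model, nPerArm, 0, seed = subSeed(seed, 1L),
                              cohortIdLabel = "control")
    treated <- simulateCohort(model, nPerArm, effectDays,
                              seed = subSeed(seed, 2L),
                              cohortIdLabel = "treated")
    list(control = control, treated = treated,
         truth = list(A = hazardA(model), G = hazardG(model),
                      effect_days = effectDays, n_per_arm = nPerArm,
                      seed = seed))
}
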