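#' Robust (Brown-Forsythe / trimmed-mean) Levene test
#'
#' Tests equality of dispersion across groups: each observation is replaced
#' by its absolute deviation from a robust group center, and a one-way
#' ANOVA F on the deviations gives the statistic W. The default center is a
#' 10\% trimmed mean (10\% removed from EACH tail before averaging), which
#' discounts large outliers; \code{center = "median"} with
#' \code{trimFraction = 0} is the classical Brown-Forsythe test and
#' \code{center = "mean"} the classical Levene test. This is the test used
#' to compare drift-variance between ages or treatments, since it compares
#' dispersions, not means.
#'
#' @param groups list of numeric vectors (each length >= 2)
#' @param center \code{"trimmed_mean"} (default), \code{"median"} or
#'   \code{"mean"}
#' @param trimFraction fraction trimmed from each tail for
#'   \code{"trimmed_mean"} (default 0.10); ignored by the other centers
#' @return an object of class \code{"htest"} with statistic \code{W},
#'   numerator/denominator df, and p-value; the center and trim fraction are
#'   recorded in \code{method}
#' @examples
#' robustLevene(list(rnorm(50), rnorm(50, sd = 3)))
#' @export
robustLevene <- function(groups, center = c("trimmed_mean", "median", "mean"),
                         trimFraction = 0.10) {
    center <- match.arg(center)
    if (!is.list(groups) || length(groups) < 2)
        stop("need at least 2 groups")
    sizes <- lengths(groups)
    if (any(sizes < 2)) stop("every group needs at least 2 values")
    if (trimFraction < 0 || trimFraction >= 0.5)
        stop("trimFraction must be in [0, 0.5)")
    centers <- vapply(groups, function(x) switch(center,
        trimmed_mean = mean(x, trim = trimFraction),
        median = stats::median(x),
        mean = mean(x)), numeric(1))
    dev <- unlist(mapply(function(x, c) abs(x - c), groups, centers,
                         SIMPLIFY = FALSE))
    g <- factor(rep(seq_along(groups), sizes))
    k <- length(groups); N <- length(dev)
    gm <- tapply(dev, g, mean)
    ssb <- sum(sizes * (gm - mean(dev))^2)
    ssw <- sum((dev - gm[g])^2)
    df1 <- k - 1L; df2 <- N - k
    if (ssw == 0 && ssb == 0) {
        W <- 0; p <- 1
    } else if (ssw == 0) {
        W <- Inf; p <- 0
    } else {
        W <- (ssb / df1) / (ssw / df2)
        p <- stats::pf(W, df1, df2, lower.tail = FALSE)
    }
    structure(list(
        statistic = c(W = W), parameter = c(df1 = df1, df2 = df2),
        p.value = p,
        method = sprintf(
            "Robust Levene test (center = %s%s)", center,
            if (center == "trimmed_mean")
                sprintf(", trim = %g per tail", trimFraction) else ""),
        data.name = deparse(substitute(groups))), class = "htest")
}

#' Two-sample t test with recorded group summaries
#'
#' Thin wrapper over \code{stats::t.test} returning the unpaired two-sided
#' test. The Welch (unequal-variance) form is the default; the pooled
#' (Student) form is available. The degenerate case of zero variance in
#' both groups with equal means returns t = 0, p = 1, flagged.
#'
#' @param a,b numeric vectors (each length >= 2)
#' @param variant \code{"welch"} (default) or \code{"pooled"}
#' @return list of class \code{"tTestResult"}: \code{t}, \code{df},
#'   \code{p.value}, \code{variant}, \code{mean_a}, \code{mean_b},
#'   \code{sd_a}, \code{sd_b}, \code{degenerate}
#' @examples
#' tTest(c(55.8, 56.2, 66.1), c(95.5, 96.1, 92.0))
#' @export
tTest <- function(a, b, variant = c("welch", "pooled")) {
    variant <- match.arg(variant)
    if (length(a) < 2 || length(b) < 2)
        stop("each group needs at least 2 values")
    res <- list(variant = variant, mean_a = mean(a), mean_b = mean(b),
                sd_a = stats::sd(a), sd_b = stats::sd(b),
                degenerate = FALSE)
    if (res$sd_a == 0 && res$sd_b == 0 && res$mean_a == res$mean_b) {
        res$t <- 0; res$df <- length(a) + length(b) - 2
        res$p.value <- 1; res$degenerate <- TRUE
    } else {
        ht <- stats::t.test(a, b, var.equal = (variant == "pooled"))
        res$t <- unname(ht$statistic)
        res$df <- unname(ht$parameter)
        res$p.value <- ht$p.value
    }
    structure(res, class = "tTestResult")
}

#' @export
print.tTestResult <- function(x, ...) {
    cat(sprintf("%s t-test: t = %.4g, df = %.4g, p = %.4g%s\n",
                x$variant, x$t, x$df, x$p.value,
                if (x$degenerate) " [degenerate: both groups constant]" else ""))
    cat(sprintf("  group means %.4g vs %.4g (sd %.4g vs %.4g)\n",
                x$mean_a, x$mean_b, x$sd_a, x$sd_b))
    invisible(x)
}

#' Exact binomial test with log-space tails
#'
#' Exact binomial tail probabilities computed in log space via
#' \code{pbinom(log.p = TRUE)}, so extreme results (down to the 1e-300
#' floor) never underflow to zero. The two-sided p-value doubles the
#' smaller tail (capped at 1), which at p0 = 0.5 is the symmetric exact
#' test; the one-sided p is the tail in the observed direction.
#'
#' @param k number of successes (0 <= k <= n)
#' @param n number of trials
#' @param p0 null success probability (default 0.5)
#' @param sided \code{"two"} (default) or \code{"one"}
#' @return the p-value, a single number in (0, 1], floored at 1e-300
#' @examples
#' binomialTestExact(4078, 6958)   # ~6.4e-47
#' @export
binomialTestExact <- function(k, n, p0 = 0.5, sided = c("two", "one")) {
    sided <- match.arg(sided)
    if (k < 0 || k > n) stop("k must be in [0, n]")
    if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
    logLower <- stats::pbinom(k, n, p0, log.p = TRUE)
    logUpper <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE, log.p = TRUE)
    logTail <- min(logLower, logUpper)
    lp <- if (sided == "one") logTail else min(logTail + log(2), 0)
    max(exp(lp), 1e-300)
}

#' Classify per-gene attenuation of drift under treatment
#'
#' A treatment attenuates a gene's age-associated drift when the treated
#' arm keeps expression closer to the young reference than the control arm
#' does. The default rule calls a gene attenuated iff its mean |td| across
#' the shared ages is strictly smaller under treatment; the alternative
#' \code{"per_age_majority"} rule requires |td| to be smaller at a strict
#' majority of the individual ages. Under the null of no treatment effect
#' each gene is a fair coin, so the attenuated count k out of n genes is
#' tested against Binomial(n, 1/2).
#'
#' @param dControl,dTreated \linkS4class{DriftMatrix} objects for control
#'   and treated arms sharing a gene universe
#' @param ages ages over which to aggregate (must exist in both matrices'
#'   colData); default: all ages shared by both arms, excluding
#'   self-referential samples
#' @param rule \code{"mean_abs_td"} (default) or \code{"per_age_majority"}
#' @return list of class \code{"attenuationResult"}: \code{calls} (named
#'   logical), \code{k}, \code{n}, \code{p.value}, \code{rule}, \code{ages}
#' @export
classifyAttenuation <- function(dControl, dTreated, ages = NULL,
                                rule = c("mean_abs_td", "per_age_majority")) {
    rule <- match.arg(rule)
    stopifnot(is(dControl, "DriftMatrix"), is(dTreated, "DriftMatrix"))
    genes <- intersect(rownames(dControl), rownames(dTreated))
    if (!length(genes)) stop("no shared genes between the two arms")
    cdc <- SummarizedExperiment::colData(dControl)
    cdt <- SummarizedExperiment::colData(dTreated)
    if (is.null(ages))
        ages <- intersect(cdc$age[!cdc$selfReferential],
                          cdt$age[!cdt$selfReferential])
    ages <- sort(unique(ages))
    if (!length(ages)) stop("no shared ages between the two arms")
    if (!all(ages %in% cdc$age) || !all(ages %in% cdt$age))
        stop("age(s) missing from one arm: ",
             paste(setdiff(ages, intersect(cdc$age, cdt$age)), collapse = ", "))
    perAge <- function(d, cd) matrix(vapply(ages, function(a) {
        ids <- rownames(cd)[cd$age == a]
        rowMeans(abs(tdMatrix(d)[genes, ids, drop = FALSE]))
    }, numeric(length(genes))), nrow = length(genes))
    absC <- perAge(dControl, cdc)
    absT <- perAge(dTreated, cdt)
    calls <- if (rule == "mean_abs_td") {
        rowMeans(absT) < rowMeans(absC)
    } else {
        rowSums(absT < absC) > length(ages) / 2
    }
    names(calls) <- genes
    k <- sum(calls); n <- length(calls)
    structure(list(calls = calls, k = k, n = n,
                   p.value = binomialTestExact(k, n, 0.5, "two"),
                   rule = rule, ages = ages),
              class = "attenuationResult")
}

#' @export
print.attenuationResult <- function(x, ...) {
    cat(sprintf(
        "Attenuation (%s over ages %s): %d / %d genes (%.1f%%), binomial p = %.3g\n",
        x$rule, paste(x$ages, collapse = ","), x$k, x$n,
        100 * x$k / x$n, x$p.value))
    invisible(x)
}

#' Overlap of attenuated gene sets between two interventions
#'
#' Restricts both attenuation results to their shared gene universe, counts
#' genes attenuated by both, and tests that count against Binomial(n, 1/2)
#' over the intersection.
#'
#' @param resA,resB \code{attenuationResult} objects
#' @return list: \code{overlap}, \code{n}, \code{p.value},
#'   \code{fraction}
#' @export
overlapAttenuation <- function(resA, resB) {
    genes <- intersect(names(resA$calls), names(resB$calls))
    if (!length(genes)) stop("empty gene-universe intersection")
    k <- sum(resA$calls[genes] & resB$calls[genes])
    list(overlap = k, n = length(genes),
         p.value = binomialTestExact(k, length(genes), 0.5, "two"),
         fraction = k / length(genes))
}

#' Spearman correlation of drift-variance with age
#'
#' Rank correlation with the tie-corrected t-approximation p-value, for
#' testing whether per-sample drift-variance increases with age.
#'
#' @param age numeric vector of ages (>= 4 pairs)
#' @param dv numeric vector of drift-variances, same length
#' @return list: \code{rho}, \code{p.value}, \code{n}, \code{degenerate}
#'   (TRUE when dv or age is constant, in which case rho is NA)
#' @export
spearmanAgeCorrelation <- function(age, dv) {
    if (length(age) != length(dv)) stop("age and dv lengths differ")
    if (length(age) < 4) stop("need at least 4 pairs")
    if (stats::sd(dv) == 0 || stats::sd(age) == 0) {
        warning("constant input; Spearman rho undefined")
        return(list(rho = NA_real_, p.value = NA_real_, n = length(age),
                    degenerate = TRUE))
    }
    ct <- suppressWarnings(
        stats::cor.test(age, dv, method = "spearman", exact = FALSE))
    list(rho = unname(ct$estimate), p.value = ct$p.value, n = length(age),
         degenerate = FALSE)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Monotone step-up q-values via \code{stats::p.adjust(method = "BH")};
#' inputs outside [0, 1] are an error.
#'
#' @param pValues numeric vector of p-values
#' @return numeric vector of q-values, order-preserving
#' @export
bhFDR <- function(pValues) {
    if (anyNA(pValues) || any(pValues < 0) || any(pValues > 1))
        stop("p-values must all lie in [0, 1]")
    stats::p.adjust(pValues, method = "BH")
}
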