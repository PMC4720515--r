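# Gompertz survival S(t) = exp(-(A/G) (e^{Gt} - 1)); G -> 0 is exponential.
gompertzSurvival <- function(t, A, G) {
    if (G < 1e-12) exp(-A * t) else exp(-(A / G) * expm1(G * t))
}

#' Mean lifespan implied by a Gompertz model
#' @param model a \linkS4class{GompertzModel}
#' @return mean lifespan in days
#' @export
gompertzMeanLifespan <- function(model) {
    stopifnot(is(model, "GompertzModel"))
    stats::integrate(gompertzSurvival, 0, Inf, A = model@A, G = model@G,
                     rel.tol = 1e-10)$value
}

#' Gompertz model matched to a target mean lifespan
#'
#' Solves the baseline hazard A so that a Gompertz hazard with the given
#' exponential rate G has the requested mean lifespan. Useful when a study
#' reports mean lifespan but not the hazard parameters.
#'
#' @param meanDays target mean lifespan (days)
#' @param G exponential rate (1/day)
#' @return a \linkS4class{GompertzModel}
#' @examples
#' gompertzFromMeanLifespan(19.8, G = 0.35)
#' @export
gompertzFromMeanLifespan <- function(meanDays, G) {
    if (meanDays <= 0) stop("meanDays must be positive")
    f <- function(logA) {
        m <- GompertzModel(exp(logA), G)
        gompertzMeanLifespan(m) - meanDays
    }
    logA <- stats::uniroot(f, c(-40, 5), tol = 1e-12)$root
    GompertzModel(exp(logA), G,
                  fitMeta = list(method = "matched_mean_lifespan",
                                 target_mean = meanDays))
}

#' Interval mortality (hazard) curve from a life table
#'
#' Estimates the hazard on the actual scoring grid: for each interval
#' between consecutive scoring days, hazard = deaths / animal-days at risk
#' (animals at risk at interval start times interval width), then smooths
#' with a centered moving average of the requested width on the day axis.
#' The log-hazard is reported where the smoothed hazard is positive.
#'
#' @param lt a \linkS4class{LifeTable} with at least one death
#' @param windowDays moving-average window (days, default 3); a window no
#'   wider than the scoring interval leaves the raw estimates unchanged
#' @return data.frame of class \code{"mortalityCurve"}: \code{day}
#'   (interval end), \code{deaths}, \code{at_risk}, \code{hazard} (raw),
#'   \code{hazard_smooth}, \code{log_hazard}
#' @export
estimateMortality <- function(lt, windowDays = 3) {
    stopifnot(is(lt, "LifeTable"))
    dd <- deathDays(lt); cc <- censoredDays(lt)
    if (!length(dd)) stop("life table has no death events")
    grid <- sort(unique(c(dd, cc)))
    starts <- c(0, grid[-length(grid)])
    deaths <- vapply(seq_along(grid), function(i)
        sum(dd > starts[i] & dd <= grid[i]), numeric(1))
    atRisk <- vapply(starts, function(s) sum(dd > s) + sum(cc > s),
                     numeric(1))
    width <- grid - starts
    hazard <- deaths / (atRisk * width)
    smooth <- vapply(seq_along(grid), function(i) {
        sel <- abs(grid - grid[i]) <= windowDays / 2
        sum(deaths[sel]) / sum(atRisk[sel] * width[sel])
    }, numeric(1))
    out <- data.frame(day = grid, deaths = deaths, at_risk = atRisk,
                      hazard = hazard, hazard_smooth = smooth,
                      log_hazard = ifelse(smooth > 0, log(smooth), NA))
    class(out) <- c("mortalityCurve", "data.frame")
    out
}

#' Maximum-likelihood Gompertz fit to a life table
#'
#' Fits h(t) = A exp(G t) by maximizing the censored log-likelihood over
#' (log A, log G) with \code{optim}; the log-parameterization enforces
#' A, G > 0. ML on death times is preferred over regression on the smoothed
#' log-hazard for small-sample robustness (the regression route is
#' available as a diagnostic via \code{\link{estimateMortality}}).
#'
#' @param lt a \linkS4class{LifeTable} with at least 20 uncensored deaths
#' @return a \linkS4class{GompertzModel} with log-likelihood and sample
#'   size in \code{fitMeta}
#' @export
fitGompertz <- function(lt) {
    stopifnot(is(lt, "LifeTable"))
    dd <- deathDays(lt); cc <- censoredDays(lt)
    if (length(dd) < 20)
        stop("refusing to fit with fewer than 20 uncensored deaths (have ",
             length(dd), ")")
    dd <- pmax(dd, 1e-8)  # deaths scored at day 0 would have log-density -Inf
    negll <- function(par) {
        A <- exp(par[1]); G <- exp(par[2])
        cumhaz <- function(t) A * expm1(G * t) / G
        -(sum(log(A) + G * dd - cumhaz(dd)) - sum(cumhaz(cc)))
    }
    init <- c(log(0.5 / mean(dd)), log(1 / stats::sd(dd)))
    fit <- stats::optim(init, negll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (fit$convergence != 0)
        stop("Gompertz fit did not converge (optim code ", fit$convergence,
             ", message: ", fit$message, ")")
    GompertzModel(exp(fit$par[1]), exp(fit$par[2]),
                  fitMeta = list(method = "mle",
                                 n_animals = nTotal(lt),
                                 n_deaths = length(dd),
                                 logLik = -fit$value))
}

#' Simulate a lifespan cohort from a Gompertz model
#'
#' Draws death times by inverse-CDF sampling from the Gompertz survival
#' function, then applies an additive day shift (floored at 0) modelling a
#' parallel displacement of the mortality curve.
#'
#' @param model a \linkS4class{GompertzModel}
#' @param n cohort size (>= 1)
#' @param shiftDays additive shift of every death time (default 0)
#' @param seed integer seed (reproducible draws); NULL uses the current RNG
#' @param cohortIdLabel cohort label for the returned table
#' @return a \linkS4class{LifeTable} with n uncensored deaths
#' @export
simulateCohort <- function(model, n, shiftDays = 0, seed = NULL,
                           cohortIdLabel = "simulated") {
    stopifnot(is(model, "GompertzModel"), n >= 1)
    A <- model@A; G <- model@G
    u <- withSeed(seed, stats::runif(n))
    t <- if (G < 1e-12) -log(u) / A else log1p(-(G / A) * log(u)) / G
    LifeTable(cohortIdLabel, pmax(t + shiftDays, 0))
}

#' Mantel-Haenszel log-rank test between two cohorts
#'
#' Standard observed-minus-expected log-rank comparison over the pooled
#' event times with hypergeometric variance at ties (the Mantel-Haenszel
#' form), via \code{survival::survdiff}; two-sided p from chi-square with
#' 1 df.
#'
#' @param a,b \linkS4class{LifeTable} objects
#' @return object of class \code{"htest"} with the chi-square statistic
#'   and p-value
#' @export
logrankTest <- function(a, b) {
    stopifnot(is(a, "LifeTable"), is(b, "LifeTable"))
    if (!length(deathDays(a)) && !length(deathDays(b)))
        stop("no death events in either cohort")
    time <- c(deathDays(a), censoredDays(a), deathDays(b), censoredDays(b))
    status <- c(rep(1, length(deathDays(a))), rep(0, length(censoredDays(a))),
                rep(1, length(deathDays(b))), rep(0, length(censoredDays(b))))
    arm <- rep(c("a", "b"), c(nTotal(a), nTotal(b)))
    sd0 <- survival::survdiff(survival::Surv(time, status) ~ arm, rho = 0)
    chisq <- unname(sd0$chisq)
    structure(list(statistic = c("chi-square" = chisq),
                   parameter = c(df = 1),
                   p.value = stats::pchisq(chisq, 1, lower.tail = FALSE),
                   method = "Mantel-Haenszel log-rank test",
                   data.name = paste(cohortId(a), "vs", cohortId(b))),
              class = "htest")
}

#' Monte-Carlo power of detection for a lifespan experiment
#'
#' Simulates replicate two-arm experiments (control vs additive day-shifted
#' cohorts of equal size) from a Gompertz model and reports the fraction in
#' which the Mantel-Haenszel log-rank test rejects at the given alpha, with
#' a Wilson 95\% confidence interval.
#'
#' @param model a \linkS4class{GompertzModel} for the control arm
#' @param nPerArm animals per arm
#' @param effectDays additive lifespan extension in the treated arm
#' @param alpha significance level (default 0.01)
#' @param nReps Monte-Carlo replicates (>= 100; default 1000)
#' @param seed integer seed
#' @return list of class \code{"powerResult"}: \code{power}, \code{ci95},
#'   \code{effect_days}, \code{n_per_arm}, \code{alpha}, \code{n_reps},
#'   \code{seed}
#' @export
powerOfDetection <- function(model, nPerArm, effectDays, alpha = 0.01,
                             nReps = 1000, seed = 1) {
    stopifnot(is(model, "GompertzModel"))
    if (nReps < 100) stop("need at least 100 Monte-Carlo replicates")
    rejections <- withSeed(seed, {
        sum(vapply(seq_len(nReps), function(i) {
            ctl <- simulateCohort(model, nPerArm, 0, seed = NULL,
                                  cohortIdLabel = "control")
            trt <- simulateCohort(model, nPerArm, effectDays, seed = NULL,
                                  cohortIdLabel = "treated")
            logrankTest(ctl, trt)$p.value < alpha
        }, logical(1)))
    })
    power <- rejections / nReps
    # Wilson 95% interval
    z <- stats::qnorm(0.975)
    den <- 1 + z^2 / nReps
    ctr <- (power + z^2 / (2 * nReps)) / den
    hw <- z * sqrt(power * (1 - power) / nReps + z^2 / (4 * nReps^2)) / den
    structure(list(power = power, ci95 = c(ctr - hw, ctr + hw),
                   effect_days = effectDays, n_per_arm = nPerArm,
                   alpha = alpha, n_reps = nReps, seed = seed),
              class = "powerResult")
}

#' @export
print.powerResult <- function(x, ...) {
    cat(sprintf(
        "Power of detection: %.3f (95%% CI %.3f-%.3f)\n  %d/arm, effect %+g days, alpha %g, %d reps (seed %d)\n",
        x$power, x$ci95[1], x$ci95[2], x$n_per_arm, x$effect_days,
        x$alpha, x$n_reps, x$seed))
    invisible(x)
}
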