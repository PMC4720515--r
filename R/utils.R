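# internal helpers

# Evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(seed)
    }
    expr
}

# Deterministic sub-seed derivation: any sub-result of a seeded computation
# can be reproduced in isolation from (seed, stream index).
subSeed <- function(seed, stream) {
    (seed * 69069 + stream * 1013) %% 2147483647L
}

# Tukey five-number summary with type-7 quartiles; whiskers at the most
# extreme observations within 1.5*IQR of the quartiles.
tukeySummary <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo.fence <- q[1] - 1.5 * iqr
    hi.fence <- q[3] + 1.5 * iqr
    inside <- x >= lo.fence & x <= hi.fence
    list(whisker_lo = min(x[inside]), q1 = q[1], median = q[2], q3 = q[3],
         whisker_hi = max(x[inside]), n_outliers = sum(!inside))
}

# full-precision float formatting used by all text writers (round-trips
# doubles exactly)
formatFloat <- function(x) {
    vapply(x, function(v) {
        if (is.na(v)) return("NA")
        if (v == floor(v) && abs(v) < 1e15) sprintf("%.0f", v)
        else sprintf("%.17g", v)
    }, character(1))
}
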