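#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' ExpressionMatrix: gene-by-sample expression values
#'
#' A \linkS4class{SummarizedExperiment} carrying one assay \code{"exprs"} of
#' nonnegative expression values (raw counts or counts-per-million) together
#' with per-sample annotations (age, treatment, dose, replicate) in
#' \code{colData}. The measurement unit is tracked in
#' \code{metadata(x)$unit} and queried with \code{\link{exprsUnit}}.
#'
#' @slot .  inherits all slots from SummarizedExperiment
#' @seealso \code{\link{ExpressionMatrix}}, \code{\link{cpmNormalize}}
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
    msg <- NULL
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        v <- SummarizedExperiment::assay(object, "exprs")
        if (anyNA(v))
            msg <- c(msg, "expression values must not contain missing entries")
        else if (any(v < 0))
            msg <- c(msg, "expression values must be nonnegative")
    }
    unit <- S4Vectors::metadata(object)$unit
    if (is.null(unit) || !unit %in% c("raw_count", "cpm"))
        msg <- c(msg, "metadata unit must be 'raw_count' or 'cpm'")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be unique")
    if (identical(unit, "cpm")) {
        cs <- colSums(SummarizedExperiment::assay(object, "exprs"))
        if (any(abs(cs - 1e6) > 1e-9 * 1e6))
            msg <- c(msg, "cpm columns must sum to 1e6 within relative tolerance 1e-9")
    }
    if (is.null(msg)) TRUE else msg
})

#' YoungReference: per-gene young-adult reference expression
#'
#' Stores the young-reference expression profile used as the denominator of
#' transcriptional drift, its construction method and provenance. Two
#' construction methods exist: \code{"pooled_mean"} averages all reference-age
#' replicates (robust, but the reference-age group becomes self-referential
#' and must not enter statistical tests) and \code{"holdout"} sets aside
#' named samples as the reference, excluding them from all downstream
#' drift-variance groups.
#'
#' @slot refExpression named numeric, per-gene reference expression (cpm scale)
#' @slot method character, \code{"pooled_mean"} or \code{"holdout"}
#' @slot refAge numeric, the reference age (in the annotation's age unit)
#' @slot sourceSamples character, sample ids the reference was built from
#' @slot holdoutExcluded logical, TRUE when sourceSamples must be dropped
#'   from all downstream analyses
#' @slot minSourceExpression named numeric, per-gene minimum expression over
#'   the source samples (drives the min-detection filter in
#'   \code{\link{computeDrift}})
#' @export
setClass("YoungReference",
    representation(refExpression = "numeric", method = "character",
                   refAge = "numeric", sourceSamples = "character",
                   holdoutExcluded = "logical", minSourceExpression = "numeric"))

setValidity("YoungReference", function(object) {
    msg <- NULL
    if (!object@method %in% c("pooled_mean", "holdout"))
        msg <- c(msg, "method must be 'pooled_mean' or 'holdout'")
    if (is.null(names(object@refExpression)))
        msg <- c(msg, "refExpression must be named by gene id")
    if (any(object@refExpression < 0))
        msg <- c(msg, "reference expression must be nonnegative")
    if (length(object@holdoutExcluded) != 1L)
        msg <- c(msg, "holdoutExcluded must be a single flag")
    if (is.null(msg)) TRUE else msg
})

#' DriftMatrix: gene-by-sample transcriptional drift values
#'
#' A \linkS4class{SummarizedExperiment} with one assay \code{"td"} holding
#' per-gene log fold-changes relative to a \linkS4class{YoungReference}.
#' Provenance (reference, log base, pseudocount) lives in \code{metadata};
#' samples that entered a pooled-mean reference are flagged
#' \code{selfReferential} in \code{colData} and are barred from statistical
#' tests downstream.
#'
#' @seealso \code{\link{computeDrift}}, \code{\link{driftVariance}}
#' @export
setClass("DriftMatrix", contains = "SummarizedExperiment")

setValidity("DriftMatrix", function(object) {
    msg <- NULL
    if (!"td" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'td' is required")
    else if (!all(is.finite(SummarizedExperiment::assay(object, "td"))))
        msg <- c(msg, "td values must be finite (check pseudocount/filter policy)")
    md <- S4Vectors::metadata(object)
    if (is.null(md$logBase) || !md$logBase %in% c(2, exp(1), 10))
        msg <- c(msg, "metadata logBase must be one of 2, e, 10")
    if (is.null(md$pseudocount) || md$pseudocount < 0)
        msg <- c(msg, "metadata pseudocount must be a nonnegative number")
    if (!is(md$reference, "YoungReference"))
        msg <- c(msg, "metadata reference must be a YoungReference")
    if (!"selfReferential" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must carry a selfReferential flag")
    if (is.null(msg)) TRUE else msg
})

#' GeneSet: a named collection of gene identifiers
#'
#' @slot name character, set name
#' @slot geneIds character, unique member gene ids (nonempty)
#' @slot source character, provenance (GMT description field or generator tag)
#' @export
setClass("GeneSet",
    representation(name = "character", geneIds = "character", source = "character"))

setValidity("GeneSet", function(object) {
    msg <- NULL
    if (length(object@geneIds) == 0L) msg <- c(msg, "gene set must be nonempty")
    if (anyDuplicated(object@geneIds)) msg <- c(msg, "gene ids must be unique within a set")
    if (is.null(msg)) TRUE else msg
})

#' LifeTable: death-time records for one cohort
#'
#' Per-animal death days plus optional right-censoring days. The cohort size
#' is the number of deaths plus the number of censored animals.
#'
#' @slot cohortId character, cohort label
#' @slot deathDays numeric, one nonnegative day per dead animal
#' @slot censoredDays numeric, one nonnegative day per censored animal
#' @export
setClass("LifeTable",
    representation(cohortId = "character", deathDays = "numeric",
                   censoredDays = "numeric"))

setValidity("LifeTable", function(object) {
    msg <- NULL
    if (any(object@deathDays < 0) || any(object@censoredDays < 0))
        msg <- c(msg, "all days must be nonnegative")
    if (anyNA(object@deathDays) || anyNA(object@censoredDays))
        msg <- c(msg, "days must not be missing")
    if (is.null(msg)) TRUE else msg
})

#' GompertzModel: parametric mortality model h(t) = A * exp(G * t)
#'
#' Canonical demographic Gompertz hazard with baseline hazard \code{A}
#' (1/day, > 0) and exponential rate \code{G} (1/day, >= 0). Survival is
#' S(t) = exp(-(A/G) (e^{Gt} - 1)); G = 0 degenerates to the exponential
#' distribution with hazard A.
#'
#' @slot A numeric, baseline hazard (1/day)
#' @slot G numeric, exponential rate of mortality (1/day)
#' @slot fitMeta list, fit provenance (method, n animals, log-likelihood)
#' @seealso \code{\link{fitGompertz}}, \code{\link{simulateCohort}}
#' @export
setClass("GompertzModel",
    representation(A = "numeric", G = "numeric", fitMeta = "list"))

setValidity("GompertzModel", function(object) {
    msg <- NULL
    if (length(object@A) != 1L || !is.finite(object@A) || object@A <= 0)
        msg <- c(msg, "A must be a single positive number")
    if (length(object@G) != 1L || !is.finite(object@G) || object@G < 0)
        msg <- c(msg, "G must be a single nonnegative number")
    if (is.null(msg)) TRUE else msg
})
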