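# accessor methods and show methods for the lightweight S4 classes

#' @rdname YoungReference
#' @export
setMethod("refExpression", "YoungReference", function(x) x@refExpression)

#' @rdname YoungReference
#' @export
setMethod("refMethod", "YoungReference", function(x) x@method)

#' @rdname YoungReference
#' @export
setMethod("sourceSamples", "YoungReference", function(x) x@sourceSamples)

setMethod("show", "YoungReference", function(object) {
    cat("YoungReference (method ", object@method, ", age ", object@refAge,
        "): ", length(object@refExpression), " genes, built from ",
        length(object@sourceSamples), " sample(s)",
        if (object@holdoutExcluded) " [held out downstream]", "\n", sep = "")
})

#' @rdname DriftMatrix
#' @export
setMethod("tdMatrix", "DriftMatrix",
          function(x) SummarizedExperiment::assay(x, "td"))

#' @rdname DriftMatrix
#' @export
setMethod("logBase", "DriftMatrix",
          function(x) S4Vectors::metadata(x)$logBase)

#' @rdname DriftMatrix
#' @export
setMethod("pseudocount", "DriftMatrix",
          function(x) S4Vectors::metadata(x)$pseudocount)

#' @rdname DriftMatrix
#' @export
setMethod("reference", "DriftMatrix",
          function(x) S4Vectors::metadata(x)$reference)

setMethod("show", "DriftMatrix", function(object) {
    cat("DriftMatrix:", nrow(object), "genes x", ncol(object), "samples",
        "(log base", format(logBase(object)),
        ", pseudocount", pseudocount(object), ")\n")
    nsr <- sum(SummarizedExperiment::colData(object)$selfReferential)
    if (nsr) cat(" ", nsr, "self-referential sample(s) barred from tests\n")
    callNextMethod()
})

#' Construct a GeneSet
#' @param name set name
#' @param geneIds character vector of member gene ids (deduplicated)
#' @param source provenance string
#' @return a \linkS4class{GeneSet}
#' @export
GeneSet <- function(name, geneIds, source = "") {
    geneIds <- as.character(geneIds)
    if (anyDuplicated(geneIds)) {
        warning("duplicated gene id(s) in set '", name, "'; deduplicated")
        geneIds <- unique(geneIds)
    }
    new("GeneSet", name = as.character(name), geneIds = geneIds,
        source = as.character(source))
}

#' @rdname GeneSet
#' @export
setMethod("geneIds", "GeneSet", function(x) x@geneIds)

#' @rdname GeneSet
#' @export
setMethod("setName", "GeneSet", function(x) x@name)

setMethod("show", "GeneSet", function(object) {
    cat("GeneSet '", object@name, "': ", length(object@geneIds),
        " genes (source: ", object@source, ")\n", sep = "")
})

#' Construct a LifeTable
#' @param cohortId cohort label
#' @param deathDays numeric vector, one death day per dead animal
#' @param censoredDays numeric vector, right-censoring days (optional)
#' @param nTotal optional declared cohort size; must equal
#'   \code{length(deathDays) + length(censoredDays)} when given
#' @return a \linkS4class{LifeTable}
#' @export
LifeTable <- function(cohortId, deathDays, censoredDays = numeric(0),
                      nTotal = NULL) {
    if (!is.null(nTotal) &&
        nTotal != length(deathDays) + length(censoredDays))
        stop("declared n_total (", nTotal, ") does not match ",
             length(deathDays), " deaths + ", length(censoredDays),
             " censored in cohort '", cohortId, "'")
    new("LifeTable", cohortId = as.character(cohortId),
        deathDays = as.numeric(deathDays),
        censoredDays = as.numeric(censoredDays))
}

#' @rdname LifeTable
#' @export
setMethod("deathDays", "LifeTable", function(x) x@deathDays)

#' @rdname LifeTable
#' @export
setMethod("censoredDays", "LifeTable", function(x) x@censoredDays)

#' @rdname LifeTable
#' @export
setMethod("nTotal", "LifeTable",
          function(x) length(x@deathDays) + length(x@censoredDays))

#' @rdname LifeTable
#' @export
setMethod("cohortId", "LifeTable", function(x) x@cohortId)

setMethod("show", "LifeTable", function(object) {
    cat("LifeTable '", object@cohortId, "': ", length(object@deathDays),
        " deaths, ", length(object@censoredDays), " censored",
        if (length(object@deathDays))
            sprintf(", mean death day %.1f", mean(object@deathDays)),
        "\n", sep = "")
})

#' Construct a GompertzModel
#' @param A baseline hazard (1/day), positive
#' @param G exponential rate (1/day), nonnegative
#' @param fitMeta list of fit provenance
#' @return a \linkS4class{GompertzModel}
#' @export
GompertzModel <- function(A, G, fitMeta = list()) {
    new("GompertzModel", A = as.numeric(A), G = as.numeric(G),
        fitMeta = fitMeta)
}

#' @rdname GompertzModel
#' @export
setMethod("hazardA", "GompertzModel", function(x) x@A)

#' @rdname GompertzModel
#' @export
setMethod("hazardG", "GompertzModel", function(x) x@G)

setMethod("show", "GompertzModel", function(object) {
    cat(sprintf("GompertzModel: h(t) = %.4g * exp(%.4g t) [1/day]\n",
                object@A, object@G))
    cat(sprintf("  mean lifespan %.2f days\n", gompertzMeanLifespan(object)))
    if (length(object@fitMeta))
        cat("  fit:", paste(names(object@fitMeta),
                            vapply(object@fitMeta, format, ""),
                            sep = "=", collapse = ", "), "\n")
})
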