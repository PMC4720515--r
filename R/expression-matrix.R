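#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes x samples, nonnegative, with unique
#'   row (gene) and column (sample) names.
#' @param unit \code{"raw_count"} or \code{"cpm"}.
#' @param annotations optional data.frame of sample annotations with a
#'   \code{sample_id} column (plus \code{age}, \code{age_unit},
#'   \code{treatment}, \code{replicate}, optional \code{dose},
#'   \code{dose_unit}); matched to columns by \code{sample_id}.
#' @return an \linkS4class{ExpressionMatrix}
#' @examples
#' m <- matrix(rpois(12, 50), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' em <- ExpressionMatrix(m)
#' exprsUnit(em)
#' @export
ExpressionMatrix <- function(values, unit = c("raw_count", "cpm"),
                             annotations = NULL) {
    unit <- match.arg(unit)
    values <- as.matrix(values)
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("expression matrix must have gene row names and sample column names")
    cd <- S4Vectors::DataFrame(row.names = colnames(values))
    if (!is.null(annotations)) {
        annotations <- as.data.frame(annotations)
        if (!"sample_id" %in% colnames(annotations))
            stop("annotations must have a 'sample_id' column")
        miss <- setdiff(colnames(values), annotations$sample_id)
        if (length(miss))
            stop("no annotation for sample(s): ", paste(miss, collapse = ", "))
        if (anyDuplicated(annotations$sample_id))
            stop("duplicated sample_id in annotations")
        idx <- match(colnames(values), annotations$sample_id)
        cd <- S4Vectors::DataFrame(annotations[idx, , drop = FALSE],
                                   row.names = colnames(values))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values), colData = cd,
        metadata = list(unit = unit))
    new("ExpressionMatrix", se)
}

#' @rdname ExpressionMatrix
#' @export
setMethod("exprsUnit", "ExpressionMatrix",
          function(x) S4Vectors::metadata(x)$unit)

#' Extract the expression values of an ExpressionMatrix
#' @param x an \linkS4class{ExpressionMatrix}
#' @return numeric matrix, genes x samples
#' @export
exprsValues <- function(x) {
    stopifnot(is(x, "ExpressionMatrix"))
    SummarizedExperiment::assay(x, "exprs")
}

setMethod("show", "ExpressionMatrix", function(object) {
    cat("ExpressionMatrix:", nrow(object), "genes x", ncol(object),
        "samples [", exprsUnit(object), "]\n")
    callNextMethod()
})

#' Depth-normalize raw counts to counts-per-million
#'
#' Divides each sample column by its total count and scales to one million,
#' so every column of the result sums to 1e6. No gene-length correction is
#' applied: drift compares the same gene across ages, never different genes
#' within a sample.
#'
#' @param m an \linkS4class{ExpressionMatrix} with unit \code{"raw_count"}
#' @return an \linkS4class{ExpressionMatrix} with unit \code{"cpm"}
#' @examples
#' m <- matrix(c(10, 30, 20, 20), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' cpmNormalize(ExpressionMatrix(m))
#' @export
cpmNormalize <- function(m) {
    stopifnot(is(m, "ExpressionMatrix"))
    if (exprsUnit(m) != "raw_count")
        stop("cpmNormalize expects raw counts, got unit '", exprsUnit(m), "'")
    v <- exprsValues(m)
    cs <- colSums(v)
    if (any(cs == 0))
        stop("all-zero sample column(s): ",
             paste(colnames(v)[cs == 0], collapse = ", "))
    out <- sweep(v, 2, cs, "/") * 1e6
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = out),
        colData = SummarizedExperiment::colData(m),
        metadata = list(unit = "cpm"))
    new("ExpressionMatrix", se)
}
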