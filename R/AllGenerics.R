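#' @rdname ExpressionMatrix
#' @param x an object
#' @export
setGeneric("exprsUnit", function(x) standardGeneric("exprsUnit"))

#' @rdname DriftMatrix
#' @param x an object
#' @export
setGeneric("tdMatrix", function(x) standardGeneric("tdMatrix"))

#' @rdname DriftMatrix
#' @export
setGeneric("logBase", function(x) standardGeneric("logBase"))

#' @rdname DriftMatrix
#' @export
setGeneric("pseudocount", function(x) standardGeneric("pseudocount"))

#' @rdname DriftMatrix
#' @export
setGeneric("reference", function(x) standardGeneric("reference"))

#' @rdname YoungReference
#' @param x an object
#' @export
setGeneric("refExpression", function(x) standardGeneric("refExpression"))

#' @rdname YoungReference
#' @export
setGeneric("refMethod", function(x) standardGeneric("refMethod"))

#' @rdname YoungReference
#' @export
setGeneric("sourceSamples", function(x) standardGeneric("sourceSamples"))

#' @rdname GeneSet
#' @param x an object
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneSet
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))

#' @rdname LifeTable
#' @param x an object
#' @export
setGeneric("deathDays", function(x) standardGeneric("deathDays"))

#' @rdname LifeTable
#' @export
setGeneric("censoredDays", function(x) standardGeneric("censoredDays"))

#' @rdname LifeTable
#' @export
setGeneric("nTotal", function(x) standardGeneric("nTotal"))

#' @rdname LifeTable
#' @export
setGeneric("cohortId", function(x) standardGeneric("cohortId"))

#' @rdname GompertzModel
#' @param x an object
#' @export
setGeneric("hazardA", function(x) standardGeneric("hazardA"))

#' @rdname GompertzModel
#' @export
setGeneric("hazardG", function(x) standardGeneric("hazardG"))
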