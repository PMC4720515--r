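#' Read a gene-by-sample count matrix
#'
#' Reads raw counts from delimited text (gene ids in the first column, sample
#' ids in the header row) or from a MatrixMarket file with
#' \code{genes.txt}/\code{samples.txt} sidecars (one id per line, in matrix
#' order). Malformed input is rejected, never coerced: duplicate gene ids,
#' negative values and ragged rows raise errors that name the offending
#' gene/sample/line.
#'
#' @param path file to read (for \code{format = "mtx"}, the .mtx file; the
#'   sidecars are looked up next to it)
#' @param format \code{"tsv"}, \code{"csv"} or \code{"mtx"}
#' @param annotations optional sample annotation data.frame (see
#'   \code{\link{ExpressionMatrix}}) or a path readable by
#'   \code{\link{readSampleAnnotations}}
#' @return an \linkS4class{ExpressionMatrix} with unit \code{"raw_count"};
#'   row and column order preserved from file
#' @seealso \code{\link{writeCounts}}, \code{\link{cpmNormalize}}
#' @export
readCounts <- function(path, format = c("tsv", "csv", "mtx"),
                       annotations = NULL) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "mtx") {
        m <- as.matrix(Matrix::readMM(path))
        gfile <- file.path(dirname(path), "genes.txt")
        sfile <- file.path(dirname(path), "samples.txt")
        if (!file.exists(gfile) || !file.exists(sfile))
            stop("mtx input requires sidecar files genes.txt and samples.txt ",
                 "next to ", path)
        rownames(m) <- readLines(gfile)
        colnames(m) <- readLines(sfile)
        values <- m
    } else {
        sep <- if (format == "tsv") "\t" else ","
        nf <- utils::count.fields(path, sep = sep, quote = "\"",
                                  comment.char = "")
        if (length(unique(nf)) > 1L) {
            bad <- which(nf != nf[1])[1]
            stop("ragged row in ", path, ": line ", bad, " has ", nf[bad],
                 " fields, expected ", nf[1])
        }
        df <- utils::read.table(path, sep = sep, header = TRUE,
                                check.names = FALSE, comment.char = "",
                                stringsAsFactors = FALSE)
        ids <- as.character(df[[1]])
        if (anyDuplicated(ids))
            stop("duplicate gene id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
        values <- as.matrix(df[, -1, drop = FALSE])
        if (!is.numeric(values))
            stop("non-numeric expression values in ", path)
        rownames(values) <- ids
    }
    if (anyNA(values)) {
        w <- which(is.na(values), arr.ind = TRUE)[1, ]
        stop("missing value at gene ", rownames(values)[w[1]], ", sample ",
             colnames(values)[w[2]])
    }
    if (any(values < 0)) {
        w <- which(values < 0, arr.ind = TRUE)[1, ]
        stop("negative value (", values[w[1], w[2]], ") at gene ",
             rownames(values)[w[1]], ", sample ", colnames(values)[w[2]])
    }
    if (is.character(annotations)) annotations <- readSampleAnnotations(annotations)
    ExpressionMatrix(values, unit = "raw_count", annotations = annotations)
}

#' Write a count/expression matrix to delimited text
#'
#' Values are written with \code{\%.17g} formatting (integers without a
#' decimal point), so text round trips reproduce doubles bit-identically.
#'
#' @param m an \linkS4class{ExpressionMatrix} or numeric matrix
#' @param path output file
#' @param format \code{"tsv"} or \code{"csv"}
#' @export
writeCounts <- function(m, path, format = c("tsv", "csv")) {
    format <- match.arg(format)
    v <- if (is(m, "ExpressionMatrix")) exprsValues(m) else as.matrix(m)
    sep <- if (format == "tsv") "\t" else ","
    txt <- apply(v, 2, formatFloat)
    if (is.null(dim(txt))) txt <- matrix(txt, nrow = nrow(v))
    out <- cbind(gene_id = rownames(v), txt)
    colnames(out) <- c("gene_id", colnames(v))
    utils::write.table(out, path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read sample annotations
#'
#' TSV with required columns \code{sample_id}, \code{age}, \code{age_unit},
#' \code{treatment}, \code{replicate}; optional \code{dose},
#' \code{dose_unit}. The age unit must be uniform within one table (no
#' automatic unit conversion is performed).
#'
#' @param path TSV file
#' @return data.frame of annotations
#' @export
readSampleAnnotations <- function(path) {
    ann <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    need <- c("sample_id", "age", "age_unit", "treatment", "replicate")
    miss <- setdiff(need, colnames(ann))
    if (length(miss))
        stop("annotation file missing column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(ann$sample_id))
        stop("duplicated sample_id in ", path)
    if (length(unique(ann$age_unit)) > 1L)
        stop("age unit must be uniform within one analysis, found: ",
             paste(unique(ann$age_unit), collapse = ", "))
    if (any(ann$age < 0)) stop("negative age in ", path)
    ann
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#' The description field is retained as the set source. Duplicated ids
#' within a line are deduplicated with a warning; lines with fewer than
#' three fields are rejected.
#'
#' @param path GMT file
#' @return named list of \linkS4class{GeneSet}
#' @seealso \code{\link{writeGeneSets}}
#' @export
readGeneSets <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- lapply(seq_along(lines), function(i) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(f) < 3L)
            stop("GMT line ", i, " has ", length(f),
                 " fields; need name, description and at least one gene id")
        GeneSet(name = f[1], geneIds = f[-(1:2)], source = f[2])
    })
    names(sets) <- vapply(sets, setName, "")
    sets
}

#' @rdname readGeneSets
#' @param sets list of \linkS4class{GeneSet}
#' @export
writeGeneSets <- function(sets, path) {
    lines <- vapply(sets, function(s)
        paste(c(s@name, if (nzchar(s@source)) s@source else ".", s@geneIds),
              collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}

#' Read life tables
#'
#' Two dialects: \code{per_animal} rows are (cohort, day, status) with
#' status \code{dead} or \code{censored}; \code{per_day_counts} rows are
#' (cohort, day, n_dead, n_censored) and are expanded to per-animal records.
#'
#' @param path TSV file with a header row
#' @param dialect \code{"per_animal"} or \code{"per_day_counts"}
#' @return named list of \linkS4class{LifeTable}, one per cohort
#' @seealso \code{\link{writeLifeTable}}
#' @export
readLifeTable <- function(path, dialect = c("per_animal", "per_day_counts")) {
    dialect <- match.arg(dialect)
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    if (any(df$day < 0)) stop("negative day in ", path)
    if (dialect == "per_animal") {
        need <- c("cohort", "day", "status")
        if (!all(need %in% colnames(df)))
            stop("per_animal life table needs columns cohort, day, status")
        bad <- setdiff(unique(df$status), c("dead", "censored"))
        if (length(bad)) stop("unknown status value(s): ",
                              paste(bad, collapse = ", "))
        out <- lapply(split(df, df$cohort), function(d)
            LifeTable(d$cohort[1], d$day[d$status == "dead"],
                      d$day[d$status == "censored"]))
    } else {
        need <- c("cohort", "day", "n_dead", "n_censored")
        if (!all(need %in% colnames(df)))
            stop("per_day_counts life table needs columns cohort, day, ",
                 "n_dead, n_censored")
        if (any(df$n_dead < 0) || any(df$n_censored < 0))
            stop("negative count in ", path)
        out <- lapply(split(df, df$cohort), function(d)
            LifeTable(d$cohort[1], rep(d$day, d$n_dead),
                      rep(d$day, d$n_censored)))
    }
    out[order(names(out))]
}

#' Write life tables
#' @param tables a \linkS4class{LifeTable} or list of them
#' @param path output TSV
#' @param dialect output dialect (see \code{\link{readLifeTable}})
#' @export
writeLifeTable <- function(tables, path,
                           dialect = c("per_animal", "per_day_counts")) {
    dialect <- match.arg(dialect)
    if (is(tables, "LifeTable")) tables <- list(tables)
    rows <- do.call(rbind, lapply(tables, function(lt) {
        d <- data.frame(cohort = cohortId(lt),
                        day = c(deathDays(lt), censoredDays(lt)),
                        status = rep(c("dead", "censored"),
                                     c(length(deathDays(lt)),
                                       length(censoredDays(lt)))))
        d
    }))
    if (dialect == "per_day_counts") {
        agg <- stats::aggregate(cbind(n_dead = status == "dead",
                                      n_censored = status == "censored") ~
                                cohort + day, data = rows, FUN = sum)
        rows <- agg[order(agg$cohort, agg$day), ]
    }
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
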