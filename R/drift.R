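#' Build a young reference expression profile
#'
#' Transcriptional drift measures each gene against the expression of young
#' adults. Two construction methods are supported. \code{"pooled_mean"}
#' averages all replicates at the reference age, gene by gene; the resulting
#' reference-age drift-variance is artificially small (circular referencing)
#' so those samples are flagged self-referential and barred from statistical
#' tests downstream. \code{"holdout"} sets aside one or several reference-age
#' samples as the reference only; they are excluded from every downstream
#' drift group, so the remaining reference-age replicates show a real
#' drift-variance.
#'
#' @param m an \linkS4class{ExpressionMatrix} with unit \code{"cpm"} and age
#'   annotations in \code{colData}
#' @param refAge the reference age (same unit as the annotations)
#' @param method \code{"pooled_mean"} or \code{"holdout"}
#' @param holdoutIds sample ids to hold out (method \code{"holdout"}); when
#'   \code{NULL}, the first reference-age sample in column order is chosen
#'   deterministically
#' @return a \linkS4class{YoungReference}
#' @examples
#' sim <- generateTranscriptome(syntheticConfig(nGenes = 50, seed = 1))
#' cpm <- cpmNormalize(sim$expression)
#' buildYoungReference(cpm, refAge = 1)
#' @export
buildYoungReference <- function(m, refAge,
                                method = c("pooled_mean", "holdout"),
                                holdoutIds = NULL) {
    method <- match.arg(method)
    stopifnot(is(m, "ExpressionMatrix"))
    if (exprsUnit(m) != "cpm")
        stop("young reference is built on cpm data; run cpmNormalize first")
    cd <- SummarizedExperiment::colData(m)
    if (!"age" %in% colnames(cd))
        stop("colData must carry an 'age' column")
    atRef <- colnames(m)[cd$age == refAge]
    if (!length(atRef)) stop("no sample at reference age ", refAge)
    if (method == "pooled_mean") {
        src <- atRef
        excluded <- FALSE
    } else {
        if (is.null(holdoutIds)) holdoutIds <- atRef[1]
        bad <- setdiff(holdoutIds, atRef)
        if (length(bad))
            stop("holdout sample(s) not at reference age ", refAge, ": ",
                 paste(bad, collapse = ", "))
        src <- holdoutIds
        excluded <- TRUE
    }
    v <- exprsValues(m)[, src, drop = FALSE]
    new("YoungReference",
        refExpression = rowMeans(v), method = method,
        refAge = as.numeric(refAge), sourceSamples = src,
        holdoutExcluded = excluded,
        minSourceExpression = apply(v, 1, min))
}

#' Compute per-gene transcriptional drift
#'
#' Drift of gene g in sample s is the log fold-change of its cpm against the
#' young reference: \code{td = log_b((cpm + pc) / (ref + pc))}. Genes failing
#' the min-detection filter (reference expression of zero in any reference
#' replicate, by default) are dropped, not imputed; the pseudocount guards
#' residual zeros at later ages. Under a pooled-mean reference the reference
#' samples are retained but flagged self-referential; under a holdout
#' reference they are removed entirely.
#'
#' @param m an \linkS4class{ExpressionMatrix} with unit \code{"cpm"}
#' @param ref a \linkS4class{YoungReference}
#' @param logBase 2 (default), \code{exp(1)} or 10; changing base rescales
#'   every td by a constant, leaving all variance-comparison p-values
#'   unchanged
#' @param pseudocount nonnegative cpm offset added to numerator and
#'   denominator (default 0.5)
#' @param minDetection drop genes whose minimum expression across the
#'   reference source samples is below this (default \code{.Machine$double.xmin},
#'   i.e. "nonzero in all reference replicates")
#' @return a \linkS4class{DriftMatrix}
#' @examples
#' sim <- generateTranscriptome(syntheticConfig(nGenes = 50, seed = 1))
#' cpm <- cpmNormalize(sim$expression)
#' ref <- buildYoungReference(cpm, refAge = 1)
#' computeDrift(cpm, ref)
#' @export
computeDrift <- function(m, ref, logBase = 2, pseudocount = 0.5,
                         minDetection = .Machine$double.xmin) {
    stopifnot(is(m, "ExpressionMatrix"), is(ref, "YoungReference"))
    if (exprsUnit(m) != "cpm") stop("computeDrift expects cpm data")
    if (!logBase %in% c(2, exp(1), 10)) stop("logBase must be 2, e or 10")
    if (pseudocount < 0) stop("pseudocount must be nonnegative")
    shared <- intersect(rownames(m), names(refExpression(ref)))
    if (!length(shared))
        stop("no genes shared between matrix and reference")
    keep <- shared[ref@minSourceExpression[shared] >= minDetection]
    if (pseudocount == 0)
        keep <- keep[refExpression(ref)[keep] > 0]
    if (!length(keep))
        stop("no genes left after the min-detection filter")
    cols <- colnames(m)
    if (ref@holdoutExcluded) cols <- setdiff(cols, sourceSamples(ref))
    if (!length(cols)) stop("all samples are held out as reference")
    v <- exprsValues(m)[keep, cols, drop = FALSE]
    td <- log((v + pseudocount) / (refExpression(ref)[keep] + pseudocount),
              base = logBase)
    cd <- SummarizedExperiment::colData(m)[cols, , drop = FALSE]
    cd$selfReferential <- !ref@holdoutExcluded &
        rownames(cd) %in% sourceSamples(ref)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(td = td), colData = cd,
        metadata = list(logBase = logBase, pseudocount = pseudocount,
                        reference = ref,
                        nGenesDropped = length(shared) - length(keep)))
    new("DriftMatrix", se)
}

# resolve a grouping specification into a named character vector
# sample -> group; `groups` may be a named vector or colData column names
resolveGroups <- function(d, groups) {
    cd <- SummarizedExperiment::colData(d)
    if (is.character(groups) && all(groups %in% colnames(cd))) {
        lab <- do.call(paste, c(lapply(groups, function(g) cd[[g]]),
                                sep = "_"))
        stats::setNames(lab, rownames(cd))
    } else {
        if (is.null(names(groups)))
            stop("groups must be colData column names or a named vector")
        miss <- setdiff(colnames(d), names(groups))
        if (length(miss))
            stop("no group for sample(s): ", paste(miss, collapse = ", "))
        stats::setNames(as.character(groups[colnames(d)]), colnames(d))
    }
}

#' Pooled drift values per sample group
#'
#' Pools the td values of all member samples of each group over the selected
#' genes. These vectors feed \code{\link{driftVariance}} and
#' \code{\link{robustLevene}}.
#'
#' @param d a \linkS4class{DriftMatrix}
#' @param groups either colData column name(s) (group label pasted from
#'   them, e.g. \code{c("age", "treatment")}) or a named character vector
#'   mapping sample id to group label
#' @param geneSet optional \linkS4class{GeneSet} restricting the gene
#'   universe
#' @param includeSelfReferential keep groups containing self-referential
#'   samples (default TRUE; they are flagged, not dropped, by
#'   \code{\link{driftVariance}})
#' @return named list of numeric td vectors, with a logical
#'   \code{"selfReferential"} attribute per group
#' @export
driftValues <- function(d, groups, geneSet = NULL,
                        includeSelfReferential = TRUE) {
    stopifnot(is(d, "DriftMatrix"))
    map <- resolveGroups(d, groups)
    td <- tdMatrix(d)
    if (!is.null(geneSet)) {
        g <- intersect(geneIds(geneSet), rownames(td))
        if (!length(g))
            stop("gene set '", setName(geneSet),
                 "' has no overlap with the drift gene universe")
        td <- td[g, , drop = FALSE]
    }
    sr <- SummarizedExperiment::colData(d)$selfReferential
    names(sr) <- colnames(d)
    out <- lapply(split(names(map), map), function(ids)
        as.vector(td[, ids, drop = FALSE]))
    flag <- vapply(split(names(map), map),
                   function(ids) any(sr[ids]), logical(1))
    if (!includeSelfReferential) {
        out <- out[!flag]; flag <- flag[!flag]
    }
    attr(out, "selfReferential") <- flag
    out
}

#' Drift-variance per sample group
#'
#' For each group, pools the td values of its member samples over the
#' selected genes and returns the sample variance (n-1 denominator) over
#' all n values, the mean td, and a Tukey five-number summary (type-7
#' quartiles; whiskers at the most extreme points within 1.5 IQR).
#' Outliers are counted for plotting but are NEVER removed from the
#' variance, which is always computed over all values. Groups containing
#' samples that constituted a pooled-mean reference are flagged
#' self-referential: their variance is biased low and must not be used in
#' statistical comparisons.
#'
#' @inheritParams driftValues
#' @return data.frame with one row per group: \code{group},
#'   \code{n_samples}, \code{n_genes}, \code{n} (pooled values),
#'   \code{mean_td}, \code{variance}, \code{whisker_lo}, \code{q1},
#'   \code{median}, \code{q3}, \code{whisker_hi}, \code{n_outliers},
#'   \code{self_referential}
#' @examples
#' sim <- generateTranscriptome(syntheticConfig(nGenes = 200, seed = 1))
#' cpm <- cpmNormalize(sim$expression)
#' d <- computeDrift(cpm, buildYoungReference(cpm, 1))
#' driftVariance(d, groups = c("age", "treatment"))
#' @export
driftVariance <- function(d, groups, geneSet = NULL) {
    vals <- driftValues(d, groups, geneSet)
    flag <- attr(vals, "selfReferential")
    map <- resolveGroups(d, groups)
    nsamp <- vapply(split(names(map), map), length, integer(1))
    ngene <- if (is.null(geneSet)) nrow(d)
             else length(intersect(geneIds(geneSet), rownames(d)))
    rows <- lapply(names(vals), function(g) {
        x <- vals[[g]]
        tk <- tukeySummary(x)
        data.frame(group = g, n_samples = nsamp[[g]], n_genes = ngene,
                   n = length(x), mean_td = mean(x), variance = stats::var(x),
                   whisker_lo = tk$whisker_lo, q1 = tk$q1,
                   median = tk$median, q3 = tk$q3,
                   whisker_hi = tk$whisker_hi, n_outliers = tk$n_outliers,
                   self_referential = flag[[g]])
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Assign samples to age bins
#'
#' Half-open binning: age a falls in bin \code{[e_i, e_{i+1})}; ages at or
#' above the last edge fall in an overflow bin \code{[e_k, Inf)}. Ages below
#' the first edge are an error, never silently dropped.
#'
#' @param ages named numeric vector of sample ages (names are sample ids),
#'   or an annotation data.frame with \code{sample_id} and \code{age}
#' @param binEdges strictly increasing numeric vector of bin lower edges
#' @return named character vector mapping sample id to bin label
#' @examples
#' binSamples(c(a = 13, b = 26, c = 35), binEdges = c(0, 30, 60))
#' @export
binSamples <- function(ages, binEdges) {
    if (is.data.frame(ages))
        ages <- stats::setNames(ages$age, ages$sample_id)
    if (is.unsorted(binEdges, strictly = TRUE))
        stop("binEdges must be strictly increasing")
    if (any(ages < binEdges[1]))
        stop("age(s) below the first bin edge: ",
             paste(names(ages)[ages < binEdges[1]], collapse = ", "))
    k <- length(binEdges)
    labels <- c(if (k > 1) sprintf("[%g,%g)", binEdges[-k], binEdges[-1]),
                sprintf("[%g,Inf)", binEdges[k]))
    idx <- findInterval(ages, binEdges)  # half-open [e_i, e_{i+1})
    stats::setNames(labels[idx], names(ages))
}

#' Partition genes into disjoint random subsets
#'
#' Draws \code{nSets} pairwise-disjoint gene sets of exactly
#' \code{setSize} genes each, without replacement, reproducibly from a
#' seed. Used to test whether drift is transcriptome-wide: disjoint
#' subsamples of a genuinely global signal show indistinguishable
#' drift-variance trajectories.
#'
#' @param geneIds character vector of available gene ids
#' @param nSets number of sets
#' @param setSize genes per set
#' @param seed integer seed
#' @return list of \linkS4class{GeneSet}
#' @export
subsampleGenes <- function(geneIds, nSets, setSize, seed) {
    if (nSets * setSize > length(geneIds))
        stop("need ", nSets * setSize, " genes but only ",
             length(geneIds), " available")
    picked <- withSeed(seed, sample(geneIds, nSets * setSize))
    lapply(seq_len(nSets), function(i)
        GeneSet(sprintf("subsample_%02d", i),
                picked[((i - 1) * setSize + 1):(i * setSize)],
                source = sprintf("subsampleGenes(seed=%d)", seed)))
}

#' Leading log fold-change sample distances and MDS
#'
#' For each pair of samples the distance is the root-mean-square of the
#' \code{topN} largest absolute log2 fold-changes between the pair (the
#' "leading" log fold-changes); classical metric scaling of the resulting
#' distance matrix gives sample coordinates. Coordinates are defined only up
#' to orthogonal transformation; compare distance matrices, not raw
#' coordinates.
#'
#' @param m an \linkS4class{ExpressionMatrix} with unit \code{"cpm"}
#' @param topN number of leading genes per pair (default 500); if larger
#'   than the gene universe, all genes are used with a warning
#' @param nDims dimensions of the scaling (default 2)
#' @param pseudocount cpm offset guarding zeros (default 0.5)
#' @return list with \code{coordinates} (samples x nDims matrix) and
#'   \code{distances} (symmetric zero-diagonal matrix)
#' @export
leadingLogFCMDS <- function(m, topN = 500, nDims = 2, pseudocount = 0.5) {
    stopifnot(is(m, "ExpressionMatrix"))
    if (exprsUnit(m) != "cpm") stop("leadingLogFCMDS expects cpm data")
    if (ncol(m) < 3) stop("need at least 3 samples")
    if (topN < 1) stop("topN must be >= 1")
    v <- exprsValues(m)
    if (topN > nrow(v)) {
        warning("topN (", topN, ") exceeds the gene universe (", nrow(v),
                "); using all genes")
        topN <- nrow(v)
    }
    lg <- log2(v + pseudocount)
    ns <- ncol(v)
    dmat <- matrix(0, ns, ns, dimnames = list(colnames(v), colnames(v)))
    for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
        fc <- abs(lg[, i] - lg[, j])
        top <- sort(fc, decreasing = TRUE)[seq_len(topN)]
        dmat[i, j] <- dmat[j, i] <- sqrt(mean(top^2))
    }
    coords <- stats::cmdscale(stats::as.dist(dmat), k = nDims)
    list(coordinates = coords, distances = dmat)
}

#' Tidy drift-plot summary table
#'
#' Arranges \code{\link{driftVariance}} results into the archival table a
#' drift plot (Tukey boxes over group variance) is drawn from.
#'
#' @param results data.frame from \code{\link{driftVariance}}, or a list of
#'   such data.frames (rbind-ed)
#' @param path optional TSV output path (full-precision formatting)
#' @return the tidy data.frame, invisibly when written to \code{path}
#' @export
driftPlotTable <- function(results, path = NULL) {
    if (is.list(results) && !is.data.frame(results))
        results <- do.call(rbind, results)
    if (!nrow(results)) stop("empty results")
    cols <- c("group", "n_samples", "n_genes", "n", "mean_td", "variance",
              "whisker_lo", "q1", "median", "q3", "whisker_hi",
              "n_outliers", "self_referential")
    out <- results[, intersect(cols, colnames(results)), drop = FALSE]
    if (!is.null(path)) {
        txt <- out
        num <- vapply(txt, is.numeric, logical(1)) &
            !vapply(txt, is.integer, logical(1))
        txt[num] <- lapply(txt[num], formatFloat)
        utils::write.table(txt, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        return(invisible(out))
    }
    out
}
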