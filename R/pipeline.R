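#' Run the transcriptional-drift pipeline from a declarative configuration
#'
#' Orchestrates the full analysis: load counts and annotations, depth
#' normalization, young-reference construction, drift computation,
#' drift-variance tables per group (and per gene set), robust Levene
#' comparisons, optional attenuation classification and MDS, writing tidy
#' TSV outputs plus a machine-readable provenance record. A rerun from the
#' stored configuration (identical inputs and seeds) reproduces every
#' output bit-identically.
#'
#' @param config a named list or a YAML file path. Recognized fields:
#'   \describe{
#'     \item{counts, annotations}{input paths (or in-memory
#'       \linkS4class{ExpressionMatrix} / data.frame)}
#'     \item{counts_format}{"tsv", "csv" or "mtx" (default "tsv")}
#'     \item{ref_age, ref_method, holdout_ids}{young-reference spec
#'       (default: minimum age, "pooled_mean")}
#'     \item{log_base, pseudocount}{drift parameters (defaults 2, 0.5)}
#'     \item{group_by}{annotation columns defining drift groups (default
#'       \code{c("age", "treatment")})}
#'     \item{gene_sets}{optional GMT path or list of \linkS4class{GeneSet}}
#'     \item{comparisons}{list of 2-vectors of group labels for Levene
#'       tests; default: one omnibus test over all testable groups.
#'       Self-referential groups are refused (circular referencing)}
#'     \item{trim_fraction}{Levene trim (default 0.10)}
#'     \item{attenuation}{optional list(control =, treated =) of treatment
#'       labels, plus optional ages and rule, for per-gene attenuation
#'       calls}
#'     \item{mds_top_n}{leading-logFC MDS gene count (default 500; set
#'       NULL to skip MDS)}
#'     \item{out_dir}{output directory (required)}
#'   }
#' @return invisible list with every computed object (\code{drift},
#'   \code{variance}, \code{levene}, \code{attenuation}, \code{mds},
#'   \code{provenance}); TSV/JSON files under \code{out_dir}
#' @export
runDriftPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- utils::modifyList(list(
        counts_format = "tsv", ref_method = "pooled_mean",
        holdout_ids = NULL, log_base = 2, pseudocount = 0.5,
        group_by = c("age", "treatment"), gene_sets = NULL,
        comparisons = NULL, trim_fraction = 0.10, attenuation = NULL,
        mds_top_n = 500, out_dir = NULL), config)
    if (is.null(cfg$out_dir)) stop("config must name an out_dir")
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    log <- list()
    note <- function(stage, ...) {
        msg <- paste0(...)
        message("[", stage, "] ", msg)
        log[[length(log) + 1]] <<- list(stage = stage, message = msg)
    }

    em <- if (is(cfg$counts, "ExpressionMatrix")) cfg$counts
          else readCounts(cfg$counts, cfg$counts_format, cfg$annotations)
    note("load", nrow(em), " genes x ", ncol(em), " samples")
    if (exprsUnit(em) == "raw_count") em <- cpmNormalize(em)

    if (is.null(cfg$ref_age))
        cfg$ref_age <- min(SummarizedExperiment::colData(em)$age)
    ref <- buildYoungReference(em, cfg$ref_age, cfg$ref_method,
                               cfg$holdout_ids)
    d <- computeDrift(em, ref, logBase = cfg$log_base,
                      pseudocount = cfg$pseudocount)
    dropped <- S4Vectors::metadata(d)$nGenesDropped
    note("drift", nrow(d), " genes used, ", dropped,
         " dropped by min-detection filter; ",
         sum(SummarizedExperiment::colData(d)$selfReferential),
         " self-referential sample(s)")
    utils::write.table(
        data.frame(gene_id = rownames(d),
                   apply(tdMatrix(d), 2, formatFloat),
                   check.names = FALSE),
        file.path(cfg$out_dir, "td.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)

    sets <- cfg$gene_sets
    if (is.character(sets)) sets <- readGeneSets(sets)
    dv <- driftVariance(d, cfg$group_by)
    dv$gene_set <- "all"
    for (s in sets) {
        x <- driftVariance(d, cfg$group_by, geneSet = s)
        x$gene_set <- setName(s)
        dv <- rbind(dv, x)
    }
    driftPlotTable(dv[, setdiff(colnames(dv), "gene_set")],
                   file.path(cfg$out_dir, "drift_variance.tsv"))
    note("variance", nrow(dv), " group rows")

    vals <- driftValues(d, cfg$group_by)
    sr <- attr(vals, "selfReferential")
    comparisons <- cfg$comparisons
    if (is.null(comparisons) && sum(!sr) >= 2)
        comparisons <- list(names(vals)[!sr])
    levene <- NULL
    for (cmp in comparisons) {
        miss <- setdiff(cmp, names(vals))
        if (length(miss)) stop("unknown group(s): ",
                               paste(miss, collapse = ", "))
        bad <- cmp[sr[cmp]]
        if (length(bad))
            stop("group(s) ", paste(bad, collapse = ", "),
                 " contain pooled-mean reference samples and cannot enter ",
                 "variance tests (circular referencing); use a holdout ",
                 "reference instead")
        lt <- robustLevene(vals[cmp], trimFraction = cfg$trim_fraction)
        levene <- rbind(levene, data.frame(
            groups = paste(cmp, collapse = " vs "),
            W = unname(lt$statistic), df1 = lt$parameter[["df1"]],
            df2 = lt$parameter[["df2"]], p_value = lt$p.value))
    }
    if (!is.null(levene)) {
        utils::write.table(levene, file.path(cfg$out_dir, "levene.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        note("levene", nrow(levene), " comparison(s)")
    }

    atten <- NULL
    if (!is.null(cfg$attenuation)) {
        cd <- SummarizedExperiment::colData(d)
        pick <- function(lab) d[, cd$treatment == lab]
        atten <- classifyAttenuation(
            pick(cfg$attenuation$control), pick(cfg$attenuation$treated),
            ages = cfg$attenuation$ages,
            rule = if (is.null(cfg$attenuation$rule)) "mean_abs_td"
                   else cfg$attenuation$rule)
        utils::write.table(
            data.frame(gene_id = names(atten$calls),
                       attenuated = unname(atten$calls)),
            file.path(cfg$out_dir, "attenuation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(
            list(k = atten$k, n = atten$n, p_value = atten$p.value,
                 rule = atten$rule, ages = atten$ages),
            file.path(cfg$out_dir, "attenuation_summary.json"),
            auto_unbox = TRUE, digits = NA)
        note("attenuation", atten$k, "/", atten$n, " genes attenuated")
    }

    mds <- NULL
    if (!is.null(cfg$mds_top_n)) {
        mds <- leadingLogFCMDS(em, topN = cfg$mds_top_n)
        utils::write.table(
            data.frame(sample_id = rownames(mds$coordinates),
                       mds$coordinates),
            file.path(cfg$out_dir, "mds.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
        note("mds", "coordinates for ", nrow(mds$coordinates), " samples")
    }

    provenance <- list(
        package = "txdrift",
        version = as.character(utils::packageVersion("txdrift")),
        config = cfg[setdiff(names(cfg), c("counts", "annotations"))],
        genes_used = nrow(d), genes_dropped = dropped,
        self_referential_samples =
            colnames(d)[SummarizedExperiment::colData(d)$selfReferential],
        log = log)
    jsonlite::write_json(provenance,
                         file.path(cfg$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(list(expression = em, reference = ref, drift = d,
                   variance = dv, levene = levene, attenuation = atten,
                   mds = mds, provenance = provenance))
}

# recipe registry: required files (with a description of what each is) and
# the preset applied on top of the standard pipeline
recipeRegistry <- list(
    fig2a = list(
        files = c(counts = "counts.tsv", annotations = "annotations.tsv"),
        what = paste("whole-transcriptome drift plot of the water/mianserin",
                     "aging time course (RNA-seq gene expression source",
                     "data); pooled-mean day-1 reference")),
    fig2b = list(
        files = c(counts = "counts.tsv", annotations = "annotations.tsv"),
        what = paste("day-5 drift-variance as a function of mianserin dose;",
                     "annotations need a 'dose' column")),
    fig2d = list(
        files = c(counts = "counts.tsv", annotations = "annotations.tsv"),
        what = paste("day-10 drift-variance as a function of the age at",
                     "which treatment started (treatment labels encode the",
                     "start day)")),
    fig2g = list(
        files = c(ch1 = "murphy_ch1netmean.tsv",
                  ch2 = "murphy_ch2normalizednetmean.tsv",
                  annotations = "murphy_annotations.tsv"),
        what = paste("two-channel microarray aging time course (Princeton",
                     "PUMA database download): expression =",
                     "ch1netmean / ch2normalizednetmean, 8h young",
                     "reference per RNAi treatment, hours binned to days")),
    fig7a = list(
        files = c(counts = "mouse_counts.tsv",
                  annotations = "mouse_annotations.tsv"),
        what = paste("mouse multi-tissue aging expression; two ages pooled",
                     "per age bin (weeks); annotations need a 'tissue'",
                     "column")),
    fig7c = list(
        files = c(counts = "human_counts.tsv",
                  annotations = "human_annotations.tsv"),
        what = paste("human frontal-cortex aging expression; holdout",
                     "reference from samples aged 25-29 years, 20-year",
                     "age bins")))

#' Run a preset drift-analysis recipe on externally supplied data
#'
#' Thin declarative presets over \code{\link{runDriftPipeline}} encoding
#' the reference construction, binning and grouping of the published
#' drift-plot analyses. The external datasets are NOT bundled; a missing
#' file raises an error naming every required file and what it must
#' contain.
#'
#' @param which recipe id: \code{"fig2a"}, \code{"fig2b"}, \code{"fig2d"},
#'   \code{"fig2g"}, \code{"fig7a"} or \code{"fig7c"}
#' @param dataDir directory holding the recipe's input files
#' @param outDir output directory (default: \code{<dataDir>/<which>_out})
#' @return the \code{\link{runDriftPipeline}} result (or a list of them for
#'   per-tissue/per-treatment recipes)
#' @export
reproduceRecipe <- function(which = names(recipeRegistry), dataDir,
                            outDir = NULL) {
    which <- match.arg(which)
    rec <- recipeRegistry[[which]]
    paths <- file.path(dataDir, rec$files)
    names(paths) <- names(rec$files)
    missing <- !file.exists(paths)
    if (any(missing))
        stop("recipe '", which, "' needs file(s) not found in ", dataDir,
             ": ", paste(rec$files[missing], collapse = ", "),
             ". Expected content: ", rec$what)
    if (is.null(outDir)) outDir <- file.path(dataDir, paste0(which, "_out"))
    ann <- readSampleAnnotations(paths[["annotations"]])

    if (which %in% c("fig2a", "fig2b", "fig2d")) {
        base <- list(counts = paths[["counts"]],
                     annotations = ann, out_dir = outDir)
        cfgExtra <- switch(which,
            fig2a = list(group_by = c("age", "treatment")),
            fig2b = list(group_by = "dose"),
            fig2d = list(group_by = "treatment"))
        return(runDriftPipeline(utils::modifyList(base, cfgExtra)))
    }

    if (which == "fig2g") {
        ch1 <- exprsValues(readCounts(paths[["ch1"]]))
        ch2 <- exprsValues(readCounts(paths[["ch2"]]))
        if (!identical(dimnames(ch1), dimnames(ch2)))
            stop("channel matrices must share genes and samples")
        if (any(ch2 <= 0)) stop("ch2normalizednetmean must be positive")
        expr <- ch1 / ch2
        # hours -> day bins: day 0 (8 h), 1 (24 h), 2 (28-52 h),
        # 4 (72-96 h), 6 (144-196 h); half-open edges, checked below
        edges <- c(8, 24, 28, 72, 144)
        if (any(ann$age < edges[1]))
            stop("fig2g expects ages in hours starting at 8 h")
        dayOf <- c(0, 1, 2, 4, 6)[findInterval(ann$age, edges)]
        out <- list()
        for (trt in unique(ann$treatment)) {
            ids <- ann$sample_id[ann$treatment == trt]
            sub <- ann[ann$treatment == trt, ]
            sub$age <- dayOf[match(sub$sample_id, ann$sample_id)]
            em <- ExpressionMatrix(expr[, ids, drop = FALSE],
                                   unit = "raw_count", annotations = sub)
            out[[trt]] <- runDriftPipeline(list(
                counts = em, ref_age = 0, group_by = "age",
                mds_top_n = NULL,
                out_dir = file.path(outDir, gsub("[^A-Za-z0-9_]", "_", trt))))
        }
        return(out)
    }

    counts <- readCounts(paths[["counts"]])
    if (which == "fig7a") {
        if (!"tissue" %in% colnames(ann))
            stop("fig7a annotations need a 'tissue' column")
        bins <- binSamples(stats::setNames(ann$age, ann$sample_id),
                           binEdges = c(0, 30, 60))
        out <- list()
        for (tis in unique(ann$tissue)) {
            ids <- ann$sample_id[ann$tissue == tis]
            sub <- ann[ann$tissue == tis, ]
            sub$bin <- bins[sub$sample_id]
            em <- ExpressionMatrix(exprsValues(counts)[, ids, drop = FALSE],
                                   unit = "raw_count", annotations = sub)
            out[[tis]] <- runDriftPipeline(list(
                counts = em, group_by = "bin", mds_top_n = NULL,
                out_dir = file.path(outDir, tis)))
        }
        return(out)
    }

    # fig7c: holdout reference from samples aged 25-29, 20-year bins
    hold <- ann$sample_id[ann$age >= 25 & ann$age <= 29]
    if (!length(hold))
        stop("fig7c needs reference samples aged 25-29 years")
    ann2 <- ann
    # the reference wants a single nominal age; the held-out samples are
    # excluded downstream so collapsing their ages is inconsequential
    ann2$age[ann2$sample_id %in% hold] <- ann2$age[ann2$sample_id %in% hold][1]
    bins <- binSamples(stats::setNames(ann$age, ann$sample_id),
                       binEdges = seq(20, 100, by = 20))
    ann2$bin <- bins[ann2$sample_id]
    em <- ExpressionMatrix(exprsValues(counts), unit = "raw_count",
                           annotations = ann2)
    runDriftPipeline(list(
        counts = em, ref_age = ann2$age[ann2$sample_id == hold[1]],
        ref_method = "holdout", holdout_ids = hold, group_by = "bin",
        mds_top_n = NULL, out_dir = outDir))
}
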