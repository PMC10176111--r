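#' @importFrom utils write.table read.delim head
NULL

#' Write a count set as TSV (plus library-size sidecar)
#'
#' Emits \code{feature_id} plus one column per sample; a companion
#' \code{<path>.libsizes.tsv} records the per-sample counted-fragment
#' totals.
#'
#' @param x a \linkS4class{TECountSet}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeCountsTSV <- function(x, path) {
    stopifnot(is(x, "TECountSet"))
    df <- data.frame(feature_id = rownames(x), countsMatrix(x),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ls <- data.frame(sample_id = colnames(x),
                     library_size = unname(librarySizes(x)))
    utils::write.table(ls, paste0(path, ".libsizes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a differential-transcription table as TSV
#'
#' Columns: feature_id, base_mean, log2fc, se, wald_z, p_value, p_adj,
#' untested — directly plottable as a volcano (-log10 p against log2fc).
#'
#' @param de a \code{DETable}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeDETable <- function(de, path) {
    utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a gene FeatureSet as GTF
#'
#' Emits one \code{gene} record per gene model and one \code{exon} record
#' per exon, each carrying the \code{gene_id} attribute, so
#' \code{\link{readGeneAnnotation}} round-trips the models.
#'
#' @param genes gene \linkS4class{FeatureSet}.
#' @param path output GTF path.
#' @return \code{path}, invisibly.
#' @export
writeGeneGtf <- function(genes, path) {
    stopifnot(is(genes, "FeatureSet"), featureKind(genes) == "gene")
    gid <- featureIds(genes)
    fmt <- function(chrom, src, type, s, e, strand, id)
        sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
                chrom, src, type, s, e, strand, id)
    lines <- character()
    ex <- mcols(genes)$exons
    for (i in seq_along(genes)) {
        g <- genes[i]
        st <- as.character(strand(g))
        if (st == "*") st <- "."
        lines <- c(lines,
                   fmt(as.character(seqnames(g)), "sim", "gene",
                       start(g), end(g), st, gid[i]))
        e <- ex[[i]]
        if (length(e))
            lines <- c(lines,
                       fmt(as.character(seqnames(e)), "sim", "exon",
                           start(e), end(e), rep(st, length(e)), gid[i]))
    }
    writeLines(lines, path)
    invisible(path)
}

#' Write a density track as bedGraph-style TSV
#'
#' @param density data.frame from \code{\link{binDensity}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDensityTSV <- function(density, path) {
    utils::write.table(density, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Run the full analysis chain on a count bundle
#'
#' Executes the study workflow end to end on per-feature count sets:
#' size-factor normalization, the main histone-replacement contrast and the
#' three methyltransferase-mutant contrasts, the two control contrasts
#' (wild-type batch 1 vs batch 2; control genotype vs wild type), the
#' stringent double-control filter, up-set selection, family-composition
#' chi-square against genome abundance, mutant membership partition,
#' genomic-context classification and piRNA cluster scoring.
#'
#' @param counts list with \code{te}, \code{genes}, \code{precursors}
#'   \linkS4class{TECountSet}s (as produced by
#'   \code{\link{simulateCounts}}, or assembled from
#'   \code{\link{countFeatures}} runs).
#' @param ann annotation bundle (\code{repeats}, \code{genes},
#'   \code{precursors}, \code{clusters}, \code{chromSizes}).
#' @param mainTreatment,mainControl the main contrast (default H3K36R vs
#'   the H3K36K control genotype).
#' @param wt wild-type condition label (must carry two batches).
#' @param mutants mutant conditions contrasted against wild type.
#' @param lfcMin,alpha,useAdjusted selection thresholds (defaults 2, 0.05,
#'   adjusted p).
#' @param expressedMinMean wild-type expression threshold for the context
#'   classification.
#' @return a list with the DE tables, filter reports, up-sets, composition
#'   table, mutant partition, context partition, density tracks and piRNA
#'   cluster summaries.
#' @export
runPipeline <- function(counts, ann,
                        mainTreatment = "H3K36R", mainControl = "H3K36K",
                        wt = "WT",
                        mutants = c("Set2KO", "NSDKO", "ash1KO"),
                        lfcMin = 2, alpha = 0.05, useAdjusted = TRUE,
                        expressedMinMean = 10) {
    te <- counts$te
    cond <- as.character(te$condition)
    batch <- as.character(te$batch)
    ## split the wild type by sequencing batch for the control-runs contrast
    gr_batch <- ifelse(cond == wt, paste0(wt, "_", batch), cond)
    k <- countsMatrix(te)

    deMain <- nbWaldTest(te, mainTreatment, mainControl)
    deMut <- lapply(stats::setNames(mutants, mutants), function(m)
        nbWaldTest(te, m, wt))
    deRuns <- nbWaldTest(k, paste0(wt, "_b1"), paste0(wt, "_b2"),
                         groups = gr_batch)
    deGeno <- nbWaldTest(te, mainControl, wt)

    filt <- controlConsistencyFilter(deMain, deRuns, deGeno,
                                     alpha = alpha,
                                     useAdjusted = useAdjusted)
    filtMut <- lapply(deMut, function(d)
        controlConsistencyFilter(d, deRuns, deGeno, alpha = alpha,
                                 useAdjusted = useAdjusted))

    upMain <- selectUp(filt$filtered, lfcMin, alpha, useAdjusted)
    upMut <- lapply(filtMut, function(f)
        selectUp(f$filtered, lfcMin, alpha, useAdjusted))

    expected <- expectedComposition(ann$repeats, "order")
    comp <- if (length(upMain))
        compositionChiSquare(upMain, ann$repeats, expected, "order")
    else NULL
    part <- partitionByMutants(upMain, upMut)

    ## wild-type gene expression and mutant-activated genes
    kg <- counts$genes
    sfg <- sizeFactorsMedianOfRatios(kg)
    yg <- sweep(countsMatrix(kg), 2L, sfg, "/")
    wtMeans <- rowMeans(yg[, cond == wt, drop = FALSE])
    deGenes <- nbWaldTest(kg, mainTreatment, mainControl)
    upGenes <- selectUp(deGenes, lfcMin, alpha, useAdjusted)
    context <- classifyGenomicContext(upMain, ann$repeats, ann$genes,
                                      wtMeans, upGenes,
                                      expressedMinMean = expressedMinMean)

    density <- if (length(upMain))
        binDensity(upMain, ann$repeats, ann$chromSizes)
    else NULL

    ## Precursor normalization uses size factors from the gene counts:
    ## nearly every precursor lies in a perturbed cluster, so factors
    ## estimated on the precursor matrix itself would absorb the signal.
    sfp <- sfg[match(colnames(counts$precursors), colnames(kg))]
    clusterTable <- summarizeClusters(counts$precursors, ann$precursors,
                                      ann$clusters, control = wt, sf = sfp)
    modes <- compareClusterTypes(clusterTable, control = wt)

    list(de = c(list(main = deMain, control_runs = deRuns,
                     control_genotype = deGeno), deMut),
         filter = c(list(main = filt$report),
                    lapply(filtMut, `[[`, "report")),
         up = c(list(main = upMain), upMut),
         composition = comp,
         partition = part,
         context = context,
         density = density,
         clusters = clusterTable,
         cluster_modes = modes,
         gene_de = deGenes,
         wt_gene_means = wtMeans)
}
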