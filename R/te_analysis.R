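#' @importFrom stats chisq.test pchisq
NULL

#' Stringent double-control consistency filter
#'
#' Removes from a differential-transcription table every feature that is
#' significantly changed in either of two control comparisons: (i) between
#' two independently sequenced wild-type batches and (ii) between a control
#' genotype and wild type. A feature significant (chosen p < \code{alpha},
#' optionally with an absolute log2 fold-change floor) in the union of the
#' two control contrasts is excluded from the main table, so that apparent
#' mutant effects that already differ between controls never enter
#' downstream selection.
#'
#' @param main \code{DETable} for the contrast of interest.
#' @param controlRuns \code{DETable} for wild-type batch 1 vs batch 2.
#' @param controlGenotypes \code{DETable} for control genotype vs wild type.
#' @param alpha significance threshold applied to the control contrasts.
#' @param useAdjusted use BH-adjusted p (default) or raw p.
#' @param lfcFloor optional absolute log2FC floor a control change must also
#'   exceed to trigger removal (default 0 = significance alone).
#' @return list with \code{filtered} (the main table restricted to
#'   consistent features) and \code{report} (removed ids, per-criterion
#'   counts, thresholds).
#' @export
controlConsistencyFilter <- function(main, controlRuns, controlGenotypes,
                                     alpha = 0.05, useAdjusted = TRUE,
                                     lfcFloor = 0) {
    pcol <- if (useAdjusted) "p_adj" else "p_value"
    uni <- intersect(main$feature_id,
                     intersect(controlRuns$feature_id,
                               controlGenotypes$feature_id))
    if (!length(uni)) stop("empty intersection of feature universes")
    if (length(uni) < max(nrow(main), nrow(controlRuns),
                          nrow(controlGenotypes)))
        warning("feature universes differ; intersecting")
    sig <- function(de) {
        de <- de[match(uni, de$feature_id), ]
        !de$untested & de[[pcol]] < alpha & abs(de$log2fc) >= lfcFloor
    }
    bad_runs <- sig(controlRuns)
    bad_geno <- sig(controlGenotypes)
    removed <- uni[bad_runs | bad_geno]
    filtered <- main[main$feature_id %in% setdiff(uni, removed), ]
    attr(filtered, "treatment") <- attr(main, "treatment")
    attr(filtered, "control") <- attr(main, "control")
    class(filtered) <- class(main)
    list(filtered = filtered,
         report = list(removed = removed,
                       n_removed = length(removed),
                       n_control_runs = sum(bad_runs),
                       n_control_genotypes = sum(bad_geno),
                       alpha = alpha, use_adjusted = useAdjusted,
                       lfc_floor = lfcFloor))
}

#' Observed-vs-expected repeat composition chi-square
#'
#' Compares the class composition of an up-regulated repeat set against the
#' genome-abundance expectation (goodness-of-fit), or two observed
#' compositions against each other (two-sample contingency mode, used e.g.
#' to compare mutant-specific activation profiles). Classes are repeat
#' orders or families.
#'
#' @param up character vector of up-regulated feature ids (or an object
#'   with such ids), resolvable in \code{repeats}.
#' @param repeats \linkS4class{FeatureSet} of kind \code{"repeat"}.
#' @param expected expected composition as returned by
#'   \code{\link{expectedComposition}} (columns \code{class},
#'   \code{expected_fraction}).
#' @param level \code{"order"} or \code{"family"}.
#' @param up2 optional second up-set: when given, a standard two-sample
#'   contingency chi-square between the two observed class vectors is
#'   performed and \code{expected} is ignored.
#' @return a list of class \code{CompositionTable} with the class labels,
#'   expected and observed fractions, \code{n_observed}, \code{chi2_stat},
#'   \code{df} and \code{p_value}.
#' @export
compositionChiSquare <- function(up, repeats, expected = NULL,
                                 level = c("order", "family"), up2 = NULL) {
    level <- match.arg(level)
    stopifnot(is(repeats, "FeatureSet"), featureKind(repeats) == "repeat")
    classOf <- function(ids) {
        idx <- match(as.character(ids), featureIds(repeats))
        if (anyNA(idx))
            stop("up-set feature(s) not in the repeat annotation: ",
                 paste(utils::head(ids[is.na(idx)], 5L), collapse = ", "))
        as.character(mcols(repeats)[[level]])[idx]
    }
    obs_cls <- classOf(up)
    if (!is.null(up2)) {
        cls2 <- classOf(up2)
        lev <- sort(unique(c(obs_cls, cls2)))
        tab <- rbind(table(factor(obs_cls, lev)), table(factor(cls2, lev)))
        ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        out <- list(classes = lev,
                    observed_fraction = as.numeric(table(factor(obs_cls, lev))) /
                        length(obs_cls),
                    observed_fraction_2 = as.numeric(table(factor(cls2, lev))) /
                        length(cls2),
                    n_observed = length(obs_cls), n_observed_2 = length(cls2),
                    chi2_stat = unname(ht$statistic),
                    df = unname(ht$parameter),
                    p_value = unname(ht$p.value))
        class(out) <- "CompositionTable"
        return(out)
    }
    stopifnot(is.data.frame(expected))
    lev <- expected$class
    O <- as.numeric(table(factor(obs_cls, lev)))
    extra <- setdiff(unique(obs_cls), lev)
    if (length(extra))
        stop("observed class(es) missing from the expected table: ",
             paste(extra, collapse = ", "))
    e <- expected$expected_fraction
    if (any(e == 0 & O > 0))
        stop("class universe mismatch: zero expectation with observations in ",
             paste(lev[e == 0 & O > 0], collapse = ", "))
    n <- length(obs_cls)
    keep <- e > 0
    if (any(n * e[keep] < 5))
        warning("expected count below 5 in some class(es); chi-square ",
                "approximation may be poor")
    ht <- suppressWarnings(stats::chisq.test(O[keep], p = e[keep] / sum(e[keep])))
    out <- list(classes = lev,
                expected_fraction = e,
                observed_fraction = O / n,
                n_observed = n,
                chi2_stat = unname(ht$statistic),
                df = unname(ht$parameter),
                p_value = unname(ht$p.value))
    class(out) <- "CompositionTable"
    out
}

#' @export
print.CompositionTable <- function(x, ...) {
    cat(sprintf("CompositionTable: n = %d, chi2 = %.4g (df = %d), p = %.3g\n",
                x$n_observed, x$chi2_stat, x$df, x$p_value))
    df <- data.frame(class = x$classes, observed = x$observed_fraction)
    if (!is.null(x$expected_fraction)) df$expected <- x$expected_fraction
    print(df, ...)
    invisible(x)
}

#' Partition a base up-set by mutant membership
#'
#' Assigns each feature of a base up-set (e.g. the repeats activated in the
#' histone-replacement mutant) its exact membership signature over a set of
#' methyltransferase-mutant up-sets, yielding the 2^m disjoint classes
#' (including \code{"none"} and the full intersection). For three mutants
#' the single and pairwise class labels follow the \code{"A"},
#' \code{"A + B"} convention.
#'
#' @param base character vector of base-set feature ids.
#' @param perMutant named list of character vectors, one up-set per mutant.
#' @return list of class \code{MutantPartition} with \code{membership}
#'   (logical matrix base x mutants), \code{class_of} (label per feature)
#'   and \code{counts} (named integer vector over all 2^m classes; sums to
#'   \code{length(base)}).
#' @export
partitionByMutants <- function(base, perMutant) {
    stopifnot(is.list(perMutant), !is.null(names(perMutant)))
    base <- as.character(base)
    mut <- names(perMutant)
    mem <- vapply(perMutant, function(s) base %in% as.character(s),
                  logical(length(base)))
    if (is.null(dim(mem))) mem <- matrix(mem, nrow = length(base))
    dimnames(mem) <- list(base, mut)
    labelOf <- function(row) {
        inn <- mut[row]
        if (!length(inn)) "none" else paste(inn, collapse = " + ")
    }
    class_of <- apply(mem, 1L, labelOf)
    ## enumerate all 2^m classes so counts are total
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(mut)))
    all_labels <- apply(as.matrix(combos), 1L, labelOf)
    counts <- stats::setNames(integer(length(all_labels)), all_labels)
    tab <- table(class_of)
    counts[names(tab)] <- as.integer(tab)
    out <- list(membership = mem, class_of = class_of, counts = counts)
    class(out) <- "MutantPartition"
    out
}

#' @export
print.MutantPartition <- function(x, ...) {
    cat(sprintf("MutantPartition over %d base feature(s):\n",
                nrow(x$membership)))
    print(x$counts, ...)
    invisible(x)
}

#' Classify activated elements by genomic context
#'
#' Partitions an up-regulated repeat set (conventionally restricted to LTR
#' and LINE orders) into \code{intergenic}, \code{expressed_gene} and
#' \code{unexpressed_gene} by >= 1 bp overlap with gene spans; a gene is
#' expressed when its mean normalized wild-type count reaches
#' \code{expressedMinMean}. On ambiguous overlap the priority is
#' expressed gene > unexpressed gene > intergenic. Elements in unexpressed
#' genes are subdivided by whether the host gene is activated in the mutant
#' (member of \code{mutantUpGenes}).
#'
#' @param up character vector of up-set repeat feature ids.
#' @param repeats repeat \linkS4class{FeatureSet}.
#' @param genes gene \linkS4class{FeatureSet}.
#' @param wtMeans named numeric vector of mean normalized wild-type counts
#'   per gene id.
#' @param mutantUpGenes character vector of genes up-regulated in the
#'   mutant.
#' @param expressedMinMean expression threshold (default 10).
#' @param restrictOrders repeat orders kept before classification
#'   (default \code{c("LTR", "LINE")}; \code{NULL} keeps all).
#' @return list of class \code{ContextPartition}: per-element labels,
#'   top-level counts and fractions over {intergenic, expressed_gene,
#'   unexpressed_gene}, and sub-fractions {activated_in_mutant,
#'   silent_in_mutant} within unexpressed genes.
#' @export
classifyGenomicContext <- function(up, repeats, genes, wtMeans,
                                   mutantUpGenes = character(),
                                   expressedMinMean = 10,
                                   restrictOrders = c("LTR", "LINE")) {
    stopifnot(is(repeats, "FeatureSet"), is(genes, "FeatureSet"))
    idx <- match(as.character(up), featureIds(repeats))
    if (anyNA(idx)) stop("up-set feature(s) absent from the repeat annotation")
    te <- repeats[idx]
    if (!is.null(restrictOrders))
        te <- te[mcols(te)$order %in% restrictOrders]
    gid <- featureIds(genes)
    expressed <- gid[!is.na(wtMeans[gid]) & wtMeans[gid] >= expressedMinMean]
    hits <- findOverlaps(te, genes, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    hostExpressed <- gid[sh] %in% expressed
    label <- rep("intergenic", length(te))
    host <- rep(NA_character_, length(te))
    ## priority: expressed > unexpressed > intergenic
    for (i in seq_along(te)) {
        j <- which(qh == i)
        if (!length(j)) next
        if (any(hostExpressed[j])) {
            label[i] <- "expressed_gene"
            host[i] <- sort(gid[sh[j][hostExpressed[j]]])[1L]
        } else {
            label[i] <- "unexpressed_gene"
            host[i] <- sort(gid[sh[j]])[1L]
        }
    }
    sub <- rep(NA_character_, length(te))
    unex <- label == "unexpressed_gene"
    sub[unex] <- ifelse(host[unex] %in% as.character(mutantUpGenes),
                        "activated_in_mutant", "silent_in_mutant")
    lev <- c("intergenic", "expressed_gene", "unexpressed_gene")
    counts <- stats::setNames(as.integer(table(factor(label, lev))), lev)
    sublev <- c("activated_in_mutant", "silent_in_mutant")
    subcounts <- stats::setNames(
        as.integer(table(factor(sub[unex], sublev))), sublev)
    out <- list(feature_id = featureIds(te), label = label, host_gene = host,
                sub_label = sub,
                counts = counts,
                fractions = counts / max(1L, length(te)),
                sub_counts = subcounts,
                sub_fractions = subcounts / max(1L, sum(unex)))
    class(out) <- "ContextPartition"
    out
}

#' @export
print.ContextPartition <- function(x, ...) {
    cat("ContextPartition:\n")
    print(round(x$fractions, 4))
    cat("within unexpressed genes:\n")
    print(round(x$sub_fractions, 4))
    invisible(x)
}

#' Positional density of an up-set along chromosomes
#'
#' Tiles each chromosome with fixed windows and counts up-set features by
#' the window containing their interval midpoint (midpoints exactly on a
#' window boundary belong to the following window, matching the half-open
#' tiling). Used to visualize e.g. pericentromeric concentration of
#' activated elements.
#'
#' @param up character vector of up-set feature ids.
#' @param repeats repeat \linkS4class{FeatureSet}.
#' @param chromSizes named numeric vector of chromosome lengths (bp).
#' @param window window size in bp (default 1e5).
#' @return data.frame (bedgraph-like) with columns \code{chrom},
#'   \code{start}, \code{end}, \code{count}; per-chromosome counts sum to
#'   the number of up-set features there. Features on chromosomes absent
#'   from \code{chromSizes} are skipped with a warning.
#' @export
binDensity <- function(up, repeats, chromSizes, window = 100000L) {
    idx <- match(as.character(up), featureIds(repeats))
    if (anyNA(idx)) stop("up-set feature(s) absent from the repeat annotation")
    te <- repeats[idx]
    chrom <- as.character(seqnames(te))
    known <- chrom %in% names(chromSizes)
    if (any(!known)) {
        warning(sum(!known), " feature(s) on chromosomes absent from ",
                "chromSizes were skipped")
        te <- te[known]; chrom <- chrom[known]
    }
    ## midpoint in 0-based coordinates: floor((start0 + end0_exclusive)/2);
    ## a midpoint landing exactly on k*window belongs to window k
    mid0 <- floor(((start(te) - 1L) + end(te)) / 2)
    out <- lapply(names(chromSizes), function(cn) {
        L <- chromSizes[[cn]]
        nwin <- ceiling(L / window)
        starts <- (seq_len(nwin) - 1L) * window
        w <- floor(mid0[chrom == cn] / window)
        cnt <- table(factor(w, levels = 0:(nwin - 1L)))
        data.frame(chrom = cn, start = starts,
                   end = pmin(starts + window, L),
                   count = as.integer(cnt), stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}
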