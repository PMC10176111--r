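#' Round half away from zero
#'
#' Decimal rounding where ties go away from zero (so 12.65 -> 12.7 at one
#' decimal), the convention that reproduces printed per-cluster fold values
#' from printed per-precursor means. Base R's \code{round} ties to even
#' instead.
#'
#' @param x numeric.
#' @param digits decimal places (default 1).
#' @return rounded numeric.
#' @export
roundHalfAway <- function(x, digits = 1L) {
    m <- 10^digits
    sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Per-precursor mean normalized counts for one condition
#'
#' For each precursor, the mean over a condition's replicates of
#' count / size factor.
#'
#' @param counts \linkS4class{TECountSet} over precursors (or matrix).
#' @param condition condition label.
#' @param sf size factors (default: median-of-ratios over all samples).
#' @param groups per-sample condition labels when \code{counts} is a bare
#'   matrix.
#' @return named numeric vector of per-precursor means.
#' @export
precursorMeans <- function(counts, condition, sf = NULL, groups = NULL) {
    k <- .countsOf(counts)
    if (is.null(groups)) {
        if (!is(counts, "TECountSet"))
            stop("supply 'groups' when counts is a bare matrix")
        groups <- as.character(counts$condition)
    }
    if (!(condition %in% groups)) stop("condition absent: ", condition)
    if (is.null(sf)) sf <- sizeFactorsMedianOfRatios(k)
    y <- sweep(k, 2L, sf, "/")
    rowMeans(y[, groups == condition, drop = FALSE])
}

#' Summarize piRNA-cluster transcription for one condition
#'
#' The cluster score is the mean, over the cluster's assigned precursors,
#' of the per-precursor mean normalized read count, with a t-based 95%
#' confidence interval across precursors (degenerate at n = 1).
#'
#' @param precMeans named per-precursor means from
#'   \code{\link{precursorMeans}}.
#' @param precursors precursor \linkS4class{FeatureSet} with cluster
#'   assignments (see \code{\link{assignPrecursors}}).
#' @param clusters \linkS4class{PiRNAClusterSet}.
#' @param condition condition label recorded in the output.
#' @return data.frame with one row per cluster: \code{cluster_id},
#'   \code{strand_mode}, \code{condition}, \code{n_precursors},
#'   \code{mean_reads_per_precursor}, \code{ci95_low}, \code{ci95_high}.
#'   Clusters with no assigned precursor raise an error.
#' @export
clusterSummary <- function(precMeans, precursors, clusters, condition) {
    stopifnot(is(precursors, "FeatureSet"),
              featureKind(precursors) == "precursor",
              is(clusters, "PiRNAClusterSet"))
    assign <- mcols(precursors)$cluster_id
    rows <- lapply(seq_along(clusters), function(i) {
        cid <- clusterIds(clusters)[i]
        ids <- featureIds(precursors)[!is.na(assign) & assign == cid]
        if (!length(ids))
            stop("cluster without assigned precursors: ", cid)
        v <- precMeans[ids]
        n <- length(v)
        m <- mean(v)
        half <- if (n > 1L) stats::qt(0.975, n - 1L) * stats::sd(v) / sqrt(n)
                else 0
        data.frame(cluster_id = cid,
                   strand_mode = clusterStrandMode(clusters)[i],
                   condition = condition,
                   n_precursors = n,
                   mean_reads_per_precursor = m,
                   ci95_low = m - half, ci95_high = m + half,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Fold change of a cluster mean over the control mean
#'
#' The raw ratio treatment mean / control mean, plus a reported value
#' rounded half-away-from-zero to \code{reportDecimals} places (the
#' convention under which, e.g., printed per-precursor means 38.51 and 3.03
#' yield the printed 12.7-fold increase).
#'
#' @param meanTreatment,meanControl cluster mean normalized reads per
#'   precursor.
#' @param reportDecimals decimals of the reported fold (default 1).
#' @return list with \code{raw} and \code{reported}; \code{reported} is
#'   \code{NA} (flagged undefined) when the control mean is 0.
#' @export
foldOverControl <- function(meanTreatment, meanControl, reportDecimals = 1L) {
    if (any(meanControl == 0)) {
        warning("control mean is zero; fold undefined")
        return(list(raw = NA_real_, reported = NA_real_, undefined = TRUE))
    }
    raw <- meanTreatment / meanControl
    list(raw = raw,
         reported = roundHalfAway(raw, reportDecimals),
         undefined = FALSE)
}

#' Full per-cluster summary table across conditions
#'
#' Convenience wrapper producing, for each cluster and each treatment
#' condition, the cluster mean with CI and its fold over the control
#' condition.
#'
#' @param counts \linkS4class{TECountSet} over precursors.
#' @param precursors assigned precursor \linkS4class{FeatureSet}.
#' @param clusters \linkS4class{PiRNAClusterSet}.
#' @param control control condition label.
#' @param treatments treatment condition labels (default: all non-control
#'   conditions in the count set).
#' @param sf size factors (default median-of-ratios).
#' @return data.frame with one row per (cluster, condition) including the
#'   control itself (fold 1), columns as \code{\link{clusterSummary}} plus
#'   \code{fold_raw} and \code{fold_reported}.
#' @export
summarizeClusters <- function(counts, precursors, clusters, control,
                              treatments = NULL, sf = NULL) {
    if (is.null(sf)) sf <- sizeFactorsMedianOfRatios(counts)
    conds <- unique(as.character(counts$condition))
    if (is.null(treatments)) treatments <- setdiff(conds, control)
    ctrl <- clusterSummary(precursorMeans(counts, control, sf = sf),
                           precursors, clusters, control)
    out <- lapply(c(control, treatments), function(cond) {
        s <- if (cond == control) ctrl
             else clusterSummary(precursorMeans(counts, cond, sf = sf),
                                 precursors, clusters, cond)
        f <- vapply(seq_len(nrow(s)), function(i) {
            m0 <- ctrl$mean_reads_per_precursor[
                ctrl$cluster_id == s$cluster_id[i]]
            if (m0 == 0) NA_real_ else s$mean_reads_per_precursor[i] / m0
        }, numeric(1))
        s$fold_raw <- f
        s$fold_reported <- roundHalfAway(f, 1L)
        s
    })
    do.call(rbind, out)
}

#' Contrast uni- vs dual-strand cluster activation
#'
#' Tabulates per-cluster folds over control by strand mode and reports the
#' per-mode mean fold; no hypothesis test is attached.
#'
#' @param summaries data.frame from \code{\link{summarizeClusters}} (rows
#'   with defined \code{fold_raw}; the control condition rows are ignored).
#' @param control control condition label to drop from the comparison.
#' @return list with \code{per_cluster} (cluster, strand_mode, condition,
#'   fold) and \code{per_mode} (strand_mode, mean_fold, n). Missing strand
#'   modes yield a partial table with a warning.
#' @export
compareClusterTypes <- function(summaries, control = NULL) {
    s <- summaries
    if (!is.null(control)) s <- s[s$condition != control, ]
    s <- s[!is.na(s$fold_raw), ]
    if (!all(c("uni", "dual") %in% s$strand_mode))
        warning("missing strand mode(s): ",
                paste(setdiff(c("uni", "dual"), s$strand_mode),
                      collapse = ", "))
    per_mode <- do.call(rbind, lapply(split(s, s$strand_mode), function(g)
        data.frame(strand_mode = g$strand_mode[1L],
                   mean_fold = mean(g$fold_raw), n = nrow(g),
                   stringsAsFactors = FALSE)))
    rownames(per_mode) <- NULL
    list(per_cluster = s[, c("cluster_id", "strand_mode", "condition",
                             "fold_raw", "fold_reported")],
         per_mode = per_mode)
}
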