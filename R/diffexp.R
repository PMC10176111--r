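#' @importFrom stats median pnorm p.adjust qt sd setNames quantile
NULL

.countsOf <- function(counts) {
    if (is(counts, "TECountSet")) countsMatrix(counts)
    else if (is.matrix(counts)) counts
    else stop("'counts' must be a TECountSet or a matrix")
}

#' Median-of-ratios size factors
#'
#' Computes per-sample scaling factors equalizing sequencing depth and
#' composition: each sample's factor is the median, over features with
#' all-positive counts, of the ratio of its count to the feature's
#' geometric mean across samples. Factors are rescaled to geometric mean 1
#' so that normalized counts stay on the scale of the raw data. If no
#' feature has all-positive counts the function falls back to total-count
#' scaling with a warning.
#'
#' @param counts a \linkS4class{TECountSet} or integer matrix
#'   (features x samples, >= 2 samples).
#' @return named numeric vector of positive size factors, geometric mean 1.
#' @export
sizeFactorsMedianOfRatios <- function(counts) {
    k <- .countsOf(counts)
    if (ncol(k) < 2L) stop("need >= 2 samples")
    ref <- rowSums(k > 0) == ncol(k)
    if (!any(ref)) {
        warning("no feature with all-positive counts; ",
                "falling back to total-count scaling")
        sf <- colSums(k)
        if (any(sf == 0)) stop("sample(s) with zero total counts")
    } else {
        logk <- log(k[ref, , drop = FALSE])
        loggeo <- rowMeans(logk)
        sf <- exp(apply(logk - loggeo, 2L, stats::median))
    }
    sf <- sf / exp(mean(log(sf)))
    stats::setNames(sf, colnames(k))
}

#' Method-of-moments negative-binomial dispersion
#'
#' Estimates a per-feature NB dispersion alpha under the
#' variance = mu + alpha * mu^2 parameterization, from size-factor
#' normalized counts. The within-group (group-mean-centred) pooled variance
#' s2 and the grand mean mu give alpha = (s2 - mu) / mu^2, clipped to
#' [\code{alphaMin}, \code{alphaMax}].
#'
#' @param counts \linkS4class{TECountSet} or matrix.
#' @param sf size factors (see \code{\link{sizeFactorsMedianOfRatios}}).
#' @param groups condition label per sample; at least one group needs >= 2
#'   replicates.
#' @param alphaMin,alphaMax clipping bounds (defaults 1e-8 and 10).
#' @return named numeric vector of per-feature dispersions.
#' @export
estimateDispersionMM <- function(counts, sf, groups,
                                 alphaMin = 1e-8, alphaMax = 10) {
    k <- .countsOf(counts)
    stopifnot(length(sf) == ncol(k), length(groups) == ncol(k))
    groups <- as.character(groups)
    if (max(table(groups)) < 2L)
        stop("all groups are singletons; supply a fixed dispersion instead")
    y <- sweep(k, 2L, sf, "/")
    gmeans <- vapply(unique(groups), function(g)
        rowMeans(y[, groups == g, drop = FALSE]), numeric(nrow(k)))
    if (is.null(dim(gmeans))) gmeans <- matrix(gmeans, nrow = 1L)
    centred <- y - gmeans[, match(groups, unique(groups)), drop = FALSE]
    df <- ncol(y) - length(unique(groups))
    s2 <- rowSums(centred^2) / df
    mu <- rowMeans(y)
    alpha <- ifelse(mu > 0, (s2 - mu) / mu^2, alphaMin)
    stats::setNames(pmin(pmax(alpha, alphaMin), alphaMax), rownames(k))
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' For each feature the treatment and control group means are estimated on
#' size-factor normalized counts; the log2 fold change is
#' \code{log2((mu_t + pc) / (mu_c + pc))} with pseudocount \code{pc}
#' (default 0.5), its standard error comes from the delta method on the NB
#' Fisher information,
#' \deqn{se^2 = (1/\ln 2)^2 [ (1/n_t)(1/\mu_t + \alpha)
#'                          + (1/n_c)(1/\mu_c + \alpha) ],}
#' evaluated with pseudocount-stabilized means, and the Wald statistic
#' \code{log2fc / se} is referred two-sided to a Student t with
#' \code{n_t + n_c - 2} degrees of freedom when the dispersion is estimated
#' from the data (the t absorbs the plug-in noise of the method-of-moments
#' estimate, which a normal reference ignores at small replicate numbers),
#' or to a standard normal when a known dispersion is supplied.
#' Features with zero counts in both groups are reported untested with
#' \code{log2fc = 0} and \code{p = 1}. Benjamini-Hochberg adjustment runs
#' over tested features only.
#'
#' @param counts \linkS4class{TECountSet} or matrix.
#' @param sf size factors; \code{NULL} computes median-of-ratios factors.
#' @param dispersion per-feature dispersions; \code{NULL} estimates them by
#'   method of moments. A single number is recycled.
#' @param treatment,control condition labels (taken from the count set's
#'   \code{condition} column, or from \code{groups}).
#' @param groups explicit per-sample condition labels when \code{counts} is
#'   a bare matrix.
#' @param pseudocount stabilizing constant (default 0.5).
#' @return a \code{DETable}: a data.frame with one row per feature and
#'   columns \code{feature_id}, \code{base_mean}, \code{log2fc}, \code{se},
#'   \code{wald_z}, \code{p_value}, \code{p_adj}, \code{untested}, plus
#'   attributes \code{treatment} and \code{control}.
#' @export
nbWaldTest <- function(counts, treatment, control, sf = NULL,
                       dispersion = NULL, groups = NULL, pseudocount = 0.5) {
    k <- .countsOf(counts)
    if (is.null(groups)) {
        if (!is(counts, "TECountSet"))
            stop("supply 'groups' when counts is a bare matrix")
        groups <- as.character(counts$condition)
    }
    stopifnot(length(groups) == ncol(k))
    if (!(treatment %in% groups)) stop("treatment condition absent: ", treatment)
    if (!(control %in% groups)) stop("control condition absent: ", control)
    sel <- groups %in% c(treatment, control)
    if (is.null(sf)) sf <- sizeFactorsMedianOfRatios(k[, sel, drop = FALSE])
    else sf <- sf[sel]
    dispersionEstimated <- is.null(dispersion)
    if (dispersionEstimated)
        dispersion <- estimateDispersionMM(k[, sel, drop = FALSE], sf,
                                           groups[sel])
    if (length(dispersion) == 1L) dispersion <- rep(dispersion, nrow(k))
    k <- k[, sel, drop = FALSE]
    groups <- groups[sel]
    y <- sweep(k, 2L, sf, "/")
    tt <- groups == treatment
    mu_t <- rowMeans(y[, tt, drop = FALSE])
    mu_c <- rowMeans(y[, !tt, drop = FALSE])
    n_t <- sum(tt); n_c <- sum(!tt)
    untested <- mu_t == 0 & mu_c == 0
    lfc <- log2((mu_t + pseudocount) / (mu_c + pseudocount))
    se2 <- (1 / log(2))^2 * ((1 / n_t) * (1 / (mu_t + pseudocount) + dispersion) +
                             (1 / n_c) * (1 / (mu_c + pseudocount) + dispersion))
    se <- sqrt(se2)
    z <- lfc / se
    p <- if (dispersionEstimated)
        2 * stats::pt(-abs(z), df = n_t + n_c - 2L)
    else 2 * stats::pnorm(-abs(z))
    lfc[untested] <- 0; z[untested] <- 0; p[untested] <- 1
    padj <- rep(1, length(p))
    padj[!untested] <- bhAdjust(p[!untested])
    de <- data.frame(feature_id = rownames(k),
                     base_mean = rowMeans(y),
                     log2fc = lfc, se = se, wald_z = z,
                     p_value = p, p_adj = padj,
                     untested = untested,
                     row.names = NULL, stringsAsFactors = FALSE)
    attr(de, "treatment") <- treatment
    attr(de, "control") <- control
    class(de) <- c("DETable", "data.frame")
    de
}

#' Benjamini-Hochberg adjustment
#'
#' Validated wrapper over \code{stats::p.adjust(method = "BH")}: step-up
#' FDR adjustment with monotone enforcement, preserving input order.
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Select up-regulated features
#'
#' Applies the strict selection \code{log2fc > lfcMin} and (adjusted) p
#' \code{< alpha} — the "log2 fold change > 2 (P < 0.05)" rule used for all
#' up-regulated transposon and precursor sets.
#'
#' @param de a \code{DETable} from \code{\link{nbWaldTest}}.
#' @param lfcMin fold-change floor on the log2 scale (default 2).
#' @param alpha significance threshold (default 0.05).
#' @param useAdjusted compare \code{alpha} against BH-adjusted p (default)
#'   or raw p.
#' @return character vector of selected feature ids, with the thresholds
#'   attached as attributes.
#' @export
selectUp <- function(de, lfcMin = 2, alpha = 0.05, useAdjusted = TRUE) {
    p <- if (useAdjusted) de$p_adj else de$p_value
    sel <- !de$untested & de$log2fc > lfcMin & p < alpha
    out <- de$feature_id[sel]
    attr(out, "lfc_min") <- lfcMin
    attr(out, "alpha") <- alpha
    attr(out, "use_adjusted") <- useAdjusted
    out
}
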