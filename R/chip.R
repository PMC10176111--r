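#' Sample random background regions
#'
#' Draws fixed-width regions uniformly from the genome: the chromosome is
#' chosen proportional to its length and the start uniformly within it.
#' Used as the neutral background class against which feature-class
#' enrichment is compared (the study design uses 10,000 regions of 80 bp).
#' Deterministic under \code{seed}: regenerating with the same seed and
#' chromosome sizes gives identical regions.
#'
#' @param chromSizes named numeric vector of chromosome lengths (bp).
#' @param n number of regions (default 10000).
#' @param width region width in bp (default 80).
#' @param seed integer seed.
#' @return \linkS4class{FeatureSet} of kind \code{"region"} with ids
#'   \code{rand_000001, ...}. Chromosomes shorter than \code{width} are
#'   excluded with a warning; an error is raised if none remain.
#' @export
sampleRandomRegions <- function(chromSizes, n = 10000L, width = 80L, seed) {
    ok <- chromSizes >= width
    if (any(!ok))
        warning("chromosome(s) shorter than the region width excluded: ",
                paste(names(chromSizes)[!ok], collapse = ", "))
    chromSizes <- chromSizes[ok]
    if (!length(chromSizes)) stop("no chromosome can hold a region of width ",
                                  width)
    rs <- .seededRNG(seed)
    on.exit(rs$restore())
    chr <- sample(names(chromSizes), n, replace = TRUE,
                  prob = chromSizes / sum(chromSizes))
    L <- chromSizes[chr]
    ## start uniform on [0, L - width] in 0-based terms -> 1-based start
    start1 <- floor(stats::runif(n, 0, L - width + 1)) + 1L
    gr <- GRanges(chr, IRanges(start1, width = width),
                  feature_id = sprintf("rand_%06d", seq_len(n)))
    FeatureSet(gr, "region")
}

#' ChIP-over-input enrichment ratio per feature
#'
#' Library-size-normalized, pseudocount-guarded ratio
#' \deqn{((chip + pc)/chipLib) / ((input + pc)/inputLib).}
#' Replicate counts are expected to be averaged before the ratio (the
#' study's convention); \code{\link{averageReplicates}} does that.
#'
#' @param chipCounts,inputCounts named per-feature counts (replicate
#'   averages) over a matching universe.
#' @param chipLib,inputLib library totals (> 0).
#' @param pseudocount stabilizer added to both counts (default 0.5).
#' @return named numeric vector of ratios.
#' @export
featureRatio <- function(chipCounts, inputCounts, chipLib, inputLib,
                         pseudocount = 0.5) {
    stopifnot(chipLib > 0, inputLib > 0,
              length(chipCounts) == length(inputCounts))
    if (!is.null(names(chipCounts)) && !is.null(names(inputCounts)) &&
        !identical(names(chipCounts), names(inputCounts)))
        stop("feature universes differ between chip and input")
    ((chipCounts + pseudocount) / chipLib) /
        ((inputCounts + pseudocount) / inputLib)
}

#' Average replicate count columns
#'
#' @param m counts matrix (features x replicates) or list of named vectors.
#' @return named per-feature mean counts.
#' @export
averageReplicates <- function(m) {
    if (is.list(m) && !is.matrix(m)) m <- do.call(cbind, m)
    rowMeans(m)
}

#' Per-class enrichment profile
#'
#' Mean ChIP/input ratio per feature class with a t-based 95% confidence
#' interval across the class's features (not across replicates, matching
#' per-class error bars over thousands of features).
#'
#' @param ratios named per-feature ratios from \code{\link{featureRatio}}.
#' @param classSets named list mapping class label -> feature id vector.
#' @return data.frame with columns \code{class}, \code{n_features},
#'   \code{mean_ratio}, \code{ci95_low}, \code{ci95_high}; empty classes
#'   are omitted with a warning.
#' @export
classProfile <- function(ratios, classSets) {
    stopifnot(is.list(classSets), !is.null(names(classSets)))
    rows <- lapply(names(classSets), function(lbl) {
        ids <- intersect(as.character(classSets[[lbl]]), names(ratios))
        if (!length(ids)) {
            warning("empty class omitted: ", lbl)
            return(NULL)
        }
        v <- ratios[ids]
        n <- length(v); m <- mean(v)
        half <- if (n > 1L) stats::qt(0.975, n - 1L) * stats::sd(v) / sqrt(n)
                else 0
        data.frame(class = lbl, n_features = n, mean_ratio = m,
                   ci95_low = m - half, ci95_high = m + half,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
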