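#' @import methods
#' @import GenomicRanges
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame Rle
#' @importFrom IRanges IRanges findOverlaps pintersect
#' @importFrom BiocGenerics start end width strand
NULL

.FEATURE_KINDS <- c("repeat", "gene", "precursor", "region")

.REPEAT_ORDERS <- c("LTR", "LINE", "DNA", "Simple_repeat", "Satellite",
                    "RC", "Other")

#' FeatureSet: a homogeneous annotation track
#'
#' A \code{FeatureSet} is a \link[GenomicRanges]{GRanges} carrying a
#' homogeneous collection of annotation features of one \code{kind}:
#' \describe{
#'   \item{\code{repeat}}{RepeatMasker-style repeat features with metadata
#'     columns \code{feature_id}, \code{repeat_name}, \code{order} (one of
#'     LTR, LINE, DNA, Simple_repeat, Satellite, RC, Other) and
#'     \code{family}.}
#'   \item{\code{gene}}{gene models with \code{feature_id} (the gene id) and
#'     an \code{exons} column holding a \link[GenomicRanges]{GRangesList} of
#'     exon spans, all within the gene span.}
#'   \item{\code{precursor}}{piRNA precursor intervals with
#'     \code{feature_id} and a \code{cluster_id} column (\code{NA} until
#'     assigned, see \code{\link{assignPrecursors}}).}
#'   \item{\code{region}}{anonymous intervals (e.g. random background
#'     regions) with only \code{feature_id}.}
#' }
#' Because the class extends \code{GRanges}, the usual range machinery
#' (\code{findOverlaps}, \code{subsetByOverlaps}, \code{width}, ...) is the
#' overlap index; no separate structure is kept.
#'
#' @slot kind single string, one of \code{"repeat"}, \code{"gene"},
#'   \code{"precursor"}, \code{"region"}.
#' @seealso \code{\link{FeatureSet}} for the constructor,
#'   \code{\link{readRepeatAnnotation}}, \code{\link{readGeneAnnotation}},
#'   \code{\link{readPiRNAAnnotations}}.
#' @exportClass FeatureSet
setClass("FeatureSet",
         contains = "GRanges",
         representation(kind = "character"),
         prototype(kind = "region"))

setValidity("FeatureSet", function(object) {
    msg <- character()
    if (length(object@kind) != 1L || !(object@kind %in% .FEATURE_KINDS))
        msg <- c(msg, sprintf("kind must be one of: %s",
                              paste(.FEATURE_KINDS, collapse = ", ")))
    ids <- mcols(object)$feature_id
    if (is.null(ids))
        msg <- c(msg, "metadata column 'feature_id' is required")
    else if (anyDuplicated(ids))
        msg <- c(msg, "feature_id values must be unique")
    if (length(object) && any(width(object) < 1L))
        msg <- c(msg, "all features must have width >= 1")
    if (identical(object@kind, "repeat")) {
        ord <- mcols(object)$order
        if (is.null(ord) || is.null(mcols(object)$family) ||
            is.null(mcols(object)$repeat_name))
            msg <- c(msg, "repeat FeatureSet needs repeat_name/order/family")
        else if (!all(ord %in% .REPEAT_ORDERS))
            msg <- c(msg, sprintf("unknown repeat order(s): %s",
                                  paste(unique(setdiff(ord, .REPEAT_ORDERS)),
                                        collapse = ", ")))
    }
    if (identical(object@kind, "gene") && length(object)) {
        ex <- mcols(object)$exons
        if (is.null(ex))
            msg <- c(msg, "gene FeatureSet needs an 'exons' GRangesList column")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a FeatureSet
#'
#' @param gr a \code{GRanges} with the metadata columns required for
#'   \code{kind} (see \linkS4class{FeatureSet}).
#' @param kind one of \code{"repeat"}, \code{"gene"}, \code{"precursor"},
#'   \code{"region"}.
#' @return a \linkS4class{FeatureSet}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr2L", IRanges::IRanges(100, 180),
#'     feature_id = "rep1", repeat_name = "Gypsy-like",
#'     order = "LTR", family = "Gypsy")
#' FeatureSet(gr, "repeat")
#' @export
FeatureSet <- function(gr, kind = c("region", "repeat", "gene", "precursor")) {
    kind <- match.arg(kind)
    if (!is(gr, "GRanges"))
        stop("'gr' must be a GRanges")
    if (is.null(mcols(gr)$feature_id))
        mcols(gr)$feature_id <- if (length(gr)) {
            if (!is.null(names(gr))) names(gr)
            else sprintf("%s_%06d", kind, seq_along(gr))
        } else character()
    if (kind == "precursor" && is.null(mcols(gr)$cluster_id))
        mcols(gr)$cluster_id <- rep(NA_character_, length(gr))
    new("FeatureSet", gr, kind = kind)
}

#' @describeIn FeatureSet kind accessor
#' @param x a FeatureSet
#' @export
featureKind <- function(x) x@kind

#' @describeIn FeatureSet feature identifier accessor
#' @export
featureIds <- function(x) as.character(mcols(x)$feature_id)

setMethod("show", "FeatureSet", function(object) {
    cat(sprintf("FeatureSet of kind '%s' with %d feature(s) on %d sequence(s)\n",
                object@kind, length(object),
                length(GenomeInfoDb::seqlevels(object))))
    callNextMethod()
})

#' PiRNAClusterSet: annotated piRNA cluster loci
#'
#' A \code{GRanges} subclass holding piRNA cluster coordinates with a
#' \code{cluster_id} and a \code{strand_mode} column. \code{strand_mode}
#' distinguishes uni-strand clusters (canonical promoter-driven,
#' single-strand transcription, e.g. 20A and flamenco) from dual-strand
#' clusters (heterochromatin-embedded, Rhino-dependent transcription from
#' both strands, e.g. 42AB and 38C). Cluster intervals may not be nested
#' within each other.
#'
#' @exportClass PiRNAClusterSet
setClass("PiRNAClusterSet", contains = "GRanges")

setValidity("PiRNAClusterSet", function(object) {
    msg <- character()
    mc <- mcols(object)
    if (is.null(mc$cluster_id) || is.null(mc$strand_mode))
        return("cluster_id and strand_mode metadata columns are required")
    if (anyDuplicated(mc$cluster_id))
        msg <- c(msg, "cluster_id values must be unique")
    if (!all(mc$strand_mode %in% c("uni", "dual")))
        msg <- c(msg, "strand_mode must be 'uni' or 'dual'")
    if (length(object) > 1L) {
        hits <- findOverlaps(object, object, type = "within")
        nested <- sum(S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits))
        if (nested > 0L)
            msg <- c(msg, "cluster intervals may not be nested")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PiRNAClusterSet
#'
#' @param gr GRanges with \code{cluster_id} and \code{strand_mode}
#'   (\code{"uni"} or \code{"dual"}) metadata columns.
#' @return a \linkS4class{PiRNAClusterSet}
#' @export
PiRNAClusterSet <- function(gr) new("PiRNAClusterSet", gr)

#' @describeIn PiRNAClusterSet cluster identifier accessor
#' @param x a PiRNAClusterSet
#' @export
clusterIds <- function(x) as.character(mcols(x)$cluster_id)

#' @describeIn PiRNAClusterSet strand mode accessor (uni/dual per cluster)
#' @export
clusterStrandMode <- function(x) as.character(mcols(x)$strand_mode)

setMethod("show", "PiRNAClusterSet", function(object) {
    cat(sprintf("PiRNAClusterSet with %d cluster(s) (%d dual, %d uni)\n",
                length(object), sum(clusterStrandMode(object) == "dual"),
                sum(clusterStrandMode(object) == "uni")))
    callNextMethod()
})

#' TECountSet: per-feature read counts across samples
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} subclass holding one
#' integer assay \code{"counts"} (features x samples) together with sample
#' metadata in \code{colData}: \code{sample_id}, \code{condition},
#' \code{batch}, \code{replicate} and \code{library_size} (the number of
#' retained fragments counted for that sample, an upper bound on any single
#' feature count only in the aggregate sense that counts are drawn from the
#' retained fragments).
#'
#' @seealso \code{\link{buildCountSet}}, \code{\link{countFeatures}}
#' @exportClass TECountSet
setClass("TECountSet", contains = "RangedSummarizedExperiment")

setValidity("TECountSet", function(object) {
    msg <- character()
    if (!("counts" %in% SummarizedExperiment::assayNames(object)))
        return("assay 'counts' is required")
    k <- SummarizedExperiment::assay(object, "counts")
    if (any(k < 0))
        msg <- c(msg, "counts must be non-negative")
    cd <- SummarizedExperiment::colData(object)
    need <- c("sample_id", "condition", "batch", "replicate", "library_size")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, sprintf("colData is missing: %s",
                              paste(miss, collapse = ", ")))
    else {
        key <- paste(cd$condition, cd$batch, cd$replicate)
        if (anyDuplicated(key))
            msg <- c(msg, "(condition, batch, replicate) must be unique")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "TECountSet", function(object) {
    cat(sprintf("TECountSet: %d feature(s) x %d sample(s); conditions: %s\n",
                nrow(object), ncol(object),
                paste(unique(object$condition), collapse = ", ")))
    callNextMethod()
})

#' Counted-fragment totals per sample
#'
#' @param x a \linkS4class{TECountSet}
#' @return named numeric vector of retained-fragment totals
#' @export
librarySizes <- function(x) {
    stats::setNames(x$library_size, colnames(x))
}

#' The integer count assay of a TECountSet
#'
#' @param x a \linkS4class{TECountSet}
#' @return integer matrix, features x samples
#' @export
countsMatrix <- function(x) SummarizedExperiment::assay(x, "counts")
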