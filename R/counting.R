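#' @importFrom Rsamtools asBam ScanBamParam scanBamFlag BamFile
#' @importFrom GenomicAlignments readGAlignments cigar
NULL

.asBamPath <- function(path) {
    ## Bioconductor BAM readers require BAM; convert text SAM transparently.
    if (tolower(tools::file_ext(path)) == "sam") {
        dest <- tempfile(fileext = "")
        suppressMessages(Rsamtools::asBam(path, dest,
                                          overwrite = TRUE, indexDestination = FALSE))
        paste0(dest, ".bam")
    } else path
}

#' Read alignments from SAM/BAM
#'
#' Returns primary mapped alignments as a \code{GRanges} whose ranges are
#' the CIGAR-derived reference spans (M/D/N/=/X consume reference, so a
#' spliced \code{50M100N50M} alignment spans 200 bp), with metadata columns
#' \code{read_id}, \code{mapq} and \code{mate} (1, 2 or NA for single-end).
#' Unmapped and secondary/supplementary records are dropped here; mapping
#' quality filtering is left to \code{\link{countFeatures}}.
#'
#' @param path SAM or BAM file (SAM is converted on the fly).
#' @return GRanges of primary alignments in file order.
#' @export
readAlignments <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    bam <- .asBamPath(path)
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
    ga <- GenomicAlignments::readGAlignments(
        bam, param = Rsamtools::ScanBamParam(what = c("qname", "mapq", "flag"),
                                             flag = flag))
    gr <- granges(ga)     # full reference span incl. N gaps
    fl <- mcols(ga)$flag
    mate <- ifelse(bitwAnd(fl, 1L) == 0L, NA_integer_,
                   ifelse(bitwAnd(fl, 64L) != 0L, 1L, 2L))
    mcols(gr) <- DataFrame(read_id = mcols(ga)$qname,
                           mapq = mcols(ga)$mapq,
                           mate = mate)
    gr
}

#' Count reads per feature under a mapping-quality filter
#'
#' Implements quantification of uniquely aligned reads within annotation
#' features: alignments with mapping quality below \code{minMapq}
#' (default 1, i.e. mapQ > 0), unmapped or secondary records are excluded;
#' retained mates sharing a read id collapse into one fragment
#' (\code{pairedCollapse}), and each fragment increments
#' \itemize{
#'   \item every feature it overlaps once (\code{"every_overlap"},
#'     default), or
#'   \item only the feature with the largest overlap, ties going to the
#'     lexicographically smallest \code{feature_id}
#'     (\code{"largest_overlap"}).
#' }
#' Fragments on chromosomes absent from the annotation's sequence universe
#' are skipped with a warning and tallied.
#'
#' @param alignments a SAM/BAM path or a GRanges from
#'   \code{\link{readAlignments}}.
#' @param features a \linkS4class{FeatureSet}.
#' @param minMapq minimum mapping quality (retained if mapq >= minMapq).
#' @param countMode \code{"every_overlap"} or \code{"largest_overlap"}.
#' @param stranded if TRUE a fragment only counts toward features on its
#'   own strand (unstranded features match either).
#' @param pairedCollapse collapse mates sharing a read id to one fragment.
#' @return a list with \code{counts} (named integer vector over
#'   \code{featureIds(features)}), \code{library_size} (retained fragments)
#'   and \code{skipped} (fragments on unannotated chromosomes).
#' @export
countFeatures <- function(alignments, features, minMapq = 1L,
                          countMode = c("every_overlap", "largest_overlap"),
                          stranded = FALSE, pairedCollapse = TRUE) {
    countMode <- match.arg(countMode)
    stopifnot(is(features, "FeatureSet"))
    if (is.character(alignments)) alignments <- readAlignments(alignments)
    fid <- featureIds(features)
    counts <- stats::setNames(integer(length(fid)), fid)

    keep <- mcols(alignments)$mapq >= minMapq
    aln <- alignments[keep]
    skipped <- 0L
    if (length(aln)) {
        onchr <- as.character(seqnames(aln)) %in%
            as.character(seqlevels(features))
        nskip <- length(unique(mcols(aln)$read_id[!onchr]))
        if (nskip > 0L) {
            warning(nskip, " fragment(s) on chromosomes absent from the ",
                    "annotation were skipped")
            skipped <- nskip
        }
        aln <- aln[onchr]
    }
    libsize <- if (pairedCollapse) length(unique(mcols(aln)$read_id))
               else length(aln)
    if (length(aln)) {
        hits <- findOverlaps(aln, features, ignore.strand = !stranded)
        qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
        if (stranded && length(qh)) {
            fstr <- as.character(strand(features))[sh]
            ok <- fstr == "*" | fstr == as.character(strand(aln))[qh]
            qh <- qh[ok]; sh <- sh[ok]
        }
        if (length(qh)) {
            frag <- if (pairedCollapse) mcols(aln)$read_id[qh]
                    else as.character(qh)
            if (countMode == "every_overlap") {
                key <- !duplicated(paste0(frag, "\r", sh))
                tab <- table(factor(sh[key], levels = seq_along(fid)))
                counts[] <- as.integer(tab)
            } else {
                ov <- width(pintersect(granges(aln)[qh],
                                       granges(features)[sh],
                                       ignore.strand = TRUE))
                ## fragment-level overlap: sum mate overlaps per feature
                agg <- rowsum(ov, group = paste0(frag, "\r", sh))
                keys <- strsplit(rownames(agg), "\r", fixed = TRUE)
                afrag <- vapply(keys, `[`, "", 1L)
                ash <- as.integer(vapply(keys, `[`, "", 2L))
                o <- order(afrag, -agg[, 1L], fid[ash])
                pick <- !duplicated(afrag[o])
                tab <- table(factor(ash[o][pick], levels = seq_along(fid)))
                counts[] <- as.integer(tab)
            }
        }
    }
    list(counts = counts, library_size = libsize, skipped = skipped)
}

#' Assemble per-sample counts into a TECountSet
#'
#' @param columns a named list of results from \code{\link{countFeatures}}
#'   (or bare named integer vectors), one per sample, over an identical
#'   feature universe.
#' @param meta a data.frame with one row per sample and columns
#'   \code{sample_id}, \code{condition}, \code{batch}, \code{replicate};
#'   column order of the result follows \code{meta}.
#' @param features optional \linkS4class{FeatureSet} stored as rowRanges.
#' @return a \linkS4class{TECountSet}.
#' @export
buildCountSet <- function(columns, meta, features = NULL) {
    stopifnot(is.data.frame(meta),
              all(c("sample_id", "condition", "batch", "replicate") %in%
                  colnames(meta)))
    if (is.null(names(columns))) names(columns) <- meta$sample_id
    columns <- columns[meta$sample_id]
    vecs <- lapply(columns, function(x) if (is.list(x)) x$counts else x)
    libs <- vapply(seq_along(columns), function(i) {
        x <- columns[[i]]
        if (is.list(x) && !is.null(x$library_size)) x$library_size
        else sum(vecs[[i]])
    }, numeric(1))
    universe <- names(vecs[[1L]])
    for (i in seq_along(vecs)) {
        d <- union(setdiff(names(vecs[[i]]), universe),
                   setdiff(universe, names(vecs[[i]])))
        if (length(d))
            stop("feature universe mismatch in sample '", meta$sample_id[i],
                 "': ", paste(utils::head(d, 10L), collapse = ", "))
    }
    m <- do.call(cbind, lapply(vecs, function(v) as.integer(v[universe])))
    dimnames(m) <- list(universe, meta$sample_id)
    if (any(colSums(m) == 0L))
        warning("sample(s) with no retained reads: ",
                paste(meta$sample_id[colSums(m) == 0L], collapse = ", "))
    cd <- S4Vectors::DataFrame(meta, library_size = libs,
                               row.names = meta$sample_id)
    if (!is.null(features)) {
        stopifnot(setequal(featureIds(features), universe))
        rr0 <- features[match(universe, featureIds(features))]
        rr <- granges(rr0)
        mcols(rr) <- mcols(rr0)
        names(rr) <- universe
    } else {
        ## coordinates unknown: empty range per feature keeps the container
        ## ranged without inventing positions
        rr <- GenomicRanges::GRangesList(
            stats::setNames(rep(list(GRanges()), length(universe)),
                            universe))
    }
    new("TECountSet",
        SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = m), rowRanges = rr, colData = cd))
}
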