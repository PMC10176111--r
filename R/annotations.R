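#' @importFrom rtracklayer import export
#' @importFrom GenomeInfoDb seqlevels seqnames seqlengths seqinfo Seqinfo
NULL

.parseRepeatClass <- function(cls) {
    ## "LTR/Gypsy" -> order LTR, family Gypsy; no "/" -> family = order token;
    ## order tokens outside the closed vocabulary fall in the Other bucket.
    parts <- strsplit(as.character(cls), "/", fixed = TRUE)
    ord_raw <- vapply(parts, `[`, "", 1L)
    fam <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else p[1L], "")
    known <- setdiff(.REPEAT_ORDERS, "Other")
    ord <- ifelse(ord_raw %in% known, ord_raw, "Other")
    list(order = ord, family = fam)
}

.repeatFeatureSet <- function(chrom, start1, end1, strand, repeat_name, cls) {
    if (any(bad <- !(end1 >= start1)))
        stop(sprintf("malformed coordinates (start > end) at record(s): %s",
                     paste(which(bad), collapse = ", ")))
    pc <- .parseRepeatClass(cls)
    strand <- ifelse(strand %in% c("+", "-"), strand, "*")
    gr <- GRanges(chrom, IRanges(start1, end1), strand = strand,
                  feature_id = make.unique(as.character(repeat_name),
                                           sep = "_"),
                  repeat_name = as.character(repeat_name),
                  order = pc$order, family = pc$family)
    FeatureSet(gr, "repeat")
}

#' Read a repeat annotation track
#'
#' Loads RepeatMasker-style repeat annotations into a
#' \linkS4class{FeatureSet} of kind \code{"repeat"}. Three dialects are
#' supported:
#' \describe{
#'   \item{\code{repeatmasker_out}}{native RepeatMasker \code{.out} with its
#'     three header lines; query coordinates are 1-based inclusive and the
#'     class/family column supplies order and family.}
#'   \item{\code{bed}}{BED with the name field encoding
#'     \code{repeat_name#order/family} (0-based half-open converted on read).}
#'   \item{\code{gtf}}{GTF with attributes \code{repeat_name},
#'     \code{order} and \code{family}.}
#' }
#' In the class/family string, the text before \code{"/"} is the order and
#' the text after it the family; if there is no \code{"/"} the family equals
#' the order (e.g. \code{Simple_repeat}). Orders outside the closed
#' vocabulary (LTR, LINE, DNA, Simple_repeat, Satellite, RC) are placed in
#' the \code{Other} bucket so composition tables are total.
#'
#' @param path path to the annotation file.
#' @param dialect one of \code{"repeatmasker_out"}, \code{"bed"},
#'   \code{"gtf"}; \code{"auto"} guesses from the file extension.
#' @return a \linkS4class{FeatureSet} of kind \code{"repeat"} with one
#'   feature per record; \code{feature_id} is the repeat name made unique in
#'   file order.
#' @export
readRepeatAnnotation <- function(path,
                                 dialect = c("auto", "repeatmasker_out",
                                             "bed", "gtf")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    if (dialect == "auto") {
        ext <- tolower(tools::file_ext(path))
        dialect <- switch(ext, out = "repeatmasker_out", bed = "bed",
                          gtf = "gtf",
                          stop("cannot guess dialect from extension: ", ext))
    }
    switch(dialect,
        repeatmasker_out = {
            ln <- readLines(path)
            ln <- trimws(ln)
            ## tolerate the standard 2 header lines + blank line, and any
            ## other line whose first field is not a numeric score
            fields <- strsplit(ln[nzchar(ln)], "\\s+")
            isdata <- vapply(fields, function(f)
                length(f) >= 11L && !is.na(suppressWarnings(as.numeric(f[1L]))),
                logical(1L))
            fields <- fields[isdata]
            if (!length(fields)) stop("no repeat records in ", path)
            getf <- function(i) vapply(fields, `[`, "", i)
            start1 <- as.integer(getf(6L)); end1 <- as.integer(getf(7L))
            if (anyNA(start1) || anyNA(end1))
                stop("malformed coordinate at line(s): ",
                     paste(which(is.na(start1) | is.na(end1)), collapse = ", "))
            strand <- ifelse(getf(9L) == "C", "-", getf(9L))
            .repeatFeatureSet(getf(5L), start1, end1, strand,
                              getf(10L), getf(11L))
        },
        bed = {
            gr <- rtracklayer::import(path, format = "BED")
            nm <- as.character(mcols(gr)$name)
            if (any(!grepl("#", nm, fixed = TRUE)))
                stop("BED repeat dialect requires name fields of the form ",
                     "'repeat_name#order/family'")
            rp <- sub("#.*$", "", nm)
            cls <- sub("^[^#]*#", "", nm)
            .repeatFeatureSet(as.character(seqnames(gr)), start(gr), end(gr),
                              as.character(strand(gr)), rp, cls)
        },
        gtf = {
            gr <- rtracklayer::import(path, format = "GTF")
            mc <- mcols(gr)
            if (is.null(mc$repeat_name) || is.null(mc$order) ||
                is.null(mc$family))
                stop("GTF repeat dialect needs repeat_name/order/family ",
                     "attributes")
            cls <- ifelse(mc$family == mc$order, mc$order,
                          paste0(mc$order, "/", mc$family))
            .repeatFeatureSet(as.character(seqnames(gr)), start(gr), end(gr),
                              as.character(strand(gr)), mc$repeat_name, cls)
        })
}

#' Read a gene annotation (GTF/GFF3)
#'
#' Builds gene models from records of type \code{gene} and \code{exon},
#' grouping exons under their parent gene via the \code{gene_id} attribute.
#' Every exon must fall within its gene's span and on the same chromosome.
#'
#' @param path path to the GTF or GFF3 file.
#' @param dialect \code{"gtf"}, \code{"gff3"}, or \code{"auto"}.
#' @return a \linkS4class{FeatureSet} of kind \code{"gene"}; the
#'   \code{exons} metadata column holds a \code{GRangesList} (empty elements,
#'   with a warning, when the source had no exon records).
#' @export
readGeneAnnotation <- function(path, dialect = c("auto", "gtf", "gff3")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    if (dialect == "auto") {
        ext <- tolower(tools::file_ext(path))
        dialect <- switch(ext, gtf = "gtf", gff3 = "gff3", gff = "gff3",
                          stop("cannot guess dialect from extension: ", ext))
    }
    gr <- rtracklayer::import(path, format = if (dialect == "gtf") "GTF"
                                             else "GFF3")
    type <- as.character(mcols(gr)$type)
    genes <- gr[type == "gene"]
    exons <- gr[type == "exon"]
    gid <- as.character(mcols(genes)$gene_id)
    if (anyNA(gid) || is.null(mcols(genes)$gene_id))
        stop("gene records must carry a gene_id attribute")
    if (anyDuplicated(gid))
        stop("duplicated gene_id: ",
             paste(unique(gid[duplicated(gid)]), collapse = ", "))
    eid <- as.character(mcols(exons)$gene_id)
    if (length(exons) && (is.null(mcols(exons)$gene_id) || anyNA(eid)))
        stop("exon records must carry a gene_id attribute")
    orphan <- setdiff(eid, gid)
    if (length(orphan))
        stop("exon(s) with no parent gene: ", paste(orphan, collapse = ", "))
    gspan <- GRanges(seqnames(genes), IRanges(start(genes), end(genes)),
                     strand = strand(genes), feature_id = gid)
    if (length(exons)) {
        hit <- match(eid, gid)
        samechr <- as.character(seqnames(exons)) ==
            as.character(seqnames(genes))[hit]
        within <- samechr & start(exons) >= start(genes)[hit] &
            end(exons) <= end(genes)[hit]
        if (any(!within))
            stop("exon outside its gene span for gene_id: ",
                 paste(unique(eid[!within]), collapse = ", "))
        ex <- GenomicRanges::GRangesList(
            split(granges(exons), factor(eid, levels = gid)))
    } else {
        warning("no exon records found; gene models have empty exon lists")
        ex <- GenomicRanges::GRangesList(
            stats::setNames(rep(list(GRanges()), length(gid)), gid))
    }
    mcols(gspan)$exons <- ex[gid]
    FeatureSet(gspan, "gene")
}

#' Read piRNA precursor and cluster annotations
#'
#' Precursors come from a plain BED file (name = precursor id). Clusters
#' come from a BED file whose name field is \code{"cluster_id|uni"} or
#' \code{"cluster_id|dual"}, declaring the cluster's transcription mode.
#' Precursors are loaded unassigned; see \code{\link{assignPrecursors}}.
#'
#' @param precursorPath BED file of precursor intervals (may be empty).
#' @param clusterPath BED file of cluster coordinates with strand-mode
#'   labels.
#' @return a list with elements \code{precursors}
#'   (\linkS4class{FeatureSet} of kind \code{"precursor"}) and
#'   \code{clusters} (\linkS4class{PiRNAClusterSet}).
#' @export
readPiRNAAnnotations <- function(precursorPath, clusterPath) {
    for (p in c(precursorPath, clusterPath))
        if (!file.exists(p)) stop("file not found: ", p)
    pre <- tryCatch(rtracklayer::import(precursorPath, format = "BED"),
                    error = function(e) GRanges(feature_id = character()))
    if (length(pre)) {
        mcols(pre) <- DataFrame(
            feature_id = make.unique(as.character(mcols(pre)$name), sep = "_"))
    } else {
        pre <- GRanges()
        mcols(pre) <- DataFrame(feature_id = character())
    }
    precursors <- FeatureSet(pre, "precursor")

    cl <- rtracklayer::import(clusterPath, format = "BED")
    nm <- as.character(mcols(cl)$name)
    parts <- strsplit(nm, "|", fixed = TRUE)
    if (any(lengths(parts) != 2L))
        stop("cluster BED name fields must be 'cluster_id|uni' or ",
             "'cluster_id|dual'")
    mode <- vapply(parts, `[`, "", 2L)
    if (any(!(mode %in% c("uni", "dual"))))
        stop("unknown strand mode token(s): ",
             paste(unique(setdiff(mode, c("uni", "dual"))), collapse = ", "))
    mcols(cl) <- DataFrame(cluster_id = vapply(parts, `[`, "", 1L),
                           strand_mode = mode)
    list(precursors = precursors, clusters = PiRNAClusterSet(cl))
}

#' Assign piRNA precursors to clusters
#'
#' A precursor is assigned to the cluster covering at least
#' \code{minOverlapFraction} of its length; when several clusters qualify,
#' the one with the largest overlap wins, ties going to the
#' lexicographically smallest \code{cluster_id}. Precursors below the
#' fraction stay unassigned (\code{cluster_id = NA}).
#'
#' @param precursors \linkS4class{FeatureSet} of kind \code{"precursor"}.
#' @param clusters \linkS4class{PiRNAClusterSet}.
#' @param minOverlapFraction minimum fraction of the precursor length inside
#'   the cluster (default 0.5).
#' @return the precursor \code{FeatureSet} with \code{cluster_id} filled in.
#' @export
assignPrecursors <- function(precursors, clusters, minOverlapFraction = 0.5) {
    stopifnot(is(precursors, "FeatureSet"),
              featureKind(precursors) == "precursor",
              is(clusters, "PiRNAClusterSet"),
              minOverlapFraction >= 0, minOverlapFraction <= 1)
    mcols(precursors)$cluster_id <- rep(NA_character_, length(precursors))
    if (!length(precursors) || !length(clusters)) return(precursors)
    hits <- findOverlaps(precursors, clusters, ignore.strand = TRUE)
    if (!length(hits)) return(precursors)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ov <- width(pintersect(granges(precursors)[qh], granges(clusters)[sh],
                           ignore.strand = TRUE))
    frac <- ov / width(precursors)[qh]
    keep <- frac >= minOverlapFraction
    qh <- qh[keep]; sh <- sh[keep]; ov <- ov[keep]
    if (!length(qh)) return(precursors)
    cid <- clusterIds(clusters)[sh]
    ## largest overlap first, then lexicographic cluster id
    o <- order(qh, -ov, cid)
    first <- !duplicated(qh[o])
    mcols(precursors)$cluster_id[qh[o][first]] <- cid[o][first]
    precursors
}

#' Genome-abundance composition of a repeat annotation
#'
#' Computes the expected class fractions of a repeat annotation — the
#' composition one would observe if transcriptional activation of repeats
#' were unbiased with respect to genome abundance. Classes are repeat orders
#' or families; abundance is measured either by counting annotation records
#' (\code{element_count}) or by summing annotated base pairs
#' (\code{base_pairs}).
#'
#' @param repeats \linkS4class{FeatureSet} of kind \code{"repeat"}.
#' @param level \code{"order"} or \code{"family"}.
#' @param weighting \code{"element_count"} (default) or \code{"base_pairs"}.
#' @return a data.frame with columns \code{class} and
#'   \code{expected_fraction} (summing to 1), sorted by class label.
#' @export
expectedComposition <- function(repeats, level = c("order", "family"),
                                weighting = c("element_count", "base_pairs")) {
    level <- match.arg(level)
    weighting <- match.arg(weighting)
    stopifnot(is(repeats, "FeatureSet"), featureKind(repeats) == "repeat")
    if (!length(repeats)) stop("empty repeat set")
    cls <- as.character(mcols(repeats)[[level]])
    w <- if (weighting == "element_count") rep(1, length(repeats))
         else as.numeric(width(repeats))
    tot <- tapply(w, cls, sum)
    out <- data.frame(class = names(tot),
                      expected_fraction = as.numeric(tot) / sum(w),
                      stringsAsFactors = FALSE)
    out[order(out$class), , drop = FALSE]
}

#' Write a FeatureSet to BED
#'
#' Repeats are written with the \code{repeat_name#order/family} name
#' dialect; all other kinds write \code{feature_id} as the name, so that
#' re-reading reproduces intervals and identifiers.
#'
#' @param fs a \linkS4class{FeatureSet}.
#' @param path output BED path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureBed <- function(fs, path) {
    stopifnot(is(fs, "FeatureSet"))
    gr <- granges(fs)
    names(gr) <- NULL
    if (featureKind(fs) == "repeat") {
        mc <- mcols(fs)
        cls <- ifelse(mc$family == mc$order, as.character(mc$order),
                      paste0(mc$order, "/", mc$family))
        mcols(gr)$name <- paste0(mc$repeat_name, "#", cls)
    } else {
        mcols(gr)$name <- featureIds(fs)
    }
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}
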