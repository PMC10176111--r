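#' Simulation configuration
#'
#' Builds the configuration for the synthetic-data generator. The defaults
#' emulate the structure of a multi-replicate histone-mutant RNA-seq study
#' of repeat transcription: a small multi-chromosome genome whose distal
#' (pericentromere-like) blocks are repeat-enriched, repeats labelled by
#' order/family (LTR/Gypsy, LTR/Pao, LTR/Copia, LINE/Jockey,
#' Simple_repeat), genes with known expression states, two dual-strand and
#' two uni-strand piRNA clusters with precursor intervals, negative-binomial
#' counts for a wild type sequenced in two batches, a control genotype and
#' four mutant conditions with five replicates each, planted log2 fold
#' changes, planted batch-inconsistent features, and ChIP/input coverage
#' with class-specific enrichment.
#'
#' @param seed master seed; all stages derive their streams from it.
#' @param chromosomes named numeric vector of chromosome lengths (bp).
#' @param pericentromereFraction fraction of each chromosome (its distal
#'   end) treated as the repeat-dense pericentromeric block.
#' @param pericentromereProb probability that an intergenic transposon is
#'   placed inside the pericentromeric block (0 = uniform placement).
#' @param repeatCounts named integer vector "order/family" -> element
#'   count.
#' @param nGenes,expressedFraction gene count and fraction expressed in
#'   wild type.
#' @param activatedGeneFraction fraction of unexpressed genes activated in
#'   the mutant (hosts of "activated_in_mutant" elements).
#' @param teInGeneProb probability a transposon is placed inside a gene.
#' @param precursorsPerCluster piRNA precursor intervals per cluster.
#' @param replicates biological replicates per condition (the study used
#'   five to seven; default 5).
#' @param conditions condition labels: wild type (two batches), control
#'   genotype, histone replacement, three methyltransferase knock-outs.
#' @param muTE,muExpressedGene,muPrecursorWT baseline negative-binomial
#'   means (per feature, wild type scale).
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2).
#' @param teUpFraction fraction of transposons planted up in each mutant
#'   (drawn with LTR/LINE bias), with log2 fold change \code{teUpLfc}.
#' @param teUpLfc planted log2 fold change for up transposons.
#' @param nBatchInconsistent features given a wild-type batch-2 effect
#'   (log2FC \code{batchLfc}) so the double-control filter has targets.
#' @param batchLfc planted batch effect (log2).
#' @param clusterFolds named list condition -> c(dual =, uni =) planted
#'   fold changes of piRNA cluster precursor means over wild type.
#' @param readLength,multiFraction simulated read length and fraction of
#'   reads emitted with mapping quality 0 (multi-mappers).
#' @param chipMultipliers list per ChIP target of named class multipliers
#'   (classes: exon, LTR, LINE, Simple_repeat; unlisted classes get 1).
#' @param chipDepth expected ChIP/input coverage in reads per bp.
#' @return a list of class \code{SimConfig}.
#' @export
simConfig <- function(seed = 1L,
                      chromosomes = c(chr2L = 6e5, chr2R = 6e5,
                                      chr3L = 5e5, chrX = 4e5),
                      pericentromereFraction = 0.3,
                      pericentromereProb = 0.75,
                      repeatCounts = c("LTR/Gypsy" = 140, "LTR/Pao" = 70,
                                       "LTR/Copia" = 50, "LINE/Jockey" = 90,
                                       "Simple_repeat" = 250),
                      nGenes = 100L, expressedFraction = 0.5,
                      activatedGeneFraction = 0.3,
                      teInGeneProb = 0.25,
                      precursorsPerCluster = 60L,
                      replicates = 5L,
                      conditions = c("WT", "H3K36K", "H3K36R", "Set2KO",
                                     "NSDKO", "ash1KO"),
                      muTE = 50, muExpressedGene = 100, muPrecursorWT = 3,
                      dispersion = 0.1,
                      teUpFraction = c(H3K36R = 0.25, Set2KO = 0.18,
                                       NSDKO = 0.08, ash1KO = 0.05),
                      teUpLfc = 3,
                      nBatchInconsistent = 30L,
                      batchLfc = 3,
                      clusterFolds = list(H3K36R = c(dual = 8, uni = 1.5),
                                          Set2KO = c(dual = 5, uni = 1.4),
                                          NSDKO = c(dual = 3, uni = 1.3),
                                          ash1KO = c(dual = 2, uni = 1.3)),
                      readLength = 75L, multiFraction = 0,
                      chipMultipliers = list(
                          me1 = c(Simple_repeat = 1.3, LTR = 0.7,
                                  LINE = 0.7),
                          me2 = c(LTR = 2.0, LINE = 2.0,
                                  Simple_repeat = 0.8),
                          me3 = c(exon = 2.0, LTR = 0.6, LINE = 0.6)),
                      chipDepth = 0.25) {
    cfg <- list(seed = seed, chromosomes = chromosomes,
                pericentromereFraction = pericentromereFraction,
                pericentromereProb = pericentromereProb,
                repeatCounts = repeatCounts, nGenes = nGenes,
                expressedFraction = expressedFraction,
                activatedGeneFraction = activatedGeneFraction,
                teInGeneProb = teInGeneProb,
                precursorsPerCluster = precursorsPerCluster,
                replicates = replicates, conditions = conditions,
                muTE = muTE, muExpressedGene = muExpressedGene,
                muPrecursorWT = muPrecursorWT,
                dispersion = dispersion, teUpFraction = teUpFraction,
                teUpLfc = teUpLfc,
                nBatchInconsistent = nBatchInconsistent, batchLfc = batchLfc,
                clusterFolds = clusterFolds, readLength = readLength,
                multiFraction = multiFraction,
                chipMultipliers = chipMultipliers, chipDepth = chipDepth)
    class(cfg) <- c("SimConfig", "list")
    cfg
}

.placeNonOverlapping <- function(chromSizes, lengths, avoid = NULL,
                                 within = NULL, maxTries = 200L) {
    ## place intervals of given lengths without overlapping each other or
    ## 'avoid'; optionally restricted to the 'within' ranges
    placed <- GRanges()
    pool <- if (is.null(within)) {
        GRanges(names(chromSizes), IRanges(1L, unname(chromSizes)))
    } else within
    poolw <- as.numeric(width(pool))
    for (len in lengths) {
        ok <- FALSE
        for (t in seq_len(maxTries)) {
            cand_pool <- sample.int(length(pool), 1L,
                                    prob = poolw / sum(poolw))
            p <- pool[cand_pool]
            if (width(p) < len) next
            s <- start(p) + floor(stats::runif(1, 0, width(p) - len + 1))
            cand <- GRanges(seqnames(p), IRanges(s, width = len))
            if ((is.null(avoid) ||
                 !length(findOverlaps(cand, avoid, ignore.strand = TRUE))) &&
                !length(findOverlaps(cand, placed, ignore.strand = TRUE))) {
                placed <- c(placed, cand)
                ok <- TRUE
                break
            }
        }
        if (!ok) stop("could not place an interval of length ", len,
                      "; requested features exceed placeable space")
    }
    placed
}

.pericentromere <- function(config) {
    cs <- config$chromosomes
    frac <- config$pericentromereFraction
    GRanges(names(cs), IRanges(pmax(1, floor(cs * (1 - frac)) + 1),
                               unname(cs)))
}

#' Simulate the annotation bundle
#'
#' Generates chromosome sizes, a repeat annotation with pericentromere-
#' enriched transposons (simple repeats placed uniformly), non-overlapping
#' genes, four piRNA clusters (two dual-, two uni-strand) with precursor
#' intervals inside them, and the per-feature truth needed by the oracle
#' checks (context label, host gene, cluster assignment). Deterministic
#' under the config seed.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return list with \code{repeats}, \code{genes}, \code{precursors}
#'   (\linkS4class{FeatureSet}s), \code{clusters}
#'   (\linkS4class{PiRNAClusterSet}), \code{chromSizes}, and \code{truth}
#'   (data.frame of planted per-repeat context labels plus gene expression
#'   states in \code{attr(truth, "genes")}).
#' @export
simulateAnnotation <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    rs <- .seededRNG(.subSeed(config$seed, 1))
    on.exit(rs$restore())
    cs <- config$chromosomes
    peri <- .pericentromere(config)

    ## genes, outside the pericentromeric blocks
    glen <- floor(stats::runif(config$nGenes, 2000, 5000))
    armpool <- GRanges(names(cs),
                       IRanges(1L, floor(cs * (1 - config$pericentromereFraction))))
    ggr <- .placeNonOverlapping(cs, glen, within = armpool)
    gid <- sprintf("gene%03d", seq_len(config$nGenes))
    exons <- GenomicRanges::GRangesList(lapply(seq_along(ggr), function(i) {
        g <- ggr[i]
        nex <- sample(2:4, 1L)
        cuts <- sort(floor(stats::runif(2L * nex, start(g), end(g))))
        GRanges(seqnames(g), IRanges(cuts[seq(1L, by = 2L,
                                              length.out = nex)],
                                     cuts[seq(2L, by = 2L,
                                              length.out = nex)]))
    }))
    mcols(ggr) <- DataFrame(feature_id = gid, exons = exons)
    genes <- FeatureSet(ggr, "gene")
    expressed <- stats::runif(config$nGenes) < config$expressedFraction
    activated <- !expressed &
        stats::runif(config$nGenes) < config$activatedGeneFraction

    ## piRNA clusters in the pericentromeric blocks of distinct chromosomes
    cl_ids <- c("42AB", "38C", "20A", "flamenco")
    cl_modes <- c("dual", "dual", "uni", "uni")
    clw <- rep(20000L, 4L)
    clgr <- .placeNonOverlapping(cs, clw, within = peri)
    mcols(clgr) <- DataFrame(cluster_id = cl_ids, strand_mode = cl_modes)
    clusters <- PiRNAClusterSet(clgr)

    ## precursors inside their clusters
    npre <- config$precursorsPerCluster
    pre <- do.call(c, lapply(seq_along(clgr), function(i) {
        g <- clgr[i]
        len <- floor(stats::runif(npre, 200, 1000))
        s <- start(g) + floor(stats::runif(npre, 0, width(g) - len))
        GRanges(seqnames(g), IRanges(s, width = len))
    }))
    mcols(pre) <- DataFrame(
        feature_id = sprintf("pre_%s_%03d", rep(cl_ids, each = npre),
                             rep(seq_len(npre), 4L)),
        cluster_id = rep(NA_character_, length(pre)))
    precursors <- FeatureSet(pre, "precursor")

    ## repeats: transposons pericentromere-biased or inside genes;
    ## simple repeats uniform
    rc <- config$repeatCounts
    cls <- rep(names(rc), rc)
    pcls <- .parseRepeatClass(cls)
    is_te <- pcls$order %in% c("LTR", "LINE")
    n <- length(cls)
    rlen <- ifelse(is_te, floor(stats::runif(n, 300, 800)),
                   floor(stats::runif(n, 50, 200)))
    in_gene <- is_te & stats::runif(n) < config$teInGeneProb
    host <- rep(NA_character_, n)
    rgr_list <- vector("list", n)
    for (i in seq_len(n)) {
        if (in_gene[i]) {
            j <- sample(which(width(ggr) > rlen[i] + 2L), 1L)
            host[i] <- gid[j]
            s <- start(ggr)[j] +
                floor(stats::runif(1, 0, width(ggr)[j] - rlen[i]))
            rgr_list[[i]] <- GRanges(seqnames(ggr)[j],
                                     IRanges(s, width = rlen[i]))
        } else {
            use_peri <- is_te[i] &&
                stats::runif(1) < config$pericentromereProb
            pool <- if (use_peri) peri else
                GRanges(names(cs), IRanges(1L, unname(cs)))
            poolw <- as.numeric(width(pool))
            repeat {
                p <- pool[sample.int(length(pool), 1L,
                                     prob = poolw / sum(poolw))]
                if (width(p) >= rlen[i]) break
            }
            s <- start(p) + floor(stats::runif(1, 0, width(p) - rlen[i] + 1))
            cand <- GRanges(seqnames(p), IRanges(s, width = rlen[i]))
            ## intergenic placements must not graze a gene
            if (!use_peri &&
                length(findOverlaps(cand, ggr, ignore.strand = TRUE))) {
                ov <- findOverlaps(cand, ggr, ignore.strand = TRUE)
                host[i] <- sort(gid[S4Vectors::subjectHits(ov)])[1L]
                in_gene[i] <- TRUE   # landed in a gene by chance; record it
            }
            rgr_list[[i]] <- cand
        }
    }
    rgr <- do.call(c, rgr_list)
    fam <- pcls$family
    rep_name <- sprintf("%s-sim%04d", fam, seq_len(n))
    mcols(rgr) <- DataFrame(feature_id = rep_name, repeat_name = rep_name,
                            order = pcls$order, family = fam)
    repeats <- FeatureSet(rgr, "repeat")

    context <- ifelse(!in_gene, "intergenic",
               ifelse(host %in% gid[expressed], "expressed_gene",
                      "unexpressed_gene"))
    sub <- rep(NA_character_, n)
    unex <- context == "unexpressed_gene"
    sub[unex] <- ifelse(host[unex] %in% gid[activated],
                        "activated_in_mutant", "silent_in_mutant")
    truth <- data.frame(feature_id = rep_name, order = pcls$order,
                        family = fam, context = context, host_gene = host,
                        context_sub = sub, stringsAsFactors = FALSE)
    attr(truth, "genes") <- data.frame(
        gene_id = gid, expressed_wt = expressed,
        activated_in_mutant = activated, stringsAsFactors = FALSE)

    list(repeats = repeats, genes = genes,
         precursors = assignPrecursors(precursors, clusters),
         clusters = clusters, chromSizes = cs, truth = truth)
}

.sampleTable <- function(config) {
    conds <- config$conditions
    reps <- config$replicates
    rows <- list()
    for (cond in conds) {
        batches <- if (cond == "WT") c("b1", "b2") else "b1"
        for (b in batches)
            for (r in seq_len(reps))
                rows[[length(rows) + 1L]] <- data.frame(
                    sample_id = sprintf("%s_%s_r%d", cond, b, r),
                    condition = cond, batch = b, replicate = r,
                    stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
}

#' Simulate negative-binomial count matrices
#'
#' Draws counts per feature and sample as
#' NB(mean = s_j * mu_i * 2^lfc_i(condition_j), dispersion alpha) with
#' lognormal per-sample scales s_j. Transposons planted up in each mutant
#' (LTR/LINE-biased draw), precursor means scaled by the planted cluster
#' folds, batch-inconsistent transposons given a wild-type batch-2 effect,
#' unexpressed genes zero in wild type with the activated subset switched
#' on in the histone-replacement mutant.
#'
#' @param config a \code{\link{simConfig}}.
#' @param ann annotation bundle from \code{\link{simulateAnnotation}}.
#' @return list with \code{te}, \code{genes}, \code{precursors}
#'   (\linkS4class{TECountSet}s), \code{samples} (the sample table) and
#'   \code{truth} (per-feature true means and planted log2 fold changes,
#'   up-set and batch-inconsistent flags, plus the annotation truth).
#' @export
simulateCounts <- function(config, ann) {
    stopifnot(inherits(config, "SimConfig"))
    rs <- .seededRNG(.subSeed(config$seed, 2))
    on.exit(rs$restore())
    samples <- .sampleTable(config)
    ns <- nrow(samples)
    sscale <- exp(stats::rnorm(ns, 0, 0.1))
    alpha <- config$dispersion
    rnb <- function(mu) {
        out <- numeric(length(mu))
        pos <- mu > 0
        out[pos] <- stats::rnbinom(sum(pos), mu = mu[pos], size = 1 / alpha)
        out
    }

    drawMatrix <- function(mu_base, lfc) {
        ## mu_base: per-feature WT mean; lfc: features x samples log2 effects
        m <- matrix(0L, nrow = length(mu_base), ncol = ns)
        for (j in seq_len(ns)) {
            mu <- sscale[j] * mu_base * 2^lfc[, j]
            m[, j] <- as.integer(rnb(mu))
        }
        m
    }

    ## --- transposons -------------------------------------------------
    rep_ids <- featureIds(ann$repeats)
    nrep <- length(rep_ids)
    ord <- mcols(ann$repeats)$order
    mu_te <- config$muTE * exp(stats::rnorm(nrep, 0, 0.25))
    lfc_te <- matrix(0, nrep, ns)
    up_sets <- list()
    te_w <- ifelse(ord %in% c("LTR", "LINE"), 3, 1)   # activation bias
    for (cond in names(config$teUpFraction)) {
        nup <- round(config$teUpFraction[[cond]] * nrep)
        up <- sample.int(nrep, nup, prob = te_w)
        up_sets[[cond]] <- rep_ids[up]
        lfc_te[up, samples$condition == cond] <- config$teUpLfc
    }
    incon <- sample.int(nrep, min(config$nBatchInconsistent, nrep))
    lfc_te[incon, samples$condition == "WT" & samples$batch == "b2"] <-
        config$batchLfc
    k_te <- drawMatrix(mu_te, lfc_te)
    rownames(k_te) <- rep_ids

    ## --- genes -------------------------------------------------------
    gtruth <- attr(ann$truth, "genes")
    gene_ids <- gtruth$gene_id
    mu_g <- ifelse(gtruth$expressed_wt, config$muExpressedGene, 0)
    lfc_g <- matrix(0, length(gene_ids), ns)
    mu_g_full <- matrix(rep(mu_g, ns), ncol = ns)
    act <- gtruth$activated_in_mutant
    ## activated genes: silent in WT, switched on in the replacement mutant
    mu_g_full[act, samples$condition == "H3K36R"] <- 30
    k_g <- matrix(0L, length(gene_ids), ns)
    for (j in seq_len(ns))
        k_g[, j] <- as.integer(rnb(sscale[j] * mu_g_full[, j]))
    rownames(k_g) <- gene_ids

    ## --- piRNA precursors -------------------------------------------
    pre_ids <- featureIds(ann$precursors)
    assign <- mcols(ann$precursors)$cluster_id
    mode_of <- stats::setNames(clusterStrandMode(ann$clusters),
                               clusterIds(ann$clusters))
    mu_pre <- config$muPrecursorWT * exp(stats::rnorm(length(pre_ids), 0, 0.3))
    lfc_pre <- matrix(0, length(pre_ids), ns)
    for (cond in names(config$clusterFolds)) {
        f <- config$clusterFolds[[cond]]
        for (i in seq_along(pre_ids)) {
            if (is.na(assign[i])) next
            fold <- unname(f[mode_of[assign[i]]])
            lfc_pre[i, samples$condition == cond] <- log2(fold)
        }
    }
    k_pre <- drawMatrix(mu_pre, lfc_pre)
    rownames(k_pre) <- pre_ids

    toSet <- function(k, fs) {
        cols <- lapply(seq_len(ncol(k)), function(j)
            list(counts = stats::setNames(k[, j], rownames(k)),
                 library_size = sum(k[, j])))
        names(cols) <- samples$sample_id
        suppressWarnings(buildCountSet(cols, samples, features = fs))
    }

    truth <- list(te_up = up_sets,
                  te_lfc = config$teUpLfc,
                  batch_inconsistent = rep_ids[incon],
                  mu_te = stats::setNames(mu_te, rep_ids),
                  mu_precursor = stats::setNames(mu_pre, pre_ids),
                  cluster_folds = config$clusterFolds,
                  sample_scale = stats::setNames(sscale, samples$sample_id),
                  genes = gtruth,
                  annotation = ann$truth)

    list(te = toSet(k_te, ann$repeats),
         genes = toSet(k_g, ann$genes),
         precursors = toSet(k_pre, ann$precursors),
         samples = samples, truth = truth)
}

#' Emit per-sample SAM files realizing a count matrix
#'
#' For every feature and sample, writes exactly the matrix's number of
#' single-end reads placed uniformly within the feature (reads are clipped
#' to the feature when it is shorter than the read length, with a warning).
#' Each read carries mapping quality 255, or 0 with probability
#' \code{config$multiFraction} (multi-mapper emulation). With a zero multi
#' fraction and disjoint features, counting the emitted SAM with
#' \code{minMapq = 1} under \code{every_overlap} reproduces the matrix
#' exactly.
#'
#' @param config a \code{\link{simConfig}}.
#' @param ann annotation bundle (for chromosome sizes).
#' @param countSet a \linkS4class{TECountSet} whose rowRanges locate the
#'   features.
#' @param dir output directory (created if needed).
#' @return named character vector of SAM paths, one per sample.
#' @export
simulateAlignments <- function(config, ann, countSet, dir) {
    stopifnot(inherits(config, "SimConfig"), is(countSet, "TECountSet"))
    rs <- .seededRNG(.subSeed(config$seed, 3))
    on.exit(rs$restore())
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cs <- ann$chromSizes
    rr <- SummarizedExperiment::rowRanges(countSet)
    if (!is(rr, "GRanges"))
        stop("countSet must carry feature coordinates in rowRanges")
    k <- countsMatrix(countSet)
    rl <- config$readLength
    if (any(width(rr) < rl))
        warning("feature(s) shorter than the read length; reads clipped")
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", names(cs), as.integer(cs)))
    paths <- character(ncol(k))
    names(paths) <- colnames(k)
    for (j in seq_len(ncol(k))) {
        tot <- sum(k[, j])
        fidx <- rep.int(seq_len(nrow(k)), k[, j])
        len <- pmin(rl, width(rr)[fidx])
        s <- start(rr)[fidx] +
            floor(stats::runif(length(fidx), 0,
                               width(rr)[fidx] - len + 1))
        mapq <- ifelse(stats::runif(length(fidx)) < config$multiFraction,
                       0L, 255L)
        lines <- if (length(fidx)) {
            sprintf("%s\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                    sprintf("read_%s_%07d", colnames(k)[j],
                            seq_along(fidx)),
                    as.character(seqnames(rr))[fidx], as.integer(s),
                    mapq, len,
                    vapply(len, function(L)
                        paste(rep("A", L), collapse = ""), ""))
        } else character()
        path <- file.path(dir, paste0(colnames(k)[j], ".sam"))
        writeLines(c(header, lines), path)
        paths[j] <- path
    }
    paths
}

#' Simulate ChIP and input counts with class-specific enrichment
#'
#' Input counts are Poisson with mean proportional to feature length
#' (\code{chipDepth} reads/bp); ChIP counts additionally carry the class
#' multiplier configured per target (me1/me2/me3). Two replicates per
#' target and for the input.
#'
#' @param config a \code{\link{simConfig}}.
#' @param features \linkS4class{FeatureSet} of the profiled regions.
#' @param classOf character vector, class label per feature (e.g.
#'   \code{"exon"}, \code{"LTR"}, \code{"LINE"}, \code{"Simple_repeat"},
#'   \code{"random"}); classes without a configured multiplier get 1.
#' @return list per target: \code{chip} (features x 2 replicate counts),
#'   \code{input}, \code{chip_lib}, \code{input_lib}.
#' @export
simulateChip <- function(config, features, classOf) {
    stopifnot(inherits(config, "SimConfig"), is(features, "FeatureSet"),
              length(classOf) == length(features))
    rs <- .seededRNG(.subSeed(config$seed, 4))
    on.exit(rs$restore())
    base <- config$chipDepth * as.numeric(width(features))
    out <- list()
    for (target in names(config$chipMultipliers)) {
        mults <- config$chipMultipliers[[target]]
        m <- ifelse(classOf %in% names(mults), mults[classOf], 1)
        chip <- cbind(stats::rpois(length(base), base * m),
                      stats::rpois(length(base), base * m))
        input <- cbind(stats::rpois(length(base), base),
                       stats::rpois(length(base), base))
        rownames(chip) <- rownames(input) <- featureIds(features)
        out[[target]] <- list(chip = chip, input = input,
                              chip_lib = sum(chip) / 2,
                              input_lib = sum(input) / 2)
    }
    out
}
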