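## shared small simulation for this file (annotation generation dominates
## runtime, so it is built once)
cfgSmall <- simConfig(
    seed = 51,
    chromosomes = c(chr2L = 3e5, chr2R = 3e5, chr3L = 2e5),
    repeatCounts = c("LTR/Gypsy" = 30, "LINE/Jockey" = 20,
                     "Simple_repeat" = 40),
    nGenes = 30L, precursorsPerCluster = 20L, replicates = 2L,
    conditions = c("WT", "H3K36K", "H3K36R"),
    teUpFraction = c(H3K36R = 0.2),
    clusterFolds = list(H3K36R = c(dual = 8, uni = 1.5)),
    nBatchInconsistent = 5L)
annSmall <- simulateAnnotation(cfgSmall)

test_that("the simulated annotation honours the requested design", {
    ann <- annSmall
    expect_equal(length(ann$repeats), 90L)
    expect_equal(sum(clusterStrandMode(ann$clusters) == "dual"), 2L)
    expect_equal(sum(clusterStrandMode(ann$clusters) == "uni"), 2L)
    ## every precursor lies within its assigned cluster
    assign <- mcols(ann$precursors)$cluster_id
    expect_true(all(!is.na(assign)))
    for (i in seq_along(ann$clusters)) {
        cid <- clusterIds(ann$clusters)[i]
        pre <- ann$precursors[assign == cid]
        hits <- findOverlaps(pre, ann$clusters[i], type = "within")
        expect_equal(length(hits), length(pre))
    }
    ## genes never overlap each other
    self <- findOverlaps(ann$genes, ann$genes, ignore.strand = TRUE)
    expect_equal(length(self), length(ann$genes))
    ## truth labels agree with a direct overlap check
    tr <- ann$truth
    ov <- findOverlaps(ann$repeats, ann$genes, ignore.strand = TRUE)
    inGene <- seq_along(ann$repeats) %in% S4Vectors::queryHits(ov)
    expect_equal(tr$context != "intergenic", inGene)
})

test_that("annotation generation is deterministic under the seed (byte-identical BED)", {
    ann2 <- simulateAnnotation(cfgSmall)
    f1 <- withr::local_tempfile(fileext = ".bed")
    f2 <- withr::local_tempfile(fileext = ".bed")
    writeFeatureBed(annSmall$repeats, f1)
    writeFeatureBed(ann2$repeats, f2)
    expect_identical(readLines(f1), readLines(f2))
    expect_identical(granges(annSmall$precursors), granges(ann2$precursors))
})

test_that("simulated counts match the NB model moments and the planted truth", {
    sim <- simulateCounts(cfgSmall, annSmall)
    expect_s4_class(sim$te, "TECountSet")
    expect_equal(nrow(sim$te), 90L)
    ## two WT batches present
    expect_setequal(unique(paste(sim$te$condition, sim$te$batch))[1:2],
                    c("WT b1", "WT b2"))
    ## truth features all exist in the annotation
    expect_true(all(sim$truth$te_up$H3K36R %in% featureIds(annSmall$repeats)))

    ## near-Poisson limit: variance ~ mean on null features
    cfgP <- simConfig(seed = 52, chromosomes = cfgSmall$chromosomes,
                      repeatCounts = cfgSmall$repeatCounts,
                      nGenes = 10L, precursorsPerCluster = 5L,
                      replicates = 20L, conditions = c("WT", "H3K36K"),
                      teUpFraction = c(H3K36R = 0),
                      clusterFolds = list(), nBatchInconsistent = 0L,
                      dispersion = 1e-8)
    annP <- simulateAnnotation(cfgP)
    simP <- simulateCounts(cfgP, annP)
    k <- countsMatrix(simP$te)
    wt1 <- k[, simP$te$condition == "WT" & simP$te$batch == "b1"]
    ## remove the per-sample scale by normalizing columns
    y <- sweep(wt1, 2, colMeans(wt1) / mean(colMeans(wt1)), "/")
    disp_index <- apply(y, 1, var) / rowMeans(y)
    expect_lt(abs(median(disp_index) - 1), 0.25)

    ## planted log2 ratios recover the configured effect
    simE <- simulateCounts(cfgSmall, annSmall)
    kE <- countsMatrix(simE$te)
    up <- simE$truth$te_up$H3K36R
    ctrl <- simE$te$condition == "WT"
    trt <- simE$te$condition == "H3K36R"
    lr <- log2(rowMeans(kE[up, trt, drop = FALSE]) /
               rowMeans(kE[up, ctrl, drop = FALSE]))
    expect_lt(abs(median(lr) - cfgSmall$teUpLfc), 0.4)
})

test_that("emitted SAM files round-trip the count matrix exactly over disjoint features", {
    sim <- simulateCounts(cfgSmall, annSmall)
    ## restrict to features overlapping no other feature (the exactness
    ## guarantee only holds for disjoint annotations)
    hits <- findOverlaps(annSmall$repeats, annSmall$repeats,
                         ignore.strand = TRUE)
    multi <- unique(S4Vectors::queryHits(hits)[
        S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)])
    disj <- setdiff(seq_along(annSmall$repeats), multi)
    te <- sim$te[disj, sim$te$sample_id[1:3]]
    dir <- withr::local_tempdir()
    paths <- suppressWarnings(simulateAlignments(cfgSmall, annSmall, te, dir))
    expect_equal(length(paths), 3L)
    sub <- annSmall$repeats[disj]
    for (j in seq_along(paths)) {
        got <- countFeatures(paths[[j]], sub, minMapq = 1)
        expect_equal(got$counts[featureIds(sub)],
                     setNames(countsMatrix(te)[, j], featureIds(sub)))
        expect_equal(got$library_size, sum(countsMatrix(te)[, j]))
    }
    ## byte-identical SAM under the same seed
    dir2 <- withr::local_tempdir()
    paths2 <- suppressWarnings(simulateAlignments(cfgSmall, annSmall, te, dir2))
    expect_identical(readLines(paths[[1]]), readLines(paths2[[1]]))
})

test_that("a configured multi-mapper fraction drops about that share of fragments", {
    cfgM <- cfgSmall
    cfgM$multiFraction <- 0.5
    sim <- simulateCounts(cfgSmall, annSmall)
    te <- sim$te[, sim$te$sample_id[1]]
    dir <- withr::local_tempdir()
    p <- suppressWarnings(simulateAlignments(cfgM, annSmall, te, dir))
    got <- countFeatures(p[[1]], annSmall$repeats, minMapq = 1)
    total <- sum(countsMatrix(te)[, 1])
    expect_gt(got$library_size / total, 0.4)
    expect_lt(got$library_size / total, 0.6)
})
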