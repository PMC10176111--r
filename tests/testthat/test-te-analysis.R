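mkDE <- function(ids, p_adj, lfc = 3) {
    de <- data.frame(feature_id = ids, base_mean = 10, log2fc = lfc,
                     se = 1, wald_z = 1, p_value = p_adj, p_adj = p_adj,
                     untested = FALSE)
    class(de) <- c("DETable", "data.frame")
    de
}

test_that("the double-control filter removes the union of control-significant features", {
    ids <- c("a", "b", "c", "d")
    main <- mkDE(ids, c(0.01, 0.01, 0.01, 0.01))
    runs <- mkDE(ids, c(0.01, 0.50, 0.50, 0.50))   # a fails batch control
    geno <- mkDE(ids, c(0.50, 0.02, 0.50, 0.50))   # b fails genotype control
    out <- controlConsistencyFilter(main, runs, geno)
    expect_setequal(out$report$removed, c("a", "b"))
    expect_equal(out$report$n_removed, 2L)
    expect_setequal(out$filtered$feature_id, c("c", "d"))

    ## idempotence: filtering the filtered table removes nothing more
    ## (the shrunken universe is intersected, with a warning)
    expect_warning(again <- controlConsistencyFilter(out$filtered, runs, geno),
                   "intersecting")
    expect_equal(again$report$n_removed, 0L)
    expect_setequal(again$filtered$feature_id, c("c", "d"))

    expect_error(controlConsistencyFilter(main, mkDE("zz", 0.5), geno),
                 "empty intersection")
})

test_that("the filter removes planted batch-inconsistent features on simulated data", {
    set.seed(21)
    n <- 1000
    incon <- sprintf("f%05d", 1:50)
    mu <- matrix(50, n, 10)
    mu[1:50, 6:10] <- 50 * 2^3      # WT batch-2 effect on 50 features
    kr <- matrix(rnbinom(length(mu), mu = mu, size = 10), n, 10,
                 dimnames = list(sprintf("f%05d", 1:n), sprintf("w%02d", 1:10)))
    runs <- nbWaldTest(kr, "WT_b2", "WT_b1",
                       groups = rep(c("WT_b1", "WT_b2"), each = 5))
    kg <- matrix(rnbinom(n * 10, mu = 50, size = 10), n, 10,
                 dimnames = list(sprintf("f%05d", 1:n), sprintf("g%02d", 1:10)))
    geno <- nbWaldTest(kg, "K", "WT", groups = rep(c("WT", "K"), each = 5))
    km <- matrix(rnbinom(n * 10, mu = 50, size = 10), n, 10,
                 dimnames = list(sprintf("f%05d", 1:n), sprintf("m%02d", 1:10)))
    main <- nbWaldTest(km, "M", "WT", groups = rep(c("WT", "M"), each = 5))
    out <- controlConsistencyFilter(main, runs, geno, alpha = 0.05)
    expect_gte(mean(incon %in% out$report$removed), 0.9)
    false_removed <- setdiff(out$report$removed, incon)
    expect_lte(length(false_removed) / (n - 50), 0.1)
})

test_that("goodness-of-fit chi-square matches hand arithmetic", {
    expected <- data.frame(class = c("LINE", "LTR"),
                           expected_fraction = c(0.5, 0.5))
    ## observed {LTR: 90, LINE: 10} vs expected 50/50 -> chi2 = 64, df = 1
    big <- makeRepeats("chr2", seq(1, by = 200, length.out = 100),
                       seq(100, by = 200, length.out = 100),
                       c(rep("LTR", 90), rep("LINE", 10)),
                       c(rep("Gypsy", 90), rep("Jockey", 10)))
    ct <- compositionChiSquare(featureIds(big), big, expected, "order")
    expect_equal(ct$chi2_stat, 64)
    expect_equal(ct$df, 1L)
    expect_equal(ct$p_value, pchisq(64, 1, lower.tail = FALSE))

    ## observed equal to expected -> chi2 0, p 1
    half <- makeRepeats("chr2", c(1, 201), c(100, 300),
                        c("LTR", "LINE"), c("Gypsy", "Jockey"))
    ct0 <- suppressWarnings(compositionChiSquare(
        featureIds(half), half, expected, "order"))
    expect_equal(ct0$chi2_stat, 0)
    expect_equal(ct0$p_value, 1)

    ## two identical observed vectors in two-sample mode -> chi2 0
    ct2 <- compositionChiSquare(featureIds(half), half, up2 = featureIds(half))
    expect_equal(ct2$chi2_stat, 0)

    ## class universe mismatch errors
    bad_exp <- data.frame(class = c("LINE", "LTR"),
                          expected_fraction = c(1, 0))
    expect_error(compositionChiSquare(featureIds(big), big, bad_exp, "order"),
                 "mismatch")
})

test_that("mutant membership partition equals a brute-force recount", {
    set.seed(22)
    base <- sprintf("t%03d", 1:300)
    per <- list(Set2 = sample(base, 150), NSD = sample(base, 80),
                ash1 = sample(base, 40))
    part <- partitionByMutants(base, per)
    expect_equal(sum(part$counts), 300L)
    expect_equal(length(part$counts), 8L)
    ## brute force over every feature
    brute <- table(vapply(base, function(f) {
        inn <- names(per)[vapply(per, function(s) f %in% s, logical(1))]
        if (!length(inn)) "none" else paste(inn, collapse = " + ")
    }, ""))
    expect_equal(part$counts[names(brute)], unclass(brute)[names(brute)],
                 ignore_attr = TRUE)
    ## disjoint cover: each feature in exactly one class
    expect_equal(sort(names(part$class_of)), sort(base))
})

test_that("genomic context classification applies the overlap priority rules", {
    genes <- FeatureSet(GRanges("chr1", IRanges(c(1000, 3000, 5000),
                                                c(1999, 3999, 5999)),
                                feature_id = c("gE", "gU", "gA"),
                                exons = GenomicRanges::GRangesList(
                                    GRanges("chr1", IRanges(1000, 1999)),
                                    GRanges("chr1", IRanges(3000, 3999)),
                                    GRanges("chr1", IRanges(5000, 5999)))),
                        "gene")
    reps <- makeRepeats("chr1", c(100, 1200, 3200, 5200, 1950),
                        c(300, 1400, 3400, 5400, 2050),
                        rep("LTR", 5), rep("Gypsy", 5),
                        names = c("interg", "inExp", "inUnexp", "inAct",
                                  "edge"))
    wtMeans <- c(gE = 50, gU = 0, gA = 0)
    ctx <- classifyGenomicContext(featureIds(reps), reps, genes, wtMeans,
                                  mutantUpGenes = "gA")
    lab <- setNames(ctx$label, ctx$feature_id)
    expect_equal(lab[["interg"]], "intergenic")
    expect_equal(lab[["inExp"]], "expressed_gene")
    expect_equal(lab[["inUnexp"]], "unexpressed_gene")
    expect_equal(lab[["inAct"]], "unexpressed_gene")
    ## 'edge' straddles gE's end: >= 1 bp overlap with an expressed gene wins
    expect_equal(lab[["edge"]], "expressed_gene")
    sub <- setNames(ctx$sub_label, ctx$feature_id)
    expect_equal(sub[["inAct"]], "activated_in_mutant")
    expect_equal(sub[["inUnexp"]], "silent_in_mutant")
    expect_equal(sum(ctx$fractions), 1)
    expect_equal(sum(ctx$sub_fractions), 1)

    ## gene annotation order does not change the partition
    ctx2 <- classifyGenomicContext(featureIds(reps), reps, genes[c(3, 1, 2)],
                                   wtMeans, mutantUpGenes = "gA")
    expect_equal(ctx2$fractions, ctx$fractions)
})

test_that("density binning assigns midpoints with the half-open boundary rule", {
    ## three features with 0-based midpoints 50, 150, 100 under window 100:
    ## the boundary midpoint (exactly 100) goes to window 1
    reps <- makeRepeats("chr1", c(1, 101, 51), c(100, 200, 152),
                        rep("LTR", 3), rep("Gypsy", 3),
                        names = c("w0", "w1", "wb"))
    ## 0-based midpoints: (0+100)/2 = 50; (100+200)/2 = 150; (50+152)/2 = 101
    d <- binDensity(featureIds(reps), reps, c(chr1 = 300), window = 100L)
    expect_equal(d$count, c(1L, 2L, 0L))
    ## an exact-boundary case: span [81,120] 1-based -> 0-based [80,120), mid 100
    repsb <- makeRepeats("chr1", 81, 120, "LTR", "Gypsy", names = "b")
    db <- binDensity("b", repsb, c(chr1 = 300), window = 100L)
    expect_equal(db$count, c(0L, 1L, 0L))

    ## counts are conserved per chromosome under random placements
    set.seed(23)
    n <- 200
    s <- sample.int(9000, n, replace = TRUE)
    rr <- makeRepeats("chrZ", s, s + 50, rep("LINE", n), rep("Jockey", n),
                      names = sprintf("r%03d", 1:n))
    dd <- binDensity(featureIds(rr), rr, c(chrZ = 10000), window = 1000L)
    expect_equal(sum(dd$count), n)

    expect_warning(binDensity("b", repsb, c(chrOther = 100)), "skipped")
})
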