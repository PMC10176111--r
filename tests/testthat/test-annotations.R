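test_that("RepeatMasker .out, BED and GTF dialects load equivalent features", {
    out <- withr::local_tempfile(fileext = ".out")
    writeRmskOut(out, c(
        "  463  10.1  2.0  1.0  chr2L  100  180  (1000)  +  Gypsy-like  LTR/Gypsy  99  180  (0)  1",
        "  200   5.0  0.0  0.0  chr2L  500  620  (400)   C  Jockey-el   LINE/Jockey 1  120  (0)  2",
        "  100   1.0  0.0  0.0  chr2R  10   59   (900)   +  (AT)n       Simple_repeat 1 50 (0) 3"))
    fs <- readRepeatAnnotation(out, "repeatmasker_out")
    expect_s4_class(fs, "FeatureSet")
    expect_identical(featureKind(fs), "repeat")
    expect_equal(length(fs), 3L)
    ## 1-based inclusive source coordinates kept as GRanges 1-based closed
    expect_equal(start(fs)[1], 100)
    expect_equal(end(fs)[1], 180)
    expect_equal(as.character(mcols(fs)$order),
                 c("LTR", "LINE", "Simple_repeat"))
    expect_equal(as.character(mcols(fs)$family),
                 c("Gypsy", "Jockey", "Simple_repeat"))
    expect_equal(as.character(strand(fs))[2], "-")

    ## same annotation as BED (0-based half-open)
    bed <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("chr2L\t99\t180\tGypsy-like#LTR/Gypsy\t0\t+",
                 "chr2L\t499\t620\tJockey-el#LINE/Jockey\t0\t-",
                 "chr2R\t9\t59\t(AT)n#Simple_repeat\t0\t+"), bed)
    fs2 <- readRepeatAnnotation(bed, "bed")
    expect_equal(start(fs2), start(fs))
    expect_equal(end(fs2), end(fs))
    expect_equal(mcols(fs2)$order, mcols(fs)$order)
    expect_equal(mcols(fs2)$family, mcols(fs)$family)

    ## and as GTF (1-based inclusive, attribute dialect)
    gtf <- withr::local_tempfile(fileext = ".gtf")
    writeLines(sprintf(
        "%s\trmsk\trepeat\t%d\t%d\t.\t%s\t.\trepeat_name \"%s\"; order \"%s\"; family \"%s\";",
        c("chr2L", "chr2L", "chr2R"), c(100, 500, 10), c(180, 620, 59),
        c("+", "-", "+"), c("Gypsy-like", "Jockey-el", "(AT)n"),
        c("LTR", "LINE", "Simple_repeat"),
        c("Gypsy", "Jockey", "Simple_repeat")), gtf)
    fs3 <- readRepeatAnnotation(gtf, "gtf")
    expect_equal(start(fs3), start(fs))
    expect_equal(mcols(fs3)$family, mcols(fs)$family)
})

test_that("class strings without '/' use the order as family; unknown orders bucket to Other", {
    pr <- TEactivity:::.parseRepeatClass(c("Simple_repeat", "LTR/Pao", "rRNA"))
    expect_equal(pr$order, c("Simple_repeat", "LTR", "Other"))
    expect_equal(pr$family, c("Simple_repeat", "Pao", "rRNA"))
})

test_that("malformed coordinates are rejected with the offending record", {
    out <- withr::local_tempfile(fileext = ".out")
    writeRmskOut(out, c(
        "  463  10.1  2.0  1.0  chr2L  180  100  (1000)  +  X  LTR/Gypsy  1 80 (0) 1"))
    expect_error(readRepeatAnnotation(out, "repeatmasker_out"),
                 "malformed|start")
})

test_that("gene GTF loads models, groups exons, and enforces span containment", {
    gtf <- withr::local_tempfile(fileext = ".gtf")
    writeLines(c(
        "chr2L\tx\tgene\t1001\t2000\t.\t+\t.\tgene_id \"gA\";",
        "chr2L\tx\texon\t1001\t1200\t.\t+\t.\tgene_id \"gA\";",
        "chr2L\tx\texon\t1800\t2000\t.\t+\t.\tgene_id \"gA\";",
        "chr2R\tx\tgene\t500\t900\t.\t-\t.\tgene_id \"gB\";",
        "chr2R\tx\texon\t500\t900\t.\t-\t.\tgene_id \"gB\";"), gtf)
    genes <- readGeneAnnotation(gtf, "gtf")
    expect_equal(length(genes), 2L)
    expect_equal(featureIds(genes), c("gA", "gB"))
    expect_equal(start(genes)[1], 1001)
    expect_equal(lengths(mcols(genes)$exons), c(gA = 2L, gB = 1L),
                 ignore_attr = TRUE)

    ## gene-only file: empty exon lists, warning
    gtf2 <- withr::local_tempfile(fileext = ".gtf")
    writeLines("chr2L\tx\tgene\t1\t100\t.\t+\t.\tgene_id \"gC\";", gtf2)
    expect_warning(g2 <- readGeneAnnotation(gtf2, "gtf"), "no exon")
    expect_equal(lengths(mcols(g2)$exons), c(gC = 0L), ignore_attr = TRUE)

    ## exon outside its gene span errors naming the gene
    gtf3 <- withr::local_tempfile(fileext = ".gtf")
    writeLines(c("chr2L\tx\tgene\t1001\t2000\t.\t+\t.\tgene_id \"gD\";",
                 "chr2L\tx\texon\t900\t1200\t.\t+\t.\tgene_id \"gD\";"),
               gtf3)
    expect_error(readGeneAnnotation(gtf3, "gtf"), "gD")

    ## orphan exon errors
    gtf4 <- withr::local_tempfile(fileext = ".gtf")
    writeLines(c("chr2L\tx\tgene\t1\t100\t.\t+\t.\tgene_id \"gE\";",
                 "chr2L\tx\texon\t10\t20\t.\t+\t.\tgene_id \"gZ\";"), gtf4)
    expect_error(readGeneAnnotation(gtf4, "gtf"), "no parent")
})

test_that("piRNA cluster BED parses strand-mode labels and rejects bad tokens", {
    preBed <- withr::local_tempfile(fileext = ".bed")
    clBed <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("chr2R\t100\t400\tpre1", "chr2R\t90000\t90400\tpre2"),
               preBed)
    writeLines(c("chr2R\t0\t100000\t42AB|dual", "chrX\t0\t50000\t20A|uni"),
               clBed)
    ann <- readPiRNAAnnotations(preBed, clBed)
    expect_equal(clusterIds(ann$clusters), c("42AB", "20A"))
    expect_equal(clusterStrandMode(ann$clusters), c("dual", "uni"))
    expect_true(all(is.na(mcols(ann$precursors)$cluster_id)))

    ## empty precursor file is fine
    empty <- withr::local_tempfile(fileext = ".bed")
    writeLines(character(), empty)
    ann2 <- readPiRNAAnnotations(empty, clBed)
    expect_equal(length(ann2$precursors), 0L)

    bad <- withr::local_tempfile(fileext = ".bed")
    writeLines("chr2R\t0\t1000\t42AB|both", bad)
    expect_error(readPiRNAAnnotations(preBed, bad), "strand mode")
})

test_that("precursor-cluster assignment honours overlap fraction and tie rules", {
    clusters <- PiRNAClusterSet(GRanges(
        "chr1", IRanges(c(1, 201), c(100, 300)),
        cluster_id = c("B", "A"), strand_mode = c("dual", "uni")))
    pre <- FeatureSet(GRanges(
        "chr1", IRanges(c(10, 96, 93), c(19, 115, 108)),
        feature_id = c("in", "frac25", "tie")), "precursor")
    ## 'in' wholly inside B; 'frac25' overlaps B by 5/20 = 0.25 < 0.5;
    ## 'tie' overlaps B by 8 and nothing else at >= 0.5 of its 16 bp
    got <- assignPrecursors(pre, clusters)
    expect_equal(mcols(got)$cluster_id, c("B", NA, "B"))

    ## exact tie between two clusters goes to the smaller cluster_id
    cl2 <- PiRNAClusterSet(GRanges(
        "chr1", IRanges(c(1, 109), c(108, 200)),
        cluster_id = c("zeta", "alpha"), strand_mode = c("dual", "uni")))
    p2 <- FeatureSet(GRanges("chr1", IRanges(101, 116),
                             feature_id = "t"), "precursor")
    got2 <- assignPrecursors(p2, cl2)   # 8 bp in each cluster
    expect_equal(mcols(got2)$cluster_id, "alpha")
})

test_that("expected composition normalizes, supports both weightings, is order-invariant", {
    fs <- makeRepeats("chr1", c(1, 401, 801, 1201), c(300, 700, 900, 1500),
                      c("LTR", "LTR", "LINE", "LINE"),
                      c("Gypsy", "Pao", "Jockey", "Jockey"))
    ec <- expectedComposition(fs, "order", "element_count")
    expect_equal(ec$expected_fraction[ec$class == "LTR"], 0.5)
    expect_equal(sum(ec$expected_fraction), 1, tolerance = 1e-9)

    ## base-pair weighting: 1 LTR of 300 bp + 1 LINE of 100 bp
    fs2 <- makeRepeats("chr1", c(1, 401), c(300, 500),
                       c("LTR", "LINE"), c("Gypsy", "Jockey"))
    ec2 <- expectedComposition(fs2, "order", "base_pairs")
    expect_equal(ec2$expected_fraction[ec2$class == "LTR"], 0.75)
    expect_equal(ec2$expected_fraction[ec2$class == "LINE"], 0.25)

    ## permutation invariance and the single-class edge
    perm <- fs[c(3, 1, 4, 2)]
    expect_equal(expectedComposition(perm, "order"), ec)
    single <- makeRepeats("chr1", 1, 100, "LTR", "Gypsy")
    expect_equal(expectedComposition(single, "order")$expected_fraction, 1)
    expect_error(expectedComposition(fs[0], "order"), "empty")
})

test_that("BED round trip preserves intervals and identifiers", {
    fs <- makeRepeats("chr2L", c(100, 500), c(180, 620),
                      c("LTR", "Simple_repeat"), c("Gypsy", "Simple_repeat"),
                      names = c("Gypsy-like", "(AT)n"))
    path <- withr::local_tempfile(fileext = ".bed")
    writeFeatureBed(fs, path)
    back <- readRepeatAnnotation(path, "bed")
    expect_equal(start(back), start(fs))
    expect_equal(end(back), end(fs))
    expect_equal(featureIds(back), featureIds(fs))
    expect_equal(mcols(back)$order, mcols(fs)$order)
})

test_that("overlap queries via the GRanges index match a brute-force linear scan", {
    set.seed(11)
    for (rep in 1:3) {
        n <- 400
        chrom <- sample(c("c1", "c2"), n, replace = TRUE)
        s <- sample.int(5000, n, replace = TRUE)
        w <- sample.int(200, n, replace = TRUE)
        fs <- FeatureSet(GRanges(chrom, IRanges(s, width = w),
                                 feature_id = sprintf("f%03d", 1:n)),
                         "region")
        qs <- sample.int(5000, 50, replace = TRUE)
        queries <- GRanges(sample(c("c1", "c2"), 50, replace = TRUE),
                           IRanges(qs, width = sample.int(300, 50, TRUE)))
        hits <- findOverlaps(queries, fs)
        for (i in seq_along(queries)) {
            brute <- which(chrom == as.character(seqnames(queries))[i] &
                           s <= end(queries)[i] & (s + w - 1) >= start(queries)[i])
            expect_equal(sort(S4Vectors::subjectHits(hits)[
                S4Vectors::queryHits(hits) == i]), sort(brute))
        }
    }
})
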