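## Small in-code fixtures shared across test files.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
})

## a minimal RepeatMasker .out with the standard two header lines + blank
writeRmskOut <- function(path, records) {
    header <- c(
        "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
        "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
        "")
    writeLines(c(header, records), path)
    path
}

## SAM writer for handcrafted alignment fixtures
writeSam <- function(path, sq, records) {
    writeLines(c("@HD\tVN:1.6\tSO:unsorted",
                 sprintf("@SQ\tSN:%s\tLN:%d", names(sq), as.integer(sq)),
                 records), path)
    path
}

samRecord <- function(qname, flag, rname, pos, mapq, cigar,
                      seqlen = NULL) {
    if (is.null(seqlen)) {
        ## reference-consuming length as read length for simplicity
        seqlen <- sum(as.integer(
            regmatches(cigar, gregexpr("[0-9]+(?=[MI=X])", cigar,
                                       perl = TRUE))[[1]]))
    }
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
            qname, flag, rname, pos, mapq, cigar,
            paste(rep("A", seqlen), collapse = ""))
}

## tiny repeat FeatureSet built in code
makeRepeats <- function(chrom, starts, ends, orders, families,
                        names = NULL) {
    if (is.null(names))
        names <- sprintf("%s-el%02d", families, seq_along(starts))
    FeatureSet(GRanges(chrom, IRanges(starts, ends),
                       feature_id = names, repeat_name = names,
                       order = orders, family = families),
               "repeat")
}

## NB count matrix with groups, for DE tests
makeNBMatrix <- function(nfeat, mu, alpha, nA, nB, lfcB = 0,
                         prefix = "f") {
    muA <- matrix(mu, nfeat, nA)
    muB <- matrix(mu * 2^lfcB, nfeat, nB)
    m <- cbind(matrix(rnbinom(nfeat * nA, mu = muA, size = 1 / alpha),
                      nfeat, nA),
               matrix(rnbinom(nfeat * nB, mu = muB, size = 1 / alpha),
                      nfeat, nB))
    dimnames(m) <- list(sprintf("%s%05d", prefix, seq_len(nfeat)),
                        sprintf("s%02d", seq_len(nA + nB)))
    m
}
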