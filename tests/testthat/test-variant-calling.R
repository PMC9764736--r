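genome <- toyGenome()
refseq <- as.character(genome[[1]])

test_that("pileups tally passing reads per strand and honor mapq", {
    refBase <- substr(refseq, 20, 20)
    alt <- setdiff(c("A", "C", "G", "T"), refBase)[1]
    rs <- substr(refseq, 11, 40)
    rsAlt <- rs
    substr(rsAlt, 10, 10) <- alt
    reads <- c(
        samRead("r1", 0, 11, "30M", rs),
        samRead("r2", 0, 11, "30M", rs),
        samRead("r3", 0, 11, "30M", rsAlt),
        samRead("r4", 16, 11, "30M", rsAlt),
        samRead("lowq", 0, 11, "30M", rs, mapq = 20))
    bam <- samToBam(reads)
    pu <- buildStrandPileup(bam)
    tl <- as.data.frame(pu@tally)
    at20 <- tl[tl$pos == 20, ]
    ## manual tally: plus strand {ref: 2, alt: 1}, minus {alt: 1};
    ## the mapq-20 read contributes nothing
    expect_equal(at20$count[at20$strand == "+" &
                            at20$nucleotide == refBase], 2)
    expect_equal(at20$count[at20$strand == "+" &
                            at20$nucleotide == alt], 1)
    expect_equal(at20$count[at20$strand == "-" &
                            at20$nucleotide == alt], 1)
    expect_equal(sum(at20$count[at20$strand == "-" &
                                at20$nucleotide == refBase]), 0)
    ## per-position totals equal passing coverage
    expect_true(all(tapply(tl$count, tl$pos, sum) == 4))
})

test_that("pileup of an empty (or fully filtered) read set is empty", {
    bam <- samToBam(samRead("only", 0, 11, "30M",
                            substr(refseq, 11, 40), mapq = 20))
    pu <- buildStrandPileup(bam)
    expect_equal(nrow(pu@tally), 0)
    expect_length(callSNVs(pu, genome), 0)
})

.snvFixture <- function(nRef, nAlt, altStrandSplit = NULL) {
    refBase <- substr(refseq, 20, 20)
    alt <- setdiff(c("A", "C", "G", "T"), refBase)[1]
    rs <- substr(refseq, 11, 40)
    rsAlt <- rs
    substr(rsAlt, 10, 10) <- alt
    if (is.null(altStrandSplit))
        altStrandSplit <- c(ceiling(nAlt / 2), floor(nAlt / 2))
    reads <- character(0)
    for (i in seq_len(nRef))
        reads <- c(reads, samRead(paste0("R", i), c(0, 16)[i %% 2 + 1],
                                  11, "30M", rs))
    k <- 0
    for (i in seq_len(altStrandSplit[1]))
        reads <- c(reads, samRead(paste0("A", k <- k + 1), 0, 11,
                                  "30M", rsAlt))
    for (i in seq_len(altStrandSplit[2]))
        reads <- c(reads, samRead(paste0("A", k <- k + 1), 16, 11,
                                  "30M", rsAlt))
    samToBam(reads)
}

test_that("SNV thresholds: coverage, alternate reads, AF, strand bias", {
    ## 6 ref + 4 alt (cov 10, AF 0.4, alt on both strands) -> called
    calls <- callSNVs(buildStrandPileup(.snvFixture(6, 4)), genome)
    expect_length(calls, 1)
    expect_equal(calls$af, 0.4)
    expect_equal(calls$kind, "SNV")
    ## 26 ref + 4 alt (AF 0.133) -> not called
    expect_length(callSNVs(buildStrandPileup(.snvFixture(26, 4)),
                           genome), 0)
    ## 5 ref + 4 alt (cov 9) -> not called
    expect_length(callSNVs(buildStrandPileup(.snvFixture(5, 4)),
                           genome), 0)
    ## all 4 alt reads on one strand -> strand-bias filtered
    oneStrand <- .snvFixture(6, 4, altStrandSplit = c(4, 0))
    expect_length(callSNVs(buildStrandPileup(oneStrand), genome), 0)
    ## ... unless the protocol is stranded
    sp <- CallingParams(strandedProtocol = TRUE)
    expect_length(callSNVs(buildStrandPileup(oneStrand, sp), genome,
                           sp), 1)
})

test_that("every emitted SNV call satisfies the calling predicates", {
    params <- CallingParams(minTotalCoverage = 5)
    calls <- callSNVs(buildStrandPileup(.snvFixture(3, 4), params),
                      genome, params)
    for (i in seq_along(calls)) {
        nAlt <- calls$nAltFwd[i] + calls$nAltRev[i]
        cov <- nAlt + calls$nRefFwd[i] + calls$nRefRev[i]
        expect_gte(cov, params@minTotalCoverage)
        expect_gte(nAlt, params@minAltReads)
        expect_gte(calls$af[i], params@minAltAF)
        expect_gte(min(calls$nAltFwd[i], calls$nAltRev[i]) / nAlt,
                   params@minAltStrandFraction)
    }
})

test_that("indel calling clusters CIGAR events and filters them", {
    delseq <- paste0(substr(refseq, 11, 20), substr(refseq, 23, 40))
    rs <- substr(refseq, 11, 40)
    reads <- c(
        vapply(1:3, function(i) samRead(paste0("d", i), 0, 11,
                                        "10M2D18M", delseq),
               character(1)),
        vapply(4:5, function(i) samRead(paste0("d", i), 16, 11,
                                        "10M2D18M", delseq),
               character(1)),
        vapply(1:3, function(i) samRead(paste0("m", i),
                                        c(0, 16)[i %% 2 + 1], 11,
                                        "30M", rs), character(1)))
    bam <- samToBam(reads)
    params <- CallingParams(minTotalCoverage = 5)
    calls <- callIndels(bam, genome, params)
    expect_length(calls, 1)
    expect_equal(calls$kind, "deletion")
    ## 5 deletion-supporting reads clustered into one call
    expect_equal(calls$nAltFwd + calls$nAltRev, 5)
    expect_gt(nchar(calls$ref), nchar(calls$alt))
    ## match-only CIGARs produce no indels
    bam2 <- samToBam(vapply(1:6, function(i)
        samRead(paste0("m", i), 0, 11, "30M", rs), character(1)))
    expect_length(callIndels(bam2, genome, params), 0)
    ## 4 alt reads all on one strand -> strand-bias filtered
    reads1s <- c(vapply(1:4, function(i)
        samRead(paste0("d", i), 0, 11, "10M2D18M", delseq),
        character(1)),
        vapply(1:4, function(i) samRead(paste0("m", i), 16, 11, "30M",
                                        rs), character(1)))
    expect_length(callIndels(samToBam(reads1s), genome, params), 0)
})

test_that("calls are sorted and VCF output round-trips", {
    calls <- callSNVs(buildStrandPileup(.snvFixture(6, 4)), genome)
    vcf <- tempfile(fileext = ".vcf")
    writeVariantVCF(calls, vcf, tsv = tempfile(fileext = ".tsv"))
    back <- readVcfVariants(vcf)
    expect_equal(start(back), start(calls))
    expect_equal(back$ref, calls$ref)
    expect_equal(back$alt, calls$alt)
    expect_equal(back$kind, calls$kind)
})
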