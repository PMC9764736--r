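genome <- toyGenome()
refseq <- as.character(genome[[1]])

test_that("allele counting assigns reads to cells via CB tags", {
    refBase <- substr(refseq, 20, 20)
    alt <- setdiff(c("A", "C", "G", "T"), refBase)[1]
    rs <- substr(refseq, 11, 40)
    rsAlt <- rs; substr(rsAlt, 10, 10) <- alt
    reads <- c(
        vapply(1:5, function(i) samRead(paste0("r", i),
                                        c(0, 16)[i %% 2 + 1], 11,
                                        "30M", rs, barcode = "CELL1"),
               character(1)),
        vapply(1:3, function(i) samRead(paste0("a", i), 0, 11, "30M",
                                        rsAlt, barcode = "CELL1"),
               character(1)),
        samRead("x", 0, 11, "30M", rs, barcode = "CELL2"),
        samRead("untagged", 0, 11, "30M", rs))
    bam <- samToBam(reads)
    vr <- makeVariant(20, refBase, alt)
    expect_message(acm <- countAlleles(bam, vr), "without CB barcode")
    ## CELL1: 3 alt + 5 ref -> AF 0.375; CELL2: covering ref read only
    expect_equal(unname(refCount(acm)[1, c("CELL1", "CELL2")]), c(5, 1))
    expect_equal(unname(altCount(acm)[1, c("CELL1", "CELL2")]), c(3, 0))
    expect_equal(unname(altAF(acm)[1, "CELL1"]), 0.375)
    expect_equal(metadata(acm)$droppedNoBarcode, 1L)
    ## a cell with no covering reads -> (0, 0), AF 0, RD 0
    acm2 <- countAlleles(bam, vr, cells = c("CELL1", "CELL2", "GHOST"))
    expect_equal(unname(readDepth(acm2)[1, "GHOST"]), 0)
    expect_equal(unname(altAF(acm2)[1, "GHOST"]), 0)
})

test_that("bulk mode makes each BAM file one column", {
    refBase <- substr(refseq, 20, 20)
    alt <- setdiff(c("A", "C", "G", "T"), refBase)[1]
    rs <- substr(refseq, 11, 40)
    rsAlt <- rs; substr(rsAlt, 10, 10) <- alt
    bam1 <- samToBam(c(samRead("r1", 0, 11, "30M", rs),
                       samRead("r2", 16, 11, "30M", rsAlt)))
    bam2 <- samToBam(samRead("r1", 0, 11, "30M", rs))
    acm <- countAlleles(c(s1 = bam1, s2 = bam2),
                        makeVariant(20, refBase, alt), mode = "bulk")
    expect_equal(colnames(acm), c("s1", "s2"))
    expect_equal(unname(altCount(acm)[1, ]), c(1, 0))
    expect_equal(unname(refCount(acm)[1, ]), c(1, 1))
})

test_that("arm-level matrix marks arms covered by half or more", {
    arms <- armsFromBands(syntheticCytoband())
    ## 17q spans [24e6, 78e6) in the synthetic table
    q17 <- arms["17q", ]
    full <- data.frame(cell = "A", chrom = "chr17", start = q17$start,
                       end = q17$end, state = "del")
    tiny <- data.frame(cell = "B", chrom = "chr17", start = q17$start,
                       end = q17$start + 1e6, state = "del")
    none <- data.frame(cell = "C", chrom = "chr2", start = 1e6,
                       end = 2e6, state = "amp")
    m <- armLevelMatrix(rbind(full, tiny, none), arms)
    expect_equal(nrow(m$del), 44)
    expect_equal(nrow(m$amp), 44)
    expect_equal(unname(assay(m$del, "calls")["del_17q", ]),
                 c(A = 1, B = 0, C = 0), ignore_attr = TRUE)
    ## cell with no CNV of a state -> all-zero column
    expect_equal(sum(assay(m$del, "calls")[, "C"]), 0)
    expect_equal(sum(assay(m$amp, "calls")[, "A"]), 0)
    expect_warning(armLevelMatrix(
        data.frame(cell = "A", chrom = "chrWeird", start = 1, end = 2,
                   state = "del"), arms), "skipped")
})

test_that("minimal segments decompose pooled breakpoints", {
    cnv <- data.frame(cell = c("A", "B"), chrom = "chr1",
                      start = c(100, 200), end = c(300, 400),
                      state = "del")
    m <- minimalSegmentMatrix(cnv)$del
    rd <- as.data.frame(rowData(m))
    expect_equal(rd$start, c(100, 200, 300))
    expect_equal(rd$end, c(200, 300, 400))
    expect_equal(unname(assay(m, "calls")[, "A"]), c(1, 1, 0))
    expect_equal(unname(assay(m, "calls")[, "B"]), c(0, 1, 1))
    ## single CNV in one cell -> one segment equal to it
    one <- minimalSegmentMatrix(data.frame(cell = "A", chrom = "chr1",
                                           start = 5, end = 50,
                                           state = "amp"))$amp
    expect_equal(nrow(one), 1)
    expect_equal(as.data.frame(rowData(one))$start, 5)
    ## identical CNVs in two cells -> one segment, both entries 1
    two <- minimalSegmentMatrix(data.frame(cell = c("A", "B"),
                                           chrom = "chr1", start = 5,
                                           end = 50, state = "del"))$del
    expect_equal(nrow(two), 1)
    expect_equal(unname(assay(two, "calls")[1, ]), c(1, 1))
})

test_that("minimal segments reconstruct every cell's intervals exactly", {
    set.seed(99)
    for (rep in 1:60) {
        cnv <- randomCNVSet()
        m <- minimalSegmentMatrix(cnv, states = "del")$del
        gr <- GRanges(cnv$chrom, IRanges::IRanges(cnv$start + 1L,
                                                  cnv$end))
        ## union of output segments equals union of input CNVs
        rd <- as.data.frame(rowData(m))
        segGR <- GRanges(rd$chrom, IRanges::IRanges(rd$start + 1L,
                                                    rd$end))
        expect_identical(reduce(segGR), reduce(gr))
        for (cc in unique(cnv$cell)) {
            want <- reduce(gr[cnv$cell == cc])
            got <- reconstructCell(m, cc)
            expect_identical(got, want)
        }
    }
})

test_that("variant-set fractions count expressed variants per cell", {
    set.seed(1)
    alt <- matrix(0L, 10, 3,
                  dimnames = list(paste0("v", 1:10), paste0("c", 1:3)))
    ref <- matrix(5L, 10, 3, dimnames = dimnames(alt))
    alt[, 1] <- 1L                      # c1 expresses all 10
    alt[1:3, 3] <- 1L                   # c3 expresses 3 of 10
    acm <- AlleleCountMatrix(ref, alt)
    f <- variantSetFraction(acm, rownames(acm))
    expect_equal(unname(f), c(1, 0, 0.3))
    ## monotone non-decreasing as the cutoff decreases
    f2 <- variantSetFraction(acm, rownames(acm), cutoff = 0.5)
    expect_true(all(f2 <= f))
    expect_error(variantSetFraction(acm, character(0)), "empty")
    ## accessible denominator: cells without accessible variants -> NA
    ref0 <- ref; ref0[, 2] <- 0L
    acm0 <- AlleleCountMatrix(ref0, alt)
    fa <- variantSetFraction(acm0, rownames(acm0),
                             denominator = "accessible")
    expect_true(is.na(fa[2]))
    expect_equal(unname(fa[c(1, 3)]), c(1, 0.3))
})

test_that("dropout rates are zero-count fractions overall and per chromosome", {
    counts <- matrix(0L, 100, 2,
                     dimnames = list(paste0("g", 1:100), c("c1", "c2")))
    counts[1:14, 2] <- 1L
    chrom <- setNames(rep(c("chr1", "chr2"), each = 50),
                      rownames(counts))
    dr <- dropoutRates(counts, chrom)
    expect_equal(unname(dr$overall), c(1, 0.86))
    expect_equal(dr$perChromosome["chr1", "c2"], 36 / 50)
    ## all genes nonzero -> 0
    expect_equal(unname(dropoutRates(counts + 1L)$overall), c(0, 0))
})

test_that("allele count matrices round-trip through TSV and MatrixMarket", {
    set.seed(5)
    ref <- matrix(rpois(12, 3), 3, 4)
    alt <- matrix(rpois(12, 1), 3, 4)
    acm <- AlleleCountMatrix(ref, alt)
    p <- tempfile(fileext = ".tsv")
    writeAlleleCountsTSV(acm, p)
    back <- readAlleleCountsTSV(p)
    expect_equal(refCount(back), refCount(acm))
    expect_equal(altCount(back), altCount(acm))
    pre <- tempfile()
    writeAlleleCountsMM(acm, pre)
    backMM <- readAlleleCountsMM(pre)
    expect_equal(altCount(backMM), altCount(acm), ignore_attr = FALSE)
})

test_that("binary CNV matrices convert to unit-depth allele counts", {
    cnv <- data.frame(cell = c("A", "B"), chrom = "chr1",
                      start = c(100, 200), end = c(300, 400),
                      state = "del")
    acm <- cnvToAlleleCounts(minimalSegmentMatrix(cnv)$del)
    expect_true(all(readDepth(acm) == 1))
    expect_equal(unname(altAF(acm)[, "A"]), c(1, 1, 0))
})
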