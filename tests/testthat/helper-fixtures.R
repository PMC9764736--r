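## Shared fixtures: in-code genome/GTF/SAM builders and independent
## brute-force oracles used across the test files.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
    library(IRanges)
    library(SummarizedExperiment)
})

## --- tiny reference genome and SAM/BAM builders ------------------------

toyGenome <- function(seed = 42, len = 60) {
    set.seed(seed)
    s <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
    g <- Biostrings::DNAStringSet(s)
    names(g) <- "chr1"
    g
}

samRead <- function(name, flag, pos, cigar, seq, mapq = 60,
                    barcode = NULL, chrom = "chr1") {
    tag <- if (is.null(barcode)) NULL else paste0("CB:Z:", barcode)
    paste(c(name, flag, chrom, pos, mapq, cigar, "*", 0, 0, seq,
            paste(rep("I", nchar(seq)), collapse = ""), tag),
          collapse = "\t")
}

## Writes a SAM (header + read lines), converts to sorted indexed BAM.
samToBam <- function(readLines0, len = 60, chrom = "chr1") {
    td <- tempfile("sam")
    dir.create(td)
    sam <- file.path(td, "t.sam")
    writeLines(c("@HD\tVN:1.6",
                 sprintf("@SQ\tSN:%s\tLN:%d", chrom, len), readLines0),
               sam)
    Rsamtools::asBam(sam, file.path(td, "t"), overwrite = TRUE,
                     indexDestination = TRUE)
}

## A toy gene model: plus-strand 2-exon CDS on the 60 bp chromosome.
## CDS1 11-22 (ATGGCTGCAAAA), intron 23-30, CDS2 31-42 (GCCGCTAAATAA).
toyCodingGenome <- function() {
    g <- paste0(strrep("T", 10), "ATGGCTGCAAAA", strrep("G", 8),
                "GCCGCTAAATAA", strrep("T", 18))
    gs <- Biostrings::DNAStringSet(g)
    names(gs) <- "chr1"
    gs
}

toyGtf <- function(path = tempfile(fileext = ".gtf")) {
    att <- "gene_id \"G1\"; transcript_id \"T1\";"
    writeLines(c(
        paste("chr1", "toy", "exon", "11", "22", ".", "+", ".", att,
              sep = "\t"),
        paste("chr1", "toy", "exon", "31", "42", ".", "+", ".", att,
              sep = "\t"),
        paste("chr1", "toy", "CDS", "11", "22", ".", "+", ".", att,
              sep = "\t"),
        paste("chr1", "toy", "CDS", "31", "42", ".", "+", ".", att,
              sep = "\t")), path)
    path
}

makeVariant <- function(pos, ref, alt, kind = "SNV", chrom = "chr1") {
    gr <- GRanges(chrom, IRanges::IRanges(pos, width = nchar(ref)))
    mcols(gr) <- DataFrame(ref = ref, alt = alt, kind = kind)
    names(gr) <- paste0(chrom, ":", pos, "_", ref, "/", alt)
    gr
}

## --- independent oracles ------------------------------------------------

## Upper-tail binomial by direct log-space term summation.
oracleBinomTail <- function(nAlt, n, p) {
    if (nAlt <= 0) return(1)
    if (nAlt > n) return(0)
    r <- nAlt:n
    terms <- lchoose(n, r) + r * log(p) + (n - r) * log1p(-p)
    if (p == 0) return(0)
    if (p == 1) return(1)
    m <- max(terms)
    exp(m) * sum(exp(terms - m))
}

## One-sided Fisher p by hypergeometric enumeration from choose().
oracleFisherUpper <- function(a, b, cc, d) {
    n <- a + b + cc + d
    k1 <- a + cc        # column-1 total
    r1 <- a + b         # row-1 total
    xs <- max(0, r1 + k1 - n):min(r1, k1)
    pr <- exp(lchoose(k1, xs) + lchoose(n - k1, r1 - xs) -
              lchoose(n, r1))
    sum(pr[xs >= a])
}

## Brute-force strict local maxima over k-nearest neighborhoods.
oracleLocalMax <- function(coords, values, k) {
    n <- nrow(coords)
    D <- as.matrix(stats::dist(coords))
    out <- integer(0)
    for (i in seq_len(n)) {
        if (values[i] <= 0) next
        nbr <- order(D[i, ])[2:(k + 1)]
        if (all(values[i] > values[nbr])) out <- c(out, i)
    }
    out
}

## Double-loop Euclidean distances.
oracleDist <- function(coords) {
    n <- nrow(coords)
    D <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
        D[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    D
}

## Reconstruct one cell's intervals from its minimal-segment calls and
## compare with its merged input intervals.
reconstructCell <- function(segMat, cell) {
    rd <- as.data.frame(SummarizedExperiment::rowData(segMat))
    hit <- SummarizedExperiment::assay(segMat, "calls")[, cell] == 1
    if (!any(hit)) return(NULL)
    gr <- GRanges(rd$chrom[hit],
                  IRanges::IRanges(rd$start[hit] + 1L, rd$end[hit]))
    GenomicRanges::reduce(gr)
}

randomCNVSet <- function(nCells = 4, maxSegs = 3, chromLen = 1000,
                         state = "del") {
    rows <- list()
    for (cc in seq_len(nCells)) {
        k <- sample.int(maxSegs, 1)
        for (s in seq_len(k)) {
            st <- sample.int(chromLen - 10, 1)
            en <- st + sample.int(200, 1)
            rows[[length(rows) + 1L]] <- data.frame(
                cell = paste0("c", cc), chrom = "chr1", start = st,
                end = min(en, chromLen), state = state)
        }
    }
    do.call(rbind, rows)
}
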