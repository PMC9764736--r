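## Binary CNV matrices at two length scales: whole chromosome arms
## (44 autosomal arms per state) and minimal disjoint segments obtained
## by pooling all breakpoints.  Coordinates are BED-style 0-based
## half-open externally and internally.

#' Read chromosome-arm definitions from a UCSC cytoBand file
#'
#' @param path cytoBand.txt-format file (chrom, start, end, band,
#'   gieStain; no header), plain or gzipped.
#' @return data.frame with one row per arm: \code{chrom}, \code{arm}
#'   (e.g. "17q"), \code{start}, \code{end} (0-based half-open).
#' @export
readCytoband <- function(path) {
    bands <- utils::read.table(path, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE,
                               col.names = c("chrom", "start", "end",
                                             "band", "gieStain"))
    armsFromBands(bands)
}

#' @param bands a cytoBand-format data.frame.
#' @rdname readCytoband
#' @export
armsFromBands <- function(bands) {
    bands$armLetter <- substr(bands$band, 1L, 1L)
    bands <- bands[bands$armLetter %in% c("p", "q"), ]
    key <- paste0(bands$chrom, bands$armLetter)
    out <- data.frame(
        chrom = tapply(bands$chrom, key, `[`, 1L),
        arm = tapply(paste0(sub("^chr", "", bands$chrom),
                            bands$armLetter), key, `[`, 1L),
        start = as.integer(tapply(bands$start, key, min)),
        end = as.integer(tapply(bands$end, key, max)),
        stringsAsFactors = FALSE)
    rownames(out) <- out$arm
    ord <- order(match(out$chrom, unique(bands$chrom)), out$arm)
    out[ord, ]
}

#' Synthetic cytoband table
#'
#' A synthetic stand-in for a UCSC cytoBand file: approximate chromosome
#' lengths for the 22 autosomes and X, with a p/q split at an approximate
#' centromere position and two bands per arm.  Intended for tests and
#' examples only; real analyses should supply the genome's cytoBand
#' file.
#'
#' @return a cytoBand-format data.frame.
#' @export
syntheticCytoband <- function() {
    lenMb <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135,
               134, 115, 107, 102, 90, 81, 78, 59, 63, 48, 51, 155)
    cenMb <- c(125, 93, 91, 50, 48, 61, 60, 45, 49, 40, 53, 36, 18, 17,
               19, 37, 24, 17, 26, 28, 13, 15, 61)
    chroms <- paste0("chr", c(1:22, "X"))
    do.call(rbind, lapply(seq_along(chroms), function(i) {
        len <- lenMb[i] * 1e6; cen <- cenMb[i] * 1e6
        data.frame(chrom = chroms[i],
                   start = c(0, cen %/% 2, cen, cen + (len - cen) %/% 2),
                   end = c(cen %/% 2, cen, cen + (len - cen) %/% 2, len),
                   band = c("p12", "p11", "q11", "q12"),
                   gieStain = c("gneg", "gpos50", "gneg", "gpos50"),
                   stringsAsFactors = FALSE)
    }))
}

#' Read per-cell CNV calls
#'
#' Expects a TSV with header \code{cell_id chrom start end state}
#' (BED-style 0-based half-open coordinates, state "amp" or "del").
#'
#' @param path input file.
#' @return data.frame of CNV calls.
#' @export
readCNVCalls <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    names(df)[names(df) == "cell_id"] <- "cell"
    stopifnot(all(c("cell", "chrom", "start", "end", "state") %in%
                  names(df)))
    df
}

.cnvGRanges <- function(cnv) {
    GRanges(cnv$chrom, IRanges(cnv$start + 1L, cnv$end),
            cell = cnv$cell, state = cnv$state)
}

.cnvStates <- function(cnv, states) {
    found <- intersect(states, unique(cnv$state))
    if (!length(found)) stop("no CNV calls in states: ",
                             paste(states, collapse = ", "))
    found
}

#' Arm-level binary CNV matrix
#'
#' For each state (amplification/deletion) separately, marks a cell as
#' carrying an arm-level event when its (merged) CNV calls of that state
#' cover at least \code{armOverlapFraction} of the arm.  The matrix has
#' one row per autosomal arm (44 rows) regardless of which arms carry
#' events.
#'
#' @param cnv CNV call data.frame (see \code{\link{readCNVCalls}}).
#' @param arms arm definitions from \code{\link{readCytoband}} /
#'   \code{\link{armsFromBands}}.
#' @param armOverlapFraction minimum fraction of the arm covered
#'   (default 0.5).
#' @param states states to build matrices for.
#' @param cells optional cell universe fixing column order.
#' @return named list of \code{\link{CNVSegmentMatrix-class}} objects,
#'   one per state.
#' @export
armLevelMatrix <- function(cnv, arms, armOverlapFraction = 0.5,
                           states = c("amp", "del"), cells = NULL) {
    autosomal <- arms[arms$chrom %in% paste0("chr", 1:22), ]
    armsGR <- GRanges(autosomal$chrom,
                      IRanges(autosomal$start + 1L, autosomal$end))
    names(armsGR) <- autosomal$arm
    if (is.null(cells)) cells <- sort(unique(cnv$cell))
    unknown <- setdiff(unique(cnv$chrom), arms$chrom)
    if (length(unknown)) {
        warning("CNV calls on chromosomes without arm definitions ",
                "skipped: ", paste(unknown, collapse = ", "))
        cnv <- cnv[!cnv$chrom %in% unknown, ]
    }
    out <- lapply(states, function(st) {
        m <- matrix(0L, length(armsGR), length(cells),
                    dimnames = list(paste0(st, "_", names(armsGR)),
                                    cells))
        sub <- cnv[cnv$state == st, , drop = FALSE]
        if (nrow(sub)) {
            gr <- .cnvGRanges(sub)
            byCell <- reduce(GenomicRanges::split(gr, gr$cell))
            for (cc in names(byCell)) {
                hits <- findOverlaps(armsGR, byCell[[cc]])
                if (!length(hits)) next
                ov <- width(pintersect(armsGR[S4Vectors::queryHits(hits)],
                                       byCell[[cc]][S4Vectors::subjectHits(hits)]))
                cov <- tapply(ov, S4Vectors::queryHits(hits), sum)
                armIdx <- as.integer(names(cov))
                frac <- cov / width(armsGR)[armIdx]
                m[armIdx, cc] <- as.integer(frac >= armOverlapFraction)
            }
        }
        rd <- DataFrame(chrom = autosomal$chrom,
                        start = autosomal$start, end = autosomal$end,
                        arm = autosomal$arm, state = st)
        new("CNVSegmentMatrix",
            SummarizedExperiment(assays = SimpleList(calls = m),
                                 rowData = rd))
    })
    names(out) <- states
    out
}

#' Minimal-segment binary CNV matrix
#'
#' For each state separately, pools the breakpoints of all cells' CNV
#' calls on each chromosome and cuts the covered regions at every
#' breakpoint, yielding the minimal set of disjoint segments none of
#' which straddles a breakpoint.  A cell's entry for a segment is 1 when
#' one of its calls of that state covers the segment (coverage is always
#' all-or-none by construction).
#'
#' @inheritParams armLevelMatrix
#' @return named list of \code{\link{CNVSegmentMatrix-class}} objects,
#'   one per state present.
#' @export
minimalSegmentMatrix <- function(cnv, states = c("amp", "del"),
                                 cells = NULL) {
    states <- .cnvStates(cnv, states)
    if (is.null(cells)) cells <- sort(unique(cnv$cell))
    out <- lapply(states, function(st) {
        sub <- cnv[cnv$state == st, , drop = FALSE]
        gr <- .cnvGRanges(sub)
        segs <- disjoin(gr)
        segs <- segs[width(segs) > 0]
        m <- matrix(0L, length(segs), length(cells),
                    dimnames = list(sprintf("%s_%s:%d-%d", st,
                                            seqnames(segs),
                                            start(segs) - 1L, end(segs)),
                                    cells))
        hits <- findOverlaps(segs, gr, type = "within")
        if (length(hits)) {
            cellIdx <- match(gr$cell[S4Vectors::subjectHits(hits)], cells)
            m[cbind(S4Vectors::queryHits(hits), cellIdx)] <- 1L
        }
        rd <- DataFrame(chrom = as.character(seqnames(segs)),
                        start = start(segs) - 1L, end = end(segs),
                        state = st)
        new("CNVSegmentMatrix",
            SummarizedExperiment(assays = SimpleList(calls = m),
                                 rowData = rd))
    })
    names(out) <- states
    out
}

#' Convert a binary CNV matrix to an allele count matrix
#'
#' Each segment becomes a pseudo-variant with one read per cell: an
#' alternate read where the cell carries the event, a reference read
#' otherwise.  The resulting AFs are the binary calls and every cell is
#' eligible for RD-aware shuffling, so CNV matrices flow through
#' \code{\link{detectClumps}} unchanged.
#'
#' @param x a \code{\link{CNVSegmentMatrix-class}}.
#' @return an \code{\link{AlleleCountMatrix-class}}.
#' @export
cnvToAlleleCounts <- function(x) {
    stopifnot(is(x, "CNVSegmentMatrix"))
    calls <- assay(x, "calls")
    AlleleCountMatrix(refCount = 1L - calls, altCount = calls,
                      rowData = rowData(x))
}
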