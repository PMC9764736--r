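## Pileup-based SNV calling and CIGAR-based indel calling with the
## relaxed coverage/AF/strand-bias filtering regime.  Pileup generation
## is delegated to Rsamtools (duplicate flag honored, mapping quality
## filtered); the calling logic on top of the tallies lives here.

#' Build strand-specific pileups from a BAM file
#'
#' Tallies A/C/G/T/N per position and strand from reads passing the
#' mapping-quality filter (mapq strictly greater than
#' \code{params@minMapq}), with duplicate-marked and unmapped reads
#' excluded.  Deletion-spanning reads are tallied under nucleotide
#' \code{"-"} and insertion starts under \code{"+"}.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param params a \code{\link{CallingParams-class}}.
#' @param which optional \code{GRanges} restricting the region.
#' @return a \code{\link{StrandPileup-class}}; empty input yields an
#'   empty pileup.
#' @export
buildStrandPileup <- function(bam, params = CallingParams(),
                              which = NULL) {
    flags <- scanBamFlag(isDuplicate = FALSE, isUnmappedQuery = FALSE)
    sbp <- if (is.null(which)) ScanBamParam(flag = flags)
           else ScanBamParam(flag = flags, which = which)
    pp <- PileupParam(max_depth = 1000000L, min_base_quality = 0L,
                      min_mapq = as.integer(params@minMapq) + 1L,
                      min_nucleotide_depth = 1L,
                      distinguish_strands = TRUE,
                      distinguish_nucleotides = TRUE,
                      include_deletions = TRUE,
                      include_insertions = TRUE)
    res <- pileup(BamFile(bam), scanBamParam = sbp, pileupParam = pp)
    tally <- DataFrame(seqnames = as.character(res$seqnames),
                       pos = res$pos,
                       strand = as.character(res$strand),
                       nucleotide = as.character(res$nucleotide),
                       count = res$count)
    new("StrandPileup", tally = tally, params = params)
}

.refBaseAt <- function(genome, chrom, pos) {
    if (!chrom %in% names(genome))
        stop("chromosome not in reference: ", chrom)
    if (any(pos < 1 | pos > length(genome[[chrom]])))
        stop("position beyond chromosome bounds on ", chrom)
    as.character(Biostrings::extractAt(genome[[chrom]],
                                       IRanges(pos, pos)))
}

.passesStrandBias <- function(fwd, rev, params) {
    if (params@strandedProtocol) return(rep(TRUE, length(fwd)))
    tot <- fwd + rev
    ok <- tot > 0 & pmin(fwd, rev) / pmax(tot, 1) >=
        params@minAltStrandFraction
    ok
}

#' Call SNVs from a strand-specific pileup
#'
#' A site/alternate-allele pair is called when: combined-strand coverage
#' is at least \code{minTotalCoverage}; alternate reads number at least
#' \code{minAltReads}; the alternate AF (alternate reads over coverage)
#' is at least \code{minAltAF}; and, unless the protocol is stranded,
#' the minority strand holds at least \code{minAltStrandFraction} of the
#' alternate reads.  Every passing alternate allele at a multi-allelic
#' site is reported as its own call.  Coverage counts every read
#' covering the position (including deletion-spanning reads); insertion
#' events do not consume a reference base and are excluded.
#'
#' @param pileup a \code{\link{StrandPileup-class}}.
#' @param genome a named \code{DNAStringSet} (chromosome sequences).
#' @param params a \code{\link{CallingParams-class}} (should match the
#'   pileup's).
#' @return a \code{GRanges} sorted by (chrom, pos, alt) with metadata
#'   columns ref, alt, kind, nRefFwd, nRefRev, nAltFwd, nAltRev, af.
#' @export
callSNVs <- function(pileup, genome, params = pileup@params) {
    tl <- as.data.frame(pileup@tally)
    tl <- tl[tl$nucleotide != "+", , drop = FALSE]
    if (!nrow(tl)) return(.emptyCalls())
    key <- paste(tl$seqnames, tl$pos)
    cov <- tapply(tl$count, key, sum)
    calls <- list()
    for (site in names(cov)[cov >= params@minTotalCoverage]) {
        rows <- tl[key == site, ]
        chrom <- rows$seqnames[1]; pos <- rows$pos[1]
        refBase <- .refBaseAt(genome, chrom, pos)
        cnt <- function(nt, str) sum(rows$count[rows$nucleotide == nt &
                                                rows$strand == str])
        for (altBase in setdiff(intersect(unique(rows$nucleotide),
                                          c("A", "C", "G", "T")),
                                refBase)) {
            aFwd <- cnt(altBase, "+"); aRev <- cnt(altBase, "-")
            nAlt <- aFwd + aRev
            af <- nAlt / cov[[site]]
            if (nAlt < params@minAltReads || af < params@minAltAF) next
            if (!all(.passesStrandBias(aFwd, aRev, params))) next
            calls[[length(calls) + 1L]] <- data.frame(
                chrom = chrom, pos = pos, ref = refBase, alt = altBase,
                kind = "SNV", nRefFwd = cnt(refBase, "+"),
                nRefRev = cnt(refBase, "-"), nAltFwd = aFwd,
                nAltRev = aRev, af = af, stringsAsFactors = FALSE)
        }
    }
    .callsToGRanges(do.call(rbind, calls))
}

.emptyCalls <- function() {
    gr <- GRanges()
    mcols(gr) <- DataFrame(ref = character(0), alt = character(0),
                           kind = character(0), nRefFwd = integer(0),
                           nRefRev = integer(0), nAltFwd = integer(0),
                           nAltRev = integer(0), af = numeric(0))
    gr
}

.callsToGRanges <- function(df) {
    if (is.null(df) || !nrow(df)) return(.emptyCalls())
    df <- df[order(df$chrom, df$pos, df$alt), , drop = FALSE]
    gr <- GRanges(df$chrom, IRanges(df$pos, width = nchar(df$ref)))
    mcols(gr) <- DataFrame(df[, c("ref", "alt", "kind", "nRefFwd",
                                  "nRefRev", "nAltFwd", "nAltRev",
                                  "af")])
    names(gr) <- paste0(df$chrom, ":", df$pos, "_", df$ref, "/", df$alt)
    gr
}

## Left-normalize a deletion/insertion event against the reference:
## shift left while the base preceding the event equals its last base.
.leftNormalize <- function(genome, chrom, start, seq) {
    while (start > 1) {
        prev <- .refBaseAt(genome, chrom, start - 1L)
        if (prev != substr(seq, nchar(seq), nchar(seq))) break
        seq <- paste0(prev, substr(seq, 1L, nchar(seq) - 1L))
        start <- start - 1L
    }
    list(start = start, seq = seq)
}

#' Call indels from CIGAR strings
#'
#' Scans duplicate- and mapq-filtered reads for insertion/deletion CIGAR
#' operations, left-normalizes each event against the reference,
#' clusters the events by (position, inserted/deleted sequence), and
#' applies the same coverage, alternate-read, AF and strand-bias filters
#' as SNV calling.  The AF denominator is the number of reads spanning
#' the event (alternate-supporting reads plus reads aligned across the
#' locus without the indel).
#'
#' Calls are reported in VCF anchored convention: position is the
#' reference base immediately left of the event, \code{ref} and
#' \code{alt} include the anchor base, so deletions have
#' \code{nchar(ref) > nchar(alt)} and insertions the reverse.
#'
#' @param bam path to a BAM file.
#' @param genome a named \code{DNAStringSet}.
#' @param params a \code{\link{CallingParams-class}}.
#' @return a \code{GRanges} of indel calls (same columns as
#'   \code{\link{callSNVs}}).
#' @export
callIndels <- function(bam, genome, params = CallingParams()) {
    reads <- .loadReadsForCounting(bam, params, FALSE)
    if (!length(reads$start)) return(.emptyCalls())
    events <- list()
    for (r in seq_along(reads$start)) {
        chrom <- reads$chrom[r]
        del <- reads$delRanges[[r]]
        for (k in seq_along(del)) {
            seq <- .refBaseAt(genome, chrom,
                              start(del)[k]:(end(del)[k]))
            seq <- paste(seq, collapse = "")
            nm <- .leftNormalize(genome, chrom, start(del)[k], seq)
            events[[length(events) + 1L]] <- data.frame(
                chrom = chrom, eventStart = nm$start, seq = nm$seq,
                type = "deletion", strand = reads$strand[r],
                stringsAsFactors = FALSE)
        }
        ins <- reads$insRanges[[r]]
        if (length(ins)) {
            insQ <- cigarRangesAlongQuerySpace(
                cigar(reads$ga)[r], ops = "I")[[1]]
            for (k in seq_along(ins)) {
                seq <- as.character(subseq(mcols(reads$ga)$seq[r],
                                           start(insQ)[k],
                                           end(insQ)[k]))
                nm <- .leftNormalize(genome, chrom, end(ins)[k] + 1L,
                                     seq)
                events[[length(events) + 1L]] <- data.frame(
                    chrom = chrom, eventStart = nm$start, seq = nm$seq,
                    type = "insertion", strand = reads$strand[r],
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(events)) return(.emptyCalls())
    ev <- do.call(rbind, events)
    key <- paste(ev$chrom, ev$eventStart, ev$type, ev$seq)
    calls <- list()
    for (kk in unique(key)) {
        grp <- ev[key == kk, ]
        chrom <- grp$chrom[1]; eventStart <- grp$eventStart[1]
        type <- grp$type[1]; seq <- grp$seq[1]
        anchor <- eventStart - 1L
        if (anchor < 1) next   # no reference anchor base
        len <- nchar(seq)
        aFwd <- sum(grp$strand == "+"); aRev <- sum(grp$strand == "-")
        nAlt <- aFwd + aRev
        ## spanning reads: cover the anchor and the base after the event
        onChrom <- reads$chrom == chrom
        spanEnd <- if (type == "deletion") anchor + len + 1L
                   else anchor + 1L
        spanning <- which(onChrom & reads$start <= anchor &
                          reads$end >= spanEnd)
        nSpan <- length(spanning)
        nRef <- max(nSpan - nAlt, 0L)
        cov <- nRef + nAlt
        af <- if (cov > 0) nAlt / cov else 0
        if (cov < params@minTotalCoverage ||
            nAlt < params@minAltReads || af < params@minAltAF) next
        if (!all(.passesStrandBias(aFwd, aRev, params))) next
        anchorBase <- .refBaseAt(genome, chrom, anchor)
        if (type == "deletion") {
            refStr <- paste0(anchorBase, seq); altStr <- anchorBase
        } else {
            refStr <- anchorBase; altStr <- paste0(anchorBase, seq)
        }
        ## strand split of reference support follows read strand mix
        refFwd <- sum(reads$strand[spanning] == "+") - aFwd
        refRev <- sum(reads$strand[spanning] == "-") - aRev
        calls[[length(calls) + 1L]] <- data.frame(
            chrom = chrom, pos = anchor, ref = refStr, alt = altStr,
            kind = type, nRefFwd = max(refFwd, 0L),
            nRefRev = max(refRev, 0L), nAltFwd = aFwd, nAltRev = aRev,
            af = af, stringsAsFactors = FALSE)
    }
    .callsToGRanges(do.call(rbind, calls))
}

#' Call SNVs and indels over one or several BAM files
#'
#' Single-cell mode calls variants on the pooled BAM (all cells
#' together); bulk mode calls each file separately and returns the union
#' of the called loci.
#'
#' @param bam one BAM path (single-cell) or several (bulk).
#' @param genome named \code{DNAStringSet}.
#' @param params a \code{\link{CallingParams-class}}.
#' @param mode "single-cell" or "bulk".
#' @return a \code{GRanges} of variant calls.
#' @export
callVariants <- function(bam, genome, params = CallingParams(),
                         mode = c("single-cell", "bulk")) {
    mode <- match.arg(mode)
    one <- function(f) {
        snv <- callSNVs(buildStrandPileup(f, params), genome, params)
        ind <- callIndels(f, genome, params)
        suppressWarnings(c(snv, ind))
    }
    if (mode == "single-cell" || length(bam) == 1L) return(one(bam))
    all <- lapply(bam, one)
    merged <- do.call(c, unname(all))
    merged[!duplicated(names(merged))]
}
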