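#' @importFrom GenomicRanges GRanges start end width seqnames strand
#'   findOverlaps reduce disjoin pintersect mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicAlignments readGAlignments cigar sequenceLayer
#'   cigarRangesAlongReferenceSpace cigarRangesAlongQuerySpace
#' @importFrom Rsamtools ScanBamParam scanBamFlag BamFile PileupParam
#'   pileup
#' @importFrom Biostrings DNAStringSet subseq readDNAStringSet
NULL

## Per-read evidence for one variant.  `lay` is the read sequence laid on
## reference coordinates (insertions removed, deletions as "-"), so base
## lookups are direct offsets.
.readBaseAt <- function(lay, starts, ends, pos) {
    ok <- starts <= pos & ends >= pos
    base <- rep(NA_character_, length(lay))
    if (any(ok))
        base[ok] <- as.character(subseq(lay[ok], pos - starts[ok] + 1L,
                                        width = 1L))
    base
}

## Classify reads as ref/alt supporters of a variant.
## Returns integer vector: 1 = ref, 2 = alt, 0 = neither.
.classifyReads <- function(variant, reads) {
    pos <- start(variant)
    kind <- variant$kind
    support <- integer(length(reads$start))
    if (kind == "SNV") {
        base <- .readBaseAt(reads$lay, reads$start, reads$end, pos)
        support[!is.na(base) & base == variant$alt] <- 2L
        support[!is.na(base) & base == variant$ref] <- 1L
    } else if (kind == "deletion") {
        ## VCF-anchored: deleted bases span [pos + 1, pos + len]
        len <- nchar(variant$ref) - nchar(variant$alt)
        delStart <- pos + 1L; delEnd <- pos + len
        for (r in seq_along(support)) {
            if (reads$start[r] > pos || reads$end[r] < delEnd + 1L) next
            del <- reads$delRanges[[r]]
            hit <- any(start(del) == delStart & end(del) == delEnd)
            if (hit) support[r] <- 2L
            else if (!any(start(del) <= delEnd & end(del) >= delStart))
                support[r] <- 1L
        }
    } else if (kind == "insertion") {
        insLen <- nchar(variant$alt) - nchar(variant$ref)
        for (r in seq_along(support)) {
            if (reads$start[r] > pos || reads$end[r] < pos + 1L) next
            ins <- reads$insRanges[[r]]
            hit <- any(end(ins) == pos & width(ins) == 0L &
                       reads$insLens[[r]] == insLen)
            if (length(reads$insLens[[r]]) == 0L) hit <- FALSE
            if (hit) support[r] <- 2L
            else if (!any(end(ins) == pos & width(ins) == 0L))
                support[r] <- 1L
        }
    }
    support
}

.loadReadsForCounting <- function(bam, params, withBarcode) {
    flags <- scanBamFlag(isDuplicate = FALSE, isUnmappedQuery = FALSE)
    param <- ScanBamParam(flag = flags, what = "seq",
                          tag = if (withBarcode) "CB" else character(0),
                          mapqFilter = as.integer(params@minMapq) + 1L)
    ga <- readGAlignments(bam, param = param)
    if (!length(ga))
        return(list(ga = ga, start = integer(0), end = integer(0)))
    seqs <- mcols(ga)$seq
    lay <- sequenceLayer(seqs, cigar(ga), to = "reference")
    insQ <- cigarRangesAlongQuerySpace(cigar(ga), ops = "I")
    list(ga = ga, start = start(ga), end = end(ga),
         chrom = as.character(seqnames(ga)),
         strand = as.character(strand(ga)), lay = lay,
         delRanges = cigarRangesAlongReferenceSpace(cigar(ga),
                                                    pos = start(ga),
                                                    ops = "D"),
         insRanges = cigarRangesAlongReferenceSpace(cigar(ga),
                                                    pos = start(ga),
                                                    ops = "I"),
         insLens = width(insQ),
         barcode = if (withBarcode) mcols(ga)$CB else NULL)
}

#' Count reference and alternate reads per variant and cell
#'
#' Tallies, for every variant and cell, the duplicate-filtered,
#' mapping-quality-filtered reads supporting the reference and alternate
#' alleles.  In single-cell mode reads are assigned to cells through
#' their \code{CB:Z} barcode tag (reads without the tag are dropped and
#' counted); in bulk mode each BAM file becomes one column.
#'
#' @param bam a BAM path (single-cell mode) or a named character vector
#'   of BAM paths (bulk mode, one column per file).
#' @param variants a \code{GRanges} of left-normalized variants with
#'   metadata columns \code{ref}, \code{alt}, \code{kind}
#'   (SNV/insertion/deletion), as produced by \code{\link{callSNVs}},
#'   \code{\link{callIndels}} or \code{\link{readVcfVariants}}.
#' @param params a \code{\link{CallingParams-class}} (mapq threshold).
#' @param cells optional barcode whitelist fixing column order.
#' @param mode "single-cell" or "bulk".
#' @return an \code{\link{AlleleCountMatrix-class}}; the number of
#'   barcode-less reads dropped is in
#'   \code{metadata(x)$droppedNoBarcode}.
#' @export
countAlleles <- function(bam, variants, params = CallingParams(),
                         cells = NULL,
                         mode = c("single-cell", "bulk")) {
    mode <- match.arg(mode)
    stopifnot(is(variants, "GRanges"),
              all(c("ref", "alt", "kind") %in% colnames(mcols(variants))))
    vid <- if (!is.null(names(variants))) names(variants) else
        paste0(seqnames(variants), ":", start(variants), "_",
               variants$ref, "/", variants$alt)
    nv <- length(variants)
    if (nv == 0L) stop("no variants to count")
    if (mode == "bulk") {
        files <- bam
        if (is.null(names(files))) names(files) <- basename(files)
        ref <- alt <- matrix(0L, nv, length(files),
                             dimnames = list(vid, names(files)))
        for (f in seq_along(files)) {
            reads <- .loadReadsForCounting(files[f], params, FALSE)
            for (v in seq_len(nv)) {
                onChrom <- reads$chrom == as.character(seqnames(variants)[v])
                if (!any(onChrom)) next
                sub <- lapply(reads[c("start", "end", "lay", "delRanges",
                                      "insRanges", "insLens")],
                              function(x) x[onChrom])
                s <- .classifyReads(variants[v], sub)
                ref[v, f] <- sum(s == 1L); alt[v, f] <- sum(s == 2L)
            }
        }
        return(AlleleCountMatrix(ref, alt,
                                 rowData = DataFrame(mcols(variants))))
    }
    reads <- .loadReadsForCounting(bam, params, TRUE)
    dropped <- 0L
    if (length(reads$start)) {
        noBc <- is.na(reads$barcode)
        dropped <- sum(noBc)
        if (dropped)
            message(dropped, " reads without CB barcode dropped")
        keep <- !noBc
        reads <- lapply(reads, function(x)
            if (length(x) == length(keep)) x[keep] else x)
    }
    if (is.null(cells))
        cells <- sort(unique(reads$barcode))
    ref <- alt <- matrix(0L, nv, length(cells),
                         dimnames = list(vid, cells))
    for (v in seq_len(nv)) {
        onChrom <- reads$chrom == as.character(seqnames(variants)[v])
        if (!any(onChrom)) next
        sub <- lapply(reads[c("start", "end", "lay", "delRanges",
                              "insRanges", "insLens")],
                      function(x) x[onChrom])
        s <- .classifyReads(variants[v], sub)
        bc <- reads$barcode[onChrom]
        hit <- s > 0L & bc %in% cells
        if (!any(hit)) next
        tab <- table(factor(bc[hit], levels = cells), s[hit])
        if ("1" %in% colnames(tab)) ref[v, ] <- ref[v, ] + tab[, "1"]
        if ("2" %in% colnames(tab)) alt[v, ] <- alt[v, ] + tab[, "2"]
    }
    AlleleCountMatrix(ref, alt, rowData = DataFrame(mcols(variants)),
                      metadata = list(droppedNoBarcode = dropped))
}

#' Fraction of a variant set expressed per cell
#'
#' For a chosen variant subset (e.g. catalogued somatic variants, or rare
#' variants with population AF below 1%), the fraction of subset variants
#' whose alternate AF exceeds the cutoff in each cell.  The denominator
#' is either the whole subset ("all", the catalogued-variant convention)
#' or only the variants with nonzero read depth in the cell
#' ("accessible", the rare-variant convention); in accessible mode a cell
#' with no accessible variant gets NA.
#'
#' @param counts an \code{AlleleCountMatrix}.
#' @param subset variant ids (must be rows of \code{counts}).
#' @param cutoff AF threshold defining "expressed" (default 0, i.e. at
#'   least one alternate read).
#' @param denominator "all" or "accessible".
#' @return named per-cell fractions.
#' @export
variantSetFraction <- function(counts, subset, cutoff = 0,
                               denominator = c("all", "accessible")) {
    denominator <- match.arg(denominator)
    if (!length(subset)) stop("empty variant subset")
    if (!all(subset %in% rownames(counts)))
        stop("subset contains unknown variant ids")
    af <- altAF(counts)[subset, , drop = FALSE]
    expressed <- colSums(af > cutoff)
    if (denominator == "all") return(expressed / length(subset))
    acc <- colSums(readDepth(counts)[subset, , drop = FALSE] > 0)
    out <- expressed / acc
    out[acc == 0] <- NA_real_
    out
}

#' Per-cell dropout rates, overall and per chromosome
#'
#' The fraction of protein-coding genes with exactly zero reads in each
#' cell, overall and stratified by chromosome.
#'
#' @param geneCounts gene x cell count matrix (protein-coding genes).
#' @param geneChrom named character vector mapping each gene (rownames of
#'   \code{geneCounts}) to its chromosome; genes with NA are ignored.
#' @return list with \code{overall} (per-cell vector) and
#'   \code{perChromosome} (chromosome x cell matrix; a chromosome with no
#'   genes is absent).
#' @export
dropoutRates <- function(geneCounts, geneChrom = NULL) {
    z <- geneCounts == 0
    overall <- colMeans(z)
    perChromosome <- NULL
    if (!is.null(geneChrom)) {
        chrom <- geneChrom[rownames(geneCounts)]
        keep <- !is.na(chrom)
        groups <- split(seq_len(nrow(geneCounts))[keep], chrom[keep])
        perChromosome <- do.call(rbind, lapply(groups, function(ii)
            colMeans(z[ii, , drop = FALSE])))
    }
    list(overall = overall, perChromosome = perChromosome)
}
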