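## Coding-impact annotation from a GTF/GFF transcript model, population
## frequency filtering, and gene-level maximum-impact summarization.

#' Transcript models for impact annotation
#'
#' Holds, per transcript: ordered CDS intervals, strand, gene, splice
#' sites (the two intronic nucleotides at each end of each intron) and
#' start/stop codon locations derived from the CDS extremes.
#'
#' @slot cds \code{GRangesList} of CDS exons per transcript, ordered
#'   5' to 3'.
#' @slot txGene named character vector: transcript -> gene id.
#' @slot txStrand named character vector: transcript strand.
#' @slot spliceSites \code{GRanges} of 2-nt splice windows with a
#'   \code{tx} column.
#'
#' @export
setClass("TranscriptModelSet", representation(
    cds = "CompressedGRangesList",
    txGene = "character",
    txStrand = "character",
    spliceSites = "GRanges"
))

setMethod("show", "TranscriptModelSet", function(object) {
    cat("TranscriptModelSet:", length(object@cds), "transcripts,",
        length(unique(object@txGene)), "genes,",
        length(object@spliceSites), "splice windows\n")
})

#' Load transcript models from a GTF/GFF file
#'
#' Reads the annotation with \code{rtracklayer} and extracts CDS
#' intervals per transcript (the \code{gene_id}/\code{transcript_id} or
#' \code{ID}/\code{Parent} attribute dialect is auto-detected).  Introns
#' are the gaps between consecutive exons of a transcript (exon features
#' when present, CDS otherwise); the two intronic nucleotides at each
#' intron end become splice windows.  Transcripts without CDS are
#' dropped (variants there annotate as non-coding).
#'
#' @param gtf path to a GTF/GFF3 file, or an imported \code{GRanges}.
#' @return a \code{\link{TranscriptModelSet-class}}.
#' @export
loadTranscriptModels <- function(gtf) {
    gr <- if (is(gtf, "GRanges")) gtf else rtracklayer::import(gtf)
    md <- mcols(gr)
    txId <- if ("transcript_id" %in% colnames(md)) md$transcript_id
            else sub("^.*:", "", as.character(md$Parent))
    geneId <- if ("gene_id" %in% colnames(md)) md$gene_id
              else as.character(md$ID)
    type <- as.character(md$type)
    isCds <- type == "CDS"
    if (!any(isCds)) stop("annotation contains no CDS features")
    cdsGR <- gr[isCds]
    cdsTx <- txId[isCds]
    cds <- GenomicRanges::split(cdsGR, cdsTx)
    ## order exons 5' -> 3' along the transcript strand
    cds <- S4Vectors::endoapply(cds, function(x)
        if (as.character(strand(x)[1]) == "-")
            x[order(-start(x))] else x[order(start(x))])
    txStrand <- vapply(cds, function(x) as.character(strand(x)[1]),
                       character(1))
    geneByTx <- tapply(geneId[isCds], cdsTx, `[`, 1L)
    txGene <- stats::setNames(as.character(geneByTx), names(geneByTx))
    ## introns from exon features when available, else from CDS
    exSel <- if (any(type == "exon")) type == "exon" else isCds
    exByTx <- GenomicRanges::split(gr[exSel], txId[exSel])
    exByTx <- exByTx[names(exByTx) %in% names(cds)]
    ss <- list()
    for (tx in names(exByTx)) {
        ex <- sort(exByTx[[tx]])
        if (length(ex) < 2) next
        introns <- GRanges(seqnames(ex)[1],
                           IRanges(utils::head(end(ex), -1) + 1L,
                                   utils::tail(start(ex), -1) - 1L))
        introns <- introns[width(introns) >= 2]
        if (!length(introns)) next
        donors <- GRanges(seqnames(introns),
                          IRanges(start(introns), start(introns) + 1L))
        acceptors <- GRanges(seqnames(introns),
                             IRanges(end(introns) - 1L, end(introns)))
        w <- c(donors, acceptors)
        mcols(w)$tx <- tx
        ss[[tx]] <- w
    }
    spliceSites <- if (length(ss)) do.call(c, unname(ss)) else {
        g <- GRanges(); mcols(g)$tx <- character(0); g
    }
    new("TranscriptModelSet", cds = cds, txGene = txGene,
        txStrand = txStrand, spliceSites = spliceSites)
}

#' Impact class severity ranking
#'
#' The default total order over impact classes, most severe first.
#' Smaller rank = more severe.  The order is a convention (configurable
#' wherever a ranking argument is accepted).
#'
#' @return character vector of impact classes, most severe first.
#' @export
impactRanking <- function() {
    c("stop-disruption", "nonsense", "start-loss", "frameshift-indel",
      "splice-loss", "in-frame-indel", "non-synonymous", "synonymous",
      "non-coding")
}

#' @return \code{damagingClasses()}: the impact classes retained by
#'   \code{\link{filterDamaging}}.
#' @rdname impactRanking
#' @export
damagingClasses <- function() {
    c("non-synonymous", "nonsense", "splice-loss", "in-frame-indel",
      "frameshift-indel", "stop-disruption", "start-loss")
}

## CDS-relative coordinate of a genomic position within a transcript's
## ordered CDS; NA when outside.
.cdsOffset <- function(cdsTx, minus, pos) {
    off <- 0L
    for (k in seq_along(cdsTx)) {
        s <- start(cdsTx)[k]; e <- end(cdsTx)[k]
        if (pos >= s && pos <= e) {
            within <- if (minus) e - pos else pos - s
            return(off + within + 1L)
        }
        off <- off + (e - s + 1L)
    }
    NA_integer_
}

.txCdsSeq <- function(genome, cdsTx, minus) {
    chrom <- as.character(seqnames(cdsTx)[1])
    pieces <- Biostrings::extractAt(genome[[chrom]],
                                    IRanges(start(cdsTx), end(cdsTx)))
    s <- Biostrings::DNAString(paste(vapply(pieces, as.character,
                                            character(1)),
                                     collapse = ""))
    if (minus) Biostrings::reverseComplement(s) else s
}

.translateCodon <- function(codon) {
    as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                       no.init.codon = TRUE,
                                       if.fuzzy.codon = "X"))
}

## Impact of one variant on one transcript.
.impactOnTranscript <- function(variant, models, tx, genome) {
    cdsTx <- models@cds[[tx]]
    minus <- models@txStrand[[tx]] == "-"
    pos <- start(variant)
    kind <- variant$kind
    ss <- models@spliceSites[models@spliceSites$tx == tx]
    varRange <- GRanges(seqnames(variant),
                        IRanges(pos, pos + nchar(variant$ref) - 1L))
    if (length(ss) && length(findOverlaps(varRange, ss)) > 0)
        return("splice-loss")
    if (kind %in% c("insertion", "deletion")) {
        if (kind == "insertion") {
            ## inserted between pos and pos+1; coding when that junction
            ## is inside a CDS exon
            inCds <- any(pos >= start(cdsTx) & pos + 1L <= end(cdsTx))
            if (!inCds) return("non-coding")
            len <- nchar(variant$alt) - nchar(variant$ref)
        } else {
            delRange <- GRanges(seqnames(variant),
                                IRanges(pos + 1L,
                                        pos + nchar(variant$ref) -
                                            nchar(variant$alt)))
            len <- sum(width(GenomicRanges::intersect(
                delRange, cdsTx, ignore.strand = TRUE)))
            if (len == 0) return("non-coding")
        }
        return(if (len %% 3L == 0L) "in-frame-indel"
               else "frameshift-indel")
    }
    ## SNV
    offset <- .cdsOffset(cdsTx, minus, pos)
    if (is.na(offset)) return("non-coding")
    cdsSeq <- .txCdsSeq(genome, cdsTx, minus)
    refBase <- variant$ref; altBase <- variant$alt
    if (minus) {
        refBase <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(refBase)))
        altBase <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(altBase)))
    }
    codonIdx <- (offset - 1L) %/% 3L + 1L
    posInCodon <- (offset - 1L) %% 3L + 1L
    from <- (codonIdx - 1L) * 3L + 1L
    if (from + 2L > length(cdsSeq)) return("non-coding")
    codon <- as.character(cdsSeq[from:(from + 2L)])
    refAA <- .translateCodon(codon)
    altCodon <- codon
    substr(altCodon, posInCodon, posInCodon) <- altBase
    altAA <- .translateCodon(altCodon)
    if (codonIdx == 1L && refAA == "M" && altAA != "M")
        return("start-loss")
    if (refAA == altAA) return("synonymous")
    if (altAA == "*") return("nonsense")
    if (refAA == "*") return("stop-disruption")
    "non-synonymous"
}

#' Annotate variants with their coding impact
#'
#' Maps each variant onto every overlapping transcript and classifies
#' its impact: splice window hits are splice-loss; CDS SNVs are
#' classified by codon reconstruction (synonymous, non-synonymous,
#' nonsense for a gained stop, stop-disruption for a lost stop,
#' start-loss for a lost initiator); CDS indels are in-frame when the
#' CDS-overlapping length is a multiple of three, frameshift otherwise.
#' Everything else (UTR, deep intronic, intergenic) is non-coding.  The
#' most severe impact across transcripts is assigned; every overlapping
#' gene is recorded.
#'
#' @param variants \code{GRanges} with ref/alt/kind columns.
#' @param models a \code{\link{TranscriptModelSet-class}}.
#' @param genome named \code{DNAStringSet}.
#' @param ranking impact severity order (most severe first).
#' @return the input \code{GRanges} with added columns \code{impact}
#'   and \code{genes} (a \code{CharacterList}).
#' @export
annotateVariants <- function(variants, models, genome,
                             ranking = impactRanking()) {
    txRanges <- unlist(range(models@cds))
    ## include splice windows in the searchable footprint
    impact <- character(length(variants))
    genes <- vector("list", length(variants))
    for (v in seq_along(variants)) {
        varRange <- GRanges(seqnames(variants)[v],
                            IRanges(start(variants)[v],
                                    start(variants)[v] +
                                        nchar(variants$ref[v]) - 1L))
        near <- names(txRanges)[S4Vectors::queryHits(
            findOverlaps(txRanges + 10L, varRange))]
        if (!length(near)) {
            impact[v] <- "non-coding"
            genes[[v]] <- character(0)
            next
        }
        imps <- vapply(near, function(tx)
            .impactOnTranscript(variants[v], models, tx, genome),
            character(1))
        impact[v] <- ranking[min(match(imps, ranking))]
        genes[[v]] <- unique(unname(models@txGene[near]))
    }
    variants$impact <- impact
    variants$genes <- IRanges::CharacterList(genes)
    variants
}

#' Attach population allele frequencies
#'
#' Exact (chrom, pos, ref, alt) matching against a dbSNP-style table;
#' variants absent from the table get a population AF of 0.
#'
#' @param variants annotated \code{GRanges}.
#' @param popTable data.frame with columns chrom, pos, ref, alt, af, or
#'   the path of such a TSV (header required).
#' @return the \code{GRanges} with a \code{popAF} column.
#' @export
addPopulationAF <- function(variants, popTable) {
    if (is.character(popTable))
        popTable <- utils::read.table(popTable, header = TRUE,
                                      sep = "\t",
                                      stringsAsFactors = FALSE)
    key <- paste(popTable$chrom, popTable$pos, popTable$ref,
                 popTable$alt)
    vkey <- paste(as.character(seqnames(variants)), start(variants),
                  variants$ref, variants$alt)
    af <- popTable$af[match(vkey, key)]
    variants$popAF <- ifelse(is.na(af), 0, af)
    variants
}

#' Filter to rare, damaging variants
#'
#' Retains variants whose population AF is strictly below
#' \code{maxPopAF} (default 1%) and whose impact is one of the damaging
#' classes.  Idempotent; the output is always a subset of the input.
#'
#' @param variants annotated \code{GRanges} with \code{impact} and
#'   \code{popAF} columns (missing popAF treated as 0).
#' @param maxPopAF population-frequency cutoff.
#' @param classes damaging impact classes.
#' @return the filtered \code{GRanges}.
#' @export
filterDamaging <- function(variants, maxPopAF = 0.01,
                           classes = damagingClasses()) {
    popAF <- if ("popAF" %in% colnames(mcols(variants)))
        variants$popAF else rep(0, length(variants))
    variants[popAF < maxPopAF & variants$impact %in% classes]
}

#' Gene-level maximum-impact summarization
#'
#' For each gene and cell, selects among the gene's variants with a
#' nonzero AF in that cell the one with the most severe impact; ties at
#' equal severity go to the higher AF, then the lower genomic
#' coordinate.  The selected variant's allele counts are carried to the
#' gene row, so the gene-level AF (sAF) equals the chosen variant's AF;
#' cells expressing no variant of the gene get zero counts.
#'
#' @param counts an \code{\link{AlleleCountMatrix-class}} whose rows are
#'   the annotated variants.
#' @param annotations annotated \code{GRanges} aligned with
#'   \code{rownames(counts)} (names must match).
#' @param ranking impact severity order.
#' @return an \code{AlleleCountMatrix} with one row per gene.
#' @export
summarizeGeneLevel <- function(counts, annotations,
                               ranking = impactRanking()) {
    stopifnot(all(rownames(counts) %in% names(annotations)))
    annotations <- annotations[rownames(counts)]
    af <- altAF(counts)
    geneList <- annotations$genes
    genes <- sort(unique(unlist(geneList)))
    ref <- refCount(counts); alt <- altCount(counts)
    outRef <- outAlt <- matrix(0L, length(genes), ncol(counts),
                               dimnames = list(genes, colnames(counts)))
    rank <- match(annotations$impact, ranking)
    for (g in seq_along(genes)) {
        vIdx <- which(vapply(geneList, function(x) genes[g] %in% x,
                             logical(1)))
        ## order candidate variants by severity, then coordinate
        vIdx <- vIdx[order(rank[vIdx], start(annotations)[vIdx])]
        assigned <- rep(FALSE, ncol(counts))
        for (rk in unique(rank[vIdx])) {
            grp <- vIdx[rank[vIdx] == rk]
            afG <- af[grp, , drop = FALSE]
            best <- max.col(t(afG), ties.method = "first")
            bestAF <- afG[cbind(best, seq_len(ncol(counts)))]
            take <- !assigned & bestAF > 0
            if (any(take)) {
                rows <- grp[best[take]]
                outRef[g, take] <- ref[cbind(rows, which(take))]
                outAlt[g, take] <- alt[cbind(rows, which(take))]
                assigned <- assigned | take
            }
            if (all(assigned)) break
        }
    }
    AlleleCountMatrix(outRef, outAlt,
                      rowData = DataFrame(gene = genes))
}
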