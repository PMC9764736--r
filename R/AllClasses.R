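#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

#' Parameters for pileup-based variant calling
#'
#' Thresholds applied when calling SNVs and indels from strand-specific
#' pileups.  Defaults follow the relaxed RNA-seq calling regime the clump
#' analysis is designed around: a site is reported when it has total read
#' coverage of at least 10, at least four alternate-supporting reads, an
#' alternate allele frequency of at least 0.2, and reads with mapping
#' quality above 30.  The strand-bias filter requires the minority strand
#' to carry at least \code{minAltStrandFraction} of the alternate reads;
#' it must be disabled (\code{strandedProtocol = TRUE}) for stranded
#' library preparations, where all reads of a transcript map to one strand.
#'
#' @slot minTotalCoverage minimum combined-strand read coverage at a site.
#' @slot minAltReads minimum number of alternate-supporting reads.
#' @slot minAltAF minimum alternate allele frequency in [0, 1].
#' @slot minMapq reads with mapping quality less than or equal to this are
#'   ignored.
#' @slot minAltStrandFraction minimum fraction of alternate reads required
#'   on the minority strand.
#' @slot strandedProtocol if TRUE the strand-bias filter is skipped.
#'
#' @export
setClass("CallingParams", representation(
    minTotalCoverage = "numeric",
    minAltReads = "numeric",
    minAltAF = "numeric",
    minMapq = "numeric",
    minAltStrandFraction = "numeric",
    strandedProtocol = "logical"
))

setValidity("CallingParams", function(object) {
    msg <- NULL
    th <- c(object@minTotalCoverage, object@minAltReads, object@minMapq,
            object@minAltStrandFraction)
    if (any(th < 0)) msg <- c(msg, "all thresholds must be >= 0")
    if (object@minAltAF < 0 || object@minAltAF > 1)
        msg <- c(msg, "minAltAF must be in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' @param minTotalCoverage,minAltReads,minAltAF,minMapq,minAltStrandFraction,strandedProtocol
#'   see the corresponding slots.
#' @return \code{CallingParams()} returns a parameter object.
#' @rdname CallingParams-class
#' @examples
#' CallingParams(minAltAF = 0.1)
#' @export
CallingParams <- function(minTotalCoverage = 10, minAltReads = 4,
                          minAltAF = 0.2, minMapq = 30,
                          minAltStrandFraction = 0.1,
                          strandedProtocol = FALSE) {
    new("CallingParams", minTotalCoverage = minTotalCoverage,
        minAltReads = minAltReads, minAltAF = minAltAF, minMapq = minMapq,
        minAltStrandFraction = minAltStrandFraction,
        strandedProtocol = strandedProtocol)
}

setMethod("show", "CallingParams", function(object) {
    cat("CallingParams: coverage >=", object@minTotalCoverage,
        "| alt reads >=", object@minAltReads,
        "| alt AF >=", object@minAltAF,
        "| mapq >", object@minMapq, "\n")
    cat("  strand bias:",
        if (object@strandedProtocol) "disabled (stranded protocol)"
        else sprintf("minority strand >= %.2f of alt reads",
                     object@minAltStrandFraction), "\n")
})

#' Strand-specific nucleotide pileup
#'
#' Per-position, per-strand tallies of A/C/G/T/N (and deletion-spanning
#' reads, recorded under nucleotide \code{"-"}, and insertion starts under
#' \code{"+"}) built from duplicate-filtered, mapping-quality-filtered
#' reads.  Positions are 1-based.
#'
#' @slot tally a \code{DataFrame} with columns \code{seqnames}, \code{pos},
#'   \code{strand}, \code{nucleotide}, \code{count}.
#' @slot params the \code{CallingParams} the pileup was built with.
#'
#' @export
setClass("StrandPileup", representation(
    tally = "DataFrame",
    params = "CallingParams"
))

setValidity("StrandPileup", function(object) {
    need <- c("seqnames", "pos", "strand", "nucleotide", "count")
    if (!all(need %in% colnames(object@tally)))
        return(paste("tally must have columns",
                     paste(need, collapse = ", ")))
    if (nrow(object@tally) && any(object@tally$count < 0))
        return("counts must be >= 0")
    TRUE
})

setMethod("show", "StrandPileup", function(object) {
    cat("StrandPileup:", nrow(object@tally), "tally records over",
        length(unique(object@tally$pos)), "positions\n")
})

#' Per-cell allele count matrix
#'
#' A \code{SummarizedExperiment} with two assays, \code{refCount} and
#' \code{altCount}, holding per-variant (rows) per-cell (columns)
#' reference- and alternate-supporting read counts.  The alternate allele
#' frequency of a cell at a variant is \code{altCount / (refCount +
#' altCount)}, defined as 0 where the read depth is 0.
#'
#' @export
setClass("AlleleCountMatrix", contains = "SummarizedExperiment")

setValidity("AlleleCountMatrix", function(object) {
    an <- names(assays(object))
    if (!all(c("refCount", "altCount") %in% an))
        return("assays must include 'refCount' and 'altCount'")
    r <- assay(object, "refCount"); a <- assay(object, "altCount")
    if (any(r < 0) || any(a < 0)) return("counts must be non-negative")
    TRUE
})

#' @param refCount,altCount numeric matrices of identical dimension with
#'   reference- and alternate-supporting read counts (variants x cells).
#' @param rowData,colData optional annotation passed to
#'   \code{\link[SummarizedExperiment]{SummarizedExperiment}}.
#' @param metadata optional list of metadata.
#' @return an \code{AlleleCountMatrix}.
#' @rdname AlleleCountMatrix-class
#' @examples
#' m <- AlleleCountMatrix(refCount = matrix(5, 2, 3), altCount = matrix(3, 2, 3))
#' altAF(m)
#' @export
AlleleCountMatrix <- function(refCount, altCount, rowData = NULL,
                              colData = NULL, metadata = list()) {
    stopifnot(all(dim(refCount) == dim(altCount)))
    if (is.null(rownames(refCount)))
        rownames(refCount) <- rownames(altCount) <-
            paste0("variant_", seq_len(nrow(refCount)))
    if (is.null(colnames(refCount)))
        colnames(refCount) <- colnames(altCount) <-
            paste0("cell_", seq_len(ncol(refCount)))
    dimnames(altCount) <- dimnames(refCount)
    args <- list(assays = SimpleList(refCount = refCount,
                                     altCount = altCount),
                 metadata = metadata)
    if (!is.null(rowData)) args$rowData <- rowData
    if (!is.null(colData)) args$colData <- colData
    se <- do.call(SummarizedExperiment, args)
    new("AlleleCountMatrix", se)
}

setMethod("show", "AlleleCountMatrix", function(object) {
    cat("AlleleCountMatrix:", nrow(object), "variants x", ncol(object),
        "cells\n")
    rd <- readDepth(object)
    cat("  covered entries (RD > 0):", sum(rd > 0),
        sprintf("(%.1f%%)\n", 100 * mean(rd > 0)))
})

#' Cell embedding with cached distance index
#'
#' Low-dimensional coordinates of cells (or bulk samples), e.g. from t-SNE,
#' UMAP or PCA, together with the full Euclidean distance matrix and, per
#' cell, neighbor identities sorted by ascending distance.  A precomputed
#' distance matrix may be supplied instead of coordinates, in which case
#' \code{coords} is a zero-column matrix.
#'
#' @slot coords numeric matrix, cells x dimensions, rownames are cell ids.
#' @slot dist full symmetric distance matrix.
#' @slot nnIndex integer matrix (cells x (cells - 1)); row i lists all other
#'   cells in ascending distance from cell i (self excluded).
#' @slot nnDist matching distances for \code{nnIndex}.
#'
#' @export
setClass("CellEmbedding", representation(
    coords = "matrix",
    dist = "matrix",
    nnIndex = "matrix",
    nnDist = "matrix"
))

setValidity("CellEmbedding", function(object) {
    n <- nrow(object@dist)
    if (n != ncol(object@dist)) return("distance matrix must be square")
    if (anyDuplicated(rownames(object@dist))) return("cell ids must be unique")
    if (n > 1 && any(abs(object@dist - t(object@dist)) > 1e-8))
        return("distance matrix must be symmetric")
    TRUE
})

setMethod("show", "CellEmbedding", function(object) {
    cat("CellEmbedding:", nrow(object@dist), "cells,",
        ncol(object@coords), "dimensions\n")
    if (ncol(object@coords))
        cat("  embedding radius:", format(embeddingRadius(object)), "\n")
})

#' Multiscale smoothing ladder
#'
#' The smoothing scales used in multiscale clump detection.  The endpoint
#' scales are the medians over cells of the distance to the
#' \code{nLower}-th and \code{nUpper}-th nearest neighbor, where the
#' neighborhood-size bounds satisfy
#' \code{0.1 * nCells > N > max(0.01 * nCells, 10)}.
#'
#' @slot sigmaMin,sigmaMax endpoint scales (embedding-distance units).
#' @slot scales strictly increasing scale sequence within
#'   [sigmaMin, sigmaMax].
#' @slot nLower,nUpper neighborhood-size bounds used to derive the scales.
#' @slot nCells number of cells the ladder was derived from.
#'
#' @export
setClass("ScaleLadder", representation(
    sigmaMin = "numeric", sigmaMax = "numeric", scales = "numeric",
    nLower = "integer", nUpper = "integer", nCells = "integer"
))

setValidity("ScaleLadder", function(object) {
    s <- object@scales
    if (any(diff(s) <= 0)) return("scales must be strictly increasing")
    if (any(s < object@sigmaMin - 1e-9) || any(s > object@sigmaMax + 1e-9))
        return("scales must lie within [sigmaMin, sigmaMax]")
    TRUE
})

setMethod("show", "ScaleLadder", function(object) {
    cat(sprintf("ScaleLadder: %d scales in [%.4g, %.4g] (N_nu bounds %d..%d over %d cells)\n",
                length(object@scales), object@sigmaMin, object@sigmaMax,
                object@nLower, object@nUpper, object@nCells))
})

#' Gaussian-smoothed allele frequency field
#'
#' Per-cell smoothed alternate allele frequencies at one scale.  Smoothing
#' averages the Gaussian-weighted AFs of the cells in each cell's
#' neighborhood (self excluded), normalized by the neighbor count.
#'
#' @slot values per-cell smoothed AF.
#' @slot sigma the smoothing scale.
#' @slot nNeighbors per-cell neighborhood size used for normalization.
#' @slot emptyNeighborhood logical flag per cell; TRUE where the
#'   neighborhood was empty and the smoothed AF was set to 0.
#'
#' @export
setClass("SmoothedField", representation(
    values = "numeric", sigma = "numeric", nNeighbors = "integer",
    emptyNeighborhood = "logical"
))

setMethod("show", "SmoothedField", function(object) {
    cat(sprintf("SmoothedField: %d cells at sigma = %.4g; %d nonzero\n",
                length(object@values), object@sigma,
                sum(object@values > 0)))
})

#' Parameters for clump detection
#'
#' @slot tau read-depth threshold: cells with RD > tau are eligible for
#'   AF shuffling in the permutation null; others keep their AF fixed.
#' @slot K number of permutations for the z-score.
#' @slot eta cell-level AF threshold for the Fisher enrichment table.
#' @slot minZ minimum permutation z-score for a reported clump
#'   (strictly greater).
#' @slot minMutatedCells minimum number of mutation-harboring cells in a
#'   clump (strictly greater).
#' @slot maxEnrichmentP both the read-level binomial and cell-level Fisher
#'   p-values must be strictly smaller than this.
#' @slot fisherDenominator "all" (default) counts every cell in the clump
#'   (and every cell in the sample) as the table denominator, so the test
#'   measures spatial concentration of high-AF cells; "expressed" counts
#'   only cells with AF > 0, a composition test that is powerless when a
#'   clump contains all expressing cells.
#' @slot seed random seed for the permutations.
#'
#' @export
setClass("DetectionParams", representation(
    tau = "numeric", K = "integer", eta = "numeric", minZ = "numeric",
    minMutatedCells = "numeric", maxEnrichmentP = "numeric",
    fisherDenominator = "character", seed = "integer"
))

setValidity("DetectionParams", function(object) {
    if (object@eta <= 0 || object@eta >= 1) return("eta must be in (0, 1)")
    if (!object@fisherDenominator %in% c("expressed", "all"))
        return("fisherDenominator must be 'expressed' or 'all'")
    TRUE
})

#' @param tau,K,eta,minZ,minMutatedCells,maxEnrichmentP,fisherDenominator,seed
#'   see the corresponding slots.
#' @return \code{DetectionParams()} returns a parameter object.
#' @rdname DetectionParams-class
#' @examples
#' DetectionParams(K = 200, seed = 1)
#' @export
DetectionParams <- function(tau = 0, K = 1000L, eta = 0.5, minZ = 2,
                            minMutatedCells = 10, maxEnrichmentP = 0.05,
                            fisherDenominator = "all", seed = 1L) {
    K <- as.integer(K)
    if (K < 100L)
        warning("K < 100 permutations gives a coarse null; ",
                "z-scores will be unstable")
    new("DetectionParams", tau = tau, K = K, eta = eta, minZ = minZ,
        minMutatedCells = minMutatedCells, maxEnrichmentP = maxEnrichmentP,
        fisherDenominator = fisherDenominator, seed = as.integer(seed))
}

setMethod("show", "DetectionParams", function(object) {
    cat(sprintf("DetectionParams: tau=%g K=%d eta=%g | filters: z>%g, mutated cells>%g, p<%g\n",
                object@tau, object@K, object@eta, object@minZ,
                object@minMutatedCells, object@maxEnrichmentP))
})

#' Set of detected clumps
#'
#' One row per (variant, center cell, scale) clump call, with the smoothed
#' AF at the center, the permutation z-score and its null moments, the
#' read-level binomial and cell-level Fisher enrichment p-values, the
#' effective radius, and member-cell bookkeeping.
#'
#' @slot calls a \code{DataFrame}; column \code{members} is a
#'   \code{CharacterList} of member cell ids.
#'
#' @export
setClass("ClumpSet", representation(calls = "DataFrame"))

setMethod("show", "ClumpSet", function(object) {
    cat("ClumpSet:", nrow(object@calls), "clumps over",
        length(unique(object@calls$variantId)), "variants\n")
    if (nrow(object@calls)) {
        df <- clumpTable(object)
        print(utils::head(df[order(-df$z), ], 5))
    }
})

#' @param x a \code{ClumpSet}.
#' @return \code{clumpTable()} returns a plain \code{data.frame} (the
#'   \code{members} list column dropped).
#' @rdname ClumpSet-class
#' @export
clumpTable <- function(x) {
    stopifnot(is(x, "ClumpSet"))
    df <- as.data.frame(x@calls[, setdiff(colnames(x@calls), "members")])
    rownames(df) <- NULL
    df
}

#' @return \code{nClumps()} returns the number of clump calls.
#' @rdname ClumpSet-class
#' @export
nClumps <- function(x) nrow(x@calls)

#' Binary CNV segment-by-cell matrix
#'
#' A \code{SummarizedExperiment} with a single binary assay \code{calls}:
#' rows are CNV segments (chromosome arms, or minimal disjoint segments)
#' of a single state (amplification or deletion); columns are cells.
#'
#' @export
setClass("CNVSegmentMatrix", contains = "SummarizedExperiment")

setValidity("CNVSegmentMatrix", function(object) {
    if (!"calls" %in% names(assays(object)))
        return("assay 'calls' required")
    m <- assay(object, "calls")
    if (length(m) && !all(m %in% c(0, 1))) return("entries must be 0/1")
    if (!all(c("chrom", "start", "end", "state") %in%
             colnames(rowData(object))))
        return("rowData must have chrom, start, end, state")
    TRUE
})

setMethod("show", "CNVSegmentMatrix", function(object) {
    cat("CNVSegmentMatrix:", nrow(object), "segments x", ncol(object),
        "cells; states:",
        paste(unique(rowData(object)$state), collapse = "/"), "\n")
})
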