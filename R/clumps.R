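## Core clump statistics: Gaussian smoothing of allele frequencies on the
## embedding, local-maximum candidate selection, RD-aware permutation
## z-scores, read- and cell-level enrichment tests, effective radii, and
## the multiscale driver.

## Neighborhoods are truncated at `truncation * sigma`: Gaussian mass
## beyond 3 sigma is negligible and the cutoff bounds the cost.
.TRUNCATION <- 3

## Per-scale geometry shared by smoothing, candidate selection and the
## permutation null: Gaussian kernel weights over each cell's
## neighborhood, row-normalized by the neighbor count (not the kernel
## mass), plus per-cell neighbor index lists.  The neighborhood is either
## the `nNeighbors` closest cells (constant size per scale, as in the
## multiscale detector) or, when `nNeighbors` is NULL, all cells within
## `truncation * sigma`.
.scaleGeometry <- function(embedding, sigma, truncation = .TRUNCATION,
                           nNeighbors = NULL) {
    D <- embedding@dist
    n <- nrow(D)
    if (is.null(nNeighbors)) {
        mask <- D <= truncation * sigma
        diag(mask) <- FALSE
        nNbr <- as.integer(rowSums(mask))
        W <- exp(-(D * D) / (sigma * sigma))
        W[!mask] <- 0
        Wn <- W / pmax(nNbr, 1L)
        nbrList <- apply(mask, 1L, which, simplify = FALSE)
    } else {
        k <- min(as.integer(nNeighbors), n - 1L)
        nNbr <- rep.int(k, n)
        Wn <- matrix(0, n, n)
        for (i in seq_len(n)) {
            nb <- embedding@nnIndex[i, seq_len(k)]
            Wn[i, nb] <- exp(-(embedding@nnDist[i, seq_len(k)]^2) /
                             (sigma * sigma)) / k
        }
        nbrList <- lapply(seq_len(n), function(i)
            embedding@nnIndex[i, seq_len(k)])
    }
    list(sigma = sigma, Wn = Wn, nNbr = nNbr, nbrList = nbrList)
}

## Map each scale to the neighborhood size whose median k-th-neighbor
## radius is closest to it, inverting the construction of the ladder.
.scaleNeighborhoodSizes <- function(embedding, ladder) {
    ks <- ladder@nLower:ladder@nUpper
    medr <- apply(embedding@nnDist[, ks, drop = FALSE], 2L,
                  stats::median)
    vapply(ladder@scales, function(s) ks[which.min(abs(medr - s))],
           integer(1))
}

.smoothValues <- function(geom, af) {
    v <- as.numeric(geom$Wn %*% af)
    v[geom$nNbr == 0L] <- 0
    v
}

#' Gaussian smoothing of allele frequencies on the embedding
#'
#' Computes, for every cell i, the smoothed alternate allele frequency
#' \deqn{\bar\phi_i = \frac{1}{|N(i)|} \sum_{j \in N(i)} \phi_j
#'   \exp(-d_{ij}^2 / \sigma^2)}
#' where the neighborhood N(i) contains all cells within
#' \code{truncation * sigma} of cell i, excluding i itself.  The
#' normalization divides by the neighbor count (not the kernel mass), so
#' the field is linear in the AF vector for fixed geometry.  Cells with an
#' empty neighborhood get a smoothed AF of 0 and are flagged.
#'
#' @param embedding a \code{\link{CellEmbedding-class}}.
#' @param af per-cell alternate allele frequencies, aligned with
#'   \code{cellIds(embedding)}.
#' @param sigma smoothing scale (> 0), in embedding-distance units.
#' @param truncation neighborhood cutoff in units of sigma (default 3),
#'   used when \code{nNeighbors} is NULL.
#' @param nNeighbors if given, the neighborhood is the \code{nNeighbors}
#'   closest cells instead of the truncation ball; this constant-size
#'   neighborhood is what the multiscale detector uses, so that the
#'   count normalization is uniform across cells.
#' @return a \code{\link{SmoothedField-class}}.
#' @examples
#' emb <- CellEmbedding(cbind(c(0, 1, -2), 0))
#' smoothAF(emb, c(0, 0.5, 1), sigma = 1)
#' @export
smoothAF <- function(embedding, af, sigma, truncation = .TRUNCATION,
                     nNeighbors = NULL) {
    stopifnot(sigma > 0, length(af) == length(cellIds(embedding)))
    geom <- .scaleGeometry(embedding, sigma, truncation, nNeighbors)
    new("SmoothedField", values = .smoothValues(geom, af), sigma = sigma,
        nNeighbors = geom$nNbr, emptyNeighborhood = geom$nNbr == 0L)
}

.candidatesFromField <- function(phibar, nbrList) {
    idx <- which(phibar > 0)
    idx[vapply(idx, function(i) {
        nbr <- nbrList[[i]]
        length(nbr) > 0L && phibar[i] > max(phibar[nbr])
    }, logical(1))]
}

#' Clump-center candidate selection
#'
#' Candidates are the cells whose smoothed AF is a strict local maximum
#' over their neighborhood: \code{phibar[i] > phibar[j]} for every
#' neighbor j.  Cells with a smoothed AF of 0, or with an empty
#' neighborhood, are never candidates.
#'
#' @param embedding a \code{CellEmbedding}.
#' @param field a \code{\link{SmoothedField-class}} computed on the same
#'   embedding.
#' @param truncation neighborhood cutoff in units of sigma (must match the
#'   smoothing call).
#' @param nNeighbors constant neighborhood size (must match the smoothing
#'   call when used there).
#' @return integer indices of candidate center cells.
#' @export
findClumpCandidates <- function(embedding, field,
                                truncation = .TRUNCATION,
                                nNeighbors = NULL) {
    geom <- .scaleGeometry(embedding, field@sigma, truncation, nNeighbors)
    .candidatesFromField(field@values, geom$nbrList)
}

## Build an n x K matrix of RD-aware permuted AF vectors: cells with
## RD > tau exchange AFs among themselves, all other cells keep theirs.
.permuteAF <- function(af, eligible, K) {
    n <- length(af)
    perm <- matrix(af, n, K)
    idx <- which(eligible)
    for (k in seq_len(K)) perm[idx, k] <- af[idx[sample.int(length(idx))]]
    perm
}

#' RD-aware permutation z-score for a candidate clump center
#'
#' Builds the empirical null for the smoothed AF at a candidate center by
#' permuting the AF vector K times and re-smoothing.  Only cells whose
#' read depth exceeds \code{tau} exchange AFs; the remaining cells keep
#' their AF fixed in every permutation, which controls for read-depth
#' (expression) structure on the embedding.  The z-score is
#' \code{(observed - mean) / sd} over the K permuted smoothed values.  A
#' degenerate null (sd = 0) is reported as z = 0 with
#' \code{degenerate = TRUE}.
#'
#' @param embedding a \code{CellEmbedding}.
#' @param af,rd per-cell alternate AF and read depth vectors.
#' @param candidate index (or cell id) of the candidate center.
#' @param sigma smoothing scale.
#' @param params a \code{\link{DetectionParams-class}} (uses \code{tau},
#'   \code{K}, \code{seed}).
#' @param truncation neighborhood cutoff in units of sigma.
#' @return a list with \code{z}, \code{observed}, \code{mu}, \code{sd},
#'   \code{degenerate}.
#' @export
permutationZ <- function(embedding, af, rd, candidate, sigma,
                         params = DetectionParams(),
                         truncation = .TRUNCATION, nNeighbors = NULL) {
    if (is.character(candidate))
        candidate <- match(candidate, cellIds(embedding))
    eligible <- rd > params@tau
    if (sum(eligible) < 2)
        stop("fewer than 2 cells have read depth > tau; ",
             "the permutation null is undefined")
    geom <- .scaleGeometry(embedding, sigma, truncation, nNeighbors)
    set.seed(params@seed)
    perm <- .permuteAF(af, eligible, params@K)
    w <- geom$Wn[candidate, ]
    nullVals <- as.numeric(w %*% perm)
    obs <- sum(w * af)
    mu <- mean(nullVals)
    sdv <- stats::sd(nullVals)
    degenerate <- !is.finite(sdv) || sdv == 0
    z <- if (degenerate) 0 else (obs - mu) / sdv
    list(z = z, observed = obs, mu = mu, sd = if (degenerate) 0 else sdv,
         degenerate = degenerate)
}

#' Read-level binomial enrichment of alternate alleles in a clump
#'
#' Upper-tail binomial probability \code{P(X >= nAlt)} for
#' \code{X ~ Binomial(nAlt + nRef, bulkAF)}, where the flipping
#' probability is the bulk alternate allele frequency of the variant
#' (alternate reads over all reads, pooled over every cell).  Evaluated in
#' log space by \code{stats::pbinom} for stability.
#'
#' @param nAlt,nRef alternate- and reference-supporting read counts summed
#'   over the clump's member cells.
#' @param bulkAF bulk alternate AF in [0, 1].
#' @return the one-sided p-value; 1 when the clump has no reads.
#' @examples
#' binomialEnrichment(1, 0, 0.5)   # 0.5
#' binomialEnrichment(5, 5, 0.1)   # ~1.63e-3
#' @export
binomialEnrichment <- function(nAlt, nRef, bulkAF) {
    stopifnot(nAlt >= 0, nRef >= 0, bulkAF >= 0, bulkAF <= 1)
    n <- nAlt + nRef
    if (n == 0) return(1)
    stats::pbinom(nAlt - 1, n, bulkAF, lower.tail = FALSE)
}

#' Cell-level Fisher enrichment of alternate-allele-expressing cells
#'
#' One-sided (enrichment) Fisher exact test on the 2x2 table
#' \preformatted{              AF > eta            AF <= eta
#'   clump      cEtaClump           c0Clump - cEtaClump
#'   bulk       cEtaBulk            c0Bulk  - cEtaBulk}
#' where by default c0 counts the cells with AF > 0 (in the clump and in
#' the whole sample, respectively), so the test asks whether expressing
#' cells inside the clump are enriched for high AFs relative to expressing
#' cells overall.  The clump row is a subset of the bulk row;
#' \code{disjointBulk = TRUE} subtracts the clump counts from the bulk row
#' first.
#'
#' @param cEtaClump,c0Clump cells in the clump with AF > eta, and the
#'   clump denominator count.
#' @param cEtaBulk,c0Bulk the same counts over all cells.
#' @param disjointBulk subtract the clump counts from the bulk row.
#' @return the one-sided p-value (1 for an empty table).
#' @examples
#' fisherEnrichment(1, 1, 1, 100)  # 2/101
#' @export
fisherEnrichment <- function(cEtaClump, c0Clump, cEtaBulk, c0Bulk,
                             disjointBulk = FALSE) {
    stopifnot(cEtaClump <= c0Clump, cEtaBulk <= c0Bulk)
    a <- cEtaClump; b <- c0Clump - cEtaClump
    cc <- cEtaBulk; d <- c0Bulk - cEtaBulk
    if (disjointBulk) { cc <- cc - a; d <- d - b }
    if (a + b + cc + d == 0) return(1)
    stats::phyper(a - 1, a + cc, b + d, a + b, lower.tail = FALSE)
}

## Vectorized one-sided Fisher p over a radius scan.
.fisherUpper <- function(a, b, cc, d) {
    stats::phyper(a - 1, a + cc, b + d, a + b, lower.tail = FALSE)
}

#' Effective radius of a clump
#'
#' Starting from the clump center, neighborhoods are grown one neighbor at
#' a time (in ascending distance) up to \code{maxNeighbors}; the radius at
#' which the cell-level Fisher enrichment p-value is minimized is the
#' effective radius.  Ties are resolved toward the smallest radius.
#'
#' @param embedding a \code{CellEmbedding}.
#' @param af per-cell alternate AFs.
#' @param center center cell index or id.
#' @param params a \code{\link{DetectionParams-class}} (uses \code{eta}
#'   and \code{fisherDenominator}).
#' @param maxNeighbors largest neighborhood scanned (default: the upper
#'   neighborhood-size bound, 10% of cells).
#' @return a list with \code{radius}, \code{k} (neighbors included) and
#'   \code{fisherP} at the optimum.
#' @export
effectiveRadius <- function(embedding, af, center,
                            params = DetectionParams(),
                            maxNeighbors = NULL) {
    if (is.character(center)) center <- match(center, cellIds(embedding))
    n <- length(cellIds(embedding))
    if (is.null(maxNeighbors)) maxNeighbors <- max(floor(0.1 * n), 1L)
    maxNeighbors <- min(maxNeighbors, n - 1L)
    eta <- params@eta
    cEtaBulk <- sum(af > eta)
    c0Bulk <- if (params@fisherDenominator == "expressed") sum(af > 0) else n
    nbr <- embedding@nnIndex[center, seq_len(maxNeighbors)]
    afPath <- af[c(center, nbr)]
    cEta <- cumsum(afPath > eta)[-1]
    c0 <- if (params@fisherDenominator == "expressed")
        cumsum(afPath > 0)[-1] else seq_len(maxNeighbors) + 1L
    p <- .fisherUpper(cEta, c0 - cEta, cEtaBulk, c0Bulk - cEtaBulk)
    k <- which.min(p)   # first minimum = smallest radius on ties
    list(radius = unname(embedding@nnDist[center, k]), k = k,
         fisherP = p[k])
}

#' Multiscale detection of expressed-variant clumps
#'
#' For every variant (row of the allele count matrix) and every scale of
#' the ladder: smooth the per-cell AFs on the embedding, select strict
#' local maxima as candidate clump centers, score each candidate with an
#' RD-aware permutation z-score, compute read-level binomial and
#' cell-level Fisher enrichment against the bulk sample, and determine the
#' effective radius.  Clumps passing all filters (z > minZ, more than
#' minMutatedCells mutation-harboring member cells, both enrichment
#' p-values below maxEnrichmentP) are reported; duplicate centers arising
#' at several scales are collapsed, keeping the call with the largest
#' z-score.  Clump membership at scale sigma is all cells within sigma of
#' the center (center included).
#'
#' Output is deterministic for a fixed \code{params@seed}.
#'
#' @param counts an \code{\link{AlleleCountMatrix-class}} whose columns
#'   align with the embedding cells.
#' @param embedding a \code{\link{CellEmbedding-class}}.
#' @param ladder a \code{\link{ScaleLadder-class}}; default
#'   \code{selectScales(embedding)}.
#' @param params a \code{\link{DetectionParams-class}}.
#' @param verbose log per-variant candidate counts.
#' @return a \code{\link{ClumpSet-class}}.
#' @export
detectClumps <- function(counts, embedding, ladder = NULL,
                         params = DetectionParams(), verbose = FALSE) {
    stopifnot(is(counts, "AlleleCountMatrix"), is(embedding, "CellEmbedding"))
    if (!identical(colnames(counts), cellIds(embedding)))
        stop("allele count matrix columns and embedding cells must align")
    if (is.null(ladder)) ladder <- selectScales(embedding)
    af <- altAF(counts); rd <- readDepth(counts)
    alt <- altCount(counts); ref <- refCount(counts)
    nbrSizes <- .scaleNeighborhoodSizes(embedding, ladder)
    geoms <- lapply(seq_along(ladder@scales), function(a)
        .scaleGeometry(embedding, ladder@scales[a],
                       nNeighbors = nbrSizes[a]))
    ids <- cellIds(embedding)
    n <- length(ids)
    set.seed(params@seed)
    rows <- list()
    for (v in seq_len(nrow(counts))) {
        phi <- af[v, ]; depth <- rd[v, ]
        eligible <- depth > params@tau
        if (sum(phi > 0) == 0 || sum(eligible) < 2) next
        bulkAlt <- sum(alt[v, ]); bulkRef <- sum(ref[v, ])
        bulkAF <- if (bulkAlt + bulkRef > 0) bulkAlt / (bulkAlt + bulkRef) else 0
        cEtaBulk <- sum(phi > params@eta)
        c0Bulk <- if (params@fisherDenominator == "expressed")
            sum(phi > 0) else n
        vrows <- list()
        for (a in seq_along(geoms)) {
            geom <- geoms[[a]]
            phibar <- .smoothValues(geom, phi)
            cand <- .candidatesFromField(phibar, geom$nbrList)
            if (verbose)
                message(sprintf("variant %s scale %.3g: %d candidates",
                                rownames(counts)[v], geom$sigma,
                                length(cand)))
            if (!length(cand)) next
            perm <- .permuteAF(phi, eligible, params@K)
            nullVals <- geom$Wn[cand, , drop = FALSE] %*% perm
            mu <- rowMeans(nullVals)
            sdv <- apply(nullVals, 1L, stats::sd)
            degenerate <- !is.finite(sdv) | sdv == 0
            z <- ifelse(degenerate, 0, (phibar[cand] - mu) / sdv)
            for (ci in seq_along(cand)) {
                ctr <- cand[ci]
                members <- which(embedding@dist[ctr, ] <= geom$sigma)
                nMut <- sum(phi[members] > 0)
                bp <- binomialEnrichment(sum(alt[v, members]),
                                         sum(ref[v, members]), bulkAF)
                cEta <- sum(phi[members] > params@eta)
                c0 <- if (params@fisherDenominator == "expressed")
                    sum(phi[members] > 0) else length(members)
                fp <- fisherEnrichment(cEta, c0, cEtaBulk, c0Bulk)
                er <- effectiveRadius(embedding, phi, ctr, params,
                                      maxNeighbors = ladder@nUpper)
                vrows[[length(vrows) + 1L]] <- list(
                    variantId = rownames(counts)[v], center = ids[ctr],
                    scale = geom$sigma, smoothedAF = phibar[ctr],
                    z = z[ci], nullMu = mu[ci],
                    nullSd = ifelse(degenerate[ci], 0, sdv[ci]),
                    degenerate = degenerate[ci], binomP = bp,
                    fisherP = fp, effectiveRadius = er$radius,
                    nCells = length(members), nMutated = nMut,
                    members = list(ids[members]))
            }
        }
        if (!length(vrows)) next
        keep <- vapply(vrows, function(r)
            r$z > params@minZ && r$nMutated > params@minMutatedCells &&
            r$binomP < params@maxEnrichmentP &&
            r$fisherP < params@maxEnrichmentP, logical(1))
        vrows <- vrows[keep]
        if (!length(vrows)) next
        ## collapse duplicate centers across scales, keeping max z
        ctrs <- vapply(vrows, function(r) r$center, character(1))
        zs <- vapply(vrows, function(r) r$z, numeric(1))
        sel <- vapply(split(seq_along(vrows), ctrs), function(ii)
            ii[which.max(zs[ii])], integer(1))
        rows <- c(rows, vrows[sort(sel)])
    }
    .buildClumpSet(rows)
}

.buildClumpSet <- function(rows) {
    if (!length(rows)) {
        calls <- DataFrame(variantId = character(0), center = character(0),
                           scale = numeric(0), smoothedAF = numeric(0),
                           z = numeric(0), nullMu = numeric(0),
                           nullSd = numeric(0), degenerate = logical(0),
                           binomP = numeric(0), fisherP = numeric(0),
                           effectiveRadius = numeric(0),
                           nCells = integer(0), nMutated = integer(0))
        calls$members <- IRanges::CharacterList()
    } else {
        grab <- function(f, mode) vapply(rows, function(r) r[[f]], mode)
        calls <- DataFrame(
            variantId = grab("variantId", character(1)),
            center = grab("center", character(1)),
            scale = grab("scale", numeric(1)),
            smoothedAF = grab("smoothedAF", numeric(1)),
            z = grab("z", numeric(1)),
            nullMu = grab("nullMu", numeric(1)),
            nullSd = grab("nullSd", numeric(1)),
            degenerate = grab("degenerate", logical(1)),
            binomP = grab("binomP", numeric(1)),
            fisherP = grab("fisherP", numeric(1)),
            effectiveRadius = grab("effectiveRadius", numeric(1)),
            nCells = as.integer(grab("nCells", numeric(1))),
            nMutated = as.integer(grab("nMutated", numeric(1))))
        calls$members <- IRanges::CharacterList(
            lapply(rows, function(r) r$members[[1]]))
    }
    new("ClumpSet", calls = calls)
}

#' Benjamini-Hochberg adjustment of clump enrichment p-values
#'
#' Optional multiple-testing correction across all clump calls; adds
#' \code{binomPAdj} and \code{fisherPAdj} columns.  The default filtering
#' regime uses raw p-values.
#'
#' @param clumps a \code{ClumpSet}.
#' @return the \code{ClumpSet} with adjusted p-value columns.
#' @export
adjustClumpP <- function(clumps) {
    stopifnot(is(clumps, "ClumpSet"))
    clumps@calls$binomPAdj <- stats::p.adjust(clumps@calls$binomP, "BH")
    clumps@calls$fisherPAdj <- stats::p.adjust(clumps@calls$fisherP, "BH")
    clumps
}

#' Write a clump table to TSV
#'
#' Columns: variant_id, center_cell, scale, smoothed_af, z, mu, sigma,
#' binom_p, fisher_p, effective_radius, n_cells_in_clump,
#' n_mutated_cells.
#'
#' @param clumps a \code{ClumpSet}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeClumpTable <- function(clumps, path) {
    df <- clumpTable(clumps)
    out <- data.frame(variant_id = df$variantId, center_cell = df$center,
                      scale = df$scale, smoothed_af = df$smoothedAF,
                      z = df$z, mu = df$nullMu, sigma = df$nullSd,
                      binom_p = df$binomP, fisher_p = df$fisherP,
                      effective_radius = df$effectiveRadius,
                      n_cells_in_clump = df$nCells,
                      n_mutated_cells = df$nMutated)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
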