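## Clump simulation by sampling-weight shuffling, detection-accuracy
## scoring, embedding locality robustness, nearest-mutated-cell distance
## statistics, and the synthetic dataset generator used for testing.

#' Clump-simulation sampling weight
#'
#' The weight used when shuffling AFs onto the embedding to plant a
#' clump: \deqn{w = \phi^{\alpha \exp(-\delta d)}} where phi is a cell's
#' alternate AF, alpha the AF weight, delta the distance weight and d the
#' distance of the position being filled to the clump center.  Near the
#' center the exponent approaches alpha, strongly favoring high-AF cells;
#' far away the exponent decays to 0 and every expressing cell has weight
#' close to 1 (a uniform shuffle).  Cells with phi = 0 are given a small
#' floor weight \code{epsilon} so the without-replacement sampler can
#' always place them.
#'
#' @param phi alternate AF in [0, 1] (vectorized).
#' @param alpha AF weight (> 0).
#' @param delta distance weight (> 0).
#' @param d distance to the clump center (embedding units).
#' @param epsilon floor weight for phi = 0 cells.
#' @return the sampling weight(s).
#' @examples
#' clumpSamplingWeight(c(0.99, 0.01), alpha = 0.4, delta = 0.005, d = 49.8)
#' @export
clumpSamplingWeight <- function(phi, alpha, delta, d, epsilon = 1e-6) {
    stopifnot(alpha > 0, delta > 0, all(phi >= 0), all(phi <= 1))
    w <- phi^(alpha * exp(-delta * d))
    w[phi == 0] <- epsilon
    w
}

#' Plant a clump by sampling-weight shuffling of allele counts
#'
#' Shuffles one variant's per-cell (refCount, altCount) pairs so that
#' high-AF cells are attracted to a chosen center cell.  Positions are
#' filled from the nearest neighbor of the center outward; at each
#' position a remaining cell is drawn with probability proportional to
#' \code{\link{clumpSamplingWeight}} evaluated at the position's distance
#' to the center, the drawn cell's counts are copied to the position, and
#' the cell is removed from the pool.  The center cell keeps its own
#' counts.  The output counts are a permutation of the input counts.
#'
#' @param embedding a \code{\link{CellEmbedding-class}}.
#' @param refCounts,altCounts per-cell counts of one variant, aligned
#'   with \code{cellIds(embedding)}.
#' @param center center cell index or id.
#' @param alpha,delta AF and distance weights.
#' @param epsilon floor weight for zero-AF cells.
#' @return list with shuffled \code{refCounts}, \code{altCounts} and the
#'   \code{center} index.
#' @export
simulateClump <- function(embedding, refCounts, altCounts, center,
                          alpha = 0.4, delta = 0.005, epsilon = 1e-6) {
    if (is.character(center)) center <- match(center, cellIds(embedding))
    n <- length(cellIds(embedding))
    stopifnot(length(refCounts) == n, length(altCounts) == n,
              !is.na(center))
    rd <- refCounts + altCounts
    phi <- ifelse(rd > 0, altCounts / rd, 0)
    posIdx <- embedding@nnIndex[center, ]   # positions, nearest first
    posDist <- embedding@nnDist[center, ]
    pool <- setdiff(seq_len(n), center)
    newRef <- refCounts; newAlt <- altCounts
    for (p in seq_along(posIdx)) {
        w <- clumpSamplingWeight(phi[pool], alpha, delta, posDist[p],
                                 epsilon)
        pick <- pool[sample.int(length(pool), 1L, prob = w)]
        newRef[posIdx[p]] <- refCounts[pick]
        newAlt[posIdx[p]] <- altCounts[pick]
        pool <- pool[pool != pick]
    }
    list(refCounts = newRef, altCounts = newAlt, center = center)
}

#' Match detected clump centers to planted centers
#'
#' A planted clump counts as recovered when some detected center for its
#' variant lies strictly within 1% of the embedding radius of the planted
#' center cell.
#'
#' @param trueCenters named character vector: planted center cell id per
#'   variant id (names).
#' @param clumps a \code{\link{ClumpSet-class}} from
#'   \code{\link{detectClumps}}.
#' @param embedding the \code{CellEmbedding} used for detection.
#' @param matchFraction match tolerance as a fraction of the embedding
#'   radius (default 0.01, strict inequality).
#' @return a data.frame per variant with \code{nDetected},
#'   \code{minCenterDistance} and \code{matched}; aggregate
#'   \code{sensitivity} in attribute \code{"sensitivity"}.
#' @export
matchClumps <- function(trueCenters, clumps, embedding,
                        matchFraction = 0.01) {
    stopifnot(is(clumps, "ClumpSet"), !is.null(names(trueCenters)))
    radius <- embeddingRadius(embedding)
    df <- clumpTable(clumps)
    res <- lapply(names(trueCenters), function(v) {
        det <- df$center[df$variantId == v]
        if (!length(det))
            return(data.frame(variantId = v, nDetected = 0L,
                              minCenterDistance = NA_real_,
                              matched = FALSE))
        dmin <- min(embedding@dist[trueCenters[[v]], det])
        data.frame(variantId = v, nDetected = length(det),
                   minCenterDistance = dmin,
                   matched = dmin < matchFraction * radius)
    })
    out <- do.call(rbind, res)
    attr(out, "sensitivity") <- mean(out$matched)
    out
}

#' Locality robustness of repeated embeddings
#'
#' For embeddings recomputed several times (e.g. t-SNE with different
#' seeds), counts for every cell and neighbor rank r how many distinct
#' cell identities occupy rank r across the runs, and averages over
#' cells.  A perfectly stable embedding gives 1 unique neighbor at every
#' rank; identity-shuffled runs approach the coupon-collector expectation
#' \code{N (1 - (1 - 1/N)^R)}.
#'
#' @param embeddings list of \code{CellEmbedding} objects sharing cell
#'   ids.
#' @param maxRank largest neighbor rank analyzed.
#' @param shuffle if TRUE, cell identities are randomly permuted within
#'   each run first (the comparison null).
#' @return numeric vector of mean unique-neighbor counts, one per rank.
#' @export
localityRobustness <- function(embeddings, maxRank, shuffle = FALSE) {
    stopifnot(length(embeddings) >= 1)
    ids <- cellIds(embeddings[[1]])
    n <- length(ids)
    maxRank <- min(maxRank, n - 1L)
    ## neighbor identity array: runs x cells x ranks
    idArr <- lapply(embeddings, function(e) {
        stopifnot(setequal(cellIds(e), ids))
        perm <- if (shuffle) sample(ids) else cellIds(e)
        ord <- match(ids, cellIds(e))
        matrix(perm[e@nnIndex[ord, seq_len(maxRank)]], nrow = n)
    })
    vapply(seq_len(maxRank), function(r) {
        m <- vapply(idArr, function(a) a[, r], character(n))
        if (is.null(dim(m))) m <- matrix(m, nrow = n)
        mean(apply(m, 1L, function(x) length(unique(x))))
    }, numeric(1))
}

#' Nearest mutated-cell distances, real versus RD-aware null
#'
#' For every cell whose alternate AF exceeds \code{eta}, the distance to
#' the nearest other such cell; repeated under RD-aware shuffles of the
#' AF vector (cells with RD > tau exchange AFs) to form the null
#' distribution.  Spatially clumped variants give a real distribution
#' stochastically smaller than the null.
#'
#' @param embedding a \code{CellEmbedding}.
#' @param af,rd per-cell AF and read-depth vectors.
#' @param eta AF threshold defining a mutated cell.
#' @param nShuffles number of RD-aware shuffles.
#' @param tau RD eligibility threshold for shuffling.
#' @return list with \code{real} (numeric vector, empty and flagged when
#'   fewer than 2 mutated cells), \code{shuffled} (pooled null vector)
#'   and \code{flagged}.
#' @export
nearestMutatedDistance <- function(embedding, af, rd, eta = 0.5,
                                   nShuffles = 100, tau = 0) {
    nn1 <- function(phi) {
        mut <- which(phi > eta)
        if (length(mut) < 2) return(numeric(0))
        sub <- embedding@dist[mut, mut, drop = FALSE]
        diag(sub) <- Inf
        apply(sub, 1L, min)
    }
    real <- nn1(af)
    eligible <- rd > tau
    shuffled <- unlist(lapply(seq_len(nShuffles), function(k) {
        phi <- af
        idx <- which(eligible)
        phi[idx] <- af[idx[sample.int(length(idx))]]
        nn1(phi)
    }))
    list(real = real, shuffled = shuffled, flagged = length(real) == 0)
}

#' Generate a synthetic embedding and allele count dataset
#'
#' Emulates the inputs of a single-cell clump analysis: a 2-D
#' Gaussian-mixture embedding (clusters of transcriptionally similar
#' cells), per-cell per-variant read depths (a covered/uncovered Bernoulli
#' layer for transcript dropout, negative-binomial depth where covered),
#' alternate counts drawn binomially from a per-cell allelic fraction
#' skewed toward 0 and 1, and optional planted clumps realized with
#' \code{\link{simulateClump}}.  Optionally adds a per-cell CNV call set
#' with deletion segments planted on the cells of one cluster.  The
#' dataset regenerates bit-identically from its seed and parameters
#' (stored in \code{$params}).
#'
#' @param nCells,nClusters,nVariants dataset dimensions.
#' @param clusterSpread cluster centers are drawn uniformly in
#'   \code{[-clusterSpread, clusterSpread]^2} (embedding units).
#' @param clusterSd within-cluster standard deviation.
#' @param coverageRate probability that a cell covers a variant.
#' @param depthMean,depthSize negative-binomial depth model (mean and
#'   size/dispersion) for covered cells; depths are shifted by +1 so a
#'   covered cell always has RD >= 1.
#' @param mutRate fraction of covered cells carrying the alternate allele.
#' @param afShape1,afShape2 Beta parameters of the per-cell allelic
#'   fraction of mutated cells (default Beta(5, 1): skewed toward 1, as
#'   observed in read-level AF spectra dominated by 0 and 100%).
#' @param plantClumps number of leading variants to re-shuffle into
#'   planted clumps (0 disables).
#' @param alpha,delta sampling weights used for planting.
#' @param cnv if TRUE, add a CNV call set (deletions over the cells of
#'   cluster 1).
#' @param seed random seed.
#' @return list with \code{embedding}, \code{counts} (an
#'   \code{AlleleCountMatrix}), \code{centers} (named planted center ids,
#'   one per planted variant), \code{cnvCalls} (data.frame or NULL) and
#'   \code{params}.
#' @export
generateSyntheticDataset <- function(nCells = 1000, nClusters = 8,
                                     nVariants = 50, clusterSpread = 700,
                                     clusterSd = 50, coverageRate = 0.3,
                                     depthMean = 6, depthSize = 2,
                                     mutRate = 0.08, afShape1 = 5,
                                     afShape2 = 1, plantClumps = 0,
                                     alpha = 0.4, delta = 0.005,
                                     cnv = FALSE, seed = 1) {
    stopifnot(nCells > 1, nClusters >= 1, nVariants >= 1)
    if (plantClumps > nVariants)
        stop("cannot plant more clumps than variants")
    params <- as.list(environment())
    set.seed(seed)
    ctrs <- matrix(stats::runif(2 * nClusters, -clusterSpread,
                                clusterSpread), ncol = 2)
    memb <- sample.int(nClusters, nCells, replace = TRUE)
    coords <- ctrs[memb, , drop = FALSE] +
        matrix(stats::rnorm(2 * nCells, sd = clusterSd), ncol = 2)
    rownames(coords) <- sprintf("cell_%04d", seq_len(nCells))
    colnames(coords) <- c("dim1", "dim2")
    embedding <- CellEmbedding(coords)

    vn <- sprintf("variant_%03d", seq_len(nVariants))
    ref <- alt <- matrix(0L, nVariants, nCells,
                         dimnames = list(vn, rownames(coords)))
    for (v in seq_len(nVariants)) {
        covered <- stats::runif(nCells) < coverageRate
        depth <- integer(nCells)
        depth[covered] <- 1L + stats::rnbinom(sum(covered),
                                              mu = depthMean - 1,
                                              size = depthSize)
        mut <- covered & stats::runif(nCells) < mutRate
        psi <- numeric(nCells)
        psi[mut] <- stats::rbeta(sum(mut), afShape1, afShape2)
        a <- integer(nCells)
        a[mut] <- stats::rbinom(sum(mut), depth[mut], psi[mut])
        alt[v, ] <- a
        ref[v, ] <- depth - a
    }

    centers <- character(0)
    if (plantClumps > 0) {
        centers <- stats::setNames(
            rownames(coords)[sample.int(nCells, plantClumps,
                                        replace = TRUE)],
            vn[seq_len(plantClumps)])
        for (v in seq_len(plantClumps)) {
            sim <- simulateClump(embedding, ref[v, ], alt[v, ],
                                 centers[[v]], alpha = alpha,
                                 delta = delta)
            ref[v, ] <- sim$refCounts
            alt[v, ] <- sim$altCounts
        }
    }

    cnvCalls <- NULL
    if (cnv) {
        carriers <- rownames(coords)[memb == 1]
        segs <- data.frame(chrom = c("chr17", "chr17", "chr10"),
                           start = c(30e6, 45e6, 50e6),
                           end = c(81e6, 60e6, 130e6),
                           state = "del")
        cnvCalls <- do.call(rbind, lapply(carriers, function(cc)
            cbind(cell = cc, segs[stats::runif(nrow(segs)) < 0.9, ,
                                  drop = FALSE])))
        rownames(cnvCalls) <- NULL
    }

    counts <- AlleleCountMatrix(ref, alt,
                                colData = DataFrame(cluster = memb),
                                metadata = list(simulation = params))
    list(embedding = embedding, counts = counts, centers = centers,
         cnvCalls = cnvCalls, params = params)
}

#' Simulation study of clump-detection sensitivity
#'
#' Generates a synthetic embedding with baseline allele counts, plants
#' one clump per variant with the sampling-weight shuffler, runs the
#' multiscale detector on every variant, and scores recovery under the
#' strict 1%-of-embedding-radius match criterion.
#'
#' @param nCells number of cells.
#' @param nSims number of simulated clumps (one variant each).
#' @param alpha,delta planting weights.
#' @param K permutations per candidate for the detector.
#' @param seed random seed (controls generation and detection).
#' @param ... further arguments to \code{\link{generateSyntheticDataset}}.
#' @return list with \code{scores} (per-variant data.frame from
#'   \code{\link{matchClumps}}), \code{sensitivity}, \code{maxClumps},
#'   \code{clumps}, \code{dataset}.
#' @export
runClumpSimulationStudy <- function(nCells = 1000, nSims = 100,
                                    alpha = 0.4, delta = 0.005, K = 200,
                                    seed = 1, ...) {
    ds <- generateSyntheticDataset(nCells = nCells, nVariants = nSims,
                                   plantClumps = nSims, alpha = alpha,
                                   delta = delta, seed = seed, ...)
    params <- DetectionParams(K = K, seed = seed)
    clumps <- detectClumps(ds$counts, ds$embedding, params = params)
    scores <- matchClumps(ds$centers, clumps, ds$embedding)
    list(scores = scores,
         sensitivity = attr(scores, "sensitivity"),
         maxClumps = max(scores$nDetected),
         clumps = clumps, dataset = ds)
}
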