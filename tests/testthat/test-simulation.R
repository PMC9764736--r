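test_that("sampling weights reproduce the worked-example values", {
    w <- clumpSamplingWeight(c(0.99, 0.01), alpha = 0.4,
                             delta = 0.005, d = 49.8)
    expect_equal(round(w, 3), c(0.997, 0.238))
    expect_equal(round(clumpSamplingWeight(0.01, 0.4, 0.05, 49.8), 3),
                 0.858)
    expect_equal(round(clumpSamplingWeight(0.01, 0.2, 0.05, 49.8), 3),
                 0.926)
    ## the exponent vanishes at large delta * d: every expressing cell
    ## approaches weight 1 (a uniform shuffle)
    expect_equal(clumpSamplingWeight(c(0.9, 0.1, 0.01), 0.4, 0.5,
                                     1e5), rep(1, 3), tolerance = 1e-9)
    ## zero-AF cells keep the epsilon floor so they remain placeable
    expect_equal(clumpSamplingWeight(0, 0.4, 0.005, 10), 1e-6)
})

test_that("clump planting permutes the count multiset and attracts high AFs", {
    set.seed(17)
    emb <- CellEmbedding(matrix(rnorm(400) * 50, ncol = 2))
    n <- 200
    ref <- rpois(n, 4)
    alt <- ifelse(runif(n) < 0.1, rpois(n, 5) + 1, 0)
    sim <- simulateClump(emb, ref, alt, center = 42, alpha = 0.4,
                         delta = 0.005)
    expect_equal(sort(sim$refCounts), sort(ref))
    expect_equal(sort(sim$altCounts), sort(alt))
    ## the center keeps its own counts
    expect_equal(sim$refCounts[42], ref[42])
    ## planted-signal property: mean AF near the center exceeds the
    ## global mean under a strong, short-range clump
    af <- ifelse(sim$refCounts + sim$altCounts > 0,
                 sim$altCounts / (sim$refCounts + sim$altCounts), 0)
    near <- distMatrix(emb)[42, ] <= sort(distMatrix(emb)[42, ])[20]
    expect_gt(mean(af[near & seq_len(n) != 42]), mean(af))
})

test_that("center matching applies the strict 1%-of-radius rule", {
    set.seed(18)
    emb <- CellEmbedding(matrix(rnorm(100) * 100, ncol = 2))
    radius <- embeddingRadius(emb)
    mkClumps <- function(centers, variant = "v1") {
        calls <- DataFrame(variantId = rep(variant, length(centers)),
                           center = centers)
        calls$members <- IRanges::CharacterList(
            rep(list(character(0)), length(centers)))
        new("ClumpSet", calls = calls)
    }
    ids <- cellIds(emb)
    ## exact center -> match at distance 0
    sc <- matchClumps(c(v1 = ids[5]), mkClumps(ids[5]), emb)
    expect_true(sc$matched)
    expect_equal(sc$minCenterDistance, 0)
    ## a center exactly at the 1% boundary does not match (strict)
    D <- distMatrix(emb)
    other <- which(D[5, ] > 0.011 * radius)[1]
    sc2 <- matchClumps(c(v1 = ids[5]), mkClumps(ids[other]), emb)
    expect_false(sc2$matched)
    ## no detections -> unmatched with NA distance
    sc3 <- matchClumps(c(v2 = ids[5]), mkClumps(ids[1], "v1"), emb)
    expect_false(sc3$matched)
    expect_equal(sc3$nDetected, 0L)
    ## scoring equals a brute-force all-pairs distance oracle
    centers <- ids[c(2, 9, 30)]
    sc4 <- matchClumps(c(v1 = ids[5]), mkClumps(centers), emb)
    expect_equal(sc4$minCenterDistance,
                 min(D[5, match(centers, ids)]))
})

test_that("locality robustness: identical runs give 1 unique neighbor per rank", {
    set.seed(19)
    co <- matrix(rnorm(120), ncol = 2)
    rownames(co) <- paste0("c", 1:60)
    emb <- CellEmbedding(co)
    u <- localityRobustness(list(emb, emb, emb), maxRank = 10)
    expect_equal(u, rep(1, 10))
    expect_equal(localityRobustness(list(emb), maxRank = 5), rep(1, 5))
})

test_that("shuffled locality matches the closed-form unique-id expectation", {
    set.seed(20)
    co <- matrix(rnorm(200), ncol = 2)
    rownames(co) <- paste0("c", 1:100)
    emb <- CellEmbedding(co)
    R <- 30
    u <- localityRobustness(rep(list(emb), R), maxRank = 12,
                            shuffle = TRUE)
    nEff <- 99   # a rank draws among the other N - 1 cells
    expected <- nEff * (1 - (1 - 1 / nEff)^R)
    ## Monte-Carlo tolerance: binomial-ish sd over 100 cells x 12 ranks
    expect_lt(max(abs(u - expected)), 1.5)
    expect_gt(mean(u), expected - 0.5)
})

test_that("nearest mutated distances contract for planted clumps", {
    set.seed(23)
    ds <- generateSyntheticDataset(nCells = 300, nVariants = 2,
                                   plantClumps = 1, seed = 23)
    af <- altAF(ds$counts); rd <- readDepth(ds$counts)
    res <- nearestMutatedDistance(ds$embedding, af[1, ], rd[1, ],
                                  eta = 0.5, nShuffles = 30)
    expect_false(res$flagged)
    expect_lt(stats::median(res$real), stats::median(res$shuffled))
    ## exactly two mutated cells -> a single separation value
    af2 <- rep(0, 300); af2[c(4, 9)] <- 1
    r2 <- nearestMutatedDistance(ds$embedding, af2, rep(1, 300),
                                 nShuffles = 2)
    expect_equal(length(r2$real), 2)
    expect_equal(unname(r2$real[1]), unname(r2$real[2]))
    expect_equal(unname(r2$real[1]),
                 distMatrix(ds$embedding)[4, 9])
    ## a single mutated cell -> empty, flagged
    af1 <- rep(0, 300); af1[4] <- 1
    expect_true(nearestMutatedDistance(ds$embedding, af1,
                                       rep(1, 300),
                                       nShuffles = 2)$flagged)
})

test_that("the synthetic generator is reproducible with stated dimensions", {
    d1 <- generateSyntheticDataset(nCells = 150, nVariants = 12,
                                   plantClumps = 3, seed = 77)
    d2 <- generateSyntheticDataset(nCells = 150, nVariants = 12,
                                   plantClumps = 3, seed = 77)
    expect_identical(refCount(d1$counts), refCount(d2$counts))
    expect_identical(altCount(d1$counts), altCount(d2$counts))
    expect_identical(d1$embedding@coords, d2$embedding@coords)
    expect_identical(d1$centers, d2$centers)
    expect_equal(dim(d1$counts), c(12L, 150L))
    expect_error(generateSyntheticDataset(nCells = 50, nVariants = 2,
                                          plantClumps = 5, seed = 1),
                 "plant")
})

test_that("synthetic depths match the stated count model", {
    ds <- generateSyntheticDataset(nCells = 2000, nVariants = 10,
                                   coverageRate = 0.4, depthMean = 6,
                                   depthSize = 2, seed = 31)
    rd <- readDepth(ds$counts)
    covered <- rd > 0
    ## coverage layer: Bernoulli(0.4) per entry
    pHat <- mean(covered)
    seP <- sqrt(0.4 * 0.6 / length(rd))
    expect_lt(abs(pHat - 0.4), 3 * seP)
    ## depth layer: 1 + NB(mu = 5, size = 2) where covered
    d <- rd[covered]
    seMu <- stats::sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - 6), 3 * seMu)
})
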