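test_that("smoothing matches hand-computed kernel averages", {
    ## center at 0 with neighbors at d = 1 (AF 0.5) and d = 2 (AF 1.0)
    emb <- CellEmbedding(cbind(c(0, 1, -2), 0))
    f <- smoothAF(emb, c(0, 0.5, 1), sigma = 1)
    expect_equal(f@values[1], (0.5 * exp(-1) + 1 * exp(-4)) / 2,
                 tolerance = 1e-12)
    ## all-zero AF -> all-zero field
    expect_true(all(smoothAF(emb, c(0, 0, 0), 1)@values == 0))
    ## very large sigma -> unweighted mean of neighbor AFs
    fBig <- smoothAF(emb, c(0, 0.5, 1), sigma = 1e6)
    expect_equal(fBig@values[1], 0.75, tolerance = 1e-9)
})

test_that("smoothing is linear in the AF vector", {
    set.seed(8)
    emb <- CellEmbedding(matrix(rnorm(100), ncol = 2))
    a <- runif(50); b <- runif(50)
    s <- function(x) smoothAF(emb, x, sigma = 0.5)@values
    expect_equal(s(2 * a + 3 * b), 2 * s(a) + 3 * s(b),
                 tolerance = 1e-12)
})

test_that("candidates are strict local maxima; flat fields yield none", {
    emb1d <- CellEmbedding(matrix(1:5, ncol = 1))
    fld <- function(v) new("SmoothedField", values = v, sigma = 1,
                           nNeighbors = rep(2L, 5),
                           emptyNeighborhood = rep(FALSE, 5))
    ## 2-nearest neighborhoods on the line
    expect_equal(findClumpCandidates(emb1d,
                                     fld(c(0.1, 0.5, 0.3, 0.2, 0.4)),
                                     nNeighbors = 2), c(2L, 5L))
    ## constant field: strict inequality never holds
    expect_length(findClumpCandidates(emb1d, fld(rep(0.3, 5)),
                                      nNeighbors = 2), 0)
    ## zero cells are never candidates
    expect_length(findClumpCandidates(emb1d, fld(rep(0, 5)),
                                      nNeighbors = 2), 0)
})

test_that("a single expressing cell is the lone candidate", {
    set.seed(10)
    emb <- CellEmbedding(matrix(rnorm(60), ncol = 2))
    af <- rep(0, 30); af[7] <- 1
    f <- smoothAF(emb, af, sigma = 0.5)
    cand <- findClumpCandidates(emb, f)
    ## the field peaks next to the expressing cell; with count-based
    ## 3-NN neighborhoods the candidate set is small and near cell 7
    expect_gt(length(cand), 0)
    expect_true(all(distMatrix(emb)[7, cand] <= 1.5))
})

test_that("candidate selection matches a brute-force oracle on 200 cells", {
    set.seed(12)
    co <- matrix(rnorm(400) * 10, ncol = 2)
    emb <- CellEmbedding(co)
    af <- ifelse(runif(200) < 0.2, runif(200), 0)
    for (k in c(5, 20)) {
        f <- smoothAF(emb, af, sigma = 3, nNeighbors = k)
        got <- findClumpCandidates(emb, f, nNeighbors = k)
        expect_identical(got, oracleLocalMax(co, f@values, k))
    }
})

test_that("RD-aware permutations fix low-depth cells and conserve AFs", {
    set.seed(13)
    af <- c(0.9, 0.5, 0, 0.2, 0, 0.7)
    rd <- c(5, 3, 0, 2, 0, 4)
    eligible <- rd > 0
    perm <- clumpscan:::.permuteAF(af, eligible, 50)
    ## cells with RD <= tau hold their AF in every permutation
    expect_true(all(perm[!eligible, ] == af[!eligible]))
    ## the multiset of eligible AFs is conserved exactly
    for (k in 1:50)
        expect_equal(sort(perm[eligible, k]), sort(af[eligible]))
})

test_that("degenerate nulls give a flagged z of 0", {
    emb <- CellEmbedding(cbind(c(0, 1, 2, 3), 0))
    res <- permutationZ(emb, af = rep(0.4, 4), rd = rep(2, 4),
                        candidate = 2, sigma = 1,
                        params = DetectionParams(K = 100, seed = 1))
    expect_true(res$degenerate)
    expect_equal(res$z, 0)
    expect_error(permutationZ(emb, rep(0.4, 4), rd = c(2, 0, 0, 0), 2,
                              1, DetectionParams(K = 100, seed = 1)),
                 "fewer than 2")
})

test_that("Monte-Carlo null moments match the exhaustive 24-permutation oracle", {
    emb <- CellEmbedding(cbind(c(0, 1, 2, 3), 0))
    af <- c(0.1, 0.4, 0.7, 0.9)
    sigma <- 1.5
    cand <- 2L
    ## independent oracle: enumerate all 4! assignments and average the
    ## smoothed value at the candidate computed from first principles
    D <- oracleDist(cbind(c(0, 1, 2, 3), 0))
    nbr <- setdiff(which(D[cand, ] <= 3 * sigma), cand)
    w <- exp(-D[cand, nbr]^2 / sigma^2) / length(nbr)
    perms <- rbind(af[c(1, 2, 3, 4)])
    idx <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
    idx <- idx[apply(idx, 1, function(r) length(unique(r)) == 4), ]
    vals <- apply(idx, 1, function(r) sum(w * af[r][nbr]))
    muEx <- mean(vals); sdEx <- stats::sd(vals)
    K <- 2000L
    res <- permutationZ(emb, af, rd = rep(1, 4), cand, sigma,
                        DetectionParams(K = K, seed = 7))
    expect_lt(abs(res$mu - muEx), 3 * sdEx / sqrt(K))
    expect_lt(abs(res$sd - sdEx), 3 * sdEx / sqrt(2 * K))
})

test_that("binomial tail matches hand values and the enumeration oracle", {
    expect_equal(binomialEnrichment(1, 0, 0.5), 0.5)
    expect_equal(binomialEnrichment(5, 5, 0.1),
                 oracleBinomTail(5, 10, 0.1), tolerance = 1e-12)
    expect_equal(binomialEnrichment(5, 5, 0.1), 1.63e-3,
                 tolerance = 0.01)
    expect_equal(binomialEnrichment(3, 4, 1), 1)   # degenerate p = 1
    expect_equal(binomialEnrichment(0, 0, 0.3), 1) # no reads
    set.seed(21)
    for (i in 1:200) {
        n <- sample.int(400, 1)
        a <- sample.int(n, 1)
        p <- runif(1, 0.01, 0.99)
        expect_equal(binomialEnrichment(a, n - a, p),
                     oracleBinomTail(a, n, p),
                     tolerance = 1e-12)
    }
})

test_that("Fisher enrichment matches enumeration, fisher.test and closed forms", {
    expect_equal(fisherEnrichment(1, 1, 1, 100), 2 / 101,
                 tolerance = 1e-12)
    expect_equal(fisherEnrichment(0, 5, 10, 80), 1)  # no high-AF cells
    expect_equal(fisherEnrichment(8, 10, 20, 100),
                 oracleFisherUpper(8, 2, 20, 80), tolerance = 1e-12)
    expect_equal(fisherEnrichment(8, 10, 20, 100),
                 stats::fisher.test(matrix(c(8, 2, 20, 80), 2,
                                           byrow = TRUE),
                                    alternative = "greater")$p.value,
                 tolerance = 1e-9)
    set.seed(22)
    for (i in 1:200) {
        c0c <- sample.int(30, 1); cec <- sample.int(c0c, 1)
        c0b <- c0c + sample.int(200, 1)
        ceb <- min(cec + sample.int(50, 1), c0b)
        expect_equal(fisherEnrichment(cec, c0c, ceb, c0b),
                     oracleFisherUpper(cec, c0c - cec, ceb, c0b - ceb),
                     tolerance = 1e-12)
    }
})

test_that("effective radius minimizes the Fisher p, smallest on ties", {
    ## mutated cells clustered within r0 of the center, none beyond
    set.seed(31)
    ctr <- c(0, 0)
    mutated <- matrix(rnorm(20, sd = 0.5), ncol = 2)
    far <- matrix(rnorm(160, sd = 8) + 50, ncol = 2)
    co <- rbind(ctr, mutated, far)
    rownames(co) <- paste0("cell_", seq_len(nrow(co)))
    emb <- CellEmbedding(co)
    af <- c(1, rep(1, 10), rep(0, 80))
    params <- DetectionParams(K = 100, seed = 1, eta = 0.5)
    er <- effectiveRadius(emb, af, 1, params, maxNeighbors = 20)
    r0 <- max(distMatrix(emb)[1, 2:11])
    expect_equal(er$radius, r0)
    ## brute-force scan oracle over every neighborhood size
    nUpper <- 9L   # small bound to exercise the scan
    nn <- nearestNeighbors(emb, 1, nUpper)
    ps <- vapply(seq_len(nUpper), function(k) {
        memb <- c(1, match(nn$cell[1:k], cellIds(emb)))
        oracleFisherUpper(sum(af[memb] > 0.5),
                          length(memb) - sum(af[memb] > 0.5),
                          sum(af > 0.5), length(af) - sum(af > 0.5))
    }, numeric(1))
    er2 <- effectiveRadius(emb, af, 1, params, maxNeighbors = nUpper)
    expect_equal(er2$k, which.min(ps))
    expect_equal(er2$fisherP, min(ps), tolerance = 1e-12)
})

test_that("no clumps are reported for an unexpressed variant", {
    set.seed(41)
    ds <- generateSyntheticDataset(nCells = 200, nVariants = 2,
                                   seed = 41)
    zero <- AlleleCountMatrix(
        refCount(ds$counts),
        matrix(0L, nrow(ds$counts), ncol(ds$counts),
               dimnames = dimnames(refCount(ds$counts))))
    cl <- detectClumps(zero, ds$embedding,
                       params = DetectionParams(K = 100, seed = 1))
    expect_equal(nClumps(cl), 0)
})

test_that("reported clumps pass every filter and are seed-reproducible", {
    ds <- generateSyntheticDataset(nCells = 300, nVariants = 4,
                                   plantClumps = 4, seed = 5)
    params <- DetectionParams(K = 150, seed = 9)
    cl <- detectClumps(ds$counts, ds$embedding, params = params)
    expect_gt(nClumps(cl), 0)
    df <- clumpTable(cl)
    expect_true(all(df$z > params@minZ))
    expect_true(all(df$nMutated > params@minMutatedCells))
    expect_true(all(df$binomP < params@maxEnrichmentP))
    expect_true(all(df$fisherP < params@maxEnrichmentP))
    ## duplicate centers collapsed per variant
    expect_false(any(duplicated(df[, c("variantId", "center")])))
    ## fixed seed -> bit-identical output
    cl2 <- detectClumps(ds$counts, ds$embedding, params = params)
    expect_identical(clumpTable(cl), clumpTable(cl2))
})
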