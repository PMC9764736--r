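#' Construct a cell embedding with its distance index
#'
#' Computes the full Euclidean distance matrix from the supplied
#' coordinates (or accepts a precomputed distance matrix) and sorts, per
#' cell, all other cells by ascending distance.  The sorted neighbor lists
#' back every neighborhood query in scale selection, smoothing and clump
#' scoring.
#'
#' @param coords numeric matrix (cells x dimensions, >= 1 dimension) with
#'   unique rownames as cell ids, or a data.frame whose first column is
#'   \code{cell_id}.
#' @param dist optional precomputed symmetric distance matrix (cells x
#'   cells, dimnames = cell ids); if given, \code{coords} may be NULL and
#'   coordinate-based utilities (e.g. \code{\link{embeddingRadius}}) are
#'   unavailable.
#' @return a \code{\link{CellEmbedding-class}} object.
#' @examples
#' emb <- CellEmbedding(cbind(x = c(0, 3, 1), y = c(0, 4, 1)))
#' distMatrix(emb)[1, 2]  # 5
#' @export
CellEmbedding <- function(coords = NULL, dist = NULL) {
    if (is.null(coords) && is.null(dist))
        stop("supply coordinates or a distance matrix")
    if (!is.null(coords)) {
        if (is.data.frame(coords)) {
            ids <- as.character(coords[[1]])
            coords <- as.matrix(coords[, -1, drop = FALSE])
            rownames(coords) <- ids
        }
        coords <- as.matrix(coords)
        storage.mode(coords) <- "double"
        if (is.null(rownames(coords)))
            rownames(coords) <- paste0("cell_", seq_len(nrow(coords)))
        bad <- which(!stats::complete.cases(coords) |
                     apply(coords, 1L, function(r) any(!is.finite(r))))
        if (length(bad))
            stop("non-finite coordinates for cell(s): ",
                 paste(utils::head(rownames(coords)[bad], 5), collapse = ", "))
        if (nrow(coords) < 2)
            stop("at least 2 cells are required")
        if (is.null(dist)) dist <- .euclideanDistance(coords)
    } else {
        coords <- matrix(numeric(0), nrow = nrow(dist), ncol = 0,
                         dimnames = list(rownames(dist), NULL))
    }
    dist <- as.matrix(dist)
    dimnames(dist) <- list(rownames(coords), rownames(coords))
    n <- nrow(dist)
    nnIndex <- matrix(0L, n, n - 1L)
    nnDist <- matrix(0, n, n - 1L)
    for (i in seq_len(n)) {
        d <- dist[i, ]
        d[i] <- Inf
        o <- order(d)[seq_len(n - 1L)]
        nnIndex[i, ] <- o
        nnDist[i, ] <- dist[i, o]
    }
    rownames(nnIndex) <- rownames(nnDist) <- rownames(dist)
    new("CellEmbedding", coords = coords, dist = dist,
        nnIndex = nnIndex, nnDist = nnDist)
}

## Pairwise Euclidean distances through the Gram matrix; clamps the tiny
## negative values that cancellation can produce on the diagonal.
.euclideanDistance <- function(coords) {
    g <- tcrossprod(coords)
    sq <- diag(g)
    d2 <- outer(sq, sq, "+") - 2 * g
    d2[d2 < 0] <- 0
    d <- sqrt(d2)
    (d + t(d)) / 2
}

#' Read embedding coordinates from a TSV file
#'
#' Expects a header line \code{cell_id dim1 dim2 [...]}.
#'
#' @param path path to a tab-separated file.
#' @return a \code{\link{CellEmbedding-class}} object.
#' @export
readEmbedding <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    CellEmbedding(df)
}

#' Nearest neighbors of a cell
#'
#' @param embedding a \code{CellEmbedding}.
#' @param cell cell id or index.
#' @param k number of neighbors.
#' @return data.frame with columns \code{cell}, \code{distance}, in
#'   ascending distance order.
#' @export
nearestNeighbors <- function(embedding, cell, k) {
    i <- if (is.character(cell)) match(cell, cellIds(embedding)) else cell
    if (is.na(i)) stop("unknown cell: ", cell)
    k <- min(k, ncol(embedding@nnIndex))
    data.frame(cell = cellIds(embedding)[embedding@nnIndex[i, seq_len(k)]],
               distance = embedding@nnDist[i, seq_len(k)])
}

#' Embedding radius
#'
#' The maximum Euclidean distance from the coordinate centroid to any
#' cell.  Used as the reference length for the strict 1%-of-radius match
#' criterion when scoring simulated clumps.
#'
#' @param x a \code{CellEmbedding} built from coordinates.
#' @return a scalar radius (0 for a single point or identical points).
#' @examples
#' embeddingRadius(CellEmbedding(cbind(cos(1:8), sin(1:8))))  # ~1
#' @export
setMethod("embeddingRadius", "CellEmbedding", function(x) {
    if (!ncol(x@coords))
        stop("embedding radius needs coordinates, not just distances")
    ctr <- colMeans(x@coords)
    sqrt(max(rowSums(sweep(x@coords, 2L, ctr)^2)))
})

#' Select multiscale smoothing scales from the embedding
#'
#' Derives the neighborhood-size bounds
#' \code{(0.1 * nCells) > N_nu > max(0.01 * nCells, 10)} (lower bound
#' rounded up, upper bound rounded down, so both lie inside the open
#' interval), computes for every cell the distance to its
#' \code{nLower}-th and \code{nUpper}-th nearest neighbor, and takes the
#' medians over cells as the endpoint scales (sigma_min, sigma_max).  The
#' ladder between the endpoints is a geometric sequence with the given
#' ratio, with sigma_max appended when not hit exactly.
#'
#' @param embedding a \code{CellEmbedding}.
#' @param ratio geometric spacing of consecutive scales (default
#'   \code{sqrt(2)}, about 7 scales for a 10x scale range).
#' @return a \code{\link{ScaleLadder-class}} object.
#' @examples
#' set.seed(1)
#' emb <- CellEmbedding(matrix(rnorm(400), ncol = 2))
#' selectScales(emb)
#' @export
selectScales <- function(embedding, ratio = sqrt(2)) {
    n <- length(cellIds(embedding))
    nLower <- as.integer(ceiling(max(0.01 * n, 10)))
    nUpper <- as.integer(floor(0.1 * n))
    if (nUpper < nLower)
        stop("too few cells (", n, ") for automatic scale selection: ",
             "the neighborhood bounds (", nLower, ", ", nUpper, ") are ",
             "infeasible; supply scales manually")
    sigmaMin <- stats::median(embedding@nnDist[, nLower])
    sigmaMax <- stats::median(embedding@nnDist[, nUpper])
    scales <- sigmaMin * ratio^(0:floor(log(sigmaMax / sigmaMin) / log(ratio)))
    if (max(scales) < sigmaMax - 1e-12) scales <- c(scales, sigmaMax)
    new("ScaleLadder", sigmaMin = sigmaMin, sigmaMax = sigmaMax,
        scales = scales, nLower = nLower, nUpper = nUpper,
        nCells = as.integer(n))
}

#' Manually specified scale ladder
#'
#' @param scales strictly increasing scales.
#' @param nLower,nUpper neighborhood bounds to record (defaults derived
#'   from \code{nCells} when supplied).
#' @param nCells number of cells.
#' @return a \code{\link{ScaleLadder-class}} object.
#' @export
manualScales <- function(scales, nCells, nLower = NULL, nUpper = NULL) {
    scales <- sort(unique(scales))
    if (is.null(nLower)) nLower <- as.integer(ceiling(max(0.01 * nCells, 10)))
    if (is.null(nUpper)) nUpper <- as.integer(max(floor(0.1 * nCells), nLower))
    new("ScaleLadder", sigmaMin = min(scales), sigmaMax = max(scales),
        scales = scales, nLower = as.integer(nLower),
        nUpper = as.integer(nUpper), nCells = as.integer(nCells))
}
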