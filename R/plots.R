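## Visualization of variant AFs and detected clumps on the embedding,
## and of segment-level CNV clump scores along genomic coordinates.
## Base graphics, in the style of the lightweight per-variant panels
## that accompany clump tables.

.afPalette <- function(n = 100) {
    grDevices::colorRampPalette(c("white", "mistyrose", "red",
                                  "darkred"))(n)
}

#' Plot cells colored by AF with detected clumps
#'
#' Scatter of embedding coordinates colored white (AF 0) to red (AF 1),
#' with a circle of the effective radius drawn at each clump center.
#' Optional side panel with the smoothed field and bottom panel with
#' per-cell read depth.
#'
#' @param embedding a \code{CellEmbedding} with 2-D coordinates.
#' @param af per-cell AF (or binary CNV row).
#' @param clumps optional \code{ClumpSet}; only rows whose
#'   \code{variantId} is in \code{variantId} (when given) are drawn.
#' @param variantId restrict drawn clumps to one variant.
#' @param rd optional per-cell read depth for a bottom panel.
#' @param smoothed optional \code{SmoothedField} for a side panel.
#' @param main plot title.
#' @return invisibly, the number of clump circles drawn.
#' @export
plotClumps <- function(embedding, af, clumps = NULL, variantId = NULL,
                       rd = NULL, smoothed = NULL, main = "") {
    co <- embedding@coords
    stopifnot(ncol(co) >= 2)
    pal <- .afPalette()
    colIdx <- pmin(pmax(ceiling(af * 99) + 1L, 1L), 100L)
    panels <- 1L + !is.null(smoothed) + !is.null(rd)
    if (panels > 1L) {
        op <- graphics::par(mfrow = c(1L, panels))
        on.exit(graphics::par(op))
    }
    graphics::plot(co[, 1], co[, 2], pch = 16, cex = 0.6,
                   col = pal[colIdx], xlab = colnames(co)[1],
                   ylab = colnames(co)[2], main = main)
    drawn <- 0L
    if (!is.null(clumps) && nClumps(clumps)) {
        df <- clumpTable(clumps)
        if (!is.null(variantId)) df <- df[df$variantId %in% variantId, ]
        if (nrow(df)) {
            ci <- match(df$center, cellIds(embedding))
            theta <- seq(0, 2 * pi, length.out = 100)
            for (k in seq_len(nrow(df))) {
                r <- df$effectiveRadius[k]
                graphics::lines(co[ci[k], 1] + r * cos(theta),
                                co[ci[k], 2] + r * sin(theta),
                                col = "blue", lwd = 2)
            }
            drawn <- nrow(df)
        }
    }
    if (!is.null(smoothed)) {
        sv <- smoothed@values
        svn <- if (max(sv) > 0) sv / max(sv) else sv
        graphics::plot(co[, 1], co[, 2], pch = 16, cex = 0.6,
                       col = pal[pmin(ceiling(svn * 99) + 1L, 100L)],
                       xlab = colnames(co)[1], ylab = colnames(co)[2],
                       main = "smoothed AF")
    }
    if (!is.null(rd)) {
        rdn <- if (max(rd) > 0) rd / max(rd) else rd
        graphics::plot(co[, 1], co[, 2], pch = 16, cex = 0.6,
                       col = grDevices::grey(1 - 0.85 * rdn),
                       xlab = colnames(co)[1], ylab = colnames(co)[2],
                       main = "read depth")
    }
    invisible(drawn)
}

#' Segment-level clump z-scores along a chromosome
#'
#' Plots per-segment clump z-scores against genomic coordinates with
#' cytoband rectangles in alternating shades underneath.
#'
#' @param segments data.frame with chrom, start, end, z (e.g. built by
#'   joining \code{rowData} of a \code{CNVSegmentMatrix} with a clump
#'   table).
#' @param bands cytoBand-format data.frame (see
#'   \code{\link{syntheticCytoband}}).
#' @param chrom chromosome to draw.
#' @param main title.
#' @return invisibly, the number of segments drawn.
#' @export
plotSegmentZscores <- function(segments, bands, chrom, main = chrom) {
    seg <- segments[segments$chrom == chrom, , drop = FALSE]
    bd <- bands[bands$chrom == chrom, , drop = FALSE]
    if (!nrow(seg)) stop("no segments on ", chrom)
    ylim <- range(c(0, seg$z)) + c(-0.5, 0.5)
    graphics::plot(NA, xlim = range(c(bd$start, bd$end, seg$end)),
                   ylim = ylim, xlab = "genomic coordinate",
                   ylab = "clump z-score", main = main)
    if (nrow(bd)) {
        shade <- rep(c("grey85", "grey95"), length.out = nrow(bd))
        graphics::rect(bd$start, ylim[1], bd$end, ylim[1] + 0.3,
                       col = shade, border = NA)
        graphics::text((bd$start + bd$end) / 2, ylim[1] + 0.15,
                       bd$band, cex = 0.5)
    }
    graphics::segments(seg$start, seg$z, seg$end, seg$z, lwd = 3,
                       col = "firebrick")
    invisible(nrow(seg))
}
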