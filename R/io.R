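## Readers and writers for the interchange formats: minimal VCF 4.2,
## long-format and MatrixMarket allele count matrices, embedding TSV.

#' Write variant calls as a minimal VCF 4.2
#'
#' Emits one record per call with strand-split supporting read counts
#' and the alternate AF in the INFO field, plus a TSV mirror when
#' \code{tsv} is given.
#'
#' @param calls \code{GRanges} from \code{\link{callSNVs}} /
#'   \code{\link{callIndels}}.
#' @param path output VCF path.
#' @param tsv optional path for a tab-separated mirror.
#' @return \code{path}, invisibly.
#' @export
writeVariantVCF <- function(calls, path, tsv = NULL) {
    header <- c(
        "##fileformat=VCFv4.2",
        "##source=clumpscan",
        "##INFO=<ID=NRF,Number=1,Type=Integer,Description=\"Reference reads, forward strand\">",
        "##INFO=<ID=NRR,Number=1,Type=Integer,Description=\"Reference reads, reverse strand\">",
        "##INFO=<ID=NAF,Number=1,Type=Integer,Description=\"Alternate reads, forward strand\">",
        "##INFO=<ID=NAR,Number=1,Type=Integer,Description=\"Alternate reads, reverse strand\">",
        "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele frequency\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    getcol <- function(nm, default = 0L) {
        v <- mcols(calls)[[nm]]
        if (is.null(v)) rep(default, length(calls)) else v
    }
    info <- sprintf("NRF=%d;NRR=%d;NAF=%d;NAR=%d;AF=%.6g",
                    getcol("nRefFwd"), getcol("nRefRev"),
                    getcol("nAltFwd"), getcol("nAltRev"),
                    getcol("af", 0))
    recs <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                    as.character(seqnames(calls)), start(calls),
                    if (!is.null(names(calls))) names(calls) else ".",
                    calls$ref, calls$alt, info)
    writeLines(c(header, recs), path)
    if (!is.null(tsv)) {
        df <- data.frame(chrom = as.character(seqnames(calls)),
                         pos = start(calls), ref = calls$ref,
                         alt = calls$alt, kind = calls$kind,
                         n_ref_fwd = calls$nRefFwd,
                         n_ref_rev = calls$nRefRev,
                         n_alt_fwd = calls$nAltFwd,
                         n_alt_rev = calls$nAltRev, af = calls$af)
        utils::write.table(df, tsv, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

#' Read variants from a VCF file
#'
#' Reads a (plain or bgzipped) VCF with
#' \code{VariantAnnotation::readVcf} when available, falling back to a
#' minimal column parser, and returns the variant \code{GRanges} layout
#' used throughout the package (multi-allelic records expanded, kind
#' inferred from allele lengths).
#'
#' @param path VCF path.
#' @param genomeName genome label passed to \code{readVcf}.
#' @return \code{GRanges} with ref/alt/kind columns.
#' @export
readVcfVariants <- function(path, genomeName = "unknown") {
    if (requireNamespace("VariantAnnotation", quietly = TRUE)) {
        vcf <- VariantAnnotation::readVcf(path, genome = genomeName)
        vcf <- VariantAnnotation::expand(vcf)
        rr <- SummarizedExperiment::rowRanges(vcf)
        df <- data.frame(chrom = as.character(seqnames(rr)),
                         pos = start(rr),
                         ref = as.character(rr$REF),
                         alt = as.character(rr$ALT),
                         stringsAsFactors = FALSE)
    } else {
        lines <- readLines(path)
        lines <- lines[!startsWith(lines, "#")]
        parts <- strsplit(lines, "\t")
        df <- do.call(rbind, lapply(parts, function(p) {
            alts <- strsplit(p[5], ",")[[1]]
            data.frame(chrom = p[1], pos = as.integer(p[2]), ref = p[4],
                       alt = alts, stringsAsFactors = FALSE)
        }))
    }
    kind <- ifelse(nchar(df$ref) == nchar(df$alt), "SNV",
                   ifelse(nchar(df$ref) > nchar(df$alt), "deletion",
                          "insertion"))
    gr <- GRanges(df$chrom, IRanges(df$pos, width = nchar(df$ref)))
    mcols(gr) <- DataFrame(ref = df$ref, alt = df$alt, kind = kind)
    names(gr) <- paste0(df$chrom, ":", df$pos, "_", df$ref, "/", df$alt)
    gr
}

#' Allele count matrix I/O
#'
#' \code{writeAlleleCountsTSV} writes the long format (variant_id,
#' cell_id, n_ref, n_alt; entries with zero depth omitted) plus a
#' sidecar header comment carrying the full variant and cell universes
#' so zero rows/columns survive the round trip.
#' \code{writeAlleleCountsMM} writes MatrixMarket triplets
#' (\code{<prefix>_ref.mtx}, \code{<prefix>_alt.mtx}) with sidecar
#' \code{<prefix>_variants.txt} / \code{<prefix>_cells.txt} id files.
#'
#' @param counts an \code{AlleleCountMatrix}.
#' @param path,prefix output location.
#' @return the written path(s), invisibly; readers return an
#'   \code{AlleleCountMatrix}.
#' @rdname alleleCountsIO
#' @export
writeAlleleCountsTSV <- function(counts, path) {
    rd <- readDepth(counts)
    idx <- which(rd > 0, arr.ind = TRUE)
    df <- data.frame(variant_id = rownames(counts)[idx[, 1]],
                     cell_id = colnames(counts)[idx[, 2]],
                     n_ref = refCount(counts)[idx],
                     n_alt = altCount(counts)[idx])
    df <- df[order(df$variant_id, df$cell_id), ]
    con <- file(path, "w")
    writeLines(c(paste0("# variants: ",
                        paste(rownames(counts), collapse = ",")),
                 paste0("# cells: ",
                        paste(colnames(counts), collapse = ","))), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    invisible(path)
}

#' @rdname alleleCountsIO
#' @export
readAlleleCountsTSV <- function(path) {
    hdr <- readLines(path, n = 2L)
    vars <- strsplit(sub("^# variants: ", "", hdr[1]), ",")[[1]]
    cells <- strsplit(sub("^# cells: ", "", hdr[2]), ",")[[1]]
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#",
                            stringsAsFactors = FALSE)
    ref <- alt <- matrix(0L, length(vars), length(cells),
                         dimnames = list(vars, cells))
    i <- cbind(match(df$variant_id, vars), match(df$cell_id, cells))
    ref[i] <- df$n_ref; alt[i] <- df$n_alt
    AlleleCountMatrix(ref, alt)
}

#' @rdname alleleCountsIO
#' @export
writeAlleleCountsMM <- function(counts, prefix) {
    paths <- c(ref = paste0(prefix, "_ref.mtx"),
               alt = paste0(prefix, "_alt.mtx"),
               variants = paste0(prefix, "_variants.txt"),
               cells = paste0(prefix, "_cells.txt"))
    Matrix::writeMM(methods::as(
        Matrix::Matrix(refCount(counts), sparse = TRUE), "CsparseMatrix"),
        paths["ref"])
    Matrix::writeMM(methods::as(
        Matrix::Matrix(altCount(counts), sparse = TRUE), "CsparseMatrix"),
        paths["alt"])
    writeLines(rownames(counts), paths["variants"])
    writeLines(colnames(counts), paths["cells"])
    invisible(paths)
}

#' @rdname alleleCountsIO
#' @export
readAlleleCountsMM <- function(prefix) {
    vars <- readLines(paste0(prefix, "_variants.txt"))
    cells <- readLines(paste0(prefix, "_cells.txt"))
    ref <- as.matrix(Matrix::readMM(paste0(prefix, "_ref.mtx")))
    alt <- as.matrix(Matrix::readMM(paste0(prefix, "_alt.mtx")))
    dimnames(ref) <- dimnames(alt) <- list(vars, cells)
    AlleleCountMatrix(ref, alt)
}

#' Write embedding coordinates as TSV
#'
#' @param embedding a \code{CellEmbedding} with coordinates.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEmbedding <- function(embedding, path) {
    co <- embedding@coords
    if (!ncol(co)) stop("embedding has no coordinates to write")
    df <- data.frame(cell_id = rownames(co), co, check.names = FALSE)
    if (is.null(colnames(co)))
        names(df)[-1] <- paste0("dim", seq_len(ncol(co)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write CNV calls as TSV
#'
#' @param cnv CNV call data.frame (cell, chrom, start, end, state).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCNVCalls <- function(cnv, path) {
    out <- data.frame(cell_id = cnv$cell, chrom = cnv$chrom,
                      start = cnv$start, end = cnv$end,
                      state = cnv$state)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
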