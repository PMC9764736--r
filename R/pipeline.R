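## End-to-end orchestration: a YAML config describes which stages to run
## (simulate, call, annotate, filter, count, cnv, scales, detect, score,
## plot), every stage writes its artifacts under the output directory,
## and a manifest records each file with an md5 checksum and the stage
## that produced it, so a rerun with the same config and seed is
## byte-comparable.

#' Read a pipeline configuration
#'
#' @param path YAML file.
#' @return named list of stage blocks.
#' @export
readPipelineConfig <- function(path) yaml::read_yaml(path)

.manifestAdd <- function(manifest, stage, files) {
    rbind(manifest,
          data.frame(stage = stage, file = basename(unlist(files)),
                     md5 = unname(tools::md5sum(unlist(files))),
                     stringsAsFactors = FALSE))
}

#' Run the clump-detection pipeline
#'
#' Stages run in dependency order; each writes its outputs under
#' \code{outDir} and registers them in the manifest.  Variant calling is
#' skipped when a VCF is supplied (\code{count$vcf}); the simulate
#' stage needs no external files at all.  An effective-config snapshot
#' (\code{config_used.yaml}) is always written.
#'
#' Config blocks (all optional): \code{seed}; \code{simulate} (arguments
#' of \code{\link{generateSyntheticDataset}}); \code{call} (\code{bam},
#' \code{genome} FASTA, \code{\link{CallingParams}} fields);
#' \code{annotate} (\code{gtf}, \code{dbsnp}); \code{filter}
#' (\code{maxPopAF}); \code{count} (\code{bam}, \code{vcf},
#' \code{cells}); \code{cnv} (\code{calls}, \code{cytoband});
#' \code{embedding} (path of a coordinates TSV); \code{detect}
#' (\code{\link{DetectionParams}} fields); \code{score}; \code{plot}
#' (\code{variants}).
#'
#' @param config list (see \code{\link{readPipelineConfig}}) or YAML
#'   path.
#' @param outDir output directory (created if missing).
#' @return the manifest data.frame, invisibly; also written as
#'   \code{manifest.tsv}.
#' @export
runPipeline <- function(config, outDir) {
    if (is.character(config)) config <- readPipelineConfig(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    seed <- if (!is.null(config$seed)) config$seed else 1L
    manifest <- data.frame(stage = character(0), file = character(0),
                           md5 = character(0), stringsAsFactors = FALSE)
    cfgPath <- file.path(outDir, "config_used.yaml")
    yaml::write_yaml(config, cfgPath)
    manifest <- .manifestAdd(manifest, "config", cfgPath)

    embedding <- NULL; counts <- NULL; centers <- NULL
    variants <- NULL; genome <- NULL

    if (!is.null(config$simulate)) {
        args <- config$simulate
        args$seed <- seed
        ds <- do.call(generateSyntheticDataset, args)
        embedding <- ds$embedding; counts <- ds$counts
        centers <- ds$centers
        p1 <- file.path(outDir, "embedding.tsv")
        writeEmbedding(embedding, p1)
        p2 <- file.path(outDir, "allele_counts.tsv")
        writeAlleleCountsTSV(counts, p2)
        files <- list(p1, p2)
        if (length(centers)) {
            p3 <- file.path(outDir, "simulated_centers.tsv")
            utils::write.table(
                data.frame(variant_id = names(centers),
                           center_cell = unname(centers)),
                p3, sep = "\t", quote = FALSE, row.names = FALSE)
            files <- c(files, p3)
        }
        manifest <- .manifestAdd(manifest, "simulate", files)
    }

    if (!is.null(config$call)) {
        cp <- do.call(CallingParams,
                      config$call[setdiff(names(config$call),
                                          c("bam", "genome"))])
        genome <- readDNAStringSet(config$call$genome)
        names(genome) <- sub(" .*", "", names(genome))
        variants <- callVariants(config$call$bam, genome, cp)
        pv <- file.path(outDir, "variants.vcf")
        writeVariantVCF(variants, pv,
                        tsv = file.path(outDir, "variants.tsv"))
        manifest <- .manifestAdd(manifest, "call",
                                 list(pv, file.path(outDir,
                                                    "variants.tsv")))
    }

    if (!is.null(config$count) && !is.null(config$count$vcf)) {
        variants <- readVcfVariants(config$count$vcf)
    }

    if (!is.null(config$annotate) && !is.null(variants)) {
        models <- loadTranscriptModels(config$annotate$gtf)
        if (is.null(genome) && !is.null(config$annotate$genome)) {
            genome <- readDNAStringSet(config$annotate$genome)
            names(genome) <- sub(" .*", "", names(genome))
        }
        variants <- annotateVariants(variants, models, genome)
        if (!is.null(config$annotate$dbsnp))
            variants <- addPopulationAF(variants,
                                        config$annotate$dbsnp)
        if (!is.null(config$filter)) {
            maxAF <- config$filter$maxPopAF
            if (is.null(maxAF)) maxAF <- 0.01
            variants <- filterDamaging(variants, maxPopAF = maxAF)
        }
        pa <- file.path(outDir, "variants_annotated.tsv")
        df <- as.data.frame(variants)
        df$genes <- vapply(variants$genes, paste, character(1),
                           collapse = ",")
        utils::write.table(df, pa, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        manifest <- .manifestAdd(manifest, "annotate", pa)
    }

    if (!is.null(config$count) && !is.null(config$count$bam) &&
        !is.null(variants)) {
        counts <- countAlleles(config$count$bam, variants,
                               cells = config$count$cells)
        pc <- file.path(outDir, "allele_counts.tsv")
        writeAlleleCountsTSV(counts, pc)
        manifest <- .manifestAdd(manifest, "count", pc)
    }

    if (!is.null(config$cnv)) {
        cnv <- readCNVCalls(config$cnv$calls)
        arms <- readCytoband(config$cnv$cytoband)
        am <- armLevelMatrix(cnv, arms)
        sm <- minimalSegmentMatrix(cnv)
        files <- list()
        for (st in names(sm)) {
            p <- file.path(outDir, paste0("cnv_segments_", st, ".tsv"))
            utils::write.table(
                cbind(as.data.frame(rowData(sm[[st]])),
                      assay(sm[[st]], "calls")),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
            files <- c(files, p)
        }
        manifest <- .manifestAdd(manifest, "cnv", files)
        if (is.null(counts) && !is.null(embedding)) {
            counts <- cnvToAlleleCounts(sm[[1]])
        }
    }

    if (!is.null(config$embedding) && is.character(config$embedding)) {
        embedding <- readEmbedding(config$embedding)
    }

    clumps <- NULL
    if (!is.null(config$detect)) {
        if (is.null(counts) || is.null(embedding))
            stop("detect stage needs allele counts and an embedding; ",
                 "run (or configure) the simulate/count stages first")
        counts <- counts[, cellIds(embedding)]
        ladder <- selectScales(embedding)
        dpArgs <- config$detect
        dpArgs$seed <- seed
        dp <- do.call(DetectionParams, dpArgs)
        clumps <- detectClumps(counts, embedding, ladder, dp)
        pd <- file.path(outDir, "clumps.tsv")
        writeClumpTable(clumps, pd)
        manifest <- .manifestAdd(manifest, "detect", pd)
    }

    if (!is.null(config$score) && !is.null(clumps) &&
        !is.null(centers) && length(centers)) {
        sc <- matchClumps(centers, clumps, embedding)
        ps <- file.path(outDir, "simulation_scores.tsv")
        utils::write.table(sc, ps, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        manifest <- .manifestAdd(manifest, "score", ps)
    }

    if (!is.null(config$plot) && !is.null(clumps) &&
        !is.null(embedding) && !is.null(counts)) {
        vids <- config$plot$variants
        if (is.null(vids))
            vids <- utils::head(unique(clumpTable(clumps)$variantId), 4)
        af <- altAF(counts)
        files <- list()
        for (vid in intersect(vids, rownames(counts))) {
            p <- file.path(outDir, paste0("clump_", vid, ".png"))
            grDevices::png(p, width = 700, height = 600)
            plotClumps(embedding, af[vid, ], clumps, variantId = vid,
                       main = vid)
            grDevices::dev.off()
            files <- c(files, p)
        }
        if (length(files))
            manifest <- .manifestAdd(manifest, "plot", files)
    }

    pm <- file.path(outDir, "manifest.tsv")
    utils::write.table(manifest, pm, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(manifest)
}
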