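#' @rdname AlleleCountMatrix-class
#' @param x an object.
#' @export
setGeneric("refCount", function(x) standardGeneric("refCount"))

#' @rdname AlleleCountMatrix-class
#' @export
setGeneric("altCount", function(x) standardGeneric("altCount"))

#' @rdname AlleleCountMatrix-class
#' @export
setGeneric("altAF", function(x) standardGeneric("altAF"))

#' @rdname AlleleCountMatrix-class
#' @export
setGeneric("readDepth", function(x) standardGeneric("readDepth"))

#' @rdname CellEmbedding-class
#' @param x an object.
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname CellEmbedding-class
#' @export
setGeneric("distMatrix", function(x) standardGeneric("distMatrix"))

#' @rdname embeddingRadius
#' @export
setGeneric("embeddingRadius", function(x) standardGeneric("embeddingRadius"))

#' @rdname AlleleCountMatrix-class
setMethod("refCount", "AlleleCountMatrix", function(x) assay(x, "refCount"))

#' @rdname AlleleCountMatrix-class
setMethod("altCount", "AlleleCountMatrix", function(x) assay(x, "altCount"))

#' @rdname AlleleCountMatrix-class
setMethod("readDepth", "AlleleCountMatrix", function(x)
    assay(x, "refCount") + assay(x, "altCount"))

#' @rdname AlleleCountMatrix-class
setMethod("altAF", "AlleleCountMatrix", function(x) {
    rd <- readDepth(x)
    af <- assay(x, "altCount") / rd
    af[rd == 0] <- 0
    af
})

#' @rdname CellEmbedding-class
setMethod("cellIds", "CellEmbedding", function(x) rownames(x@dist))

#' @rdname CellEmbedding-class
setMethod("cellIds", "AlleleCountMatrix", function(x) colnames(x))

#' @rdname CellEmbedding-class
setMethod("distMatrix", "CellEmbedding", function(x) x@dist)
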