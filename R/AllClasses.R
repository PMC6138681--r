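#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData colData<- rowData<-
NULL

#' Container for qPCR quantification-cycle (Cq) panel data
#'
#' A `CqExperiment` holds one Cq value per assay (row) and sample (column),
#' the experimental group of every sample, and the designation of the
#' housekeeping (reference) assays used for normalization. It extends
#' \linkS4class{SummarizedExperiment}; the single assay is named `"cq"`,
#' sample groups live in `colData(x)$group` and the reference flag in
#' `rowData(x)$reference`.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @export
setClass("CqExperiment", contains = "SummarizedExperiment")

setValidity("CqExperiment", function(object) {
    msg <- character()
    if (!"cq" %in% names(assays(object)))
        msg <- c(msg, "assay 'cq' is required")
    else {
        cq <- assay(object, "cq")
        if (!is.numeric(cq))
            msg <- c(msg, "Cq values must be numeric")
        else if (any(is.infinite(cq)) || any(cq <= 0, na.rm = TRUE))
            msg <- c(msg, "Cq values must be finite and > 0 (or NA if missing)")
    }
    if (!"group" %in% names(colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    if (!"reference" %in% names(rowData(object)))
        msg <- c(msg, "rowData must contain a logical 'reference' column")
    else if (!any(rowData(object)$reference))
        msg <- c(msg, "at least one reference assay is required")
    if (length(msg)) msg else TRUE
})

#' Construct a CqExperiment
#'
#' @param cq numeric matrix of Cq values, assays in rows, samples in columns.
#' @param group factor or character vector of group labels, one per sample.
#' @param reference_assays character vector naming the housekeeping assays
#'   (must match rownames of `cq`).
#' @return A [CqExperiment-class] object.
#' @examples
#' cq <- matrix(c(20, 21, 19, 24), nrow = 4,
#'              dimnames = list(c("Ref1", "Ref2", "Ref3", "GeneA"), "s1"))
#' ce <- CqExperiment(cq, group = "Sham", reference_assays = paste0("Ref", 1:3))
#' @export
CqExperiment <- function(cq, group, reference_assays) {
    cq <- as.matrix(cq)
    if (is.null(rownames(cq)))
        stop("Cq matrix must have assay rownames")
    if (length(group) != ncol(cq))
        stop("'group' must have one label per sample (column)")
    missing_ref <- setdiff(reference_assays, rownames(cq))
    if (length(missing_ref))
        stop("reference assays not found in Cq matrix: ",
             paste(missing_ref, collapse = ", "))
    se <- SummarizedExperiment(
        assays = list(cq = cq),
        colData = DataFrame(group = factor(group),
                            row.names = colnames(cq)),
        rowData = DataFrame(reference = rownames(cq) %in% reference_assays,
                            row.names = rownames(cq)))
    new("CqExperiment", se)
}

#' Container for small-RNA count matrices
#'
#' Non-negative integer counts, features in rows and samples in columns, with
#' the experimental group of each sample in `colData(x)$group`. Extends
#' \linkS4class{SummarizedExperiment} with the assay named `"counts"`.
#'
#' @export
setClass("MirnaCountExperiment", contains = "SummarizedExperiment")

setValidity("MirnaCountExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% names(assays(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        k <- assay(object, "counts")
        if (any(is.na(k)) || any(k < 0) || any(k != round(k)))
            msg <- c(msg, "counts must be non-negative integers")
    }
    if (!"group" %in% names(colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    if (length(msg)) msg else TRUE
})

#' Construct a MirnaCountExperiment
#'
#' @param counts integer matrix, features x samples.
#' @param group group label per sample.
#' @return A [MirnaCountExperiment-class] object.
#' @export
MirnaCountExperiment <- function(counts, group) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (length(group) != ncol(counts))
        stop("'group' must have one label per sample (column)")
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        colData = DataFrame(group = factor(group),
                            row.names = colnames(counts)))
    new("MirnaCountExperiment", se)
}

#' Relative-quantity (fold-change) table from the delta-delta-Cq method
#'
#' Holds the per-sample relative quantity of each target assay, expressed so
#' that the calibrator-group mean delta-delta-Cq is zero (hence the geometric
#' mean of calibrator-group quantities is 1).
#'
#' @slot quantity numeric matrix, targets x samples, all values > 0.
#' @slot group factor of sample group labels.
#' @slot calibrator the calibrator group label.
#' @export
setClass("FoldChangeTable",
    representation(quantity = "matrix", group = "factor",
                   calibrator = "character"))

setValidity("FoldChangeTable", function(object) {
    msg <- character()
    if (any(object@quantity <= 0, na.rm = TRUE))
        msg <- c(msg, "relative quantities must be > 0")
    if (length(object@group) != ncol(object@quantity))
        msg <- c(msg, "one group label per sample is required")
    if (!object@calibrator %in% levels(object@group))
        msg <- c(msg, "calibrator group not present among sample groups")
    if (length(msg)) msg else TRUE
})

#' Score-thresholded interaction network
#'
#' An undirected, score-weighted graph over selected features after edge
#' thresholding and removal of isolated nodes, together with the list of
#' nodes dropped because no retained edge touches them.
#'
#' @slot graph an [igraph::igraph] object (edge attribute `score`, optional
#'   vertex attribute `panel`).
#' @slot dropped character vector of nodes removed as isolated.
#' @slot minScore the score threshold applied.
#' @export
setClass("InteractionGraph",
    representation(graph = "ANY", dropped = "character",
                   minScore = "numeric"))

## ---- generics ----

#' Group labels of the samples in a container
#' @param x a CqExperiment, MirnaCountExperiment or FoldChangeTable.
#' @return factor of group labels, one per sample.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "SummarizedExperiment",
          function(x) colData(x)$group)

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "FoldChangeTable", function(x) x@group)

#' Names of the housekeeping (reference) assays
#' @param x a CqExperiment.
#' @return character vector of reference assay names.
#' @export
setGeneric("referenceAssays", function(x) standardGeneric("referenceAssays"))

#' @rdname referenceAssays
#' @export
setMethod("referenceAssays", "CqExperiment",
          function(x) rownames(x)[rowData(x)$reference])

#' Relative-quantity matrix of a FoldChangeTable
#' @param x a FoldChangeTable.
#' @return numeric matrix, targets x samples.
#' @export
setGeneric("quantityMatrix", function(x) standardGeneric("quantityMatrix"))

#' @rdname quantityMatrix
#' @export
setMethod("quantityMatrix", "FoldChangeTable", function(x) x@quantity)

#' Calibrator group of a FoldChangeTable
#' @param x a FoldChangeTable.
#' @export
setGeneric("calibratorGroup", function(x) standardGeneric("calibratorGroup"))

#' @rdname calibratorGroup
#' @export
setMethod("calibratorGroup", "FoldChangeTable", function(x) x@calibrator)

#' Underlying igraph of an InteractionGraph
#' @param x an InteractionGraph.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "InteractionGraph", function(x) x@graph)

#' Nodes dropped as isolated during graph assembly
#' @param x an InteractionGraph.
#' @export
setGeneric("droppedNodes", function(x) standardGeneric("droppedNodes"))

#' @rdname droppedNodes
#' @export
setMethod("droppedNodes", "InteractionGraph", function(x) x@dropped)

setMethod("show", "FoldChangeTable", function(object) {
    cat("FoldChangeTable:", nrow(object@quantity), "targets x",
        ncol(object@quantity), "samples\n")
    cat("  groups:", paste(levels(object@group), collapse = ", "),
        "| calibrator:", object@calibrator, "\n")
})

setMethod("show", "InteractionGraph", function(object) {
    g <- object@graph
    cat("InteractionGraph: ", igraph::vcount(g), " nodes, ",
        igraph::ecount(g), " edges (score >= ", object@minScore, ")\n",
        sep = "")
    if (length(object@dropped))
        cat("  isolated nodes omitted:", length(object@dropped), "\n")
})
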