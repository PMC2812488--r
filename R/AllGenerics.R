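#' @include AllClasses.R
NULL

#' Basic tree accessors
#'
#' @param x a [PhyloTree-class] object.
#' @return \code{nNodes}: total node count. \code{nLeaves}: leaf count.
#'   \code{isLeaf}: logical vector indexed by node id. \code{leafNodes}:
#'   leaf node ids in depth-first (display) order. \code{leafLabels}: their
#'   labels, in the same order. \code{nodeLabels}: all node labels indexed by
#'   node id. \code{branchLengths}: per-node length of the edge to the parent
#'   (NA at the root unless a stem length was given). \code{hasBranchLengths}:
#'   TRUE iff every edge except (optionally) the root stem carries a length.
#'   \code{rootNode}: the root's node id.
#' @name tree-accessors
#' @aliases nNodes nLeaves isLeaf leafNodes leafLabels nodeLabels
#'   branchLengths hasBranchLengths rootNode
NULL

#' @rdname tree-accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname tree-accessors
#' @export
setGeneric("nLeaves", function(x) standardGeneric("nLeaves"))

#' @rdname tree-accessors
#' @export
setGeneric("isLeaf", function(x) standardGeneric("isLeaf"))

#' @rdname tree-accessors
#' @export
setGeneric("leafNodes", function(x) standardGeneric("leafNodes"))

#' @rdname tree-accessors
#' @export
setGeneric("leafLabels", function(x) standardGeneric("leafLabels"))

#' @rdname tree-accessors
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname tree-accessors
#' @export
setGeneric("branchLengths", function(x) standardGeneric("branchLengths"))

#' @rdname tree-accessors
#' @export
setGeneric("hasBranchLengths", function(x) standardGeneric("hasBranchLengths"))

#' @rdname tree-accessors
#' @export
setGeneric("rootNode", function(x) standardGeneric("rootNode"))

#' @rdname tree-accessors
#' @export
setMethod("nNodes", "PhyloTree", function(x) length(x@parent))

#' @rdname tree-accessors
#' @export
setMethod("nLeaves", "PhyloTree", function(x) sum(lengths(x@children) == 0L))

#' @rdname tree-accessors
#' @export
setMethod("isLeaf", "PhyloTree", function(x) lengths(x@children) == 0L)

#' @rdname tree-accessors
#' @export
setMethod("leafNodes", "PhyloTree", function(x) {
    ord <- dfsNodes(x)
    ord[lengths(x@children)[ord] == 0L]
})

#' @rdname tree-accessors
#' @export
setMethod("leafLabels", "PhyloTree", function(x) x@label[leafNodes(x)])

#' @rdname tree-accessors
#' @export
setMethod("nodeLabels", "PhyloTree", function(x) x@label)

#' @rdname tree-accessors
#' @export
setMethod("branchLengths", "PhyloTree", function(x) x@edgeLength)

#' @rdname tree-accessors
#' @export
setMethod("hasBranchLengths", "PhyloTree", function(x) {
    !anyNA(x@edgeLength[-x@rootNode])
})

#' @rdname tree-accessors
#' @export
setMethod("rootNode", "PhyloTree", function(x) x@rootNode)

#' Children / parent of a node
#'
#' @param x a [PhyloTree-class] object.
#' @param node a node id.
#' @return \code{childrenOf}: integer vector of child ids in input order
#'   (empty for a leaf); \code{parentOf}: the parent id (NA for the root).
#' @export
childrenOf <- function(x, node) {
    stopifnot(is(x, "PhyloTree"))
    x@children[[checkNodeId(x, node)]]
}

#' @rdname childrenOf
#' @export
parentOf <- function(x, node) {
    stopifnot(is(x, "PhyloTree"))
    x@parent[checkNodeId(x, node)]
}

setMethod("show", "PhyloTree", function(object) {
    nl <- nLeaves(object)
    cat(sprintf("PhyloTree: %d nodes, %d leaves, branch lengths: %s\n",
        nNodes(object), nl,
        if (hasBranchLengths(object)) "yes" else "no"))
    lab <- leafLabels(object)
    lab <- lab[!is.na(lab)]
    if (length(lab)) {
        shown <- utils::head(lab, 6L)
        cat("  leaves: ", paste(shown, collapse = ", "),
            if (length(lab) > 6L) ", ..." else "", "\n", sep = "")
    }
})

setMethod("show", "LayoutResult", function(object) {
    cat(sprintf("LayoutResult: %d nodes on a %.1f x %.1f px canvas (%d leaf rows)\n",
        length(object@x), object@canvasWidth, object@canvasHeight,
        length(object@leafOrder)))
})

setMethod("show", "SvgDocument", function(object) {
    cat(sprintf("SvgDocument: %.1f x %.1f px, %d bytes%s\n",
        object@width, object@height, nchar(object@content, type = "bytes"),
        if (length(object@assetRefs))
            paste0(", assets: ", paste(object@assetRefs, collapse = ", "))
        else ""))
})

setMethod("show", "LayoutOptions", function(object) {
    cat(sprintf("LayoutOptions: %s, rowHeight=%g, xScale=%g, alignedLabels=%s\n",
        object@mode, object@rowHeight, object@xScale, object@alignedLabels))
})

setMethod("show", "RenderOptions", function(object) {
    cat(sprintf("RenderOptions: %s branches, precision=%d, assets %s\n",
        object@branchShape, object@coordPrecision,
        if (object@embedAssets) "embedded" else "external"))
})
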