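#' @import methods
NULL

#' Rooted phylogenetic tree
#'
#' \code{PhyloTree} is the package's central data structure: a rooted tree
#' stored in flat parallel vectors indexed by node id. Node ids are the
#' integers \code{1..n} in the order nodes were encountered in the input
#' (preorder for trees built by the package itself), so child order in the
#' source text is preserved exactly and is never re-sorted.
#'
#' @slot parent integer vector; \code{parent[i]} is the node id of node
#'   \code{i}'s parent, \code{NA} for the root.
#' @slot children list of integer vectors; \code{children[[i]]} holds the ids
#'   of node \code{i}'s children in input order (empty for leaves).
#' @slot label character vector of node labels; \code{NA} where absent.
#'   Leaf labels name taxa; internal labels are clade names or support values.
#' @slot edgeLength numeric vector; \code{edgeLength[i]} is the length of the
#'   edge from node \code{i} to its parent, in the units of the input tree
#'   (e.g. substitutions per site); \code{NA} where absent. A value on the
#'   root is a stem length: it is preserved on round trips but ignored by
#'   layout and dropped by subtree extraction.
#' @slot rootNode integer scalar, the id of the root node.
#' @slot treeAnnotations named list of character scalars carrying
#'   tree-level metadata (e.g. \code{rooting = "U"} from a NEXUS
#'   \code{[&U]} comment).
#'
#' @seealso [readNewick()], [writeNewick()], [generateTree()]
#' @export
setClass("PhyloTree", slots = c(
    parent = "integer",
    children = "list",
    label = "character",
    edgeLength = "numeric",
    rootNode = "integer",
    treeAnnotations = "list"
))

setValidity("PhyloTree", function(object) {
    n <- length(object@parent)
    if (n < 1L) return("tree must contain at least one node")
    if (length(object@label) != n || length(object@edgeLength) != n ||
        length(object@children) != n)
        return("slot lengths differ")
    if (length(object@rootNode) != 1L || is.na(object@rootNode) ||
        object@rootNode < 1L || object@rootNode > n)
        return("rootNode must be a single valid node id")
    roots <- which(is.na(object@parent))
    if (!identical(roots, object@rootNode))
        return("exactly one node (the root) may lack a parent")
    kids <- unlist(object@children, use.names = FALSE)
    if (length(kids) != n - 1L || anyDuplicated(kids) ||
        any(kids == object@rootNode))
        return("tree must be acyclic and singly rooted (every non-root node has exactly one parent)")
    for (i in seq_len(n)) {
        ch <- object@children[[i]]
        if (length(ch) && !all(object@parent[ch] == i))
            return(sprintf("children of node %d disagree with parent pointers", i))
    }
    bl <- object@edgeLength
    if (any(!is.na(bl) & bl < 0))
        return("branch lengths must be non-negative")
    TRUE
})

# Internal constructor. children derived from parent: node ids are assigned in
# encounter order, so which(parent == i) is the input child order.
newPhyloTree <- function(parent, label, edgeLength, treeAnnotations = list(),
                         warnDuplicates = TRUE) {
    n <- length(parent)
    children <- vector("list", n)
    for (i in seq_len(n)) children[[i]] <- integer(0)
    for (i in seq_len(n)) {
        p <- parent[i]
        if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
    tr <- new("PhyloTree",
        parent = as.integer(parent),
        children = children,
        label = as.character(label),
        edgeLength = as.numeric(edgeLength),
        rootNode = which(is.na(parent)),
        treeAnnotations = treeAnnotations)
    if (warnDuplicates) {
        lv <- tr@label[isLeaf(tr)]
        lv <- lv[!is.na(lv)]
        dup <- unique(lv[duplicated(lv)])
        if (length(dup))
            warning("duplicate leaf labels: ", paste(dup, collapse = ", "),
                    call. = FALSE)
    }
    tr
}

#' Layout options for tree drawing
#'
#' Geometry knobs shared by all rendering styles. All distances are in SVG
#' user units (pixels at 1:1 zoom).
#'
#' @slot mode \code{"phylogram"} (x proportional to branch length) or
#'   \code{"cladogram"} (x proportional to topological depth).
#' @slot rowHeight vertical space per leaf row, px.
#' @slot xScale px per branch-length unit (phylogram) or per depth step
#'   (cladogram).
#' @slot margins numeric of length 4: top, right, bottom, left, px.
#' @slot alignedLabels if \code{TRUE} all leaf labels share one column at the
#'   right of the deepest leaf, connected by leader lines.
#' @slot fontSize label font size, px; also drives the label-extent estimate
#'   used to size the canvas.
#' @slot labelGap horizontal gap between a leaf tip (or the aligned column)
#'   and its label, px.
#' @export
setClass("LayoutOptions", slots = c(
    mode = "character",
    rowHeight = "numeric",
    xScale = "numeric",
    margins = "numeric",
    alignedLabels = "logical",
    fontSize = "numeric",
    labelGap = "numeric"
))

setValidity("LayoutOptions", function(object) {
    if (!object@mode %in% c("phylogram", "cladogram"))
        return("mode must be 'phylogram' or 'cladogram'")
    if (length(object@margins) != 4L || any(object@margins < 0))
        return("margins must be four non-negative numbers (top, right, bottom, left)")
    for (s in c("rowHeight", "xScale", "fontSize"))
        if (slot(object, s) <= 0) return(paste(s, "must be > 0"))
    if (object@labelGap < 0) return("labelGap must be >= 0")
    TRUE
})

#' Node coordinates for a laid-out tree
#'
#' Coordinates follow the SVG convention: origin top-left, x rightward,
#' y downward. Values are exact reals; rounding happens only at SVG
#' serialization.
#'
#' @slot x,y numeric vectors of per-node coordinates, indexed by node id, px.
#' @slot labelX numeric vector of label anchor x per leaf (NA for internal
#'   nodes), px.
#' @slot canvasWidth,canvasHeight canvas dimensions, px.
#' @slot leafOrder integer vector of leaf node ids in depth-first
#'   left-to-right order (the top-to-bottom display order).
#' @slot aligned whether labels sit in one shared column (drives leader
#'   lines at render time).
#' @slot fontSize the font size the layout was computed for, px.
#' @export
setClass("LayoutResult", slots = c(
    x = "numeric",
    y = "numeric",
    labelX = "numeric",
    canvasWidth = "numeric",
    canvasHeight = "numeric",
    leafOrder = "integer",
    aligned = "logical",
    fontSize = "numeric"
))

#' Rendering options for SVG output
#'
#' @slot branchShape \code{"rectangular"} (elbow: vertical then horizontal
#'   segment) or \code{"triangular"} (straight parent-to-child segment). Both
#'   are drawn from the same layout coordinates.
#' @slot cssHref,scriptHref paths of the external stylesheet / script
#'   referenced from the document; ignored when \code{embedAssets} is TRUE.
#' @slot embedAssets inline the default stylesheet and script instead of
#'   referencing external files.
#' @slot cladeUrlTemplate optional URL template containing the placeholder
#'   \code{\{leaves\}} exactly once; when set, every internal-node hotspot is
#'   wrapped in a link whose URL substitutes the comma-joined, percent-encoded
#'   labels of the node's descendant leaves.
#' @slot hotspotRadius radius of internal-node hotspot circles, px.
#' @slot coordPrecision decimal places kept when serializing coordinates.
#' @slot showBranchLengths draw branch-length text at edge midpoints.
#' @export
setClass("RenderOptions", slots = c(
    branchShape = "character",
    cssHref = "character",
    scriptHref = "character",
    embedAssets = "logical",
    cladeUrlTemplate = "character",
    hotspotRadius = "numeric",
    coordPrecision = "integer",
    showBranchLengths = "logical"
))

setValidity("RenderOptions", function(object) {
    if (!object@branchShape %in% c("rectangular", "triangular"))
        return("branchShape must be 'rectangular' or 'triangular'")
    if (object@hotspotRadius <= 0) return("hotspotRadius must be > 0")
    if (object@coordPrecision < 0L) return("coordPrecision must be >= 0")
    tpl <- object@cladeUrlTemplate
    if (!is.na(tpl)) {
        nPlaceholder <- lengths(regmatches(tpl, gregexpr("{leaves}", tpl, fixed = TRUE)))
        if (nPlaceholder != 1L)
            return("cladeUrlTemplate must contain the placeholder {leaves} exactly once")
    }
    TRUE
})

#' An emitted SVG document
#'
#' @slot content the complete SVG text (well-formed XML, UTF-8).
#' @slot width,height canvas dimensions, px.
#' @slot assetRefs character vector of externally referenced asset paths
#'   (stylesheet, script); empty when assets are embedded.
#' @export
setClass("SvgDocument", slots = c(
    content = "character",
    width = "numeric",
    height = "numeric",
    assetRefs = "character"
))
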