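#' @include AllClasses.R AllGenerics.R utils-internal.R
NULL

#' Create layout options
#'
#' Defaults draw a phylogram at 14 px per leaf row with 500 px per
#' branch-length unit and a 10 px margin on every side.
#'
#' @param mode \code{"phylogram"} or \code{"cladogram"}.
#' @param rowHeight px per leaf row.
#' @param xScale px per branch-length unit (phylogram) or per depth step
#'   (cladogram).
#' @param margins numeric(4): top, right, bottom, left, px.
#' @param alignedLabels put all leaf labels in one shared column.
#' @param fontSize label font size, px.
#' @param labelGap gap between leaf tip (or label column) and label, px.
#' @return a [LayoutOptions-class].
#' @export
layoutOptions <- function(mode = c("phylogram", "cladogram"),
                          rowHeight = 14, xScale = 500,
                          margins = c(10, 10, 10, 10),
                          alignedLabels = FALSE, fontSize = 10,
                          labelGap = 5) {
    mode <- match.arg(mode)
    new("LayoutOptions", mode = mode, rowHeight = as.numeric(rowHeight),
        xScale = as.numeric(xScale), margins = as.numeric(margins),
        alignedLabels = isTRUE(alignedLabels), fontSize = as.numeric(fontSize),
        labelGap = as.numeric(labelGap))
}

# Estimated horizontal extent of a label: 0.6 em per character. A fixed
# factor keeps canvas sizing deterministic across platforms (no font
# metrics dependency).
labelExtent <- function(label, fontSize) {
    ifelse(is.na(label), 0, nchar(label) * fontSize * 0.6)
}

#' Compute 2-D coordinates for a tree
#'
#' Maps every node to a point in SVG user units (origin top-left, x
#' rightward, y downward). Leaf \code{i} (0-based, depth-first input order)
#' sits at \code{y = marginTop + (i + 0.5) * rowHeight}; an internal node's
#' y is the arithmetic mean of its children's. In phylogram mode
#' \code{x = marginLeft + xScale * (root-to-node branch-length sum)} (root
#' stem excluded); in cladogram mode the path sum is replaced by the
#' topological depth. Label anchors sit \code{labelGap} px right of each
#' leaf, or in a single shared column right of the deepest leaf when
#' \code{alignedLabels} is set.
#'
#' @param tree a [PhyloTree-class].
#' @param options a [LayoutOptions-class]; phylogram mode requires the tree
#'   to have branch lengths.
#' @return a [LayoutResult-class].
#' @export
treeLayout <- function(tree, options = layoutOptions()) {
    stopifnot(is(tree, "PhyloTree"), is(options, "LayoutOptions"))
    if (options@mode == "phylogram" && !hasBranchLengths(tree))
        stop("tree has no branch lengths; phylogram layout needs them ",
             "(use cladogram mode)", call. = FALSE)

    n <- nNodes(tree)
    ord <- dfsNodes(tree)
    leaf <- isLeaf(tree)
    leaves <- ord[leaf[ord]]
    nl <- length(leaves)
    mTop <- options@margins[1L]; mRight <- options@margins[2L]
    mBottom <- options@margins[3L]; mLeft <- options@margins[4L]

    y <- numeric(n)
    y[leaves] <- mTop + (seq_len(nl) - 0.5) * options@rowHeight
    for (node in rev(ord)) {
        ch <- tree@children[[node]]
        if (length(ch)) y[node] <- mean(y[ch])
    }

    x <- numeric(n)
    root <- tree@rootNode
    for (node in ord) {
        p <- tree@parent[node]
        if (is.na(p)) {
            x[node] <- mLeft
        } else if (options@mode == "phylogram") {
            x[node] <- x[p] + options@xScale * tree@edgeLength[node]
        } else {
            x[node] <- x[p] + options@xScale
        }
    }

    labelX <- rep(NA_real_, n)
    if (options@alignedLabels) {
        labelX[leaves] <- max(x[leaves]) + options@labelGap
    } else {
        labelX[leaves] <- x[leaves] + options@labelGap
    }

    extent <- max(labelExtent(tree@label[leaves], options@fontSize), 0)
    canvasHeight <- mTop + mBottom + nl * options@rowHeight
    canvasWidth <- max(labelX[leaves], x) + extent + mRight

    new("LayoutResult", x = x, y = y, labelX = labelX,
        canvasWidth = canvasWidth, canvasHeight = canvasHeight,
        leafOrder = leaves, aligned = options@alignedLabels,
        fontSize = options@fontSize)
}
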