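#' @include newick.R
NULL

# Resolve leaf labels to node ids; errors list every unresolved name and
# reject names matching more than one leaf. Matching is exact and
# case-sensitive.
resolveLeaves <- function(tree, labels) {
    leaves <- which(isLeaf(tree))
    leafLab <- tree@label[leaves]
    hits <- lapply(labels, function(nm) leaves[!is.na(leafLab) & leafLab == nm])
    nHit <- lengths(hits)
    if (any(nHit == 0L))
        stop("unknown leaf name(s): ",
             paste(labels[nHit == 0L], collapse = ", "), call. = FALSE)
    if (any(nHit > 1L))
        stop("leaf name(s) matching more than one leaf: ",
             paste(labels[nHit > 1L], collapse = ", "), call. = FALSE)
    vapply(hits, `[[`, integer(1), 1L)
}

#' Most recent common ancestor of a set of leaves
#'
#' @param tree a [PhyloTree-class].
#' @param labels character vector of leaf labels (length >= 1).
#' @return the node id of the MRCA.
#' @export
mrcaNode <- function(tree, labels) {
    ids <- resolveLeaves(tree, unique(labels))
    chain <- ancestorChain(tree, ids[1L])
    for (id in ids[-1L]) {
        node <- id
        while (!(node %in% chain)) node <- tree@parent[node]
        # trim the chain so it starts at the common ancestor found so far
        chain <- chain[which(chain == node):length(chain)]
    }
    chain[1L]
}

#' Restrict a tree to a set of leaves
#'
#' Returns the induced display tree for the selected leaves, using the
#' relationships of the parent topology only: the result is rooted at the
#' most recent common ancestor of the selection, nodes left with a single
#' child are suppressed with their edge lengths summed, child order follows
#' the parent tree, and no branch length is re-estimated. Pairwise patristic
#' distances among the selected leaves are exactly those of the parent tree.
#' The result's root carries no stem length.
#'
#' @param tree a [PhyloTree-class].
#' @param labels character vector of at least two distinct leaf labels.
#' @return a [PhyloTree-class] containing exactly the selected leaves.
#' @examples
#' tr <- readNewick(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' writeNewick(extractByLeaves(tr, c("A", "C")))
#' @export
extractByLeaves <- function(tree, labels) {
    stopifnot(is(tree, "PhyloTree"))
    labels <- as.character(labels)
    if (anyDuplicated(labels))
        labels <- unique(labels)
    if (length(labels) < 2L)
        stop("select at least two distinct leaf names", call. = FALSE)
    ids <- resolveLeaves(tree, labels)

    # count selected leaves below each node (postorder)
    n <- nNodes(tree)
    count <- integer(n)
    count[ids] <- 1L
    for (node in rev(dfsNodes(tree))) {
        ch <- tree@children[[node]]
        if (length(ch)) count[node] <- sum(count[ch])
    }
    k <- length(ids)
    # MRCA: deepest node covering all selected leaves
    mrca <- tree@rootNode
    repeat {
        ch <- tree@children[[mrca]]
        full <- ch[count[ch] == k]
        if (length(full) == 1L) mrca <- full else break
    }

    # mark-delete-splice, accumulating lengths across suppressed unary nodes
    rec <- function(node) {
        ch <- tree@children[[node]]
        kept <- ch[count[ch] > 0L]
        if (!length(kept))       # a selected leaf
            return(list(label = tree@label[node],
                        len = tree@edgeLength[node], children = list()))
        if (length(kept) == 1L) {
            sub <- rec(kept)
            sub$len <- sub$len + tree@edgeLength[node]
            return(sub)          # suppressed node: label discarded, lengths summed
        }
        list(label = tree@label[node], len = tree@edgeLength[node],
             children = lapply(kept, rec))
    }
    spec <- rec(mrca)
    spec$len <- NA_real_         # the display tree stands alone: stem dropped

    flattenTreeSpec(spec)
}

# Convert the nested list produced by extraction into a PhyloTree with
# preorder ids (preserving child order).
flattenTreeSpec <- function(spec) {
    parent <- integer(0)
    label <- character(0)
    elen <- numeric(0)
    walk <- function(s, par) {
        id <- length(parent) + 1L
        parent[id] <<- par
        label[id] <<- s$label
        elen[id] <<- s$len
        for (ch in s$children) walk(ch, id)
    }
    walk(spec, NA_integer_)
    newPhyloTree(parent, label, elen, warnDuplicates = FALSE)
}

#' Extract the clade below an internal node
#'
#' Returns a standalone copy of the subtree rooted at \code{node}: all
#' labels, branch lengths and child order preserved, the stem length of the
#' clade root dropped. This is the operation behind per-node "show this
#' clade" links in rendered trees.
#'
#' @param tree a [PhyloTree-class].
#' @param node the id of a non-leaf node.
#' @return a [PhyloTree-class].
#' @export
extractBelowNode <- function(tree, node) {
    stopifnot(is(tree, "PhyloTree"))
    node <- checkNodeId(tree, node)
    if (length(tree@children[[node]]) == 0L)
        stop("node ", node, " is a leaf; select an internal node", call. = FALSE)

    # preorder walk from the clade root, remapping ids to 1..m
    ids <- integer(0)
    stack <- node
    while (length(stack)) {
        nd <- stack[length(stack)]
        stack <- stack[-length(stack)]
        ids <- c(ids, nd)
        ch <- tree@children[[nd]]
        if (length(ch)) stack <- c(stack, rev(ch))
    }
    remap <- integer(nNodes(tree))
    remap[ids] <- seq_along(ids)
    parent <- ifelse(ids == node, NA_integer_, remap[tree@parent[ids]])
    elen <- tree@edgeLength[ids]
    elen[1L] <- NA_real_         # stem dropped
    newPhyloTree(as.integer(parent), tree@label[ids], elen,
                 warnDuplicates = FALSE)
}

#' Patristic distance between two leaves
#'
#' Sum of branch lengths along the unique path connecting two distinct
#' leaves.
#'
#' @param tree a [PhyloTree-class] with branch lengths.
#' @param a,b leaf labels (distinct).
#' @return non-negative numeric.
#' @export
patristicDistance <- function(tree, a, b) {
    stopifnot(is(tree, "PhyloTree"))
    if (identical(a, b))
        stop("patristic distance requires two distinct leaves", call. = FALSE)
    ids <- resolveLeaves(tree, c(a, b))
    chainA <- ancestorChain(tree, ids[1L])
    node <- ids[2L]
    pathB <- integer(0)
    while (!(node %in% chainA)) {
        pathB <- c(pathB, node)
        node <- tree@parent[node]
    }
    lca <- node
    pathA <- chainA[seq_len(which(chainA == lca) - 1L)]
    lens <- tree@edgeLength[c(pathA, pathB)]
    if (anyNA(lens))
        stop("missing branch length on the path between ", a, " and ", b,
             call. = FALSE)
    sum(lens)
}
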