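#' @include AllClasses.R
NULL

# Depth-first preorder over node ids; children visited in input order.
# Iterative (explicit stack) so arbitrarily deep trees never hit the
# recursion limit.
dfsNodes <- function(tree) {
    n <- length(tree@parent)
    out <- integer(n)
    stack <- integer(n + 1L)
    stack[1L] <- tree@rootNode
    sp <- 1L
    k <- 0L
    children <- tree@children
    while (sp > 0L) {
        node <- stack[sp]
        sp <- sp - 1L
        k <- k + 1L
        out[k] <- node
        ch <- children[[node]]
        nc <- length(ch)
        if (nc) {
            stack[(sp + 1L):(sp + nc)] <- ch[nc:1L]
            sp <- sp + nc
        }
    }
    out
}

checkNodeId <- function(tree, node) {
    node <- as.integer(node)
    if (length(node) != 1L || is.na(node) || node < 1L ||
        node > length(tree@parent))
        stop("unknown node id: ", node, call. = FALSE)
    node
}

# Chain of ancestors of `node`, starting at the node itself, ending at the root.
ancestorChain <- function(tree, node) {
    chain <- integer(0)
    while (!is.na(node)) {
        chain <- c(chain, node)
        node <- tree@parent[node]
    }
    chain
}

# Fixed-point decimal with trailing zeros trimmed; vectorised.
# digits = 0 gives integers. Used for branch lengths and SVG coordinates.
fmtNum <- function(x, digits) {
    s <- sprintf("%.*f", digits, x)
    if (digits > 0L) {
        s <- sub("(\\.[0-9]*?)0+$", "\\1", s)
        s <- sub("\\.$", "", s)
    }
    # normalise "-0" arising from tiny negatives introduced by rounding
    s[s == "-0"] <- "0"
    s
}

xmlEscape <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
}

xmlEscapeAttr <- function(x) {
    x <- xmlEscape(x)
    gsub("\"", "&quot;", x, fixed = TRUE)
}

# Structural equality of two trees: same topology, labels, child order;
# branch lengths equal within `tolerance` (NA must match NA).
#' Compare two trees structurally
#'
#' Two trees are considered identical when they have the same topology with
#' the same child order, the same labels, and branch lengths equal within
#' \code{tolerance} (missing lengths must be missing in both).
#'
#' @param a,b [PhyloTree-class] objects.
#' @param tolerance numeric tolerance for branch-length comparison.
#' @return TRUE or FALSE.
#' @export
treeIdentical <- function(a, b, tolerance = 1e-6) {
    if (nNodes(a) != nNodes(b)) return(FALSE)
    oa <- dfsNodes(a)
    ob <- dfsNodes(b)
    if (!identical(lengths(a@children)[oa], lengths(b@children)[ob]))
        return(FALSE)
    la <- a@label[oa]; lb <- b@label[ob]
    if (!identical(is.na(la), is.na(lb)) ||
        !identical(la[!is.na(la)], lb[!is.na(lb)]))
        return(FALSE)
    ea <- a@edgeLength[oa]; eb <- b@edgeLength[ob]
    if (!identical(is.na(ea), is.na(eb))) return(FALSE)
    ok <- is.na(ea) | abs(ea - eb) <= tolerance
    all(ok)
}
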