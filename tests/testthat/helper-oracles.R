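# Independent oracles used across the suite. The established ape parser and
# pruner stand on the other side of every dual-route check: trees are passed
# between the two implementations only as Newick text.

apeFromTree <- function(tree) {
    ape::read.tree(text = writeNewick(tree, precision = 10))
}

# Pairwise patristic distances according to ape, as a labelled matrix.
apeDistances <- function(tree) {
    ape::cophenetic.phylo(apeFromTree(tree))
}

# Pairwise patristic distances according to this package, for a label set.
pkgDistances <- function(tree, labels) {
    k <- length(labels)
    m <- matrix(0, k, k, dimnames = list(labels, labels))
    if (k < 2) return(m)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
        d <- patristicDistance(tree, labels[i], labels[j])
        m[i, j] <- d
        m[j, i] <- d
    }
    m
}

# Root-to-leaf branch-length path sums in my model (used where the oracle is
# the path-sum definition itself).
rootToLeafSums <- function(tree) {
    vapply(leafNodes(tree), function(lf) {
        s <- 0
        nd <- lf
        while (!is.na(parentOf(tree, nd))) {
            s <- s + branchLengths(tree)[nd]
            nd <- parentOf(tree, nd)
        }
        s
    }, numeric(1))
}

# Parse a rendered SvgDocument for structural queries; errors if not
# well-formed XML.
svgDoc <- function(doc) {
    x <- xml2::read_xml(doc@content)
    xml2::xml_ns_strip(x)
    x
}

countElems <- function(x, xpath) length(xml2::xml_find_all(x, xpath))
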