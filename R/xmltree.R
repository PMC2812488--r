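#' @include newick.R
NULL

#' Export a tree as XML
#'
#' Writes the tree in a minimal nested-clade XML dialect of this package's
#' own definition: a \code{<tree>} root containing one \code{<clade>}
#' element per node, nested by topology, with optional \code{label} and
#' \code{branch_length} attributes. Child order is element order.
#' [readTreeXML()] is the exact inverse.
#'
#' @param tree a [PhyloTree-class].
#' @param file optional path to write to.
#' @return the XML string, invisibly when \code{file} is given.
#' @export
writeTreeXML <- function(tree, file = NULL) {
    stopifnot(is(tree, "PhyloTree"))
    doc <- xml2::xml_new_root("tree")
    addClade <- function(parentElt, node) {
        elt <- xml2::xml_add_child(parentElt, "clade")
        if (!is.na(tree@label[node]))
            xml2::xml_set_attr(elt, "label", tree@label[node])
        if (!is.na(tree@edgeLength[node]))
            xml2::xml_set_attr(elt, "branch_length",
                               sprintf("%.12g", tree@edgeLength[node]))
        for (ch in tree@children[[node]]) addClade(elt, ch)
    }
    addClade(doc, tree@rootNode)
    out <- as.character(doc)
    if (!is.null(file)) {
        writeLines(out, file, useBytes = TRUE)
        return(invisible(out))
    }
    out
}

#' Read a tree from the package's XML export
#'
#' Inverse of [writeTreeXML()].
#'
#' @param file path to an XML file.
#' @param text alternatively, the XML content as a string.
#' @return a [PhyloTree-class].
#' @export
readTreeXML <- function(file = NULL, text = NULL) {
    doc <- if (is.null(text)) xml2::read_xml(file) else xml2::read_xml(text)
    root <- xml2::xml_find_first(doc, "./clade")
    if (is.na(xml2::xml_name(root)))
        stop("XML tree: no <clade> element under the root", call. = FALSE)

    parent <- integer(0)
    label <- character(0)
    elen <- numeric(0)
    walk <- function(elt, par) {
        id <- length(parent) + 1L
        parent[id] <<- par
        lab <- xml2::xml_attr(elt, "label")
        label[id] <<- if (is.na(lab)) NA_character_ else lab
        bl <- xml2::xml_attr(elt, "branch_length")
        elen[id] <<- if (is.na(bl)) NA_real_ else as.numeric(bl)
        for (ch in xml2::xml_find_all(elt, "./clade")) walk(ch, id)
    }
    walk(root, NA_integer_)
    newPhyloTree(parent, label, elen)
}
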