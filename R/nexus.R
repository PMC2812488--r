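#' @include newick.R
NULL

# Split text into ';'-terminated statements, honouring single-quoted tokens
# (a ';' inside quotes does not terminate a statement).
splitNexusStatements <- function(text) {
    chars <- strsplit(text, "", fixed = TRUE)[[1L]]
    out <- character(0)
    buf <- character(0)
    inQuote <- FALSE
    for (ch in chars) {
        if (ch == "'") inQuote <- !inQuote
        if (ch == ";" && !inQuote) {
            out <- c(out, paste(buf, collapse = ""))
            buf <- character(0)
        } else {
            buf <- c(buf, ch)
        }
    }
    if (length(buf) && any(grepl("[^[:space:]]", buf)))
        out <- c(out, paste(buf, collapse = ""))
    out
}

# Tokenise a TRANSLATE body "tok1 lab1, tok2 lab2, ..." into a named
# character vector token -> label. Labels may be single-quoted.
parseTranslate <- function(body) {
    entries <- strsplit(body, ",", fixed = TRUE)[[1L]]
    toks <- character(0)
    labs <- character(0)
    for (e in entries) {
        e <- trimws(e)
        if (e == "") next
        m <- regmatches(e, regexec("^(\\S+)\\s+(.*)$", e))[[1L]]
        if (length(m) != 3L)
            stop("malformed TRANSLATE entry: '", e, "'", call. = FALSE)
        lab <- trimws(m[3L])
        if (startsWith(lab, "'")) {
            lab <- sub("^'", "", sub("'$", "", lab))
            lab <- gsub("''", "'", lab, fixed = TRUE)
        }
        toks <- c(toks, m[2L])
        labs <- c(labs, lab)
    }
    stats::setNames(labs, toks)
}

#' Read trees from a NEXUS TREES block
#'
#' Extracts the first \code{BEGIN TREES ... END} block (keywords are
#' case-insensitive), applies the optional \code{TRANSLATE} token-to-label
#' table to leaf tokens, and parses each \code{TREE} statement as Newick.
#' A leading \code{[&R]} / \code{[&U]} rooting comment is recorded in the
#' tree's annotations (key \code{rooting}) and otherwise ignored. Other
#' NEXUS blocks are skipped.
#'
#' @param file path to a NEXUS file.
#' @param text alternatively, the NEXUS content as a string.
#' @return a named list of [PhyloTree-class] objects, one per \code{TREE}
#'   statement, in file order; names are the tree names.
#' @export
readNexusTrees <- function(file = NULL, text = NULL) {
    if (is.null(text)) {
        if (is.null(file)) stop("provide either 'file' or 'text'")
        text <- paste(readLines(file, warn = FALSE), collapse = "\n")
    }
    if (!grepl("^\\s*#NEXUS", text, ignore.case = TRUE))
        stop("not a NEXUS file: missing #NEXUS header", call. = FALSE)

    m <- regexpr("begin\\s+trees\\s*;", text, ignore.case = TRUE)
    if (m == -1L) stop("no TREES block found", call. = FALSE)
    rest <- substr(text, m + attr(m, "match.length"), nchar(text))
    e <- regexpr("\\bend\\s*;", rest, ignore.case = TRUE)
    if (e == -1L) stop("TREES block not terminated by END;", call. = FALSE)
    block <- substr(rest, 1L, e - 1L)

    translate <- NULL
    trees <- list()
    for (stmt in splitNexusStatements(block)) {
        s <- trimws(stmt)
        if (s == "") next
        if (grepl("^translate\\b", s, ignore.case = TRUE)) {
            body <- sub("^translate\\s*", "", s, ignore.case = TRUE)
            translate <- parseTranslate(body)
        } else if (grepl("^u?tree\\b", s, ignore.case = TRUE)) {
            m2 <- regmatches(s, regexec("^u?tree\\s+(\\S+)\\s*=\\s*(.*)$", s,
                                        ignore.case = TRUE))[[1L]]
            if (length(m2) != 3L)
                stop("malformed TREE statement: '",
                     substr(s, 1L, 40L), "'", call. = FALSE)
            name <- sub("^\\*", "", m2[2L])   # default-tree marker
            rhs <- m2[3L]
            ann <- list()
            rm <- regmatches(rhs, regexec("^\\s*\\[&([RU])\\]\\s*", rhs))[[1L]]
            if (length(rm) == 2L) {
                ann$rooting <- rm[2L]
                rhs <- sub("^\\s*\\[&[RU]\\]\\s*", "", rhs)
            }
            tr <- parseNewickString(paste0(rhs, ";"))
            tr@treeAnnotations <- ann
            if (!is.null(translate)) {
                lv <- which(isLeaf(tr))
                toks <- tr@label[lv]
                known <- is.na(toks) | toks %in% names(translate)
                if (!all(known))
                    stop("TRANSLATE token not defined: ",
                         paste(unique(toks[!known]), collapse = ", "),
                         call. = FALSE)
                hit <- !is.na(toks)
                tr@label[lv[hit]] <- unname(translate[toks[hit]])
            }
            trees[[name]] <- tr
        }
        # other statements in the block are ignored
    }
    if (!length(trees)) stop("TREES block contains no TREE statement", call. = FALSE)
    trees
}
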