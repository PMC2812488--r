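#' @include AllClasses.R AllGenerics.R utils-internal.R
NULL

# Character-level recursive-descent state machine over a single Newick
# expression. Offsets in error messages are 0-based, counted in characters
# of the input string.
parseNewickString <- function(text) {
    if (length(text) != 1L || is.na(text))
        stop("newick parse error: input must be a single string", call. = FALSE)
    chars <- strsplit(text, "", fixed = TRUE)[[1L]]
    nch <- length(chars)

    cap <- 64L
    parent <- rep(NA_integer_, cap)
    label <- rep(NA_character_, cap)
    elen <- rep(NA_real_, cap)
    closed <- logical(cap)     # TRUE once the node's ')' has been seen
    nNode <- 0L

    ensure <- function(k) {
        if (k > cap) {
            cap2 <- max(2L * cap, k)
            length(parent) <<- cap2
            length(label) <<- cap2
            length(elen) <<- cap2
            length(closed) <<- cap2
            cap <<- cap2
        }
    }
    addNode <- function(par) {
        nNode <<- nNode + 1L
        ensure(nNode)
        parent[nNode] <<- par
        label[nNode] <<- NA_character_
        elen[nNode] <<- NA_real_
        closed[nNode] <<- FALSE
        nNode
    }
    perr <- function(msg, pos) {   # pos is a 1-based index into chars
        stop(sprintf("newick parse error at offset %d: %s", pos - 1L, msg),
             call. = FALSE)
    }

    ws <- c(" ", "\t", "\n", "\r")
    delims <- c("(", ")", "[", "]", ":", ";", ",", "'", ws)

    root <- addNode(NA_integer_)
    cur <- root
    done <- FALSE
    sawAny <- FALSE
    i <- 1L
    while (i <= nch) {
        ch <- chars[i]
        if (ch %in% ws) { i <- i + 1L; next }
        if (ch == "[") {
            j <- i + 1L
            while (j <= nch && chars[j] != "]") j <- j + 1L
            if (j > nch) perr("unterminated [comment]", i)
            i <- j + 1L
            next
        }
        if (done)
            perr("unexpected text after ';'", i)
        sawAny <- TRUE
        if (ch == "(") {
            if (length(which(parent[seq_len(nNode)] == cur)) > 0L ||
                closed[cur] || !is.na(label[cur]) || !is.na(elen[cur]))
                perr("unexpected '('", i)
            cur <- addNode(cur)
            i <- i + 1L
        } else if (ch == ",") {
            p <- parent[cur]
            if (is.na(p)) perr("unexpected ',' outside parentheses", i)
            cur <- addNode(p)
            i <- i + 1L
        } else if (ch == ")") {
            p <- parent[cur]
            if (is.na(p)) perr("unbalanced ')'", i)
            cur <- p
            closed[cur] <- TRUE
            i <- i + 1L
        } else if (ch == ":") {
            if (!is.na(elen[cur])) perr("duplicate branch length", i)
            j <- i + 1L
            while (j <= nch && chars[j] %in% ws) j <- j + 1L
            k <- j
            while (k <= nch &&
                   (chars[k] %in% c(as.character(0:9), ".", "-", "+", "e", "E")))
                k <- k + 1L
            if (k == j) perr("missing branch length after ':'", j)
            val <- suppressWarnings(as.numeric(paste(chars[j:(k - 1L)], collapse = "")))
            if (is.na(val)) perr("invalid branch length", j)
            if (val < 0) perr("negative branch length", j)
            elen[cur] <- val
            i <- k
        } else if (ch == ";") {
            if (!is.na(parent[cur]))
                perr("unbalanced parentheses: ';' before all groups closed", i)
            done <- TRUE
            i <- i + 1L
        } else if (ch == "'") {
            if (!is.na(label[cur]) || !is.na(elen[cur]))
                perr("unexpected quoted label", i)
            j <- i + 1L
            buf <- character(0)
            repeat {
                if (j > nch) perr("unterminated quote", i)
                if (chars[j] == "'") {
                    if (j + 1L <= nch && chars[j + 1L] == "'") {
                        buf <- c(buf, "'")   # doubled quote -> literal quote
                        j <- j + 2L
                    } else {
                        j <- j + 1L
                        break
                    }
                } else {
                    buf <- c(buf, chars[j])
                    j <- j + 1L
                }
            }
            label[cur] <- paste(buf, collapse = "")
            i <- j
        } else {
            if (!is.na(label[cur]) || !is.na(elen[cur]))
                perr(sprintf("unexpected label '%s'", ch), i)
            j <- i
            while (j <= nch && !(chars[j] %in% delims)) j <- j + 1L
            # underscores are kept literal (no underscore-to-space conversion)
            label[cur] <- paste(chars[i:(j - 1L)], collapse = "")
            i <- j
        }
    }
    if (!sawAny)
        stop("newick parse error: empty input", call. = FALSE)
    if (!done)
        perr("missing terminal ';'", nch + 1L)

    newPhyloTree(parent[seq_len(nNode)], label[seq_len(nNode)],
                 elen[seq_len(nNode)])
}

#' Read a tree in Newick format
#'
#' Parses a single parenthesis-notation tree. Labels may be bare or
#' single-quoted (a doubled quote inside a quoted label denotes a literal
#' quote); square-bracket comments are dropped; underscores in bare labels
#' are kept literal. Child order, labels and branch lengths are preserved
#' exactly as written. Duplicate leaf labels are accepted with a warning;
#' operations that look leaves up by name refuse them later.
#'
#' @param file path to a file whose first non-empty content is a Newick
#'   expression terminated by \code{";"}.
#' @param text alternatively, the Newick string itself.
#' @return a [PhyloTree-class].
#' @examples
#' tr <- readNewick(text = "((A:1,B:1):1,C:2);")
#' nLeaves(tr)
#' @export
readNewick <- function(file = NULL, text = NULL) {
    if (is.null(text)) {
        if (is.null(file)) stop("provide either 'file' or 'text'")
        text <- paste(readLines(file, warn = FALSE), collapse = "\n")
    }
    parseNewickString(text)
}

# Serialise one branch length at `digits` decimal places, trailing zeros
# trimmed.
fmtBranchLength <- function(x, digits) fmtNum(x, digits)

quoteNewickLabel <- function(label) {
    needs <- label == "" | grepl("[][ \t()':;,]", label)
    esc <- gsub("'", "''", label[needs], fixed = TRUE)
    label[needs] <- paste0("'", esc, "'")
    label
}

#' Write a tree in Newick format
#'
#' The output re-parses to a tree structurally identical to the input: same
#' topology, labels and child order, branch lengths equal within
#' \code{10^-precision}. Labels containing spaces, parentheses, brackets,
#' commas, colons, quotes or semicolons are single-quoted with internal
#' quotes doubled.
#'
#' @param tree a [PhyloTree-class].
#' @param precision decimal places for branch lengths (>= 1).
#' @param file optional path; when given the string is also written there.
#' @return the Newick string, invisibly when \code{file} is given.
#' @export
writeNewick <- function(tree, precision = 6L, file = NULL) {
    stopifnot(is(tree, "PhyloTree"))
    precision <- as.integer(precision)
    if (is.na(precision) || precision < 1L)
        stop("precision must be an integer >= 1")
    n <- nNodes(tree)
    lab <- tree@label
    lab[is.na(lab)] <- ""
    lab[!is.na(tree@label)] <- quoteNewickLabel(tree@label[!is.na(tree@label)])
    lenStr <- character(n)
    hasLen <- !is.na(tree@edgeLength)
    lenStr[hasLen] <- paste0(":", fmtBranchLength(tree@edgeLength[hasLen], precision))

    # children before parents: reverse preorder
    ord <- rev(dfsNodes(tree))
    part <- character(n)
    for (node in ord) {
        ch <- tree@children[[node]]
        inner <- if (length(ch))
            paste0("(", paste(part[ch], collapse = ","), ")")
        else ""
        part[node] <- paste0(inner, lab[node], lenStr[node])
    }
    out <- paste0(part[tree@rootNode], ";")
    if (!is.null(file)) {
        writeLines(out, file, useBytes = TRUE)
        return(invisible(out))
    }
    out
}
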