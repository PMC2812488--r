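#' @include layout.R assets.R
NULL

#' Create rendering options
#'
#' Defaults give rectangular branches, 1-decimal coordinates (sub-pixel at
#' default scales while keeping files small), and externally referenced
#' default assets.
#'
#' @param branchShape \code{"rectangular"} or \code{"triangular"}.
#' @param cssHref,scriptHref external asset paths written into the document.
#' @param embedAssets inline the default assets instead.
#' @param cladeUrlTemplate optional URL template with one \code{\{leaves\}}
#'   placeholder for per-clade subtree links.
#' @param hotspotRadius internal-node hotspot radius, px.
#' @param coordPrecision decimal places for serialized coordinates.
#' @param showBranchLengths draw branch-length text at edge midpoints.
#' @return a [RenderOptions-class].
#' @export
renderOptions <- function(branchShape = c("rectangular", "triangular"),
                          cssHref = "svgphylo.css",
                          scriptHref = "svgphylo.js",
                          embedAssets = FALSE,
                          cladeUrlTemplate = NA_character_,
                          hotspotRadius = 3,
                          coordPrecision = 1L,
                          showBranchLengths = FALSE) {
    branchShape <- match.arg(branchShape)
    new("RenderOptions", branchShape = branchShape,
        cssHref = as.character(cssHref), scriptHref = as.character(scriptHref),
        embedAssets = isTRUE(embedAssets),
        cladeUrlTemplate = as.character(cladeUrlTemplate),
        hotspotRadius = as.numeric(hotspotRadius),
        coordPrecision = as.integer(coordPrecision),
        showBranchLengths = isTRUE(showBranchLengths))
}

#' Read leaf annotations from TSV
#'
#' Expects the header \code{label<TAB>href<TAB>tooltip<TAB>class} followed
#' by one row per leaf; empty cells mean "no value". A label appearing more
#' than once keeps the last row, with a warning.
#'
#' @param file path to a TSV file.
#' @param text alternatively, the TSV content as a string.
#' @return a data.frame with columns \code{label}, \code{href},
#'   \code{tooltip}, \code{class} (NA for empty cells), one row per leaf
#'   label.
#' @export
loadAnnotationsTSV <- function(file = NULL, text = NULL) {
    lines <- if (is.null(text)) readLines(file, warn = FALSE)
             else strsplit(text, "\n", fixed = TRUE)[[1L]]
    if (!length(lines))
        stop("annotation TSV: empty input", call. = FALSE)
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (!identical(header, c("label", "href", "tooltip", "class")))
        stop("annotation TSV: malformed header (expected ",
             "'label\\thref\\ttooltip\\tclass')", call. = FALSE)
    out <- data.frame(label = character(0), href = character(0),
                      tooltip = character(0), class = character(0),
                      stringsAsFactors = FALSE)
    for (i in seq_along(lines)[-1L]) {
        ln <- lines[i]
        if (ln == "") next
        cells <- strsplit(paste0(ln, "\t<END>"), "\t", fixed = TRUE)[[1L]]
        cells <- cells[-length(cells)]   # keep trailing empty fields
        if (length(cells) != 4L)
            stop("annotation TSV: line ", i, " has ", length(cells),
                 " columns (expected 4)", call. = FALSE)
        cells[cells == ""] <- NA_character_
        if (is.na(cells[1L]))
            stop("annotation TSV: line ", i, " has an empty label", call. = FALSE)
        if (!is.na(cells[4L]) &&
            !grepl("^-?[A-Za-z_][A-Za-z0-9_-]*$", cells[4L]))
            stop("annotation TSV: line ", i, ": '", cells[4L],
                 "' is not a valid CSS class identifier", call. = FALSE)
        if (cells[1L] %in% out$label) {
            warning("annotation TSV: duplicate label '", cells[1L],
                    "'; later row overrides", call. = FALSE)
            out <- out[out$label != cells[1L], , drop = FALSE]
        }
        out <- rbind(out, data.frame(label = cells[1L], href = cells[2L],
                                     tooltip = cells[3L], class = cells[4L],
                                     stringsAsFactors = FALSE))
    }
    rownames(out) <- NULL
    out
}

# Percent-encode a leaf label for use inside a clade URL.
encodeLeafName <- function(x) {
    vapply(x, function(s) utils::URLencode(s, reserved = TRUE), character(1),
           USE.NAMES = FALSE)
}

#' Render a laid-out tree to SVG
#'
#' Serializes the tree to a compact, well-formed, deterministic SVG 1.1
#' document: one branch element per edge (an elbow \code{<path>} or a
#' straight \code{<line>}), one \code{<text>} per labelled leaf (wrapped in
#' a link when the leaf has an \code{href} annotation, carrying a native
#' \code{<title>} tooltip plus \code{data-label}/\code{data-tooltip}
#' attributes when it has a tooltip), a dashed leader line per leaf in
#' aligned-labels mode, and one hotspot circle per internal node (wrapped
#' in a subtree link when \code{cladeUrlTemplate} is set, substituting the
#' comma-joined percent-encoded descendant leaf labels for
#' \code{\{leaves\}}). All elements carry the documented CSS classes
#' (\code{branch}, \code{leaf-label}, \code{leaf-tick}, \code{leader},
#' \code{node-hotspot}, \code{clade-link}, \code{branch-length}). Output
#' bytes are a deterministic function of the inputs.
#'
#' @param tree a [PhyloTree-class].
#' @param layout the [LayoutResult-class] computed for this tree.
#' @param annotations optional data.frame as returned by
#'   [loadAnnotationsTSV()]; labels that match no leaf produce a warning.
#' @param options a [RenderOptions-class].
#' @return an [SvgDocument-class].
#' @export
renderSVG <- function(tree, layout, annotations = NULL,
                      options = renderOptions()) {
    stopifnot(is(tree, "PhyloTree"), is(layout, "LayoutResult"),
              is(options, "RenderOptions"))
    n <- nNodes(tree)
    if (length(layout@x) != n || length(layout@y) != n)
        stop("layout does not match tree: no coordinate for node ",
             max(length(layout@x), n), call. = FALSE)
    missingCoord <- which(!is.finite(layout@x) | !is.finite(layout@y))
    if (length(missingCoord))
        stop("layout does not match tree: no coordinate for node ",
             missingCoord[1L], call. = FALSE)

    prec <- options@coordPrecision
    fx <- function(v) fmtNum(v, prec)
    x <- layout@x; y <- layout@y
    leaf <- isLeaf(tree)
    ord <- dfsNodes(tree)
    internal <- ord[!leaf[ord]]
    leaves <- layout@leafOrder

    ann <- annotations
    if (!is.null(ann) && nrow(ann)) {
        leafLab <- tree@label[leaves]
        unresolved <- setdiff(ann$label, leafLab[!is.na(leafLab)])
        if (length(unresolved))
            warning("annotation label(s) matching no leaf: ",
                    paste(unresolved, collapse = ", "), call. = FALSE)
    }
    annFor <- function(lab) {
        if (is.null(ann) || is.na(lab)) return(NULL)
        i <- which(ann$label == lab)
        if (!length(i)) NULL else ann[i[length(i)], ]
    }

    # --- branches: one element per edge (every non-root node) -------------
    edgeNodes <- ord[ord != tree@rootNode]
    p <- tree@parent[edgeNodes]
    branches <- if (options@branchShape == "rectangular") {
        sprintf('<path class="branch" d="M%s,%s V%s H%s"/>',
                fx(x[p]), fx(y[p]), fx(y[edgeNodes]), fx(x[edgeNodes]))
    } else {
        sprintf('<line class="branch" x1="%s" y1="%s" x2="%s" y2="%s"/>',
                fx(x[p]), fx(y[p]), fx(x[edgeNodes]), fx(y[edgeNodes]))
    }
    if (options@showBranchLengths) {
        hasLen <- !is.na(tree@edgeLength[edgeNodes])
        en <- edgeNodes[hasLen]
        ep <- tree@parent[en]
        lenTxt <- fmtNum(tree@edgeLength[en], max(prec, 3L))
        branches <- c(branches,
            sprintf('<text class="branch-length" x="%s" y="%s">%s</text>',
                    fx((x[ep] + x[en]) / 2), fx(y[en] - 2), xmlEscape(lenTxt)))
    }

    # --- leaves: leaders, ticks, labels, links, tooltips ------------------
    leafParts <- character(0)
    baseShift <- 0.35 * layout@fontSize   # crude vertical centring of text
    for (nd in leaves) {
        lab <- tree@label[nd]
        lx <- layout@labelX[nd]
        ly <- y[nd]
        if (isTRUE(layout@aligned) && !is.na(lab) && lx - 2 > x[nd]) {
            leafParts <- c(leafParts,
                sprintf('<line class="leader" x1="%s" y1="%s" x2="%s" y2="%s"/>',
                        fx(x[nd]), fx(ly), fx(lx - 2), fx(ly)))
        }
        if (is.na(lab)) {
            # unlabelled leaf: a tick, never placeholder text
            leafParts <- c(leafParts,
                sprintf('<line class="leaf-tick" x1="%s" y1="%s" x2="%s" y2="%s"/>',
                        fx(x[nd]), fx(ly - 2), fx(x[nd]), fx(ly + 2)))
            next
        }
        a <- annFor(lab)
        cls <- "leaf-label"
        if (!is.null(a) && !is.na(a$class)) cls <- paste(cls, a$class)
        extra <- ""
        inner <- xmlEscape(lab)
        if (!is.null(a) && !is.na(a$tooltip)) {
            cls <- paste(cls, "has-info")
            extra <- sprintf(' data-label="%s" data-tooltip="%s"',
                             xmlEscapeAttr(lab), xmlEscapeAttr(a$tooltip))
            inner <- paste0(sprintf("<title>%s</title>", xmlEscape(a$tooltip)),
                            inner)
        }
        el <- sprintf('<text class="%s" x="%s" y="%s"%s>%s</text>',
                      cls, fx(lx), fx(ly + baseShift), extra, inner)
        if (!is.null(a) && !is.na(a$href))
            el <- sprintf('<a xlink:href="%s">%s</a>',
                          xmlEscapeAttr(a$href), el)
        leafParts <- c(leafParts, el)
    }

    # --- hotspots: one circle per internal node ---------------------------
    hotspots <- character(0)
    if (length(internal)) {
        tpl <- options@cladeUrlTemplate
        if (!is.na(tpl)) {
            # encoded leaf-label list per internal node, in display order
            enc <- character(n)
            lv <- tree@label
            for (node in rev(ord)) {
                if (leaf[node]) {
                    enc[node] <- if (is.na(lv[node])) NA_character_
                                 else encodeLeafName(lv[node])
                } else {
                    parts <- enc[tree@children[[node]]]
                    enc[node] <- paste(parts[!is.na(parts)], collapse = ",")
                }
            }
        }
        for (nd in internal) {
            circ <- sprintf('<circle class="node-hotspot" cx="%s" cy="%s" r="%s"/>',
                            fx(x[nd]), fx(y[nd]), fmtNum(options@hotspotRadius, prec))
            if (!is.na(options@cladeUrlTemplate)) {
                url <- sub("{leaves}", enc[nd], options@cladeUrlTemplate,
                           fixed = TRUE)
                circ <- sprintf('<a class="clade-link" xlink:href="%s">%s</a>',
                                xmlEscapeAttr(url), circ)
            }
            hotspots <- c(hotspots, circ)
        }
    }

    # --- document ---------------------------------------------------------
    w <- layout@canvasWidth
    h <- layout@canvasHeight
    assets <- character(0)
    head <- '<?xml version="1.0" encoding="UTF-8"?>'
    if (!options@embedAssets && !is.na(options@cssHref)) {
        head <- c(head, sprintf(
            '<?xml-stylesheet type="text/css" href="%s"?>',
            xmlEscapeAttr(options@cssHref)))
        assets <- c(assets, options@cssHref)
    }
    svgOpen <- sprintf(paste0(
        '<svg xmlns="http://www.w3.org/2000/svg" ',
        'xmlns:xlink="http://www.w3.org/1999/xlink" ',
        'width="%s" height="%s" viewBox="0 0 %s %s">'),
        fx(w), fx(h), fx(w), fx(h))
    body <- c(head, svgOpen)
    if (options@embedAssets) {
        d <- defaultAssets()
        body <- c(body,
            sprintf("<style type=\"text/css\">%s</style>", d$css),
            sprintf("<script type=\"application/ecmascript\">//<![CDATA[\n%s//]]></script>",
                    d$js))
    } else if (!is.na(options@scriptHref)) {
        body <- c(body, sprintf(
            '<script type="application/ecmascript" xlink:href="%s"/>',
            xmlEscapeAttr(options@scriptHref)))
        assets <- c(assets, options@scriptHref)
    }
    body <- c(body,
        '<g class="branches">', branches, "</g>",
        '<g class="leaves">', leafParts, "</g>",
        '<g class="hotspots">', hotspots, "</g>",
        "</svg>")
    content <- paste(body, collapse = "\n")
    new("SvgDocument", content = content, width = w, height = h,
        assetRefs = assets)
}

#' Write an SVG document to a file
#'
#' @param doc an [SvgDocument-class].
#' @param file output path.
#' @param writeAssets also write the default stylesheet/script next to
#'   \code{file} under the names the document references.
#' @return \code{file}, invisibly.
#' @export
writeSVG <- function(doc, file, writeAssets = FALSE) {
    stopifnot(is(doc, "SvgDocument"))
    con <- file(file, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(enc2utf8(doc@content)), con)
    writeBin(charToRaw("\n"), con)
    if (writeAssets && length(doc@assetRefs)) {
        d <- defaultAssets()
        dir <- dirname(file)
        for (ref in doc@assetRefs) {
            txt <- if (grepl("\\.css$", ref)) d$css else d$js
            writeLines(txt, file.path(dir, basename(ref)), useBytes = TRUE)
        }
    }
    invisible(file)
}
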