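# SVG serialization: structure, interactivity hooks, determinism.

renderTree <- function(text, lopt = layoutOptions(), ...) {
    tr <- readNewick(text = text)
    lay <- treeLayout(tr, lopt)
    renderSVG(tr, lay, ...)
}

test_that("a small tree renders to well-formed SVG with the expected census", {
    doc <- renderTree("(A:1,B:2);")
    x <- svgDoc(doc)
    expect_equal(xml2::xml_name(x), "svg")
    expect_equal(countElems(x, "//text[contains(@class,'leaf-label')]"), 2L)
    expect_equal(countElems(x, "//path[@class='branch']"), 2L)
    expect_equal(countElems(x, "//circle[@class='node-hotspot']"), 1L)
    # root carries width, height and a matching viewBox
    expect_false(is.na(xml2::xml_attr(x, "width")))
    vb <- strsplit(xml2::xml_attr(x, "viewBox"), " ")[[1]]
    expect_equal(vb[3], xml2::xml_attr(x, "width"))
    expect_equal(vb[4], xml2::xml_attr(x, "height"))
})

test_that("element census scales with tree structure across the corpus", {
    for (nm in c("basic", "polytomy", "quotedLabels", "zeroLength")) {
        tr <- fixtureCorpus()[[nm]]
        doc <- renderSVG(tr, treeLayout(tr, layoutOptions(mode = "cladogram")))
        x <- svgDoc(doc)
        nInternal <- sum(!isLeaf(tr))
        nLabelled <- sum(!is.na(leafLabels(tr)))
        expect_equal(countElems(x, "//path[@class='branch']"),
                     nNodes(tr) - 1L, label = nm)
        expect_equal(countElems(x, "//text[contains(@class,'leaf-label')]"),
                     nLabelled, label = nm)
        expect_equal(countElems(x, "//circle[@class='node-hotspot']"),
                     nInternal, label = nm)
    }
})

test_that("leaf hyperlinks and tooltips come from annotations", {
    ann <- loadAnnotationsTSV(text = paste(
        "label\thref\ttooltip\tclass",
        "A\thttp://example.org/A\tEukaryota; Metazoa\tfancy",
        "B\t\t\t", sep = "\n"))
    doc <- renderTree("(A:1,B:2);", annotations = ann)
    x <- svgDoc(doc)
    linked <- xml2::xml_find_first(
        x, "//a[@*[local-name()='href']='http://example.org/A']/text")
    expect_false(is.na(xml2::xml_name(linked)))
    expect_match(xml2::xml_attr(linked, "class"), "fancy")
    expect_match(xml2::xml_attr(linked, "class"), "has-info")
    expect_equal(xml2::xml_attr(linked, "data-tooltip"), "Eukaryota; Metazoa")
    expect_equal(xml2::xml_text(
        xml2::xml_find_first(linked, "./title")), "Eukaryota; Metazoa")
    # B has no href: its text element is not inside a link
    expect_equal(countElems(x, "//a"), 1L)
})

test_that("annotations that match no leaf warn instead of failing", {
    ann <- loadAnnotationsTSV(text = "label\thref\ttooltip\tclass\nZZZ\thttp://x\t\t")
    expect_warning(renderTree("(A:1,B:2);", annotations = ann), "ZZZ")
})

test_that("clade hotspots link to the URL template with percent-encoded leaves", {
    tr <- readNewick(text = "((A,B),C);")
    lay <- treeLayout(tr, layoutOptions(mode = "cladogram"))
    doc <- renderSVG(tr, lay,
                     options = renderOptions(cladeUrlTemplate = "tree?sel={leaves}"))
    x <- svgDoc(doc)
    urls <- xml2::xml_attr(xml2::xml_find_all(x, "//a[@class='clade-link']"), "href")
    expect_setequal(urls, c("tree?sel=A,B", "tree?sel=A,B,C"))
    # names needing escaping are percent-encoded
    tr2 <- readNewick(text = "('Homo sapiens':1,'x/y':1);")
    doc2 <- renderSVG(tr2, treeLayout(tr2),
                      options = renderOptions(cladeUrlTemplate = "q={leaves}"))
    x2 <- svgDoc(doc2)
    url2 <- xml2::xml_attr(xml2::xml_find_first(x2, "//a[@class='clade-link']"), "href")
    expect_equal(url2, "q=Homo%20sapiens,x%2Fy")
})

test_that("rendering is deterministic down to the byte", {
    tr <- generateTree(40, seed = 5, labelStyle = "genome_like")
    lay <- treeLayout(tr)
    ann <- loadAnnotationsTSV(text = paste0("label\thref\ttooltip\tclass\n",
        leafLabels(tr)[1], "\thttp://x\ttip\t"))
    o <- renderOptions(cladeUrlTemplate = "u={leaves}")
    d1 <- renderSVG(tr, lay, annotations = ann, options = o)
    d2 <- renderSVG(tr, lay, annotations = ann, options = o)
    expect_identical(d1@content, d2@content)
})

test_that("triangular mode draws straight lines from the same coordinates", {
    tr <- readNewick(text = "(A:1,B:2);")
    lay <- treeLayout(tr)
    doc <- renderSVG(tr, lay, options = renderOptions(branchShape = "triangular"))
    x <- svgDoc(doc)
    expect_equal(countElems(x, "//line[@class='branch']"), 2L)
    expect_equal(countElems(x, "//path[@class='branch']"), 0L)
})

test_that("aligned-labels mode adds leader lines", {
    tr <- readNewick(text = "((A:1,B:2):1,C:5);")
    lay <- treeLayout(tr, layoutOptions(alignedLabels = TRUE))
    x <- svgDoc(renderSVG(tr, lay))
    expect_gt(countElems(x, "//line[@class='leader']"), 0L)
    lay2 <- treeLayout(tr, layoutOptions(alignedLabels = FALSE))
    x2 <- svgDoc(renderSVG(tr, lay2))
    expect_equal(countElems(x2, "//line[@class='leader']"), 0L)
})

test_that("external assets are referenced; embedding inlines them instead", {
    tr <- readNewick(text = "(A:1,B:2);")
    lay <- treeLayout(tr)
    ext <- renderSVG(tr, lay, options = renderOptions(cssHref = "my.css",
                                                      scriptHref = "my.js"))
    expect_equal(ext@assetRefs, c("my.css", "my.js"))
    expect_match(ext@content, 'xml-stylesheet type="text/css" href="my.css"',
                 fixed = TRUE)
    expect_match(ext@content, 'script type="application/ecmascript" xlink:href="my.js"',
                 fixed = TRUE)
    emb <- renderSVG(tr, lay, options = renderOptions(embedAssets = TRUE))
    expect_length(emb@assetRefs, 0L)
    expect_match(emb@content, "<style", fixed = TRUE)
    expect_match(emb@content, "data-tooltip", fixed = TRUE)  # inlined script
    expect_s3_class(xml2::read_xml(emb@content), "xml_document")
})

test_that("branch-length labels are opt-in", {
    tr <- readNewick(text = "(A:1.25,B:2.5);")
    lay <- treeLayout(tr)
    off <- svgDoc(renderSVG(tr, lay))
    expect_equal(countElems(off, "//text[@class='branch-length']"), 0L)
    on <- svgDoc(renderSVG(tr, lay,
                           options = renderOptions(showBranchLengths = TRUE)))
    expect_equal(countElems(on, "//text[@class='branch-length']"), 2L)
})

test_that("unlabelled leaves get a tick, never fabricated text", {
    tr <- readNewick(text = "(A:1,:2);")   # second leaf unlabelled
    x <- svgDoc(renderSVG(tr, treeLayout(tr)))
    expect_equal(countElems(x, "//text[contains(@class,'leaf-label')]"), 1L)
    expect_equal(countElems(x, "//line[@class='leaf-tick']"), 1L)
})

test_that("layout/tree mismatch is reported with the offending node", {
    tr <- readNewick(text = "((A:1,B:1):1,C:2);")
    other <- readNewick(text = "(A:1,B:2);")
    expect_error(renderSVG(tr, treeLayout(other)), "node")
})

test_that("annotation TSV parsing honours the header contract", {
    m <- loadAnnotationsTSV(text = "label\thref\ttooltip\tclass\nA\thttp://x\tEukaryota; Metazoa\t")
    expect_equal(nrow(m), 1L)
    expect_equal(m$tooltip, "Eukaryota; Metazoa")
    expect_true(is.na(m$class))
    expect_equal(nrow(loadAnnotationsTSV(text = "label\thref\ttooltip\tclass")), 0L)
    expect_error(loadAnnotationsTSV(text = "label\thref\ttooltip\tclass\nA\tx"),
                 "line 2")
    expect_error(loadAnnotationsTSV(text = "name\turl\n"), "header")
    expect_warning(
        loadAnnotationsTSV(text = "label\thref\ttooltip\tclass\nA\tu1\t\t\nA\tu2\t\t"),
        "duplicate")
})

test_that("default assets style the documented classes and use only documented data attributes", {
    a1 <- defaultAssets()
    for (cls in c("branch", "leaf-label", "leaf-tick", "leader",
                  "node-hotspot", "clade-link", "branch-length"))
        expect_match(a1$css, paste0(".", cls), fixed = TRUE)
    expect_match(a1$js, "data-tooltip", fixed = TRUE)
    expect_match(a1$js, "data-label", fixed = TRUE)
    dataAttrs <- unique(unlist(regmatches(a1$js, gregexpr("data-[a-z-]+", a1$js))))
    expect_true(all(dataAttrs %in% c("data-label", "data-tooltip")))
    expect_identical(a1, defaultAssets())
})
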