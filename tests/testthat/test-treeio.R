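# Newick / NEXUS / XML reading and writing.

test_that("readNewick parses structure, labels and lengths exactly", {
    tr <- readNewick(text = "(A:1.0,B:2.0);")
    expect_s4_class(tr, "PhyloTree")
    expect_equal(nNodes(tr), 3L)
    kids <- childrenOf(tr, rootNode(tr))
    expect_equal(nodeLabels(tr)[kids], c("A", "B"))
    expect_equal(branchLengths(tr)[kids], c(1, 2))
    expect_true(hasBranchLengths(tr))

    tr2 <- readNewick(text = "((A:1,B:1):1,C:2);")
    expect_equal(patristicDistance(tr2, "A", "B"), 2)
    expect_equal(patristicDistance(tr2, "A", "C"), 4)

    poly <- readNewick(text = "(A,B,C);")
    expect_equal(length(childrenOf(poly, rootNode(poly))), 3L)
    expect_false(hasBranchLengths(poly))

    q <- readNewick(text = "('Homo sapiens':0.1,Pan:0.2);")
    expect_true("Homo sapiens" %in% leafLabels(q))
    # doubled quotes unescape to one quote
    q2 <- readNewick(text = "('it''s':1,B:1);")
    expect_true("it's" %in% leafLabels(q2))
})

test_that("child order follows the input text and is never re-sorted", {
    tr <- readNewick(text = "(Zebra:1,Aardvark:1,Mouse:1);")
    expect_equal(leafLabels(tr), c("Zebra", "Aardvark", "Mouse"))
})

test_that("square-bracket comments are dropped, underscores kept literal", {
    tr <- readNewick(text = "(A[comment]:1,B_b:2)[&meta];")
    expect_equal(sort(leafLabels(tr)), c("A", "B_b"))
    expect_equal(sum(!is.na(branchLengths(tr))), 2L)
})

test_that("parse errors name a 0-based character offset", {
    expect_error(readNewick(text = "((A,B);"), "offset")
    expect_error(readNewick(text = "(A,B)"), "offset.*;|;.*offset")
    expect_error(readNewick(text = "('A:1,B:2);"), "unterminated quote")
    expect_error(readNewick(text = "(A:-1,B:2);"), "negative branch length")
    expect_error(readNewick(text = "   "), "empty input")
    expect_error(readNewick(text = "(A,B);x"), "after ';'")
    # offset is 0-based: the bad '-' of "(A:-1..." sits at offset 3
    expect_error(readNewick(text = "(A:-1,B:2);"), "offset 3")
})

test_that("duplicate leaf labels parse with a warning", {
    expect_warning(readNewick(text = "(A:1,(A:1,B:1):1);"),
                   "duplicate leaf labels.*A")
})

test_that("writeNewick round-trips topology, labels, child order and lengths", {
    fixtures <- fixtureCorpus()
    for (nm in names(fixtures)) {
        tr <- fixtures[[nm]]
        back <- suppressWarnings(readNewick(text = writeNewick(tr, 6)))
        expect_true(treeIdentical(tr, back, tolerance = 1e-6), label = nm)
    }
    expect_equal(writeNewick(readNewick(text = "A;")), "A;")
    # labels needing quoting are single-quoted
    tr <- readNewick(text = "('sp. nov':1,B:2);")
    expect_match(writeNewick(tr), "'sp. nov'", fixed = TRUE)
})

test_that("parser agrees with the independent ape parser", {
    for (seed in 1:20) {
        tr <- generateTree(5 + seed, seed = seed)
        at <- apeFromTree(tr)
        expect_setequal(leafLabels(tr), at$tip.label)
        labs <- leafLabels(tr)[1:4]
        expect_equal(pkgDistances(tr, labs),
                     apeDistances(tr)[labs, labs], tolerance = 1e-8)
    }
})

test_that("a strictly bifurcating n-leaf tree has 2n-1 nodes", {
    for (n in c(2, 5, 33)) {
        tr <- generateTree(n, seed = n)
        expect_equal(nNodes(tr), 2L * n - 1L)
        expect_equal(nLeaves(tr), n)
    }
})

test_that("NEXUS TREES blocks parse with TRANSLATE substitution", {
    nx <- "#NEXUS\nbegin trees;\n  translate 1 A, 2 B;\n  tree t1 = (1:1,2:2);\nend;"
    trees <- readNexusTrees(text = nx)
    expect_named(trees, "t1")
    expect_true(treeIdentical(trees$t1, readNewick(text = "(A:1,B:2);")))

    two <- readNexusTrees(text = paste0(
        "#NEXUS\nBEGIN TREES;\nTREE a = (x:1,y:1);\nTREE b = ((x:1,y:1):1,z:1);\nEND;"))
    expect_equal(names(two), c("a", "b"))

    rooted <- readNexusTrees(text =
        "#NEXUS\nbegin trees;\ntree t = [&U] (A:1,B:2);\nend;")
    expect_true(treeIdentical(rooted$t, readNewick(text = "(A:1,B:2);")))
    expect_equal(rooted$t@treeAnnotations$rooting, "U")
})

test_that("NEXUS errors: missing block, undefined TRANSLATE token", {
    expect_error(readNexusTrees(text = "#NEXUS\nbegin data;\nend;"),
                 "no TREES block")
    expect_error(readNexusTrees(
        text = "#NEXUS\nbegin trees;\ntranslate 1 A;\ntree t = (1:1,2:2);\nend;"),
        "token.*2")
    expect_error(readNexusTrees(text = "(A,B);"), "#NEXUS")
})

test_that("XML export nests one clade element per node and round-trips", {
    single <- readNewick(text = "A;")
    x <- xml2::read_xml(writeTreeXML(single))
    clades <- xml2::xml_find_all(x, "//clade")
    expect_length(clades, 1L)
    expect_equal(xml2::xml_attr(clades[[1]], "label"), "A")

    tr <- readNewick(text = "(A:1,B:2);")
    x2 <- xml2::read_xml(writeTreeXML(tr))
    expect_length(xml2::xml_find_all(x2, "//clade"), 3L)

    for (tr in fixtureCorpus()[c("basic", "polytomy", "quotedLabels",
                                 "missingLengths", "zeroLength")]) {
        back <- readTreeXML(text = writeTreeXML(tr))
        expect_true(treeIdentical(tr, back, tolerance = 1e-9))
    }
})
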