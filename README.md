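# svgphylo

Scalable, interactive phylogenetic trees for the web, drawn as compact SVG.

## What it does and who it is for

Groups running genome databases and comparative-genomics servers need tree
figures that are not static images: trees with hundreds of taxa that can be
zoomed and panned in a browser without loss of quality, whose leaf labels
link to genome pages, whose nodes reveal extra information (say, a full NCBI
taxonomy lineage) on rollover, and whose clades link to views of just that
clade. `svgphylo` is an R toolkit for producing exactly that kind of figure:

- **Tree I/O** — Newick (quoted labels, comments, polytomies) and NEXUS
  `TREES` blocks with `TRANSLATE` tables; plus a simple nested-clade XML
  export.
- **Display subtrees without re-inference** — given a cached parent topology
  with `n` leaves and a selection `S` of leaf names, `extractByLeaves()`
  returns the induced restriction: the tree rooted at the most recent common
  ancestor MRCA(S), with unary nodes suppressed and their edge lengths
  summed, so that every patristic distance d(i, j) = Σ branch lengths on the
  i–j path, for i, j ∈ S, is *identical* to its value in the parent tree.
  Relationships always come from the full-data tree; nothing is re-estimated
  for the subset.
- **Layout** — phylogram (x ∝ cumulative branch length from the root) or
  cladogram (x ∝ topological depth); leaf *i* at
  y = marginTop + (i + ½)·rowHeight in depth-first input order; internal
  node y = mean of its children's y. Rectangular-elbow or triangular
  branches and an aligned-labels column are drawn from the same coordinates.
- **Compact interactive SVG** — one element per edge/leaf/internal node,
  coordinates rounded to a configurable precision, stable CSS classes
  (`branch`, `leaf-label`, `leaf-tick`, `leader`, `node-hotspot`,
  `clade-link`, `branch-length`), per-leaf hyperlinks and native tooltips,
  per-clade URL hotspots, and externally referenced (or inlined) stylesheet
  and script. Output is byte-deterministic.
- **Seeded simulation** — a Yule (pure-birth) generator, optionally
  ultrametric, so every feature is demonstrable and testable with no data
  download.

## Worked example

```r
library(svgphylo)

tr <- readNewick(text = "((A:1,B:1):1,(C:1,D:1):1);")
tr
#> PhyloTree: 7 nodes, 4 leaves, branch lengths: yes
#>   leaves: A, B, C, D

# restrict the display to A and C: path lengths to their MRCA are summed
writeNewick(extractByLeaves(tr, c("A", "C")))
#> [1] "(A:2,C:2);"
patristicDistance(tr, "A", "C")
#> [1] 4

# lay out and render
lay <- treeLayout(tr, layoutOptions(mode = "phylogram"))
doc <- renderSVG(tr, lay,
                 options = renderOptions(cladeUrlTemplate = "tree?sel={leaves}"))
doc
#> SvgDocument: 1031.0 x 76.0 px, 1167 bytes, assets: svgphylo.css, svgphylo.js
writeSVG(doc, "tree.svg", writeAssets = TRUE)
```

The numbers read: the A–C restriction keeps the parent-tree path sums
(1 + 1 = 2 per side, patristic distance 4), and the rendered document is a
1.2 kB standalone SVG referencing an editable stylesheet and script.

From a shell, the same pipeline is:

```sh
inst/cli/svgphylo render tree.nwk --mode phylogram --extract A,C --out sub.svg
inst/cli/svgphylo gen --leaves 64 --seed 1 --label-style genome_like --out big.nwk
```

Preference files (`key = value`, one per line, `#` comments) set any flag's
default; CLI flags override them.

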