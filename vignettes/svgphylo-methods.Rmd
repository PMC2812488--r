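---
title: "Drawing interactive phylogenies as SVG: models, geometry and design choices"
author: "svgphylo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drawing interactive phylogenies as SVG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svgphylo)
```

## The problem

A phylogenetic tree served from a genome database is not a print figure: it
must scale to hundreds of taxa, stay sharp while zoomed, and act as a
navigation surface — leaf labels linking to genome pages, nodes revealing
taxonomy on rollover, clades linking to views of just that clade. Vector
output solves the scaling half (an SVG is rendered client-side at any zoom
with constant file size), and embedding web hooks in the markup solves the
navigation half. `svgphylo` implements that pipeline end to end: parse,
restrict, lay out, serialize.

This vignette documents the models and the decisions behind each stage: what
is computed, which knobs matter, which conventions were genuinely open
choices, and what the shipped tests do and do not establish.

## The tree model

A `PhyloTree` is a rooted ordered tree in flat parallel vectors indexed by
node id (1..n, assigned in input-encounter order). Three modelling rules are
deliberate:

- **Child order is data.** The order children appear in the source text is
  kept and drives the top-to-bottom display order; no stage ever re-sorts.
- **Missing branch lengths stay missing.** `hasBranchLengths()` is true only
  when every edge except (optionally) the root stem has a length. Phylogram
  layout refuses a tree without lengths rather than silently substituting
  unit lengths, which would misrepresent the data; the error suggests
  cladogram mode.
- **A root stem length is preserved but inert.** It round-trips through all
  readers and writers, but layout ignores it and subtree extraction drops
  it: a displayed tree stands alone.

Duplicate leaf labels are legal Newick, so the parser accepts them with a
warning; any operation that must look a leaf up by name (extraction,
annotation binding) rejects ambiguous names instead of guessing.

### Newick dialect

Labels may be bare or single-quoted; a doubled quote inside a quoted label
is a literal quote; square-bracket comments are dropped; underscores in bare
labels are kept literal (no underscore-to-space conversion — the lossless,
least surprising reading). Parse errors name a 0-based character offset so
tooling can point at the byte. On writing, branch lengths are emitted at a
caller-chosen number of decimals (default 6) with trailing zeros trimmed;
the round-trip guarantee is structural identity with lengths equal to
`10^-precision`.

### NEXUS subset

Only the `TREES` block is interpreted: an optional `TRANSLATE` table is
applied to leaf tokens (an unknown token is an error naming the token), a
leading `[&R]`/`[&U]` comment is recorded as a `rooting` annotation, and all
other blocks are skipped. This is the subset tree-inference packages emit.

### XML export

The export format is a minimal nested-clade dialect defined by this package:
a `<tree>` root, one `<clade>` element per node with optional `label` and
`branch_length` attributes, child order as element order. No public schema
is targeted; the dialect exists so downstream XML tooling can consume the
topology, and `readTreeXML()` is its exact inverse (tested by round trip).

## Subtree restriction without re-inference

`extractByLeaves(tree, S)` answers "show me just these taxa, with the
relationships taken from the full tree". The algorithm is the classical
induced-restriction construction:

1. count selected leaves under each node (one postorder pass);
2. root the result at the MRCA of `S` (the deepest node covering all of
   `S`);
3. keep only children whose subtree contains a selected leaf; a node left
   with exactly one kept child is suppressed and its edge length added to
   that child's edge (its label is discarded — a suppressed node no longer
   names a displayed clade);
4. drop the MRCA's stem.

Because edges are only ever summed along paths, every pairwise patristic
distance within `S` is numerically identical to the parent tree — that is
the point of restriction over re-inference: small selections inherit the
accuracy of the full-data estimate. Polytomies pass through untouched; the
parent topology is authoritative. Selections of size one are rejected: a
one-leaf display has no relationships to show, and a clear error beats
degenerate output.

The test suite checks this operation two ways on hundreds of seeded
(tree, selection) pairs: topological agreement with `ape::keep.tip` (an
independent implementation of keep-and-collapse) and distance preservation
to `1e-9` against `ape::cophenetic.phylo` on the parent tree.

## Layout geometry

Coordinates use the SVG convention (origin top-left, y downward) and are
exact reals; rounding happens only at serialization.

| Parameter | Default | Meaning |
|---|---|---|
| `mode` | `phylogram` | x from branch lengths, or `cladogram`: x from depth |
| `rowHeight` | 14 px | vertical space per leaf row |
| `xScale` | 500 px | per branch-length unit (phylogram) / per depth step (cladogram) |
| `margins` | 10 px × 4 | top, right, bottom, left |
| `alignedLabels` | off | one shared label column with leader lines |
| `fontSize` | 10 px | label size; also drives canvas-width estimation |
| `labelGap` | 5 px | gap between tip (or column) and label |

Leaf *i* (0-based, depth-first input order) sits at
`y = marginTop + (i + 0.5) * rowHeight`; an internal node's y is the
arithmetic mean of its children's y. The mean — rather than the midpoint of
the outermost children — behaves sensibly for polytomies (a heavy side pulls
the node toward it) and is trivially swappable. Phylogram
`x = marginLeft + xScale * (root-to-node length sum)`, root stem excluded.

Two conventions were genuinely open and are documented choices:

- **Cladogram x = depth from the root**, not a leaf-aligned right edge.
  Aligned *data* geometry and aligned *labels* are distinct concerns; the
  `alignedLabels` option supplies the visually aligned right-hand column
  (with dashed leader lines), so the cladogram can keep honest depth
  geometry underneath.
- **Label extent is estimated as `0.6 * fontSize` per character** instead of
  querying font metrics. Real metrics differ per platform and font; a fixed
  factor keeps canvas dimensions — and therefore output bytes —
  deterministic everywhere, at the cost of slightly generous right margins
  for narrow glyphs.

Branch shape (rectangular elbow vs triangular diagonal) is purely a
rendering concern: both are drawn from the same node points, so switching
shape never changes geometry or tests of it.

## SVG serialization

The renderer emits one element per visual atom: a `<path>` (elbow) or
`<line>` (diagonal) per edge, a `<text>` per labelled leaf, a tick per
unlabelled leaf (placeholder text would fabricate data), a hotspot
`<circle>` per internal node, and leader `<line>`s in aligned mode. Element
classes — `branch`, `leaf-label`, `leaf-tick`, `leader`, `node-hotspot`,
`clade-link`, `branch-length` — are a frozen contract so user stylesheets
survive upgrades. Per-edge elements (rather than one merged path) keep every
branch individually addressable from CSS and script.

Interactivity degrades gracefully by design. A leaf tooltip is emitted
twice: as a native `<title>` child (works with no script anywhere) and as
`data-label`/`data-tooltip` attributes consumed by the shipped script, which
swaps the visible label for the extended text on rollover — the "taxonomy
instead of organism name" behaviour. Clade hotspots become links only when a
`cladeUrlTemplate` containing `{leaves}` is supplied; the substitution is
the comma-joined, percent-encoded descendant leaf labels in display order,
chosen because it is deterministic and reversible server-side.

The stylesheet and script are referenced externally by default (one shared
asset pair serves any number of trees; editing them restyles every figure
without touching the SVG), or inlined with `embedAssets = TRUE` for
fully self-contained files.

Numerical choices: coordinates are serialized at `coordPrecision` decimals,
default 1 — sub-pixel fidelity at default scales while keeping files small;
trailing zeros are trimmed; `-0` is normalised to `0`. Output bytes are a
pure function of the inputs: no timestamps, no environment lookups, no map
iteration order. The suite asserts byte-identical repeated renders and
linear file-size growth in leaf count.

## The synthetic-data generator

`generateTree()` produces the inputs every test and example uses. It
emulates the one thing the renderer cares about — tree shape and scale — via
a Yule pure-birth process: starting from two lineages, a uniformly chosen
extant lineage splits until `nLeaves` leaves exist (so leaf count is exact
by construction, `2n - 1` nodes). Branch lengths are i.i.d. exponential with
mean `meanBranchLength` (default 0.1, a typical substitutions-per-site scale
for genome-wide trees); the `ultrametric_yule` variant instead runs the
process in continuous time at per-lineage rate `1/meanBranchLength` and
extends all pending lineages to the common end time, giving exactly equal
root-to-leaf path sums — the fixture for "all leaves at one x" layout tests.
`genome_like` labels are pronounceable 15–30-character
`Genus_species_strain_NN` strings, unique within a tree, matching the label
lengths of complete-genome displays; the 677-leaf corpus fixture mirrors the
scale of a complete-genomes tree on a production server. Generation is a
pure function of its arguments: a private RNG stream is seeded and the
caller's stream restored.

What the generator does *not* emulate: realistic sequence evolution,
extinction, rate heterogeneity across lineages, or the ragged label-length
and annotation-density distributions of curated databases. Passing tests
therefore establish the geometric and structural contracts on realistic
*shapes and sizes*, not fidelity to any particular published phylogeny; the
file-size measurements in particular depend on label lengths, which the
generator fixes to the genome-name regime.

## Problem sizes in the shipped suite

The default test run exercises: 1000 seeded trees (2–64 leaves) through the
Newick round trip; 500 (tree, selection) pairs against the independent
restriction oracle; layout invariants on the fixture corpus plus 200 random
trees (3–60 leaves) and 20 ultrametric trees; structural/determinism checks
on 15 rendered trees; file-size growth at 50–800 leaves; and the 677-leaf
compactness measurement. These sizes were chosen to exercise the asymptotic
claims (linearity, no quadratic blow-up) while keeping a full run in well
under a minute per suite on one core.

## Known limitations

- Layouts are rectangular only; circular/radial and unrooted drawings are
  out of scope.
- NEXUS support is the `TREES` block subset; `CHARACTERS`/`DATA` blocks are
  skipped, and the XML export is this package's own dialect, not phyloXML
  or NeXML.
- No raster export: SVG is the native and only output; external converters
  handle PNG/PDF when needed.
- The label-extent estimate can over- or under-shoot for extreme glyph
  mixes; the canvas is sized for the estimate, not the rendered ink.
- Trees are never re-rooted, and inference is explicitly out of scope: the
  package draws and restricts trees produced upstream.
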