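#' @include AllClasses.R
NULL

# The stylesheet and script shipped with the package. Emitted documents
# reference them externally by default, or inline them when
# embedAssets = TRUE. The CSS class names used here (branch, leaf-label,
# leaf-tick, leader, node-hotspot, clade-link, branch-length) are a frozen
# contract: user stylesheets may rely on them.

.defaultCSS <- "/* svgphylo default stylesheet */
.branch { stroke: #333333; stroke-width: 1; fill: none; }
.leaf-label { font-family: sans-serif; fill: #1a3f8f; }
.leaf-label.has-info { cursor: help; }
.leaf-tick { stroke: #333333; stroke-width: 1; }
.leader { stroke: #bbbbbb; stroke-width: 0.5; stroke-dasharray: 2,2; }
.node-hotspot { fill: #cc0000; fill-opacity: 0.6; stroke: none; }
.node-hotspot:hover { fill-opacity: 1; }
.clade-link { cursor: pointer; }
.branch-length { font-family: sans-serif; font-size: 70%; fill: #777777; }
"

.defaultJS <- "// svgphylo rollover template: swap a leaf label for the
// extended text carried in its data-tooltip attribute (for example a full
// taxonomy lineage), restoring the original data-label text on mouseout.
(function () {
  var labels = document.querySelectorAll('text.has-info');
  function lastTextNode(el) {
    for (var i = el.childNodes.length - 1; i >= 0; i--)
      if (el.childNodes[i].nodeType === 3) return el.childNodes[i];
    return null;
  }
  labels.forEach(function (el) {
    el.addEventListener('mouseover', function () {
      var t = lastTextNode(el);
      if (t) t.nodeValue = el.getAttribute('data-tooltip');
    });
    el.addEventListener('mouseout', function () {
      var t = lastTextNode(el);
      if (t) t.nodeValue = el.getAttribute('data-label');
    });
  });
})();
"

#' Default stylesheet and script
#'
#' Returns the static stylesheet and script templates shipped with the
#' package: the stylesheet styles every documented CSS class
#' (\code{branch}, \code{leaf-label}, \code{leaf-tick}, \code{leader},
#' \code{node-hotspot}, \code{clade-link}, \code{branch-length}); the
#' script implements the rollover label swap via the emitted
#' \code{data-label} / \code{data-tooltip} attributes. Both can be copied
#' next to rendered SVG files and edited freely.
#'
#' @return a list with elements \code{css} and \code{js}, each a single
#'   string.
#' @export
defaultAssets <- function() {
    list(css = .defaultCSS, js = .defaultJS)
}
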