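#' @include AllClasses.R
NULL

# Registry of preference keys. Every key mirrors a CLI flag; settings
# resolve with precedence built-in defaults < preference file < CLI flags.
.prefKeys <- c(
    "format",        # newick | nexus (input auto-detected when unset)
    "tree_name",     # which tree of a multi-tree NEXUS file to use
    "mode",          # phylogram | cladogram
    "shape",         # rectangular | triangular
    "align_labels",  # true | false
    "row_height",    # px per leaf row
    "x_scale",       # px per branch-length unit / depth step
    "font_size",     # px
    "label_gap",     # px
    "margin",        # "top,right,bottom,left" px
    "css",           # external stylesheet path written into the SVG
    "js",            # external script path written into the SVG
    "embed_assets",  # true | false
    "annotations",   # leaf annotation TSV path
    "clade_url",     # URL template with {leaves} for per-clade links
    "out",           # output path
    "precision"      # coordinate decimal places
)

#' Read a preference file
#'
#' Preference files hold one \code{key = value} pair per line; \code{#}
#' starts a comment and blank lines are ignored. Keys must belong to the
#' known-key registry (they mirror the CLI flags; see the package vignette
#' for the full list). Values from a preference file override built-in
#' defaults and are themselves overridden by CLI flags.
#'
#' @param file path to a preference file.
#' @param text alternatively, its content as a string.
#' @return a named list of character values.
#' @examples
#' loadPreferences(text = "mode = cladogram\n# a comment\nrow_height = 12")
#' @export
loadPreferences <- function(file = NULL, text = NULL) {
    lines <- if (is.null(text)) readLines(file, warn = FALSE)
             else strsplit(text, "\n", fixed = TRUE)[[1L]]
    prefs <- list()
    for (i in seq_along(lines)) {
        ln <- sub("#.*$", "", lines[i])
        ln <- trimws(ln)
        if (ln == "") next
        m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", ln))[[1L]]
        if (length(m) != 3L)
            stop("preference file line ", i, ": malformed (expected 'key = value'): '",
                 lines[i], "'", call. = FALSE)
        key <- m[2L]
        if (!key %in% .prefKeys)
            stop("preference file line ", i, ": unknown key '", key, "'",
                 call. = FALSE)
        prefs[[key]] <- trimws(m[3L])
    }
    prefs
}
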