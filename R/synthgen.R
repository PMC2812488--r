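#' @include newick.R
NULL

# Run expr with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards, so generation is a pure function of its
# arguments.
withPrivateSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    expr
}

genusFragment <- function(nch) {
    vowels <- c("a", "e", "i", "o", "u")
    cons <- setdiff(letters, vowels)
    out <- character(nch)
    for (i in seq_len(nch))
        out[i] <- if (i %% 2L == 1L) sample(cons, 1L) else sample(vowels, 1L)
    paste(out, collapse = "")
}

genomeLikeLabel <- function() {
    genus <- genusFragment(sample(6:9, 1L))
    substr(genus, 1L, 1L) <- toupper(substr(genus, 1L, 1L))
    species <- genusFragment(sample(6:10, 1L))
    strain <- sprintf("%s_%02d", sample(c("str", "ATCC", "DSM", "NCTC"), 1L),
                      sample(0:99, 1L))
    paste(genus, species, strain, sep = "_")
}

#' Generate a random bifurcating tree
#'
#' Simulates a rooted, strictly bifurcating tree under a Yule (pure-birth)
#' process: starting from two lineages, a uniformly chosen extant lineage
#' splits until \code{nLeaves} leaves exist. Under \code{model = "yule"}
#' every edge receives an independent exponential length with mean
#' \code{meanBranchLength}. Under \code{model = "ultrametric_yule"} the
#' process runs in continuous time (each lineage splits at rate
#' \code{1/meanBranchLength}) and all extant lineages are extended to the
#' common final time, so every root-to-leaf path sum is equal. Identical
#' arguments give identical trees; the caller's RNG state is untouched.
#'
#' @param nLeaves integer >= 2.
#' @param seed integer seed; the tree is a pure function of the arguments.
#' @param model \code{"yule"} or \code{"ultrametric_yule"}.
#' @param labelStyle \code{"short"} (\code{t1, t2, ...}) or
#'   \code{"genome_like"} (15-30 character \code{Genus_species_strain_NN}
#'   names, unique within the tree).
#' @param meanBranchLength mean edge length, in branch-length units.
#' @return a [PhyloTree-class] with \code{2 * nLeaves - 1} nodes.
#' @examples
#' tr <- generateTree(8, seed = 1)
#' writeNewick(tr, precision = 3)
#' @export
generateTree <- function(nLeaves, seed, model = c("yule", "ultrametric_yule"),
                         labelStyle = c("short", "genome_like"),
                         meanBranchLength = 0.1) {
    model <- match.arg(model)
    labelStyle <- match.arg(labelStyle)
    nLeaves <- as.integer(nLeaves)
    if (is.na(nLeaves) || nLeaves < 2L) stop("nLeaves must be >= 2")
    if (!is.numeric(meanBranchLength) || meanBranchLength <= 0)
        stop("meanBranchLength must be > 0")

    withPrivateSeed(seed, {
        nTotal <- 2L * nLeaves - 1L
        parent <- rep(NA_integer_, nTotal)
        birth <- numeric(nTotal)
        nNode <- 1L                     # node 1 = root
        extant <- integer(nLeaves)
        # root splits immediately into two lineages
        parent[2L] <- 1L; parent[3L] <- 1L
        nNode <- 3L
        extant[1:2] <- c(2L, 3L)
        k <- 2L
        t <- 0
        rate <- 1 / meanBranchLength
        birth[2:3] <- 0
        while (k < nLeaves) {
            dt <- stats::rexp(1L, rate * k)
            t <- t + dt
            i <- sample.int(k, 1L)
            nd <- extant[i]
            c1 <- nNode + 1L; c2 <- nNode + 2L
            parent[c1] <- nd; parent[c2] <- nd
            birth[c(c1, c2)] <- t
            nNode <- nNode + 2L
            extant[i] <- c1
            k <- k + 1L
            extant[k] <- c2
        }
        elen <- rep(NA_real_, nTotal)
        if (model == "yule") {
            elen[2:nTotal] <- stats::rexp(nTotal - 1L, rate)
        } else {
            tEnd <- t + stats::rexp(1L, rate * k)
            isTip <- rep(TRUE, nTotal)
            isTip[parent[seq_len(nTotal)][!is.na(parent)]] <- FALSE
            # internal edge: from own birth to the time it split (= birth of
            # its children); tip edge: from birth to tEnd
            childBirth <- rep(NA_real_, nTotal)
            for (i in 2:nTotal)
                if (!is.na(parent[i])) {
                    p <- parent[i]
                    childBirth[p] <- birth[i]
                }
            for (i in 2:nTotal) {
                elen[i] <- if (isTip[i]) tEnd - birth[i]
                           else childBirth[i] - birth[i]
            }
        }

        label <- rep(NA_character_, nTotal)
        # leaves = nodes that are nobody's parent
        tipIds <- setdiff(seq_len(nTotal), parent[!is.na(parent)])
        if (labelStyle == "short") {
            label[tipIds] <- paste0("t", seq_along(tipIds))
        } else {
            seen <- character(0)
            for (i in tipIds) {
                repeat {
                    lab <- genomeLikeLabel()
                    if (!(lab %in% seen)) break
                }
                seen <- c(seen, lab)
                label[i] <- lab
            }
        }
        newPhyloTree(parent, label, elen, warnDuplicates = FALSE)
    })
}

#' Hand-written edge-case fixture trees
#'
#' A named list of small trees exercising parser and layout corner cases
#' (single leaf, unary root branch, polytomy, quoted labels, missing
#' lengths, duplicate labels, zero-length edges) plus \code{genomes677}, a
#' seeded 677-leaf tree with genome-style labels matching the scale of a
#' complete-genomes display tree. All fixtures are valid \code{PhyloTree}
#' objects; \code{duplicateLabels} carries duplicate leaf names on purpose
#' (its parse warning is suppressed here).
#'
#' @return named list of [PhyloTree-class] objects.
#' @export
fixtureCorpus <- function() {
    list(
        leafOnly = readNewick(text = "A;"),
        singleBranch = readNewick(text = "(A:1.5);"),
        basic = readNewick(text = "((A:1,B:1):1,(C:1,D:1):1);"),
        polytomy = readNewick(text = "(A:1,B:2,C:1,(D:1,E:1):0.5);"),
        quotedLabels = readNewick(
            text = "('Homo sapiens':0.1,('Pan ''paniscus''':0.2,Gorilla:0.3):0.1);"),
        missingLengths = readNewick(text = "(A,(B,C));"),
        duplicateLabels = suppressWarnings(
            readNewick(text = "(A:1,(A:1,B:1):1);")),
        zeroLength = readNewick(text = "(A:0,(B:0,C:1):0);"),
        genomes677 = generateTree(677L, seed = 677L, model = "yule",
                                  labelStyle = "genome_like")
    )
}
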