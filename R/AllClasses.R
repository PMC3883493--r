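setOldClass("phylo")

#' Type IIB restriction enzyme
#'
#' Holds the degenerate (IUPAC) recognition pattern of a Type IIB enzyme
#' together with its fragment geometry: the blunt fragment length and the
#' number of bases excised to the left and right of the recognition site.
#' The invariant `leftFlank + nchar(pattern) + rightFlank == bluntLength`
#' always holds.
#'
#' @slot name Enzyme name, e.g. `"AlfI"`.
#' @slot pattern Recognition pattern written 5'->3' in IUPAC codes,
#'   e.g. `"GCANNNNNNTGC"`.
#' @slot bluntLength Length in bp of the blunt fragment the enzyme releases.
#' @slot leftFlank Bases retained 5' of the recognition site.
#' @slot rightFlank Bases retained 3' of the recognition site.
#'
#' @seealso [TypeIIBEnzyme()] for the user constructor, [typeIIBEnzymes()]
#'   for the built-in enzyme set.
#' @exportClass TypeIIBEnzyme
setClass("TypeIIBEnzyme",
    representation(
        name = "character",
        pattern = "character",
        bluntLength = "integer",
        leftFlank = "integer",
        rightFlank = "integer"
    )
)

setValidity("TypeIIBEnzyme", function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "name must be a single non-empty string")
    chk <- tryCatch({
        parseIupacPattern(object@pattern)
        NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(chk)) msg <- c(msg, chk)
    if (object@leftFlank < 0L || object@rightFlank < 0L)
        msg <- c(msg, "flank lengths must be non-negative")
    if (is.null(chk) &&
        object@leftFlank + nchar(object@pattern) + object@rightFlank !=
            object@bluntLength)
        msg <- c(msg, sprintf(
            "leftFlank + pattern length + rightFlank (%d) != bluntLength (%d)",
            object@leftFlank + nchar(object@pattern) + object@rightFlank,
            object@bluntLength))
    if (length(msg)) msg else TRUE
})

#' Representative fragment set of one genome for one enzyme
#'
#' The distinct canonical (strand-collapsed) fragment sequences that remain
#' after collapsing identical copies and removing divergent within-genome
#' fragment families. The `stats` slot records how the raw digest was
#' reduced: `singleCopy` representatives seen once, `multiCopy`
#' representatives that collapsed several identical copies, and
#' `familyRemoved` distinct sequences discarded because they had a
#' within-genome neighbor at small Hamming distance.
#'
#' @slot taxon Genome (taxon) identifier.
#' @slot enzyme Enzyme name the fragments derive from.
#' @slot fragmentLength Common length in bp of all representatives.
#' @slot representatives Sorted distinct canonical sequences.
#' @slot stats Named integer vector
#'   `c(singleCopy=, multiCopy=, familyRemoved=)`.
#'
#' @seealso [buildRepresentativeSet()], [representatives()],
#'   [writeFragmentSet()].
#' @exportClass FragmentSet
setClass("FragmentSet",
    representation(
        taxon = "character",
        enzyme = "character",
        fragmentLength = "integer",
        representatives = "character",
        stats = "integer"
    )
)

setValidity("FragmentSet", function(object) {
    msg <- character()
    if (anyDuplicated(object@representatives))
        msg <- c(msg, "representatives must be pairwise distinct")
    if (length(object@representatives) &&
        any(nchar(object@representatives) != object@fragmentLength))
        msg <- c(msg, "all representatives must have length fragmentLength")
    need <- c("singleCopy", "multiCopy", "familyRemoved")
    if (!all(need %in% names(object@stats)))
        msg <- c(msg, "stats must carry singleCopy, multiCopy, familyRemoved")
    else {
        if (any(object@stats[need] < 0L))
            msg <- c(msg, "stats counts must be non-negative")
        if (object@stats[["singleCopy"]] + object@stats[["multiCopy"]] !=
            length(object@representatives))
            msg <- c(msg,
                "singleCopy + multiCopy must equal the representative count")
    }
    if (length(msg)) msg else TRUE
})

#' Shared-fragment counts for one genome pair
#'
#' Tallies of representative fragments of one genome with an identical
#' counterpart (`identical`) or a counterpart within `maxMismatch`
#' mismatches (`similar`) in the other genome, counted in both directions,
#' together with the two set sizes. These are the numerator and denominator
#' terms of the log-ratio distance.
#'
#' @slot taxonA,taxonB Taxon identifiers of the pair.
#' @slot enzyme Enzyme name.
#' @slot identical Fragments matched exactly (both directions summed).
#' @slot similar Fragments matched at 1..`maxMismatch` mismatches.
#' @slot nA,nB Representative set sizes.
#' @slot maxMismatch Mismatch tolerance used.
#'
#' @seealso [countShared()], [pairDistance()].
#' @exportClass SharedCount
setClass("SharedCount",
    representation(
        taxonA = "character",
        taxonB = "character",
        enzyme = "character",
        identical = "integer",
        similar = "integer",
        nA = "integer",
        nB = "integer",
        maxMismatch = "integer"
    )
)

setValidity("SharedCount", function(object) {
    msg <- character()
    if (object@identical < 0L || object@similar < 0L ||
        object@nA < 0L || object@nB < 0L)
        msg <- c(msg, "all counts must be non-negative")
    if (object@identical + object@similar > object@nA + object@nB)
        msg <- c(msg, "identical + similar cannot exceed nA + nB")
    if (length(msg)) msg else TRUE
})

#' Pairwise fragment-sharing distance matrix
#'
#' Symmetric matrix of log-ratio distances between taxa for one enzyme,
#' with a zero diagonal and all entries finite (pairs sharing nothing are
#' capped; see [pairDistance()]).
#'
#' @slot enzyme Enzyme name (may be `""` when read from a bare PHYLIP file).
#' @slot labels Ordered taxon identifiers.
#' @slot values Symmetric numeric matrix, `values[i, j] >= 0`.
#'
#' @seealso [buildDistanceMatrix()], [writePhylip()], [neighborJoining()].
#' @exportClass FragmentDistances
setClass("FragmentDistances",
    representation(
        enzyme = "character",
        labels = "character",
        values = "matrix"
    )
)

setValidity("FragmentDistances", function(object) {
    msg <- character()
    v <- object@values
    n <- length(object@labels)
    if (!is.numeric(v) || nrow(v) != n || ncol(v) != n)
        msg <- c(msg, "values must be an n x n numeric matrix")
    else {
        if (any(!is.finite(v))) msg <- c(msg, "all distances must be finite")
        else {
            if (any(abs(diag(v)) > 0)) msg <- c(msg, "diagonal must be zero")
            if (any(v < 0)) msg <- c(msg, "distances must be non-negative")
            if (!isTRUE(all.equal(v, t(v), tolerance = 1e-12)))
                msg <- c(msg, "matrix must be symmetric")
        }
    }
    if (anyDuplicated(object@labels))
        msg <- c(msg, "taxon labels must be unique")
    if (length(msg)) msg else TRUE
})

#' Majority-rule consensus tree with enzyme support
#'
#' Consensus topology over a set of per-enzyme trees. Each retained internal
#' branch (leaf bipartition present in more than half of the input trees)
#' carries the number of supporting trees and the corresponding percentage.
#' The embedded `phylo` tree stores the support counts as internal node
#' labels.
#'
#' @slot tree The consensus topology as an [ape::ape-package] `phylo`
#'   object, node labels = supporting-tree counts.
#' @slot support `data.frame` with one row per retained non-trivial split:
#'   `clade` (comma-joined smaller side of the bipartition), `count`,
#'   `percent`.
#' @slot nTrees Number of input trees.
#'
#' @seealso [majorityConsensus()].
#' @exportClass ConsensusTree
setClass("ConsensusTree",
    representation(
        tree = "phylo",
        support = "data.frame",
        nTrees = "integer"
    )
)

setValidity("ConsensusTree", function(object) {
    msg <- character()
    if (object@nTrees < 1L) msg <- c(msg, "nTrees must be >= 1")
    if (nrow(object@support)) {
        if (any(object@support$count > object@nTrees))
            msg <- c(msg, "support counts cannot exceed nTrees")
        if (any(object@support$count * 2L <= object@nTrees))
            msg <- c(msg, "retained splits must satisfy count > nTrees/2")
    }
    if (length(msg)) msg else TRUE
})
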