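#' Accessors for rad2b classes
#'
#' Small generics giving read access to the slots of the package's S4
#' classes: the enzyme a result derives from, the taxa it covers, the
#' representative sequences of a [FragmentSet-class], the numeric matrix of a
#' [FragmentDistances-class], and the per-branch support table of a
#' [ConsensusTree-class].
#'
#' @param x An object of one of the package's classes.
#' @return `enzymeName()` a string; `taxa()` a character vector;
#'   `representatives()` a character vector of canonical sequences;
#'   `distanceMatrix()` a named symmetric numeric matrix;
#'   `supportTable()` a `data.frame` with columns `clade`, `count`,
#'   `percent`.
#' @examples
#' e <- TypeIIBEnzyme("BslFI", "GGGAC", 21L)
#' enzymeName(e)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("enzymeName", function(x) standardGeneric("enzymeName"))

#' @rdname accessors
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @rdname accessors
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @rdname accessors
#' @export
setGeneric("distanceMatrix", function(x) standardGeneric("distanceMatrix"))

#' @rdname accessors
#' @export
setGeneric("supportTable", function(x) standardGeneric("supportTable"))

#' @rdname accessors
setMethod("enzymeName", "TypeIIBEnzyme", function(x) x@name)
#' @rdname accessors
setMethod("enzymeName", "FragmentSet", function(x) x@enzyme)
#' @rdname accessors
setMethod("enzymeName", "SharedCount", function(x) x@enzyme)
#' @rdname accessors
setMethod("enzymeName", "FragmentDistances", function(x) x@enzyme)

#' @rdname accessors
setMethod("taxa", "FragmentSet", function(x) x@taxon)
#' @rdname accessors
setMethod("taxa", "SharedCount", function(x) c(x@taxonA, x@taxonB))
#' @rdname accessors
setMethod("taxa", "FragmentDistances", function(x) x@labels)
#' @rdname accessors
setMethod("taxa", "ConsensusTree", function(x) x@tree$tip.label)

#' @rdname accessors
setMethod("representatives", "FragmentSet", function(x) x@representatives)

#' @rdname accessors
setMethod("distanceMatrix", "FragmentDistances", function(x) {
    v <- x@values
    dimnames(v) <- list(x@labels, x@labels)
    v
})

#' @rdname accessors
setMethod("supportTable", "ConsensusTree", function(x) x@support)

setMethod("show", "TypeIIBEnzyme", function(object) {
    cat(sprintf(
        "TypeIIBEnzyme %s: %s (blunt %d bp; flanks %d/%d; %s)\n",
        object@name, object@pattern, object@bluntLength,
        object@leftFlank, object@rightFlank,
        if (isPalindromic(object@pattern)) "palindromic"
        else "non-palindromic"))
})

setMethod("show", "FragmentSet", function(object) {
    cat(sprintf(
        "FragmentSet: %d representative %d-bp fragments (%s, %s)\n",
        length(object@representatives), object@fragmentLength,
        object@taxon, object@enzyme))
    cat(sprintf("  single-copy %d, multi-copy %d, family-removed %d\n",
        object@stats[["singleCopy"]], object@stats[["multiCopy"]],
        object@stats[["familyRemoved"]]))
})

setMethod("show", "SharedCount", function(object) {
    cat(sprintf(
        "SharedCount %s vs %s (%s): identical %d, similar %d (<=%d mm), n = %d + %d\n",
        object@taxonA, object@taxonB, object@enzyme, object@identical,
        object@similar, object@maxMismatch, object@nA, object@nB))
})

setMethod("show", "FragmentDistances", function(object) {
    cat(sprintf("FragmentDistances: %d taxa%s\n", length(object@labels),
        if (nzchar(object@enzyme)) paste0(" (", object@enzyme, ")") else ""))
    print(round(distanceMatrix(object), 4))
})

setMethod("show", "ConsensusTree", function(object) {
    cat(sprintf(
        "ConsensusTree: majority-rule over %d trees, %d taxa, %d supported splits\n",
        object@nTrees, length(object@tree$tip.label), nrow(object@support)))
})
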