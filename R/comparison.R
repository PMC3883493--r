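#' Hamming distance between equal-length sequences
#'
#' @param a,b Sequences of equal length.
#' @return Integer count of differing positions.
#' @examples
#' hammingDistance("ACGTACGT", "ACGAACGA")  # 2
#' @export
hammingDistance <- function(a, b) {
    cpp_hamming(as.character(a), as.character(b))
}

.set_sequences <- function(x) {
    if (is(x, "FragmentSet")) x@representatives else as.character(x)
}

#' Best match class of a fragment against a fragment set
#'
#' A fragment is `"identical"` when its canonical form occurs verbatim in
#' the other set; otherwise `"similar"` when its nearest member of the
#' other set -- taking, for each member, the smaller Hamming distance of
#' the two strand alignments (canonical vs canonical and canonical vs
#' reverse complement) -- lies within `maxMismatch` mismatches; otherwise
#' `"none"`. Each fragment therefore contributes at most one match class.
#'
#' @param fragment A single canonical fragment sequence.
#' @param other A [FragmentSet-class] or character vector of canonical
#'   sequences, all the same length as `fragment`.
#' @param maxMismatch Mismatch tolerance (default 5).
#' @return One of `"identical"`, `"similar"`, `"none"`.
#' @export
bestMatchClass <- function(fragment, other, maxMismatch = 5L) {
    seqs <- .set_sequences(other)
    if (length(seqs) && any(nchar(seqs) != nchar(fragment)))
        stop("fragment and set sequences must have equal length")
    cls <- .match_classes(as.character(fragment), seqs, maxMismatch)
    c("none", "identical", "similar")[cls + 1L]
}

.match_classes <- function(query, target, maxMismatch) {
    if (!length(target)) return(integer(length(query)))
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(target)))
    cpp_match_class(query, target, rc, as.integer(maxMismatch))
}

#' Count shared fragments between two genomes
#'
#' Classifies every representative fragment of set `a` against set `b` and
#' vice versa (see [bestMatchClass()]) and sums the two directions:
#' `identical` is the number of fragments (of either genome) with an exact
#' counterpart in the other genome, `similar` the number matched at
#' 1..`maxMismatch` mismatches. With this bidirectional convention two
#' identical fragment sets give `identical == nA + nB`, hence a log-ratio
#' distance of exactly 0.
#'
#' @param a,b [FragmentSet-class] objects for the same enzyme.
#' @param maxMismatch Mismatch tolerance (default 5).
#' @return A [SharedCount-class].
#' @examples
#' a <- buildRepresentativeSet(c(ACGTACGTA = 1L), "demo", "t1")
#' countShared(a, a)
#' @export
countShared <- function(a, b, maxMismatch = 5L) {
    stopifnot(is(a, "FragmentSet"), is(b, "FragmentSet"))
    if (!identical(a@enzyme, b@enzyme))
        stop(sprintf("enzyme mismatch: '%s' vs '%s'", a@enzyme, b@enzyme))
    if (length(a@representatives) && length(b@representatives) &&
        a@fragmentLength != b@fragmentLength)
        stop(sprintf("fragment length mismatch: %d vs %d",
            a@fragmentLength, b@fragmentLength))
    clsA <- .match_classes(a@representatives, b@representatives, maxMismatch)
    clsB <- .match_classes(b@representatives, a@representatives, maxMismatch)
    new("SharedCount", taxonA = a@taxon, taxonB = b@taxon,
        enzyme = a@enzyme,
        identical = sum(clsA == 1L) + sum(clsB == 1L),
        similar = sum(clsA == 2L) + sum(clsB == 2L),
        nA = length(a@representatives), nB = length(b@representatives),
        maxMismatch = as.integer(maxMismatch))
}
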