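#' Build the representative fragment set of a genome
#'
#' Reduces a raw digest (canonical sequences with copy counts, as returned
#' by [digestGenome()]) to the representative list used for between-genome
#' comparison: identical copies collapse to a single representative, and
#' divergent within-genome fragment families -- distinct sequences with at
#' least one other distinct sequence within `familyRadius` mismatches --
#' are removed entirely (every member of every such family). Removing the
#' whole family is equivalent to removing every sequence that has any
#' neighbor at Hamming distance `<= familyRadius`, because each member of
#' a connected family is adjacent to at least one other member.
#'
#' @param raw Named integer vector of canonical sequences and copy counts,
#'   or a plain character vector of fragment occurrences.
#' @param enzyme A [TypeIIBEnzyme-class] object (names the set and fixes
#'   the expected fragment length), or an enzyme name string.
#' @param taxon Genome (taxon) identifier.
#' @param familyRadius Mismatch radius defining a within-genome fragment
#'   family (`>= 1`); default 2.
#' @return A [FragmentSet-class].
#' @examples
#' buildRepresentativeSet(c(AAAACCGG = 2L, CCCCGGTA = 1L), "demo", "t1")
#' @export
buildRepresentativeSet <- function(raw, enzyme, taxon, familyRadius = 2L) {
    if (is.character(raw) && is.null(names(raw))) {
        tab <- table(raw)
        raw <- structure(as.integer(tab), names = names(tab))
    }
    if (familyRadius < 1L) stop("familyRadius must be >= 1")
    enzymeName <- if (is(enzyme, "TypeIIBEnzyme")) enzyme@name
        else as.character(enzyme)
    seqs <- names(raw)
    lens <- unique(nchar(seqs))
    if (length(lens) > 1L)
        stop("mixed fragment lengths in raw multiset: ",
            paste(lens, collapse = ", "))
    if (is(enzyme, "TypeIIBEnzyme") && length(lens) &&
        lens != enzyme@bluntLength)
        stop(sprintf("fragment length %d does not match enzyme %s (%d bp)",
            lens, enzyme@name, enzyme@bluntLength))
    fragLen <- if (length(lens)) as.integer(lens)
        else if (is(enzyme, "TypeIIBEnzyme")) enzyme@bluntLength else 0L
    if (length(seqs)) {
        inFamily <- cpp_has_neighbor(seqs, as.integer(familyRadius))
        reps <- sort(seqs[!inFamily])
        counts <- raw[reps]
        stats <- c(
            singleCopy = sum(counts == 1L),
            multiCopy = sum(counts > 1L),
            familyRemoved = sum(inFamily)
        )
    } else {
        reps <- character()
        stats <- c(singleCopy = 0L, multiCopy = 0L, familyRemoved = 0L)
    }
    storage.mode(stats) <- "integer"
    new("FragmentSet", taxon = as.character(taxon), enzyme = enzymeName,
        fragmentLength = fragLen, representatives = unname(reps),
        stats = stats)
}

#' Write / read a representative fragment set
#'
#' Serializes a [FragmentSet-class] as a plain TSV file: `#key=value`
#' header lines carrying taxon, enzyme, fragment length and the reduction
#' stats, then one canonical sequence per line under a `canonical_sequence`
#' column. `readFragmentSet()` is the exact inverse.
#'
#' @param fs A [FragmentSet-class].
#' @param path Output (input) file path.
#' @return `writeFragmentSet()` returns `path` invisibly;
#'   `readFragmentSet()` returns a [FragmentSet-class].
#' @export
writeFragmentSet <- function(fs, path) {
    stopifnot(is(fs, "FragmentSet"))
    validObject(fs)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        sprintf("#taxon=%s", fs@taxon),
        sprintf("#enzyme=%s", fs@enzyme),
        sprintf("#fragment_length=%d", fs@fragmentLength),
        sprintf("#single_copy=%d", fs@stats[["singleCopy"]]),
        sprintf("#multi_copy=%d", fs@stats[["multiCopy"]]),
        sprintf("#family_removed=%d", fs@stats[["familyRemoved"]]),
        "canonical_sequence",
        fs@representatives), con)
    invisible(path)
}

#' @rdname writeFragmentSet
#' @export
readFragmentSet <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^#", lines)
    if (length(hdr) < 6L || !identical(hdr, seq_len(length(hdr))))
        stop("malformed fragment-set file (missing header block): ", path)
    kv <- sub("^#", "", lines[hdr])
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    names(vals) <- keys
    need <- c("taxon", "enzyme", "fragment_length", "single_copy",
        "multi_copy", "family_removed")
    miss <- setdiff(need, keys)
    if (length(miss))
        stop("fragment-set file missing header key(s): ",
            paste(miss, collapse = ", "))
    colLine <- length(hdr) + 1L
    if (colLine > length(lines) ||
        !identical(lines[colLine], "canonical_sequence"))
        stop(sprintf("parse error at line %d: expected 'canonical_sequence'",
            colLine))
    seqs <- lines[seq.int(colLine + 1L, length.out = length(lines) - colLine)]
    seqs <- seqs[nzchar(seqs)]
    fragLen <- as.integer(vals[["fragment_length"]])
    badLen <- which(nchar(seqs) != fragLen)
    if (length(badLen))
        stop(sprintf("parse error at line %d: sequence length %d, expected %d",
            colLine + badLen[1], nchar(seqs[badLen[1]]), fragLen))
    bad <- which(grepl("[^ACGT]", seqs))
    if (length(bad))
        stop(sprintf("parse error at line %d: non-ACGT sequence",
            colLine + bad[1]))
    new("FragmentSet", taxon = vals[["taxon"]], enzyme = vals[["enzyme"]],
        fragmentLength = fragLen, representatives = seqs,
        stats = c(singleCopy = as.integer(vals[["single_copy"]]),
            multiCopy = as.integer(vals[["multi_copy"]]),
            familyRemoved = as.integer(vals[["family_removed"]])))
}
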