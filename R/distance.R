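#' Log-ratio distance for one genome pair
#'
#' Converts shared-fragment counts to the evolutionary distance
#' `-ln((identical + similar) / (nA + nB))`. The negative natural log of
#' the sharing ratio is always non-negative because the numerator cannot
#' exceed the denominator. A pair sharing no fragments at all would give an
#' infinite distance; it is returned as the finite `cap` instead so that
#' downstream tree building stays computable.
#'
#' @param sc A [SharedCount-class].
#' @param cap Distance assigned when `identical + similar == 0`
#'   (default 30, roughly `-ln(1e-13)`).
#' @return Non-negative finite distance.
#' @examples
#' sc <- new("SharedCount", taxonA = "a", taxonB = "b", enzyme = "e",
#'           identical = 50L, similar = 50L, nA = 100L, nB = 100L,
#'           maxMismatch = 5L)
#' pairDistance(sc)  # ln 2
#' @export
pairDistance <- function(sc, cap = 30) {
    stopifnot(is(sc, "SharedCount"))
    tot <- sc@nA + sc@nB
    if (tot == 0L) stop("empty comparison: nA + nB == 0")
    shared <- sc@identical + sc@similar
    if (shared == 0L) return(cap)
    -log(shared / tot)
}

#' Assemble a per-enzyme distance matrix
#'
#' Builds the symmetric [FragmentDistances-class] matrix from exactly one
#' [SharedCount-class] per unordered taxon pair (`choose(n, 2)` records for
#' `n` taxa -- 210 for 21 taxa). Missing or duplicated pairs are an error
#' naming the offending pair.
#'
#' @param counts List of [SharedCount-class] objects, one per pair.
#' @param taxa Ordered character vector of taxon ids.
#' @param cap Passed to [pairDistance()].
#' @return A [FragmentDistances-class].
#' @export
buildDistanceMatrix <- function(counts, taxa, cap = 30) {
    taxa <- as.character(taxa)
    n <- length(taxa)
    if (n < 2L) stop("need at least two taxa")
    if (anyDuplicated(taxa)) stop("duplicate taxon ids")
    enz <- unique(vapply(counts, function(sc) sc@enzyme, character(1)))
    if (length(enz) > 1L)
        stop("counts mix enzymes: ", paste(enz, collapse = ", "))
    m <- matrix(NA_real_, n, n, dimnames = list(taxa, taxa))
    diag(m) <- 0
    for (sc in counts) {
        i <- match(sc@taxonA, taxa)
        j <- match(sc@taxonB, taxa)
        if (is.na(i) || is.na(j))
            stop(sprintf("pair (%s, %s) names unknown taxa",
                sc@taxonA, sc@taxonB))
        if (i == j)
            stop("self-pair for taxon ", sc@taxonA)
        if (!is.na(m[i, j]))
            stop(sprintf("duplicate pair (%s, %s)", sc@taxonA, sc@taxonB))
        m[i, j] <- m[j, i] <- pairDistance(sc, cap = cap)
    }
    miss <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)
    if (nrow(miss))
        stop(sprintf("missing pair (%s, %s)%s",
            taxa[miss[1, 1]], taxa[miss[1, 2]],
            if (nrow(miss) > 1)
                sprintf(" and %d more", nrow(miss) - 1) else ""))
    new("FragmentDistances", enzyme = if (length(enz)) enz else "",
        labels = taxa, values = unname(m))
}

#' Write / read a PHYLIP square distance matrix
#'
#' `writePhylip()` emits the classic square PHYLIP format: a first line
#' with the taxon count, then one row per taxon with the name padded to 10
#' characters followed by the distances. Names longer than 10 characters
#' are truncated; truncation collisions are an error. `readPhylip()` reads
#' the format back (the enzyme name is not part of the format and comes
#' back empty unless supplied).
#'
#' @param m A [FragmentDistances-class].
#' @param path File path.
#' @param enzyme Enzyme name to attach on read.
#' @return `writePhylip()` the path, invisibly; `readPhylip()` a
#'   [FragmentDistances-class].
#' @export
writePhylip <- function(m, path) {
    stopifnot(is(m, "FragmentDistances"))
    validObject(m)
    short <- substr(m@labels, 1L, 10L)
    if (anyDuplicated(short))
        stop("taxon names collide after truncation to 10 characters: ",
            paste(unique(short[duplicated(short)]), collapse = ", "))
    rows <- vapply(seq_along(short), function(i) {
        paste0(formatC(short[i], width = -10),
            paste(sprintf("%.6f", m@values[i, ]), collapse = " "))
    }, character(1))
    writeLines(c(sprintf("%5d", length(short)), rows), path)
    invisible(path)
}

#' @rdname writePhylip
#' @export
readPhylip <- function(path, enzyme = "") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    n <- suppressWarnings(as.integer(trimws(lines[1])))
    if (is.na(n) || n < 2L)
        stop("malformed PHYLIP file: bad taxon count line")
    if (length(lines) != n + 1L)
        stop(sprintf("malformed PHYLIP file: expected %d rows, found %d",
            n, length(lines) - 1L))
    labels <- character(n)
    m <- matrix(0, n, n)
    for (i in seq_len(n)) {
        row <- lines[i + 1L]
        labels[i] <- trimws(substr(row, 1L, 10L))
        vals <- as.numeric(strsplit(trimws(substring(row, 11L)),
            "\\s+")[[1]])
        if (length(vals) != n || anyNA(vals))
            stop(sprintf("malformed PHYLIP row %d: expected %d distances",
                i, n))
        m[i, ] <- vals
    }
    m <- (m + t(m)) / 2   # absorb printed rounding asymmetry
    diag(m) <- 0
    new("FragmentDistances", enzyme = enzyme, labels = labels, values = m)
}
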