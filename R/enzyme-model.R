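# IUPAC nucleotide ambiguity codes and their base sets / complements.
.IUPAC_SETS <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.IUPAC_COMPLEMENT <- c(
    A = "T", C = "G", G = "C", T = "A",
    R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
    B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Parse and validate a degenerate recognition pattern
#'
#' Validates that every position of a recognition pattern is a legal IUPAC
#' nucleotide code and returns the per-position degeneracies (the size of
#' the base set each code denotes: 1 for A/C/G/T, 2 for R/Y/S/W/K/M, 3 for
#' B/D/H/V, 4 for N).
#'
#' @param text Recognition pattern as a single string, e.g.
#'   `"GCANNNNNNTGC"`. Lower case is accepted and upper-cased.
#' @return A list with elements `pattern` (the upper-cased string),
#'   `positions` (character vector of codes) and `degeneracy` (integer
#'   vector, same length).
#' @examples
#' p <- parseIupacPattern("ACNNNNGTAYC")
#' p$degeneracy
#' @export
parseIupacPattern <- function(text) {
    if (!is.character(text) || length(text) != 1L || is.na(text) ||
        !nzchar(text))
        stop("pattern must be a single non-empty string")
    chars <- strsplit(toupper(text), "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% names(.IUPAC_SETS))
    if (length(bad))
        stop(sprintf("invalid IUPAC code '%s' at position %d of pattern '%s'",
            chars[bad[1]], bad[1], text))
    list(
        pattern = paste(chars, collapse = ""),
        positions = chars,
        degeneracy = vapply(.IUPAC_SETS[chars], length, integer(1),
            USE.NAMES = FALSE)
    )
}

#' Reverse-complement a degenerate pattern
#'
#' Reverses the pattern and complements every IUPAC code (A-T, C-G, R-Y,
#' K-M; S, W and N are self-complementary; B-V, D-H).
#'
#' @param pattern Recognition pattern string (IUPAC codes).
#' @return The reverse-complemented pattern string.
#' @examples
#' reverseComplementPattern("GGGAC")         # "GTCCC"
#' reverseComplementPattern("GAYNNNNNRTC")   # itself
#' @export
reverseComplementPattern <- function(pattern) {
    p <- parseIupacPattern(pattern)
    paste(rev(unname(.IUPAC_COMPLEMENT[p$positions])), collapse = "")
}

#' Is a recognition pattern palindromic (self-reverse-complementary)?
#'
#' A pattern is palindromic when it equals its own reverse complement
#' position-wise. For such patterns a double-stranded recognition site is
#' found by scanning a single strand; for non-palindromic patterns both
#' orientations must be scanned.
#'
#' @param pattern Recognition pattern string (IUPAC codes).
#' @return `TRUE` or `FALSE`.
#' @examples
#' isPalindromic("GCANNNNNNTGC")  # TRUE
#' isPalindromic("GGGAC")         # FALSE
#' @export
isPalindromic <- function(pattern) {
    p <- parseIupacPattern(pattern)
    identical(p$pattern, reverseComplementPattern(pattern))
}

#' Per-position probability of a recognition site
#'
#' Probability that a pattern matches at a fixed position of one strand of
#' an i.i.d. random sequence with equal base frequencies: the product over
#' positions of degeneracy/4 (N positions contribute factor 1).
#'
#' @param pattern Recognition pattern string (IUPAC codes).
#' @return Probability in (0, 1].
#' @examples
#' siteProbability("GGGAC")        # (1/4)^5
#' siteProbability("ACNNNNGTAYC")  # (1/4)^6 * 1/2
#' @export
siteProbability <- function(pattern) {
    p <- parseIupacPattern(pattern)
    prod(p$degeneracy / 4)
}

#' Expected distance between cut sites
#'
#' Expected spacing in bp between recognition sites of an enzyme on random
#' double-stranded sequence with equal base frequencies. A palindromic
#' (self-reverse-complementary) pattern recognizes each double-stranded
#' site once, giving spacing `1/p`; a non-palindromic pattern is recognized
#' in either orientation, halving the spacing to `1/(2p)`, where `p` is
#' [siteProbability()].
#'
#' @param enzyme A [TypeIIBEnzyme-class] object, or a pattern string.
#' @return Expected spacing in bp.
#' @examples
#' expectedSiteSpacing(TypeIIBEnzyme("AlfI", "GCANNNNNNTGC", 32L))  # 4096
#' expectedSiteSpacing("GGGAC")                                     # 512
#' @export
expectedSiteSpacing <- function(enzyme) {
    pattern <- if (is(enzyme, "TypeIIBEnzyme")) enzyme@pattern else enzyme
    p <- siteProbability(pattern)
    if (isPalindromic(pattern)) 1 / p else 1 / (2 * p)
}

#' Probability that a given fragment occurs in a genome
#'
#' Probability that one particular k-bp sequence occurs one or more times
#' in a random genome of length L (single-strand occurrence model,
#' independent positions): `1 - (1 - 4^-k)^L`.
#'
#' @param k Fragment length in bp (`k >= 1`).
#' @param L Genome length in bp (`L >= k`).
#' @return Probability in (0, 1].
#' @examples
#' fragmentOccurrenceProbability(21, 1.5e8)  # ~3.41e-5, i.e. 0.00341%
#' @export
fragmentOccurrenceProbability <- function(k, L) {
    if (any(k < 1)) stop("k must be >= 1")
    if (any(L < k)) stop("L must be >= k")
    -expm1(L * log1p(-4^(-k)))
}

#' Construct a Type IIB enzyme
#'
#' Builds a validated [TypeIIBEnzyme-class]. When the flank lengths (the
#' number of bases the enzyme excises on each side of its recognition site)
#' are not given, the blunt length minus the pattern length is split
#' symmetrically, the left flank taking the extra base when it is odd.
#'
#' @param name Enzyme name.
#' @param pattern Recognition pattern (IUPAC codes).
#' @param bluntLength Blunt fragment length in bp.
#' @param leftFlank,rightFlank Optional explicit flank lengths in bp; both
#'   or neither must be supplied.
#' @return A [TypeIIBEnzyme-class] object.
#' @examples
#' TypeIIBEnzyme("AlfI", "GCANNNNNNTGC", 32L)
#' @export
TypeIIBEnzyme <- function(name, pattern, bluntLength,
                          leftFlank = NULL, rightFlank = NULL) {
    p <- parseIupacPattern(pattern)
    bluntLength <- as.integer(bluntLength)
    npat <- length(p$positions)
    if (is.null(leftFlank) != is.null(rightFlank))
        stop("supply both leftFlank and rightFlank, or neither")
    if (is.null(leftFlank)) {
        spare <- bluntLength - npat
        if (spare < 0)
            stop(sprintf("bluntLength (%d) shorter than pattern (%d)",
                bluntLength, npat))
        leftFlank <- as.integer(ceiling(spare / 2))
        rightFlank <- spare - leftFlank
    }
    new("TypeIIBEnzyme", name = as.character(name), pattern = p$pattern,
        bluntLength = bluntLength, leftFlank = as.integer(leftFlank),
        rightFlank = as.integer(rightFlank))
}

#' Read an enzyme definition table
#'
#' Reads a tab-separated enzyme table with header columns `name`,
#' `recognition`, `blunt_length` and optional `left_flank` / `right_flank`
#' overrides (leave empty for the symmetric default split).
#'
#' @param path Path to the TSV file.
#' @return Named list of [TypeIIBEnzyme-class] objects.
#' @seealso [typeIIBEnzymes()] for the built-in table.
#' @export
readEnzymeTable <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("name", "recognition", "blunt_length")
    if (!all(need %in% names(tab)))
        stop("enzyme table must have columns name, recognition, blunt_length")
    out <- lapply(seq_len(nrow(tab)), function(i) {
        lf <- if ("left_flank" %in% names(tab)) tab$left_flank[i] else NA
        rf <- if ("right_flank" %in% names(tab)) tab$right_flank[i] else NA
        if (is.na(lf) || is.na(rf)) lf <- rf <- NULL
        TypeIIBEnzyme(tab$name[i], tab$recognition[i], tab$blunt_length[i],
            leftFlank = lf, rightFlank = rf)
    })
    names(out) <- tab$name
    out
}

#' Built-in Type IIB enzyme set
#'
#' The 13 commercially characterized Type IIB enzymes shipped with the
#' package (AlfI, AloI, BaeI, BcgI, BplI, BsaXI, BslFI, Bsp24I, CspCI,
#' FalI, HaeIV, PpiI, PsrI), each with its recognition pattern and blunt
#' fragment length.
#'
#' @param names Optional character vector restricting the result to a
#'   subset of enzymes (error if unknown).
#' @return Named list of [TypeIIBEnzyme-class] objects.
#' @examples
#' sapply(typeIIBEnzymes(), expectedSiteSpacing)
#' @export
typeIIBEnzymes <- function(names = NULL) {
    path <- system.file("extdata", "type2b_enzymes.tsv", package = "rad2b",
        mustWork = TRUE)
    enz <- readEnzymeTable(path)
    if (!is.null(names)) {
        miss <- setdiff(names, base::names(enz))
        if (length(miss))
            stop("unknown enzyme(s): ", paste(miss, collapse = ", "))
        enz <- enz[names]
    }
    enz
}
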