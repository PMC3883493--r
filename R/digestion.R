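#' Read a genome assembly from FASTA
#'
#' Reads a (multi-)FASTA file into a `DNAStringSet`, upper-casing soft-masked
#' bases and keeping only the first whitespace-delimited token of each
#' description line as the contig id. Contig ids must be unique.
#'
#' @param path Path to the FASTA file.
#' @return A [Biostrings::DNAStringSet] of contigs.
#' @export
readGenome <- function(path) {
    gen <- Biostrings::readDNAStringSet(path)
    if (!length(gen)) stop("no sequences found in ", path)
    names(gen) <- sub("\\s.*$", "", names(gen))
    if (any(!nzchar(names(gen)))) stop("empty contig id in ", path)
    if (anyDuplicated(names(gen)))
        stop("duplicate contig ids in ", path)
    gen
}

.as_contig_string <- function(contig) {
    if (is(contig, "DNAString") || is(contig, "DNAStringSet"))
        contig <- as.character(contig)
    toupper(contig)
}

# Match positions (1-based starts) of an IUPAC pattern on the forward
# strand; ambiguous genome bases never match because any matched window
# containing a non-ACGT character is discarded.
.match_starts <- function(pattern, subject) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject,
        fixed = "subject")
    st <- BiocGenerics::start(m)
    if (length(st)) {
        seqs <- as.character(m)
        st <- st[!grepl("[^ACGT]", seqs)]
    }
    st
}

#' Locate Type IIB recognition sites on both strands
#'
#' Scans a contig for occurrences of an enzyme's recognition pattern on the
#' forward strand (strand `+`) and, for non-palindromic enzymes, of its
#' reverse complement (reported as strand `-`). Pattern IUPAC codes match
#' their base sets; ambiguous genome bases (N and friends) match nothing.
#' Palindromic enzymes report each double-stranded site once, as `+`.
#'
#' @param contig Contig sequence: a string, `DNAString`, or length-one
#'   `DNAStringSet`.
#' @param enzyme A [TypeIIBEnzyme-class] object.
#' @return `data.frame` with columns `position` (0-based start of the
#'   recognition site on the forward strand) and `strand` (`"+"`/`"-"`),
#'   ordered by position.
#' @examples
#' bslfi <- typeIIBEnzymes("BslFI")[[1]]
#' findSites("TTGGGACTT", bslfi)
#' @export
findSites <- function(contig, enzyme) {
    stopifnot(is(enzyme, "TypeIIBEnzyme"))
    s <- .as_contig_string(contig)
    subject <- Biostrings::DNAString(s)
    fwd <- .match_starts(enzyme@pattern, subject)
    pos <- fwd - 1L
    strand <- rep("+", length(fwd))
    if (!isPalindromic(enzyme@pattern)) {
        rev <- .match_starts(reverseComplementPattern(enzyme@pattern),
            subject)
        pos <- c(pos, rev - 1L)
        strand <- c(strand, rep("-", length(rev)))
    }
    ord <- order(pos, strand)
    data.frame(position = pos[ord], strand = strand[ord],
        stringsAsFactors = FALSE)
}

#' Canonical (strand-collapsed) form of fragment sequences
#'
#' The canonical form of a fragment is the lexicographic minimum of the
#' sequence and its reverse complement, so that homologous fragments read
#' from either strand compare equal.
#'
#' @param x Character vector of ACGT-only sequences.
#' @return Character vector of canonical sequences.
#' @examples
#' canonicalSequence(c("TTTT", "AAAA"))
#' @export
canonicalSequence <- function(x) {
    if (!length(x)) return(character())
    if (any(grepl("[^ACGT]", x)))
        stop("canonicalSequence requires ACGT-only sequences")
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(x)))
    ifelse(x <= rc, x, rc)
}

#' Extract predicted 2b-RAD fragments from one contig
#'
#' For every recognition site the blunt fragment window is cut out of the
#' forward strand: `[p - leftFlank, p + patternLength + rightFlank)` for a
#' `+` site at 0-based position `p`, with the flanks swapped for a `-`
#' site. Windows running past either contig end and windows containing any
#' non-ACGT character are dropped. The fragment sequence is reported 5'->3'
#' on the strand of the recognition site (i.e. reverse-complemented for
#' `-` sites) together with its canonical form.
#'
#' @param contig Contig sequence (string, `DNAString`, or length-one
#'   `DNAStringSet`).
#' @param enzyme A [TypeIIBEnzyme-class] object.
#' @param contigId Optional contig id recorded in the provenance columns.
#' @return `data.frame` with columns `sequence`, `canonical`, `contig`,
#'   `start` (0-based forward-strand start of the window) and `strand`.
#' @examples
#' alfi <- typeIIBEnzymes("AlfI")[[1]]
#' win <- paste0(strrep("A", 10), "GCA", strrep("T", 6), "TGC",
#'               strrep("C", 10))
#' extractFragments(win, alfi)
#' @export
extractFragments <- function(contig, enzyme, contigId = NA_character_) {
    stopifnot(is(enzyme, "TypeIIBEnzyme"))
    s <- .as_contig_string(contig)
    sites <- findSites(s, enzyme)
    empty <- data.frame(sequence = character(), canonical = character(),
        contig = character(), start = integer(), strand = character(),
        stringsAsFactors = FALSE)
    if (!nrow(sites)) return(empty)
    npat <- nchar(enzyme@pattern)
    lf <- ifelse(sites$strand == "+", enzyme@leftFlank, enzyme@rightFlank)
    rf <- ifelse(sites$strand == "+", enzyme@rightFlank, enzyme@leftFlank)
    win_start <- sites$position - lf              # 0-based inclusive
    win_end <- sites$position + npat + rf         # 0-based exclusive
    keep <- win_start >= 0L & win_end <= nchar(s)
    sites <- sites[keep, , drop = FALSE]
    win_start <- win_start[keep]
    win_end <- win_end[keep]
    if (!nrow(sites)) return(empty)
    seqs <- substring(s, win_start + 1L, win_end)
    keep <- !grepl("[^ACGT]", seqs)
    sites <- sites[keep, , drop = FALSE]
    win_start <- win_start[keep]
    seqs <- seqs[keep]
    if (!length(seqs)) return(empty)
    minus <- sites$strand == "-"
    if (any(minus))
        seqs[minus] <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(seqs[minus])))
    data.frame(sequence = seqs, canonical = canonicalSequence(seqs),
        contig = rep(as.character(contigId), length(seqs)),
        start = win_start, strand = sites$strand, stringsAsFactors = FALSE)
}

#' Digest a whole genome in silico
#'
#' Runs [extractFragments()] over every contig of a genome and aggregates
#' the result as a multiset of canonical fragment sequences with copy
#' counts. Deterministic given its input.
#'
#' @param genome A `DNAStringSet` of contigs (see [readGenome()]), or a
#'   named character vector of contig sequences.
#' @param enzyme A [TypeIIBEnzyme-class] object.
#' @return Named integer vector: canonical sequence -> copy count, sorted
#'   by sequence.
#' @examples
#' bslfi <- typeIIBEnzymes("BslFI")[[1]]
#' g <- Biostrings::DNAStringSet(c(chr1 = strrep("TTTAGGGACGATTCAA", 20)))
#' head(digestGenome(g, bslfi))
#' @export
digestGenome <- function(genome, enzyme) {
    if (is(genome, "DNAStringSet")) genome <- as.character(genome)
    if (!length(genome) || all(!nzchar(genome)))
        stop("empty genome")
    frags <- unlist(lapply(seq_along(genome), function(i) {
        extractFragments(genome[[i]], enzyme,
            contigId = if (!is.null(names(genome))) names(genome)[i]
                       else NA_character_)$canonical
    }), use.names = FALSE)
    if (!length(frags)) return(structure(integer(), names = character()))
    tab <- table(frags)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
    counts[order(names(counts))]
}
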