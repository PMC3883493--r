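# Internal integer encoding of bases: 1=A, 2=C, 3=G, 4=T.
.BASE_CHARS <- c("A", "C", "G", "T")
.BASE_CODES <- utf8ToInt("ACGT")

.ints_to_dna <- function(ints) intToUtf8(.BASE_CODES[ints])

.dna_to_ints <- function(x) {
    ints <- match(utf8ToInt(x), .BASE_CODES)
    if (anyNA(ints)) stop("sequence contains non-ACGT characters")
    ints
}

#' Random genome with a prescribed GC content
#'
#' Draws i.i.d. bases with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1-gc)/2`.
#'
#' @param length Genome length in bp (`>= 1`).
#' @param gc GC fraction, strictly between 0 and 1 (default 0.42, typical
#'   of a *Drosophila*-sized insect genome).
#' @param seed Optional integer seed for reproducibility.
#' @return A one-contig `DNAStringSet` named `"chr1"`.
#' @examples
#' g <- randomGenome(1000, gc = 0.42, seed = 1)
#' @export
randomGenome <- function(length, gc = 0.42, seed = NULL) {
    if (length < 1) stop("length must be >= 1")
    if (!is.numeric(gc) || gc <= 0 || gc >= 1)
        stop("gc must lie strictly between 0 and 1")
    if (!is.null(seed)) set.seed(seed)
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    ints <- sample.int(4L, size = length, replace = TRUE, prob = p)
    Biostrings::DNAStringSet(structure(.ints_to_dna(ints),
        names = "chr1"))
}

# Substitute sites of an integer-coded sequence along one branch under
# JC69: each site changes with probability 3/4 (1 - exp(-4 b / 3)), the
# new base uniform over the three alternatives.
.evolve_branch <- function(ints, b) {
    if (b < 0) stop("branch lengths must be >= 0")
    if (b == 0) return(ints)
    p <- 0.75 * (1 - exp(-4 * b / 3))
    hit <- which(runif(length(ints)) < p)
    if (length(hit))
        ints[hit] <- (ints[hit] - 1L +
            sample.int(3L, length(hit), replace = TRUE)) %% 4L + 1L
    ints
}

#' Evolve a root genome along a known tree
#'
#' Simulates Jukes-Cantor (JC69) substitution of every contig along each
#' branch of a tree whose branch lengths are expected substitutions per
#' site: a site substitutes with probability `3/4 (1 - exp(-4b/3))` on a
#' branch of length `b`, the replacement drawn uniformly from the three
#' alternative bases. No indels are introduced, so leaf genomes stay
#' positionally homologous to the root.
#'
#' @param root Root genome: a `DNAStringSet` (ACGT only).
#' @param tree A `phylo` tree or Newick string; every leaf must be
#'   labeled, branch lengths `>= 0`.
#' @param seed Optional integer seed.
#' @return Named list of `DNAStringSet` leaf genomes, in `tip.label`
#'   order.
#' @examples
#' root <- randomGenome(5000, seed = 1)
#' leaves <- evolveAlongTree(root, "((a:0.05,b:0.05):0.05,c:0.1);", seed = 2)
#' @export
evolveAlongTree <- function(root, tree, seed = NULL) {
    if (is.character(tree)) tree <- ape::read.tree(text = tree)
    if (is.null(tree$tip.label) || any(is.na(tree$tip.label)) ||
        any(!nzchar(tree$tip.label)))
        stop("every leaf of the tree must carry a label")
    if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
    if (is.null(tree$edge.length)) stop("tree must carry branch lengths")
    if (!is.null(seed)) set.seed(seed)
    if (is(root, "DNAStringSet")) root <- as.character(root)
    contigs <- lapply(root, .dna_to_ints)
    ntip <- length(tree$tip.label)
    rootNode <- ntip + 1L
    # preorder over edges so parents are always evolved first
    ord <- ape::reorder.phylo(tree, "cladewise")
    edges <- ord$edge
    lens <- ord$edge.length
    state <- vector("list", max(tree$edge))
    state[[rootNode]] <- contigs
    out <- vector("list", ntip)
    names(out) <- tree$tip.label
    for (k in seq_len(nrow(edges))) {
        parent <- edges[k, 1]
        child <- edges[k, 2]
        evolved <- lapply(state[[parent]], .evolve_branch, b = lens[k])
        if (child <= ntip) {
            out[[child]] <- Biostrings::DNAStringSet(structure(
                vapply(evolved, .ints_to_dna, character(1)),
                names = names(root)))
        } else {
            state[[child]] <- evolved
        }
    }
    out
}

#' Simulate leaf genomes on a known phylogeny
#'
#' Convenience wrapper: draws a random root genome ([randomGenome()]) and
#' evolves it along the given tree ([evolveAlongTree()]). Identical seeds
#' and arguments give byte-identical genomes.
#'
#' @param tree `phylo` or Newick string with branch lengths in expected
#'   substitutions per site.
#' @param rootLength Root genome length in bp; must be at least ten times
#'   the largest blunt fragment length of the built-in enzymes (330 bp).
#' @param gc Root GC fraction (default 0.42).
#' @param seed Optional integer seed governing both the root draw and the
#'   substitutions.
#' @return List with elements `genomes` (named list of `DNAStringSet`) and
#'   `tree` (the `phylo` used).
#' @examples
#' sim <- simulateGenomes("((a:0.02,b:0.02):0.02,c:0.04);",
#'                        rootLength = 10000, seed = 1)
#' @export
simulateGenomes <- function(tree, rootLength = 2e6, gc = 0.42,
                            seed = NULL) {
    if (rootLength < 330)
        stop("rootLength must be >= 330 (10 x the largest blunt length)")
    if (is.character(tree)) tree <- ape::read.tree(text = tree)
    if (!is.null(seed)) set.seed(seed)
    root <- randomGenome(rootLength, gc = gc)
    genomes <- evolveAlongTree(root, tree)
    list(genomes = genomes, tree = tree)
}

#' Write simulated genomes to FASTA plus a manifest
#'
#' Writes one FASTA file per leaf genome and a small JSON-like manifest
#' (plain text) echoing the true tree, for use by external tools.
#'
#' @param sim Result of [simulateGenomes()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the FASTA paths, invisibly.
#' @export
writeSimulatedGenomes <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(names(sim$genomes), function(taxon) {
        p <- file.path(dir, paste0(taxon, ".fasta"))
        Biostrings::writeXStringSet(sim$genomes[[taxon]], p)
        p
    }, character(1))
    writeLines(sprintf('{"tree": "%s"}',
        ape::write.tree(sim$tree)), file.path(dir, "manifest.json"))
    invisible(paths)
}
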