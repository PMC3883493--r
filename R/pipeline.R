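#' Run the full 2b-RAD phylogeny workflow
#'
#' Executes the complete pipeline for a set of genomes: in-silico digestion
#' with every requested enzyme ([digestGenome()]), reduction to
#' representative fragment sets ([buildRepresentativeSet()]), pairwise
#' shared-fragment counting ([countShared()]), log-ratio distance matrices
#' ([buildDistanceMatrix()]), one neighbor-joining tree per enzyme
#' ([neighborJoining()]), and the majority-rule consensus with per-branch
#' enzyme support ([majorityConsensus()]).
#'
#' @param genomes Named list of genomes (`DNAStringSet` or named character
#'   vectors of contigs); names are the taxon ids. At least 3 genomes.
#' @param enzymes Named list of [TypeIIBEnzyme-class] objects (default all
#'   13 built-ins, [typeIIBEnzymes()]).
#' @param maxMismatch Mismatch tolerance for similar fragments (default 5).
#' @param familyRadius Within-genome fragment-family radius (default 2).
#' @param cap Distance cap for pairs sharing nothing (default 30).
#' @param verbose Emit per-stage progress messages.
#' @return List with elements `fragmentSets` (enzyme -> taxon ->
#'   [FragmentSet-class]), `matrices` (enzyme -> [FragmentDistances-class]),
#'   `trees` (enzyme -> `phylo`), and `consensus`
#'   ([ConsensusTree-class]).
#' @examples
#' \donttest{
#' sim <- simulateGenomes("((a:0.03,b:0.03):0.03,(c:0.03,d:0.03):0.03);",
#'                        rootLength = 2e5, seed = 1)
#' res <- radPhylogeny(sim$genomes, typeIIBEnzymes(c("BslFI", "HaeIV")))
#' res$consensus
#' }
#' @export
radPhylogeny <- function(genomes, enzymes = typeIIBEnzymes(),
                         maxMismatch = 5L, familyRadius = 2L, cap = 30,
                         verbose = FALSE) {
    if (is.null(names(genomes)) || any(!nzchar(names(genomes))))
        stop("genomes must be a named list (taxon ids as names)")
    if (anyDuplicated(names(genomes))) stop("duplicate taxon ids")
    if (length(genomes) < 3L) stop("need at least 3 genomes")
    if (is(enzymes, "TypeIIBEnzyme")) enzymes <- list(enzymes)
    if (is.null(names(enzymes)))
        names(enzymes) <- vapply(enzymes, function(e) e@name, character(1))
    taxaIds <- names(genomes)
    pairIdx <- utils::combn(length(taxaIds), 2)
    fragmentSets <- list()
    matrices <- list()
    trees <- list()
    for (enzName in names(enzymes)) {
        enz <- enzymes[[enzName]]
        sets <- lapply(taxaIds, function(tx) {
            raw <- digestGenome(genomes[[tx]], enz)
            buildRepresentativeSet(raw, enz, tx,
                familyRadius = familyRadius)
        })
        names(sets) <- taxaIds
        if (verbose)
            message(sprintf("%s: %s representative fragments", enzName,
                paste(vapply(sets, function(s)
                    length(s@representatives), integer(1)),
                    collapse = "/")))
        counts <- lapply(seq_len(ncol(pairIdx)), function(k) {
            countShared(sets[[pairIdx[1, k]]], sets[[pairIdx[2, k]]],
                maxMismatch = maxMismatch)
        })
        m <- buildDistanceMatrix(counts, taxaIds, cap = cap)
        fragmentSets[[enzName]] <- sets
        matrices[[enzName]] <- m
        trees[[enzName]] <- neighborJoining(m)
    }
    consensus <- majorityConsensus(trees)
    list(fragmentSets = fragmentSets, matrices = matrices, trees = trees,
        consensus = consensus)
}
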