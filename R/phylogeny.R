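#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomerative neighbor joining: the pair of clusters minimizing
#' the Q-criterion `(r-2) d(i,j) - R_i - R_j` is joined, branch lengths to
#' the new node follow the two-point formulas, the matrix is reduced, and
#' the last three clusters are resolved with the closed-form star lengths.
#' On an additive matrix this recovers the generating tree exactly.
#' Determinism: ties in Q are broken by the lexicographic order of the
#' joined clusters' smallest leaf labels. Negative branch lengths (possible
#' on non-additive input) are clamped to zero with the deficit transferred
#' to the sibling branch; a message is emitted when this happens.
#'
#' @param m A [FragmentDistances-class], or a symmetric numeric matrix with
#'   dimnames.
#' @return An unrooted `phylo` tree with branch lengths in the input
#'   distance units.
#' @examples
#' m <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' neighborJoining(m)
#' @export
neighborJoining <- function(m) {
    if (is(m, "FragmentDistances")) {
        D <- m@values
        labs <- m@labels
    } else {
        D <- as.matrix(m)
        labs <- rownames(D)
        if (is.null(labs)) stop("matrix must carry taxon names as dimnames")
    }
    n <- nrow(D)
    if (n < 3L) stop("neighbor joining needs at least 3 taxa")
    if (anyDuplicated(labs)) stop("duplicate taxon labels")
    clamped <- FALSE
    nwk <- labs        # growing Newick substring per active cluster
    minleaf <- labs    # smallest leaf label per cluster, for tie-breaking
    while (nrow(D) > 3L) {
        r <- nrow(D)
        R <- rowSums(D)
        Q <- (r - 2) * D - outer(R, R, "+")
        diag(Q) <- Inf
        qmin <- min(Q)
        tol <- 1e-12 * max(1, abs(qmin))
        cand <- which(Q <= qmin + tol, arr.ind = TRUE)
        cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
        keys <- apply(cand, 1L, function(ij)
            paste(sort(minleaf[ij]), collapse = "\r"))
        pick <- cand[order(keys)[1L], ]
        i <- pick[[1]]; j <- pick[[2]]
        li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
        lj <- D[i, j] - li
        if (li < 0) { lj <- lj + li; li <- 0; clamped <- TRUE }
        if (lj < 0) { li <- max(0, li + lj); lj <- 0; clamped <- TRUE }
        nwk_new <- sprintf("(%s:%.15g,%s:%.15g)", nwk[i], li, nwk[j], lj)
        dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
        keep <- setdiff(seq_len(r), c(i, j))
        D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
            c(dnew[keep], 0))
        nwk <- c(nwk[keep], nwk_new)
        minleaf <- c(minleaf[keep], min(minleaf[c(i, j)]))
    }
    la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    if (la < 0) { lb <- lb + la; la <- 0; clamped <- TRUE }
    if (lb < 0) { lc <- lc + lb; lb <- 0; clamped <- TRUE }
    if (lc < 0) { la <- max(0, la + lc); lc <- 0; clamped <- TRUE }
    if (clamped)
        message("neighborJoining: negative branch length(s) clamped to 0")
    text <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
        nwk[1], la, nwk[2], lb, nwk[3], lc)
    ape::read.tree(text = text)
}

# Non-trivial leaf bipartitions of an unrooted tree, as canonical keys:
# each split is represented by the side NOT containing the reference leaf
# (the alphabetically first label), its members sorted and joined by "|".
.tree_splits <- function(tree) {
    tree <- ape::unroot(tree)
    tips <- tree$tip.label
    n <- length(tips)
    ref <- sort(tips)[1]
    pp <- ape::prop.part(tree)
    keys <- character()
    for (clade in pp) {
        side <- tips[clade]
        if (ref %in% side) side <- setdiff(tips, side)
        if (length(side) >= 2L && length(side) <= n - 2L)
            keys <- c(keys, paste(sort(side), collapse = "|"))
    }
    unique(keys)
}

.check_same_leaves <- function(trees) {
    ref <- sort(trees[[1]]$tip.label)
    for (t in trees) {
        lbl <- sort(t$tip.label)
        if (!identical(lbl, ref))
            stop("trees must share an identical leaf set")
    }
    ref
}

#' Robinson-Foulds distance between two trees
#'
#' Number of non-trivial leaf bipartitions present in exactly one of the
#' two trees; 0 if and only if the unrooted topologies agree.
#'
#' @param a,b `phylo` trees on the identical leaf set.
#' @return Non-negative integer.
#' @examples
#' t1 <- ape::read.tree(text = "((A,B),(C,D));")
#' t2 <- ape::read.tree(text = "((A,C),(B,D));")
#' robinsonFoulds(t1, t2)  # 2
#' @export
robinsonFoulds <- function(a, b) {
    .check_same_leaves(list(a, b))
    sa <- .tree_splits(a)
    sb <- .tree_splits(b)
    length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

# Recursively assemble a Newick string from a laminar family of splits.
# `sets` is a list of character vectors (members), `counts` parallel
# integer support counts; all sets are subsets of `members`.
.assemble_newick <- function(members, sets, counts) {
    strict_subset <- function(a, b) length(a) < length(b) && all(a %in% b)
    maximal <- vapply(seq_along(sets), function(k)
        !any(vapply(sets, strict_subset, logical(1), a = sets[[k]])),
        logical(1))
    covered <- character()
    parts <- character()
    idx <- which(maximal)
    if (length(idx)) {
        ord <- idx[order(-vapply(sets[idx], length, integer(1)),
            vapply(sets[idx], function(s) paste(sort(s), collapse = "|"),
                character(1)))]
        for (k in ord) {
            s <- sets[[k]]
            inner <- vapply(sets, function(x)
                all(x %in% s) && length(x) < length(s), logical(1))
            parts <- c(parts, sprintf("(%s)%d",
                .assemble_newick(s, sets[inner], counts[inner]), counts[k]))
            covered <- c(covered, s)
        }
    }
    loose <- sort(setdiff(members, covered))
    paste(c(parts, loose), collapse = ",")
}

#' Majority-rule consensus with per-branch tree support
#'
#' Decomposes every input tree into its non-trivial leaf bipartitions,
#' retains exactly the splits present in more than half of the trees
#' (strict majority rule) -- such splits are pairwise compatible and
#' assemble into a single tree -- and annotates every retained branch with
#' the number of supporting trees and the corresponding percentage.
#' Consensus branches carry no lengths.
#'
#' @param trees List (or `multiPhylo`) of `phylo` trees on the identical
#'   leaf set.
#' @return A [ConsensusTree-class].
#' @examples
#' ts <- list(ape::read.tree(text = "((A,B),(C,D),E);"),
#'            ape::read.tree(text = "((A,B),(C,E),D);"),
#'            ape::read.tree(text = "((A,B),(C,D),E);"))
#' majorityConsensus(ts)
#' @export
majorityConsensus <- function(trees) {
    if (inherits(trees, "phylo")) trees <- list(trees)
    trees <- unclass(trees)
    if (!length(trees)) stop("need at least one tree")
    leaves <- .check_same_leaves(trees)
    nT <- length(trees)
    tab <- table(unlist(lapply(trees, .tree_splits)))
    keep <- names(tab)[as.integer(tab) * 2L > nT]
    counts <- as.integer(tab[keep])
    sets <- strsplit(keep, "|", fixed = TRUE)
    inner <- .assemble_newick(leaves, sets, counts)
    tree <- ape::read.tree(text = sprintf("(%s);", inner))
    smaller_side <- function(s) {
        comp <- setdiff(leaves, s)
        if (length(comp) < length(s)) comp else s
    }
    support <- data.frame(
        clade = vapply(sets, function(s)
            paste(sort(smaller_side(s)), collapse = ","), character(1)),
        count = counts,
        percent = 100 * counts / nT,
        stringsAsFactors = FALSE)
    support <- support[order(-support$count, support$clade), , drop = FALSE]
    rownames(support) <- NULL
    new("ConsensusTree", tree = tree, support = support,
        nTrees = as.integer(nT))
}

#' Write / read trees in Newick format
#'
#' Thin wrappers around [ape::write.tree()] and [ape::read.tree()].
#' `writeNewick()` accepts a `phylo` or a [ConsensusTree-class] (whose
#' support counts are written as internal node labels). `readNewick()`
#' first checks the parenthesis structure and reports the character offset
#' of the first imbalance.
#'
#' @param tree A `phylo` or [ConsensusTree-class].
#' @param path File path.
#' @return `writeNewick()` the path, invisibly; `readNewick()` a `phylo`
#'   (or `multiPhylo` when the file holds several trees).
#' @export
writeNewick <- function(tree, path) {
    if (is(tree, "ConsensusTree")) tree <- tree@tree
    if (!inherits(tree, c("phylo", "multiPhylo")))
        stop("tree must be a phylo, multiPhylo or ConsensusTree")
    ape::write.tree(tree, file = path, digits = 10)
    invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) {
    text <- paste(readLines(path, warn = FALSE), collapse = "\n")
    depth <- 0L
    chars <- strsplit(text, "", fixed = TRUE)[[1]]
    for (k in seq_along(chars)) {
        if (chars[k] == "(") depth <- depth + 1L
        if (chars[k] == ")") {
            depth <- depth - 1L
            if (depth < 0L)
                stop("Newick parse error: unmatched ')' at character ", k)
        }
    }
    if (depth != 0L)
        stop("Newick parse error: ", depth,
            " unclosed '(' at end of input (character ", length(chars), ")")
    out <- tryCatch(ape::read.tree(text = text),
        error = function(e) stop("Newick parse error: ",
            conditionMessage(e)))
    if (is.null(out)) stop("Newick parse error: no tree found")
    out
}
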