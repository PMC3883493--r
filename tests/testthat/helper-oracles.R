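# Independent brute-force oracles, kept deliberately separate from the
# package implementation: plain string/linear-algebra routes used to verify
# the optimized paths.

o_revcomp <- function(x) {
    vapply(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE),
        function(ch) paste(rev(ch), collapse = ""), character(1))
}

o_hamming <- function(a, b) {
    ca <- strsplit(a, "", fixed = TRUE)[[1]]
    cb <- strsplit(b, "", fixed = TRUE)[[1]]
    stopifnot(length(ca) == length(cb))
    sum(ca != cb)
}

o_canonical <- function(x) {
    rc <- o_revcomp(x)
    ifelse(x <= rc, x, rc)
}

# n distinct random ACGT sequences of length L
r_frags <- function(n, L) {
    out <- character(0)
    while (length(out) < n) {
        new <- vapply(seq_len(n - length(out)), function(i)
            paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                collapse = ""), character(1))
        out <- unique(c(out, new))
    }
    out
}

# FragmentSet constructor bypassing the pipeline (sequences must be
# distinct and same-length)
make_set <- function(seqs, taxon = "x", enzyme = "enz") {
    new("FragmentSet", taxon = taxon, enzyme = enzyme,
        fragmentLength = if (length(seqs)) nchar(seqs[1]) else 0L,
        representatives = seqs,
        stats = c(singleCopy = length(seqs), multiCopy = 0L,
            familyRemoved = 0L))
}

# one-hot encoding: (4L x n) 0/1 matrix, one column per sequence
o_onehot <- function(seqs) {
    L <- nchar(seqs[1])
    ints <- vapply(strsplit(seqs, "", fixed = TRUE),
        function(ch) match(ch, c("A", "C", "G", "T")), integer(L))
    ints <- matrix(ints, nrow = L)
    M <- matrix(0, 4 * L, length(seqs))
    for (j in seq_along(seqs))
        M[(seq_len(L) - 1L) * 4L + ints[, j], j] <- 1
    M
}

# all-pairs Hamming distances via agreement counts (L - one-hot inner
# product); rows = a, cols = b
o_cross_hamming <- function(a, b) {
    L <- nchar(a[1])
    L - crossprod(o_onehot(a), o_onehot(b))
}

# brute-force shared-fragment counting in both directions
o_count_shared <- function(a, b, mm) {
    if (!length(a) || !length(b))
        return(c(identical = 0L, similar = 0L))
    dp_ab <- o_cross_hamming(a, b)
    dr_ab <- o_cross_hamming(a, o_revcomp(b))
    id_a <- apply(dp_ab == 0, 1, any)
    sim_a <- !id_a & apply(pmin(dp_ab, dr_ab) <= mm, 1, any)
    id_b <- apply(dp_ab == 0, 2, any)
    sim_b <- !id_b & apply(pmin(t(dp_ab), o_cross_hamming(b, o_revcomp(a)))
        <= mm, 1, any)
    c(identical = sum(id_a) + sum(id_b), similar = sum(sim_a) + sum(sim_b))
}

# brute-force within-set family detection
o_has_neighbor <- function(seqs, radius) {
    n <- length(seqs)
    out <- logical(n)
    if (n < 2) return(out)
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
        if (o_hamming(seqs[i], seqs[j]) <= radius) out[i] <- out[j] <- TRUE
    }
    out
}

# random unrooted tree with its additive (patristic) distance matrix
r_additive <- function(ntaxa) {
    tr <- ape::rtree(ntaxa, rooted = FALSE)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
    list(tree = tr, m = ape::cophenetic.phylo(tr))
}

# exhaustive least-squares topology search over all 15 unrooted 5-taxon
# topologies: fit branch lengths by OLS for each, return the minimal-RSS
# topology
o_best_topology5 <- function(m) {
    labs <- rownames(m)
    tops <- phangorn::allTrees(5, tip.label = labs)
    pairs <- t(combn(labs, 2))
    y <- m[cbind(pairs[, 1], pairs[, 2])]
    rss <- vapply(tops, function(tp) {
        ntip <- length(tp$tip.label)
        X <- vapply(seq_len(nrow(tp$edge)), function(e) {
            below <- phangorn::Descendants(tp, tp$edge[e, 2],
                "tips")[[1]]
            inC <- pairs[, 1] %in% tp$tip.label[below]
            jnC <- pairs[, 2] %in% tp$tip.label[below]
            as.numeric(xor(inC, jnC))
        }, numeric(nrow(pairs)))
        fit <- lm.fit(X, y)
        sum(fit$residuals^2)
    }, numeric(1))
    tops[[which.min(rss)]]
}
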