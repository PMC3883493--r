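test_that("three-taxon NJ uses the closed-form star lengths", {
    m <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
        dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
    tr <- neighborJoining(m)
    expect_equal(sort(tr$tip.label), c("a", "b", "c"))
    lens <- tr$edge.length[match(seq_along(tr$tip.label), tr$edge[, 2])]
    names(lens) <- tr$tip.label
    expect_equal(lens[["a"]], (3 + 4 - 5) / 2)
    expect_equal(lens[["b"]], (3 + 5 - 4) / 2)
    expect_equal(lens[["c"]], (4 + 5 - 3) / 2)
    expect_error(neighborJoining(m[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers a 4-taxon tree exactly from its additive matrix", {
    # quartet ((A,B),(C,D)) with leaf branches 0.1, 0.2, 0.3, 0.4 and
    # internal branch 0.25: distances are path lengths on that tree
    m <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    m["A", "B"] <- 0.1 + 0.2
    m["A", "C"] <- 0.1 + 0.25 + 0.3
    m["A", "D"] <- 0.1 + 0.25 + 0.4
    m["B", "C"] <- 0.2 + 0.25 + 0.3
    m["B", "D"] <- 0.2 + 0.25 + 0.4
    m["C", "D"] <- 0.3 + 0.4
    m <- m + t(m)
    tr <- neighborJoining(m)
    truth <- ape::read.tree(
        text = "((A:0.1,B:0.2):0.25,C:0.3,D:0.4);")
    expect_equal(robinsonFoulds(tr, truth), 0)
    cm <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
    expect_lt(max(abs(cm - m)), 1e-9)
})

test_that("NJ topology on an ultrametric matrix matches exhaustive LS", {
    skip_if_not_installed("phangorn")
    set.seed(13)
    for (rep in 1:5) {
        tr0 <- ape::rcoal(5)          # ultrametric 5-taxon tree
        tr0$edge.length <- tr0$edge.length + 0.05
        m <- ape::cophenetic.phylo(tr0)
        best <- o_best_topology5(m)
        tr <- neighborJoining(m)
        expect_equal(robinsonFoulds(tr, best), 0)
    }
})

test_that("NJ is consistent on random additive matrices", {
    skip_if_not_installed("phangorn")
    set.seed(101)
    for (rep in 1:20) {
        gen <- r_additive(sample(6:10, 1))
        tr <- neighborJoining(gen$m)
        expect_equal(robinsonFoulds(tr, gen$tree), 0)
        labs <- rownames(gen$m)
        expect_lt(max(abs(ape::cophenetic.phylo(tr)[labs, labs] -
            gen$m)), 1e-9)
        # independent route: ape's NJ agrees on the topology
        expect_equal(robinsonFoulds(tr, ape::nj(gen$m)), 0)
    }
})

test_that("negative branch lengths are clamped with deficit transfer", {
    # non-metric triangle: the closed-form star length for c is negative
    m <- matrix(c(0, 10, 1, 10, 0, 1, 1, 1, 0), 3,
        dimnames = list(letters[1:3], letters[1:3]))
    expect_message(tr <- neighborJoining(m), "clamped")
    expect_true(all(tr$edge.length >= 0))
})

test_that("majority-rule consensus keeps splits in more than half the trees", {
    t1 <- ape::read.tree(text = "(((A,B),C),(D,E));")
    t2 <- ape::read.tree(text = "(((A,B),D),(C,E));")
    t3 <- ape::read.tree(text = "(((A,C),B),(D,E));")
    cons <- majorityConsensus(list(t1, t2, t3))
    st <- supportTable(cons)
    # {A,B} appears in 2 of 3 trees; {D,E} in 2 of 3; {A,B,C} only in 1
    expect_setequal(st$clade, c("A,B", "D,E"))
    expect_equal(st$count, c(2L, 2L))
    expect_equal(st$percent, c(200 / 3, 200 / 3))
    # 13 copies of one topology: same topology, all supports 13 / 100%
    many <- rep(list(t1), 13)
    cons13 <- majorityConsensus(many)
    expect_equal(robinsonFoulds(cons13@tree, t1), 0)
    expect_true(all(supportTable(cons13)$count == 13))
    expect_true(all(supportTable(cons13)$percent == 100))
    expect_equal(nrow(supportTable(cons13)), 2)  # 5-taxon binary: 2 splits
    # a single tree is its own consensus at 100%
    cons1 <- majorityConsensus(list(t2))
    expect_equal(robinsonFoulds(cons1@tree, t2), 0)
    expect_true(all(supportTable(cons1)$percent == 100))
    # mismatched leaf sets are refused
    t4 <- ape::read.tree(text = "((A,B),(C,F),E);")
    expect_error(majorityConsensus(list(t1, t4)), "leaf set")
})

test_that("Robinson-Foulds agrees with an independent implementation", {
    skip_if_not_installed("phangorn")
    t1 <- ape::read.tree(text = "((A,B),(C,D));")
    t2 <- ape::read.tree(text = "((A,C),(B,D));")
    expect_equal(robinsonFoulds(t1, t1), 0)
    expect_equal(robinsonFoulds(t1, t2), 2)
    set.seed(55)
    for (rep in 1:10) {
        n <- sample(5:12, 1)
        a <- ape::rtree(n, rooted = FALSE)
        b <- ape::rtree(n, rooted = FALSE)
        b$tip.label <- sample(a$tip.label)
        expect_equal(robinsonFoulds(a, b),
            as.integer(phangorn::RF.dist(a, b)))
        expect_equal(robinsonFoulds(a, b), robinsonFoulds(b, a))
    }
    expect_error(robinsonFoulds(t1,
        ape::read.tree(text = "((A,B),(C,E));")), "leaf set")
})

test_that("Newick files round-trip through write/read", {
    p <- tempfile(fileext = ".nwk")
    writeLines("(A:1,B:1);", p)
    tr <- readNewick(p)
    expect_equal(sort(tr$tip.label), c("A", "B"))
    set.seed(66)
    big <- ape::rtree(21, rooted = FALSE)
    writeNewick(big, p)
    back <- readNewick(p)
    expect_equal(robinsonFoulds(big, back), 0)
    labs <- big$tip.label
    expect_lt(max(abs(ape::cophenetic.phylo(big)[labs, labs] -
        ape::cophenetic.phylo(back)[labs, labs])), 1e-6)
    # consensus supports survive serialization as node labels
    ts <- rep(list(ape::read.tree(text = "(((A,B),C),(D,E));")), 3)
    cons <- majorityConsensus(ts)
    writeNewick(cons, p)
    again <- readNewick(p)
    expect_equal(robinsonFoulds(again, cons@tree), 0)
    expect_setequal(setdiff(again$node.label, ""), "3")
    # malformed input is a parse error with a character offset
    writeLines("((A:1,B:1);", p)
    expect_error(readNewick(p), "unclosed")
    writeLines("(A:1,B:1));", p)
    expect_error(readNewick(p), "character 10")
})
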