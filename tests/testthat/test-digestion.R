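enz <- typeIIBEnzymes()

test_that("recognition sites are found on both strands, palindromes once", {
    bslfi <- enz$BslFI
    expect_equal(findSites("TTGGGACTT", bslfi),
        data.frame(position = 2L, strand = "+"))
    # reverse-complement site: oracle is a scan of the revcomp contig
    expect_equal(findSites("TTGTCCCTT", bslfi),
        data.frame(position = 2L, strand = "-"))
    contig <- "TTGTCCCTT"
    rc <- o_revcomp(contig)
    hit <- findSites(rc, bslfi)
    expect_equal(hit$strand, "+")
    expect_equal(hit$position, nchar(contig) - 5 - 2)
    # palindromic enzyme: one report per double-stranded site
    expect_equal(nrow(findSites("GCAAAAAAATGC", enz$AlfI)), 1)
    expect_equal(findSites("GCAAAAAAATGC", enz$AlfI)$strand, "+")
    # ambiguous genome bases match nothing, even against pattern N
    expect_equal(nrow(findSites("GCANAAAAATGC", enz$AlfI)), 0)
    expect_equal(nrow(findSites("TTGGNACTT", bslfi)), 0)
})

test_that("fragment windows respect geometry, boundaries and ambiguity", {
    alfi <- enz$AlfI
    win <- paste0(strrep("A", 10), "GCA", "TTTTTT", "TGC", strrep("C", 10))
    expect_equal(nchar(win), 32)
    fr <- extractFragments(win, alfi)
    expect_equal(nrow(fr), 1)
    expect_equal(nchar(fr$sequence), 32)
    expect_equal(fr$sequence, win)
    expect_equal(fr$start, 0L)
    # site too close to the contig start is dropped
    fr2 <- extractFragments(paste0("AAA", "GCA", "TTTTTT", "TGC",
        strrep("C", 10)), alfi)
    expect_equal(nrow(fr2), 0)
    # a window containing an N is dropped
    frN <- extractFragments(sub("CCCCCCCCCC$", "CCCCCCCCCN", win), alfi)
    expect_equal(nrow(frN), 0)
    # minus-strand fragments are reported 5'->3' on the site's strand
    bslfi <- enz$BslFI
    plus <- paste0("TTTTAAAA", "GGGAC", "AACCTTGG")
    stopifnot(nrow(findSites(plus, bslfi)) == 1)
    fp <- extractFragments(plus, bslfi)
    fm <- extractFragments(o_revcomp(plus), bslfi)
    expect_equal(fm$strand, "-")
    expect_equal(fm$sequence, fp$sequence)
})

test_that("canonical form is the lexicographic min of strand readings", {
    expect_equal(canonicalSequence("TTTT"), "AAAA")
    expect_equal(canonicalSequence("AAAA"), "AAAA")
    expect_error(canonicalSequence("ACGN"), "ACGT")
    set.seed(11)
    x <- r_frags(60, 27)
    expect_equal(canonicalSequence(x), o_canonical(x))
    expect_equal(canonicalSequence(o_revcomp(x)), canonicalSequence(x))
})

test_that("digestGenome aggregates canonical fragments with copy counts", {
    alfi <- enz$AlfI
    expect_error(digestGenome(character(), alfi), "empty")
    # genome without sites digests to an empty multiset
    expect_length(digestGenome(c(chr1 = strrep("AT", 100)), alfi), 0)
    # one window repeated three times -> a single canonical count of 3
    win <- paste0(strrep("A", 10), "GCA", "TTTTTT", "TGC", strrep("C", 10))
    set.seed(5)
    repeat {
        spacers <- vapply(1:4, function(i) paste(sample(c("A", "C", "G",
            "T"), 50, TRUE), collapse = ""), character(1))
        genome <- paste0(spacers[1], win, spacers[2], win, spacers[3],
            win, spacers[4])
        if (nrow(findSites(genome, alfi)) == 3) break
    }
    raw <- digestGenome(c(chr1 = genome), alfi)
    expect_length(raw, 1)
    expect_equal(unname(raw), 3L)
    expect_equal(names(raw), canonicalSequence(win))
})

test_that("canonical fragment multisets are strand-symmetric", {
    set.seed(21)
    g <- as.character(randomGenome(40000, gc = 0.5))
    names(g) <- "chr1"
    grc <- o_revcomp(g)
    names(grc) <- "chr1"
    for (e in enz[c("BslFI", "AlfI", "BaeI")]) {
        raw <- digestGenome(g, e)
        rawrc <- digestGenome(grc, e)
        expect_gt(sum(raw), 0)
        expect_identical(raw, rawrc)
    }
})

test_that("fragment yield on uniform sequence matches the expected spacing", {
    set.seed(31)
    L <- 5e6
    g <- as.character(randomGenome(L, gc = 0.5))
    for (e in enz[c("BslFI", "HaeIV")]) {
        raw <- digestGenome(g, e)
        expect_true(all(nchar(names(raw)) == e@bluntLength))
        expect_false(any(grepl("[^ACGT]", names(raw))))
        expected <- L / expectedSiteSpacing(e)
        expect_lt(abs(sum(raw) - expected), 3 * sqrt(expected))
    }
})
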