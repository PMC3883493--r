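test_that("pattern parsing validates IUPAC codes and reports degeneracies", {
    p <- parseIupacPattern("GCANNNNNNTGC")
    expect_length(p$positions, 12)
    expect_equal(sum(p$degeneracy == 1), 6)
    expect_equal(sum(p$degeneracy == 4), 6)

    p <- parseIupacPattern("ACNNNNGTAYC")
    expect_length(p$positions, 11)
    expect_equal(p$degeneracy[which(p$positions == "Y")], 2)

    expect_error(parseIupacPattern("GCAX"), "position 4")
    expect_error(parseIupacPattern(""), "non-empty")
})

test_that("pattern reverse complement follows the IUPAC complement map", {
    expect_equal(reverseComplementPattern("GGGAC"), "GTCCC")
    expect_equal(reverseComplementPattern("A"), "T")
    # oracle: complement map applied position-wise then reversed
    pats <- c("GAYNNNNNRTC", "GCANNNNNNTGC", "ACNNNNGTAYC", "CAANNNNNGTGG",
        "RYSWKMBDHVN")
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
        S = "S", W = "W", K = "M", M = "K", B = "V", V = "B", D = "H",
        H = "D", N = "N")
    for (p in pats) {
        oracle <- paste(rev(comp[strsplit(p, "")[[1]]]), collapse = "")
        expect_equal(reverseComplementPattern(p), oracle)
    }
    expect_equal(reverseComplementPattern("GAYNNNNNRTC"), "GAYNNNNNRTC")
})

test_that("palindromy is reverse-complement self-identity", {
    for (p in c("GCANNNNNNTGC", "AAGNNNNNCTT", "GAYNNNNNRTC", "GGGAC",
        "CAANNNNNGTGG")) {
        expect_identical(isPalindromic(p),
            identical(reverseComplementPattern(p), p))
        # palindromy is itself invariant under reverse complementation
        expect_identical(isPalindromic(p),
            isPalindromic(reverseComplementPattern(p)))
    }
})

test_that("site probability multiplies per-position degeneracy/4", {
    expect_equal(siteProbability("GGGAC"), (1 / 4)^5)
    expect_equal(siteProbability("ACNNNNGTAYC"), (1 / 4)^6 * 1 / 2)
    expect_equal(siteProbability("N"), 1)
    # invariant under reverse complementation
    for (p in c("GGGAC", "ACNNNNGTAYC", "GAYNNNNNRTC"))
        expect_equal(siteProbability(reverseComplementPattern(p)),
            siteProbability(p))
})

test_that("expected cut-site spacing halves for non-palindromic patterns", {
    alfi <- TypeIIBEnzyme("AlfI", "GCANNNNNNTGC", 32L)
    expect_equal(expectedSiteSpacing(alfi), 4096)
    expect_equal(expectedSiteSpacing("GGGAC"), 512)
    expect_equal(expectedSiteSpacing("GAYNNNNNRTC"), 1024)
})

test_that("fragment occurrence probability follows the one-strand model", {
    expect_equal(fragmentOccurrenceProbability(1, 1), 0.25)
    expect_equal(fragmentOccurrenceProbability(2, 2), 1 - (15 / 16)^2)
    # monotone increasing in L, decreasing in k
    expect_true(all(diff(fragmentOccurrenceProbability(21,
        c(1e6, 1e7, 1e8, 1e9))) > 0))
    expect_true(all(diff(vapply(20:30, fragmentOccurrenceProbability,
        numeric(1), L = 1e8)) < 0))
})

test_that("enzyme construction enforces the flank geometry invariant", {
    e <- TypeIIBEnzyme("BaeI", "ACNNNNGTAYC", 28L)
    expect_equal(e@leftFlank + nchar(e@pattern) + e@rightFlank,
        e@bluntLength)
    expect_equal(e@leftFlank, 9L)  # ceil((28 - 11) / 2)
    expect_equal(e@rightFlank, 8L)
    expect_error(TypeIIBEnzyme("x", "GGGAC", 4L), "shorter")
    expect_error(new("TypeIIBEnzyme", name = "x", pattern = "GGGAC",
        bluntLength = 21L, leftFlank = 5L, rightFlank = 5L),
        "bluntLength")
})

test_that("the shipped enzyme table round-trips through readEnzymeTable", {
    enz <- typeIIBEnzymes()
    expect_length(enz, 13)
    for (e in enz)
        expect_equal(e@leftFlank + nchar(e@pattern) + e@rightFlank,
            e@bluntLength)
    expect_equal(enzymeName(enz$BslFI), "BslFI")
    expect_error(typeIIBEnzymes("NoSuchEnzyme"), "unknown")
    # flank overrides are honoured
    tmp <- tempfile(fileext = ".tsv")
    writeLines(c("name\trecognition\tblunt_length\tleft_flank\tright_flank",
        "DemoI\tGGGAC\t21\t12\t4"), tmp)
    e <- readEnzymeTable(tmp)[[1]]
    expect_equal(c(e@leftFlank, e@rightFlank), c(12L, 4L))
})
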