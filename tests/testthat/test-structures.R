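test_that("dot-bracket parsing recovers pairs, pages and rejects bad input", {
    s <- parseDotBracket("((..[[..))..]]")
    expect_equal(structureLength(s), 14L)
    expect_equal(basePairs(s)[pairPages(s) == 1L, , drop = FALSE],
                 cbind(i = c(1L, 2L), j = c(10L, 9L)))
    expect_equal(basePairs(s)[pairPages(s) == 2L, , drop = FALSE],
                 cbind(i = c(5L, 6L), j = c(14L, 13L)))

    s2 <- parseDotBracket("(((...)))")
    expect_equal(unname(basePairs(s2)), cbind(1:3, 9:7))
    expect_true(all(pairPages(s2) == 1L))

    expect_error(parseDotBracket("((.))"), "j >= i \\+ 3")
    expect_error(parseDotBracket("(((...))"), "unbalanced")
    expect_error(parseDotBracket("((...)))"), "unbalanced")
    expect_error(parseDotBracket("((.{.}.))"), "illegal")
    expect_error(parseDotBracket("[..(..].)"), NA)  # cross-layer is fine
})

test_that("write/parse round-trip is the identity on random fixtures", {
    expect_equal(writeDotBracket(parseDotBracket("((..[[..))..]]")),
                 "((..[[..))..]]")
    expect_equal(writeDotBracket(pairedStructure(matrix(integer(0), 0, 2), 4L)),
                 "....")
    set.seed(11)
    for (k in 1:25) {
        s <- randomTwoPageStructure(sample(20:30, 1), sample(2:5, 1),
                                    sample(c(0L, 2L, 3L), 1))
        db <- dotBracket(s)
        expect_identical(writeDotBracket(parseDotBracket(db)), db)
    }
})

test_that("two-page split matches exhaustive 2-coloring and is canonical", {
    expect_equal(twoPageSplit(rbind(c(1, 4), c(5, 8)), 8), c(1L, 1L))
    expect_equal(twoPageSplit(rbind(c(1, 5), c(3, 8)), 8), c(1L, 2L))
    # odd crossing triangle: every one of the 2^3 colorings is improper
    tri <- list(c(1, 4), c(2, 5), c(3, 6))
    expect_length(oracleColorings(tri), 0L)
    expect_error(twoPageSplit(do.call(rbind, tri), 6),
                 class = "knotdesign_page_error")
    expect_false(isTwoPage(do.call(rbind, tri), 6))

    set.seed(21)
    for (k in 1:40) {
        n <- sample(10:16, 1)
        npairs <- sample(2:5, 1)
        pos <- sample(sort(sample(n, 2 * npairs)))
        prs <- lapply(seq_len(npairs), function(r)
            sort(pos[c(2 * r - 1, 2 * r)]))
        if (any(vapply(prs, function(p) p[2] < p[1] + 3, logical(1)))) next
        mat <- do.call(rbind, prs)
        canonical <- oracleCanonicalPages(prs)
        if (is.null(canonical)) {
            expect_false(isTwoPage(mat, n))
        } else {
            expect_equal(twoPageSplit(mat, n), canonical)
        }
    }
})

test_that("nested-only structures always land on a single page", {
    set.seed(5)
    for (k in 1:10) {
        s <- randomTwoPageStructure(sample(12:24, 1), sample(3:5, 1), 0L)
        expect_true(all(pairPages(s) == 1L))
        expect_true(isTwoPage(basePairs(s), structureLength(s)))
        expect_false(grepl("\\[", dotBracket(s)))
    }
})

test_that("structure matrix is the augmented indicator with unit row sums", {
    s <- parseDotBracket(".(...).")
    S <- structureMatrix(s)
    expect_equal(dim(S), c(7L, 8L))
    expect_equal(S[2, 6], 1L)
    expect_equal(S[6, 2], 1L)
    expect_equal(which(S[1, ] == 1L), 8L)
    expect_equal(rowSums(S), rep(1, 7))

    allUnpaired <- pairedStructure(matrix(integer(0), 0, 2), 3L)
    expect_equal(structureMatrix(allUnpaired)[, 4], rep(1L, 3))

    set.seed(31)
    for (k in 1:10) {
        s <- randomTwoPageStructure(sample(16:25, 1), sample(2:5, 1),
                                    sample(c(0L, 2L), 1))
        expect_equal(rowSums(structureMatrix(s)), rep(1, structureLength(s)))
    }
})

test_that("design templates validate length, alphabet and locked pairs", {
    hh <- hammerheadTarget()
    expect_equal(nchar(templateText(hh$template)), 85L)
    expect_equal(structureLength(hh$structure), 85L)
    expect_equal(substr(templateText(hh$template), 17, 25), "CCUGAUGAG")
    expect_equal(substr(templateText(hh$template), 41, 46), "GCGAAA")
    expect_equal(substr(templateText(hh$template), 69, 71), "UCG")

    tgt5 <- parseDotBracket(".....")
    expect_error(designTemplate("AAAA", tgt5), "length")
    expect_error(designTemplate("AToAA", tgt5), "T")

    tgt <- parseDotBracket("(((...)))")
    expect_error(designTemplate("GooooooooG" , tgt), "length")
    expect_error(designTemplate("GoooooooG", tgt), "not an allowed base pair")
    expect_s4_class(designTemplate("GoooooooC", tgt), "DesignTemplate")
})

test_that("pair compatibility honours the six allowed pairs", {
    tgt <- parseDotBracket("(((...)))")
    expect_true(isCompatible("GGGAAACCC", tgt))
    expect_false(isCompatible("AAAAAAAAA", tgt))
    expect_true(isCompatible("GGGAAAUUU", tgt))  # wobble
    expect_error(isCompatible("GGGAAACC", tgt), "length")
    expect_error(isCompatible("GGGATACCC", tgt), "T")
})
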