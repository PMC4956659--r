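test_that("seeds are pair-compatible, template-true and GC-controllable", {
    tgt <- parseDotBracket("(((...)))")
    set.seed(61)
    for (k in 1:30) {
        seed <- initializeSeed(tgt)
        expect_true(isCompatible(seed, tgt))
    }
    # locked motif is copied verbatim into every seed
    hh <- hammerheadTarget()
    for (k in 1:10) {
        seed <- initializeSeed(hh$structure, hh$template)
        expect_equal(substr(seed, 17, 25), "CCUGAUGAG")
        expect_equal(substr(seed, 41, 46), "GCGAAA")
        expect_equal(substr(seed, 69, 71), "UCG")
    }
    # GC fraction extremes on an all-unpaired target
    open10 <- pairedStructure(matrix(integer(0), 0, 2), 10L)
    expect_true(grepl("^[GC]+$", initializeSeed(open10, gcContent = 1)))
    expect_true(grepl("^[AU]+$", initializeSeed(open10, gcContent = 0)))
    # paired positions drawn jointly as pair types
    s0 <- initializeSeed(tgt, gcContent = 0)
    ch <- strsplit(s0, "")[[1]]
    expect_true(all(paste0(ch[1:3], ch[9:7]) %in% c("AU", "UA")))
})

test_that("single-nucleotide operator mutates one unpaired unlocked position", {
    tgt <- parseDotBracket("(((..[[...)))..]]...")
    n <- structureLength(tgt)
    P <- pairProbabilityMatrices(initializeSeed(tgt))
    unp <- unpairedPositions(tgt)
    set.seed(62)
    seq0 <- initializeSeed(tgt)
    for (k in 1:50) {
        seq1 <- mutateSingleNucleotide(seq0, tgt, P)
        diffs <- which(strsplit(seq0, "")[[1]] != strsplit(seq1, "")[[1]])
        expect_length(diffs, 1L)
        expect_true(diffs %in% unp)
    }
    # inapplicable on a fully paired-or-locked target
    tgt2 <- parseDotBracket("((((...))))")
    tpl <- designTemplate("ooooAAAoooo", tgt2)
    expect_error(mutateSingleNucleotide("GGGGAAACCCC", tgt2,
                                        pairProbabilityMatrices("GGGGAAACCCC"),
                                        tpl),
                 class = "knotdesign_inapplicable_operator")
})

test_that("single-nucleotide selection frequencies follow 1 - P[i, n+1]", {
    tgt <- parseDotBracket("....(...)...")  # pair (5, 9), rest unpaired
    n <- structureLength(tgt)
    unp <- unpairedPositions(tgt)
    # frozen augmented matrix with controlled unpaired probabilities
    P <- matrix(0, n, n + 1L)
    P[, n + 1L] <- 1
    gates <- c(0.9, 0.5, 0.1, 0.7, 0.3, 0.2, 0.8, 0.4, 0.6, 0.25)
    P[unp, n + 1L] <- 1 - gates
    seq0 <- "AAAAGAAACAAA"
    set.seed(63)
    draws <- 10000L
    hits <- table(factor(vapply(seq_len(draws), function(k) {
        s1 <- mutateSingleNucleotide(seq0, tgt, P)
        which(strsplit(seq0, "")[[1]] != strsplit(s1, "")[[1]])
    }, numeric(1)), levels = unp))
    pExp <- gates / sum(gates)
    for (j in seq_along(unp)) {
        se <- sqrt(draws * pExp[j] * (1 - pExp[j]))
        expect_lt(abs(hits[j] - draws * pExp[j]), 3 * se + 1)
    }
})

test_that("pair operator edits one target pair with the printed alphabets", {
    tgt <- parseDotBracket("(((..[[...)))..]]...")
    prs <- basePairs(tgt)
    set.seed(64)
    seq0 <- initializeSeed(tgt)
    m <- pairProbabilityMatrices(seq0)
    sawNested <- character(0)
    sawNonNested <- character(0)
    for (k in 1:200) {
        s1 <- mutateBasepair(seq0, tgt, m)
        ch0 <- strsplit(seq0, "")[[1]]
        ch1 <- strsplit(s1, "")[[1]]
        diffs <- which(ch0 != ch1)
        expect_gte(length(diffs), 1L)
        expect_lte(length(diffs), 2L)
        hit <- which(apply(prs, 1, function(p) all(diffs %in% p)))
        expect_length(hit, 1L)
        duo <- paste0(ch1[prs[hit, 1]], ch1[prs[hit, 2]])
        if (pairPages(tgt)[hit] == 1L) sawNested <- c(sawNested, duo)
        else sawNonNested <- c(sawNonNested, duo)
    }
    expect_true(all(sawNested %in% c("AU", "GC", "GU")))
    expect_true(all(sawNonNested %in% c("AU", "GC", "GU", "UA", "CG", "UG")))
    expect_true(any(sawNonNested %in% c("UA", "CG", "UG")))
})

test_that("pair-operator acceptance follows the 1 - P'' defect gates", {
    # two pk pairs with contrasting frozen non-nested probabilities
    tgt <- parseDotBracket("((..[[..))..]]")
    n <- structureLength(tgt)
    Pn <- matrix(0, n, n)
    Pnn <- matrix(0, n, n)
    Pn[1, 10] <- 0.95; Pn[2, 9] <- 0.95   # nested pairs nearly frozen
    Pnn[5, 14] <- 0.9; Pnn[6, 13] <- 0.3  # gates 0.1 vs 0.7
    seq0 <- "GCAAGCAAGCAAGC"
    set.seed(65)
    draws <- 10000L
    prs <- basePairs(tgt)
    hit <- vapply(seq_len(draws), function(k) {
        s1 <- mutateBasepair(seq0, tgt, Pn, Pnn)
        d <- which(strsplit(seq0, "")[[1]] != strsplit(s1, "")[[1]])
        which(apply(prs, 1, function(p) all(d %in% p)))
    }, numeric(1))
    # pairs sorted by i: (1,10), (2,9), (5,14), (6,13)
    gates <- c(0.05, 0.05, 0.1, 0.7)
    pExp <- gates / sum(gates)
    counts <- table(factor(hit, levels = 1:4))
    for (r in 1:4) {
        se <- sqrt(draws * pExp[r] * (1 - pExp[r]))
        expect_lt(abs(counts[r] - draws * pExp[r]), 3 * se + 1)
    }
})

test_that("one-end-locked pairs mutate only the free end, locked pairs never", {
    tgt9 <- parseDotBracket("(((...)))")
    tpl <- designTemplate("Goooooooo", tgt9)
    seq0 <- "GGGAAACCC"
    m <- pairProbabilityMatrices(seq0)
    set.seed(66)
    sawLockedPair <- FALSE
    for (k in 1:200) {
        s1 <- mutateBasepair(seq0, tgt9, m, template = tpl)
        expect_equal(substr(s1, 1, 1), "G")  # locked end never moves
        d <- which(strsplit(seq0, "")[[1]] != strsplit(s1, "")[[1]])
        if (9 %in% d) {
            # the one-end-locked pair (1, 9): only the free end changed
            expect_identical(d, 9L)
            expect_true(substr(s1, 9, 9) %in% c("C", "U"))
            sawLockedPair <- TRUE
        }
    }
    expect_true(sawLockedPair)
})

test_that("adaptive m follows floor(|Normal(m', m'/5)|) clamped to >= 1", {
    set.seed(67)
    expect_equal(replicate(50, computeM(0, 30)), rep(1L, 50))
    draws <- replicate(1e5, computeM(0.5, 100, 5))  # m' = 10
    oracle <- pmax(1, floor(abs(rnorm(1e5, 10, 2))))
    expect_gt(mean(draws), 9.2)
    expect_lt(mean(draws), 9.8)
    expect_lt(abs(mean(draws) - mean(oracle)), 0.1)
})

test_that("m-mutation counts exactly m (pairs counting double)", {
    tgt <- parseDotBracket("(((..[[...)))..]]...")
    seq0 <- initializeSeed(tgt)
    m0 <- pairProbabilityMatrices(seq0)
    set.seed(68)
    hds <- vapply(1:300, function(k) {
        m <- sample(1:6, 1)
        out <- mMutation(m, seq0, tgt, m0)
        expect_equal(attr(out, "mutationCount"), m)
        hd <- sum(strsplit(seq0, "")[[1]] != strsplit(as.character(out), "")[[1]])
        expect_lte(hd, m)  # later draws may revert earlier ones, so hd can
        hd                 # fall below m (rarely all the way to 0)
    }, numeric(1))
    expect_gt(mean(hds >= 1), 0.95)
    # m = 1 can only be a single-nucleotide mutation
    for (k in 1:50) {
        out <- mMutation(1L, seq0, tgt, m0)
        expect_equal(attr(out, "mutationCount"), 1L)
        expect_equal(sum(strsplit(seq0, "")[[1]] !=
                         strsplit(as.character(out), "")[[1]]), 1L)
    }
})

test_that("design runs converge, trace faithfully, and reproduce bit-for-bit", {
    tgt <- parseDotBracket("(((..[[[..))).]]]")
    cfg <- designConfig(fstop = 0.05, maxIt = 150L, seed = 101L,
                        maxStructures = 2e7)
    res <- designSequence(tgt, config = cfg, debug = TRUE)
    expect_s4_class(res, "DesignResult")
    expect_true(isCompatible(res@sequence, tgt))
    expect_lte(res@iterationsUsed, 150L)
    expect_equal(res@reachedFstop, res@normalizedDefect <= 0.05)
    # returned N is the minimum over the trace (seed row included)
    expect_equal(res@normalizedDefect, min(res@trace$N), tolerance = 1e-12)
    expect_lte(nrow(res@trace), 151L)
    expect_true(all(res@trace$operator[-1] %in% 1:3))
    expect_true(all(res@trace$m[which(res@trace$operator == 3L)] >= 1))
    # bit-reproducibility under the same config
    res2 <- designSequence(tgt, config = cfg)
    expect_identical(res@sequence, res2@sequence)
    expect_equal(res@trace$N, res2@trace$N)
    # trials are independently seeded and reproducible
    trials <- runDesignTrials(tgt, config = cfg, trials = 3L)
    again <- runDesignTrials(tgt, config = cfg, trials = 3L)
    expect_identical(vapply(trials, function(r) r@sequence, character(1)),
                     vapply(again, function(r) r@sequence, character(1)))
})

test_that("fully locked templates and empty operator sets are rejected", {
    tgt <- parseDotBracket("(...)")
    tpl <- designTemplate("GAAAC", tgt)
    expect_error(designSequence(tgt, tpl, designConfig(seed = 1L)),
                 "nothing to mutate")
})
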