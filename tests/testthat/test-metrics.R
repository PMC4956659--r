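test_that("ensemble defect follows its matrix definition", {
    tgt <- parseDotBracket(".(...).")
    S <- structureMatrix(tgt)
    # P identical to the (augmented) structure matrix: zero defect
    d0 <- ensembleDefect(S * 1.0, tgt)
    expect_equal(unname(d0), c(0, 0))
    # uniform P over n + 1 columns, n = 4
    Pu <- matrix(1 / 5, 4, 5)
    tgt4 <- pairedStructure(matrix(integer(0), 0, 2), 4L)
    du <- ensembleDefect(Pu, tgt4)
    expect_equal(du[["defect"]], 4 - 4 / 5)
    expect_equal(du[["normalized"]], 0.8)
    # ACGU against the single-pair target: rows 2 and 3 always correct
    tgtP <- pairedStructure(rbind(c(1L, 4L)), 4L)
    P <- pairProbabilityMatrices("ACGU")
    d <- ensembleDefect(P, tgtP)
    expect_equal(d[["defect"]], 2 * (1 - P@P[1, 4]), tolerance = 1e-12)
    expect_error(ensembleDefect(Pu, tgt), "dimensions")
})

test_that("matrix-form defect equals the direct ensemble average", {
    set.seed(51)
    for (k in 1:5) {
        s <- randomRnaSequence(sample(9:12, 1))
        o <- oracleEnsemble(s)
        e <- enumerateEnsemble(s, listStructures = TRUE)
        tgt <- parseDotBracket(e@structures$dotbracket[
            sample.int(nrow(e@structures), 1)])
        direct <- sum(vapply(seq_along(o$dbs), function(r)
            o$probs[r] * structureDistance(parseDotBracket(o$dbs[r]), tgt),
            numeric(1)))
        viaMatrix <- ensembleDefect(pairProbabilityMatrices(s), tgt)[["defect"]]
        expect_equal(viaMatrix, direct, tolerance = 1e-9)
    }
})

test_that("probability defect and Boltzmann frequency are complements", {
    expect_equal(probabilityDefect(1), 0)
    expect_equal(probabilityDefect(0.85), 0.15)
    expect_error(probabilityDefect(1.2), "\\[0, 1\\]")
    kT <- energyModel()@thermalEnergy
    tgt <- pairedStructure(rbind(c(1L, 4L)), 4L)
    expect_equal(probabilityDefect(equilibriumProbability("ACGU", tgt)),
                 1 / (1 + exp(2 / kT)), tolerance = 1e-12)
    set.seed(52)
    for (k in 1:5) {
        s <- randomRnaSequence(10)
        e <- enumerateEnsemble(s, listStructures = TRUE)
        tgt <- parseDotBracket(e@structures$dotbracket[
            which.max(e@structures$probability)])
        bf <- boltzmannFrequency(s, tgt)
        expect_equal(bf, equilibriumProbability(s, tgt), tolerance = 1e-12)
        expect_equal(bf + probabilityDefect(equilibriumProbability(s, tgt)), 1,
                     tolerance = 1e-12)
    }
})

test_that("MFE defect is the per-position structure Hamming distance", {
    a <- parseDotBracket("(((...)))")
    b <- parseDotBracket(".((...)).")
    expect_equal(structureDistance(a, b), 2)
    expect_equal(structureDistance(a, a), 0)
    expect_equal(mfeDefect("GGGAAACCC", a), 0)  # successful design
    # single-structure ensemble: N = 0, pi = 0, mu = 0 simultaneously
    open4 <- pairedStructure(matrix(integer(0), 0, 2), 4L)
    expect_equal(ensembleDefect(pairProbabilityMatrices("AAAA"),
                                open4)[["normalized"]], 0)
    expect_equal(probabilityDefect(equilibriumProbability("AAAA", open4)), 0)
    expect_equal(mfeDefect("AAAA", open4), 0)
})

test_that("modal-structure theorem: pi below one half forces mu = 0", {
    set.seed(53)
    checked <- 0L
    for (k in 1:12) {
        s <- randomRnaSequence(sample(9:12, 1))
        e <- enumerateEnsemble(s, listStructures = TRUE)
        top <- which.max(e@structures$probability)
        if (e@structures$probability[top] <= 0.5) next
        tgt <- parseDotBracket(e@structures$dotbracket[top])
        expect_lt(probabilityDefect(equilibriumProbability(s, tgt)), 0.5)
        expect_equal(mfeDefect(s, tgt), 0)
        checked <- checked + 1L
    }
    expect_gte(checked, 3L)
})

test_that("sequence identity averages pairwise fractional identity", {
    expect_equal(sequenceIdentity(c("AAAA", "AAAA")), 1)
    expect_equal(sequenceIdentity(c("AAAA", "CCCC")), 0)
    expect_equal(sequenceIdentity(c("AAAA", "AACC")), 0.5)
    expect_equal(sequenceIdentity(c("AAAA", "AAAA", "CCCC")), 1 / 3)
    expect_error(sequenceIdentity("AAAA"), "two sequences")
    expect_error(sequenceIdentity(c("AAAA", "AA")), "equal length")
})
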