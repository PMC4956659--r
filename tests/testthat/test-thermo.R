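pairsOnly <- energyModel(stackEnergy = 0)

test_that("free energy is additive over pairs, stacks and pk penalties", {
    open4 <- pairedStructure(matrix(integer(0), 0, 2), 4L)
    expect_equal(freeEnergy("ACGU", open4), 0)
    # pairs-only arithmetic
    expect_equal(freeEnergy("GGGAAACCC", parseDotBracket("(((...)))"),
                            pairsOnly), -9)
    expect_equal(freeEnergy("GCAAGCAAGCAAGC", parseDotBracket("((..[[..))..]]"),
                            pairsOnly), -11)
    # default model adds -2 per adjacent pair of pairs: the hairpin has two
    expect_equal(freeEnergy("GGGAAACCC", parseDotBracket("(((...)))")), -13)
    expect_error(freeEnergy("GGGAAACCG", parseDotBracket("(((...)))")),
                 "allowed pair")
})

test_that("tiny ensembles match closed forms", {
    kT <- energyModel()@thermalEnergy
    e1 <- enumerateEnsemble("AAAA", listStructures = TRUE)
    expect_equal(e1@Q, 1)
    expect_equal(e1@numStructures, 1)
    expect_equal(e1@structures$dotbracket, "....")

    e2 <- enumerateEnsemble("ACGU", listStructures = TRUE)
    expect_equal(e2@Q, 1 + exp(2 / kT), tolerance = 1e-12)
    expect_equal(e2@numStructures, 2)
    P <- pairProbabilityMatrices("ACGU")
    expect_equal(P@P[1, 4], exp(2 / kT) / (1 + exp(2 / kT)), tolerance = 1e-12)
    expect_equal(P@P[1, 5], 1 - P@P[1, 4], tolerance = 1e-12)
})

test_that("compiled enumeration agrees with the independent oracle", {
    set.seed(41)
    seqs <- c("GCGCGCGC", replicate(6, randomRnaSequence(sample(8:11, 1))))
    for (s in seqs) for (pk in c(TRUE, FALSE)) {
        o <- oracleEnsemble(s, pkAllowed = pk)
        e <- enumerateEnsemble(s, pkAllowed = pk, listStructures = TRUE)
        expect_equal(e@numStructures, o$count)
        expect_equal(e@Q, o$Q, tolerance = 1e-9)
        expect_equal(sort(e@structures$dotbracket), sort(o$dbs))
        expect_equal(sum(e@structures$probability), 1, tolerance = 1e-9)
        expect_equal(dotBracket(e@mfeStructure), o$mfeDb)
        expect_equal(e@mfeEnergy, o$mfeEnergy, tolerance = 1e-9)
    }
})

test_that("pair probability matrices obey the matrix laws and match the oracle", {
    set.seed(42)
    for (k in 1:6) {
        s <- randomRnaSequence(sample(9:12, 1))
        o <- oracleEnsemble(s)
        m <- pairProbabilityMatrices(s)
        n <- nchar(s)
        expect_equal(rowSums(m@P), rep(1, n), tolerance = 1e-9)
        expect_equal(m@Pnested + m@Pnonnested, m@P[, seq_len(n)],
                     tolerance = 1e-12)
        expect_equal(m@P, o$P, tolerance = 1e-9)
        expect_equal(m@Pnested, o$Pnested, tolerance = 1e-9)
        expect_equal(m@Pnonnested, o$Pnonnested, tolerance = 1e-9)
    }
})

test_that("nested DP partition function equals nested-only enumeration", {
    expect_equal(nestedPartitionFunction("AAAA"), 1)
    g <- enumerateEnsemble("GGGAAACCC", pkAllowed = FALSE)
    expect_equal(nestedPartitionFunction("GGGAAACCC"), g@Q,
                 tolerance = 1e-9 * g@Q)
    set.seed(43)
    for (k in 1:20) {
        s <- randomRnaSequence(sample(6:12, 1))
        qEnum <- enumerateEnsemble(s, pkAllowed = FALSE)@Q
        expect_equal(nestedPartitionFunction(s), qEnum,
                     tolerance = 1e-9 * qEnum)
    }
})

test_that("nested backend matrices equal nested-only enumeration matrices", {
    set.seed(44)
    for (k in 1:5) {
        s <- randomRnaSequence(sample(9:12, 1))
        dp <- pairProbabilityMatrices(s, backend = "nested")
        o <- oracleEnsemble(s, pkAllowed = FALSE)
        expect_equal(dp@P, o$P, tolerance = 1e-9)
        expect_true(all(dp@Pnonnested == 0))
    }
})

test_that("equilibrium probabilities normalize and match the two-term case", {
    kT <- energyModel()@thermalEnergy
    tgt <- pairedStructure(rbind(c(1L, 4L)), 4L)
    expect_equal(equilibriumProbability("ACGU", tgt),
                 exp(2 / kT) / (1 + exp(2 / kT)), tolerance = 1e-12)
    # single-structure ensemble
    open4 <- pairedStructure(matrix(integer(0), 0, 2), 4L)
    expect_equal(equilibriumProbability("AAAA", open4), 1)
    # probabilities over the whole ensemble sum to one
    set.seed(45)
    s <- randomRnaSequence(10)
    e <- enumerateEnsemble(s, listStructures = TRUE)
    probs <- vapply(e@structures$dotbracket, function(db)
        equilibriumProbability(s, parseDotBracket(db)), numeric(1))
    expect_equal(sum(probs), 1, tolerance = 1e-9)
})

test_that("adding the pseudoknot class never decreases Q", {
    set.seed(46)
    for (k in 1:10) {
        s <- randomRnaSequence(sample(8:12, 1))
        expect_gte(enumerateEnsemble(s, pkAllowed = TRUE)@Q,
                   enumerateEnsemble(s, pkAllowed = FALSE)@Q - 1e-12)
    }
})

test_that("MFE structure is the deterministic lexicographic argmin", {
    expect_equal(dotBracket(mfeStructure("GGGAAACCC", pairsOnly)), "(((...)))")
    expect_equal(freeEnergy("GGGAAACCC", mfeStructure("GGGAAACCC", pairsOnly),
                            pairsOnly), -9)
    expect_equal(dotBracket(mfeStructure("AAAA")), "....")
    # two isoenergetic nested single-pair structures: '(' sorts before '.'
    expect_equal(dotBracket(mfeStructure("AUAUA", backend = "nested")), "(..).")
    # oracle agreement (covers tie-breaking on random fixtures)
    set.seed(47)
    for (k in 1:8) {
        s <- randomRnaSequence(sample(8:11, 1))
        expect_equal(dotBracket(mfeStructure(s)), oracleEnsemble(s)$mfeDb)
    }
})

test_that("enumeration guards trip on oversized problems", {
    expect_error(enumerateEnsemble(strrep("A", 40)), "length guard")
    expect_error(enumerateEnsemble("GCGCGCGCGCGC", maxStructures = 3),
                 "maxStructures")
})
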