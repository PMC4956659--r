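# S4 class definitions and validity methods.

#' PairedStructure: a (possibly pseudoknotted) RNA secondary structure
#'
#' A target secondary structure over `n` nucleotides: a set of base pairs
#' `(i, j)` (1-based, `i < j`, `j >= i + 3`), each assigned to page 1
#' (nested, round brackets) or page 2 (non-nested, square brackets). Pairs
#' on the same page never cross; crossings between the pages are what makes
#' the structure pseudoknotted.
#'
#' @slot n Integer, number of nucleotides.
#' @slot pairs Integer matrix with one row per base pair, columns `i`, `j`.
#' @slot pages Integer vector, page (1 or 2) of each pair.
#' @slot dotbracket Character scalar, the dot-bracket rendering over
#'   `.()[]`; `write(parse(s)) == s` for all valid `s`.
#'
#' @seealso [parseDotBracket()], [writeDotBracket()], [twoPageSplit()]
#' @exportClass PairedStructure
setClass("PairedStructure",
    representation(
        n = "integer",
        pairs = "matrix",
        pages = "integer",
        dotbracket = "character"
    )
)

setValidity("PairedStructure", function(object) {
    n <- object@n
    p <- object@pairs
    msgs <- character()
    if (length(n) != 1L || is.na(n) || n < 1L)
        return("n must be a single positive integer")
    if (!is.numeric(p) || ncol(p) != 2L)
        return("pairs must be a two-column integer matrix")
    if (nrow(p) != length(object@pages))
        return("one page per pair required")
    if (nrow(p) > 0L) {
        if (any(p < 1L) || any(p > n))
            msgs <- c(msgs, "pair indices out of range")
        if (any(p[, 2L] < p[, 1L] + 3L))
            msgs <- c(msgs, "every pair must satisfy j >= i + 3")
        if (anyDuplicated(as.vector(p)))
            msgs <- c(msgs, "a position may occur in at most one pair")
        if (!all(object@pages %in% c(1L, 2L)))
            msgs <- c(msgs, "pages must be 1 or 2")
        for (pg in 1:2) {
            sel <- object@pages == pg
            if (sum(sel) > 1L && .anyCrossing(p[sel, , drop = FALSE]))
                msgs <- c(msgs, sprintf("page %d pairs cross each other", pg))
        }
    }
    if (nchar(object@dotbracket) != n)
        msgs <- c(msgs, "dotbracket length differs from n")
    if (length(msgs)) msgs else TRUE
})

#' DesignTemplate: per-position sequence constraints for design
#'
#' A string of length `n` over `A`, `C`, `G`, `U`, `o`. Non-`o` positions
#' are copied into the seed sequence and are immune to mutation throughout
#' a design run; `o` positions are free.
#'
#' @slot text Character scalar over `{A,C,G,U,o}`.
#' @seealso [designTemplate()]
#' @exportClass DesignTemplate
setClass("DesignTemplate", representation(text = "character"))

setValidity("DesignTemplate", function(object) {
    ch <- strsplit(object@text, "", fixed = TRUE)[[1L]]
    if (!length(ch)) return("template must be non-empty")
    bad <- setdiff(unique(ch), c("A", "C", "G", "U", "o"))
    if (length(bad))
        return(sprintf("illegal template character(s): %s (DNA 'T' is rejected, not converted)",
                       paste(bad, collapse = ", ")))
    TRUE
})

#' EnergyModel: additive pair-energy model for the structure ensemble
#'
#' Assigns each canonical base pair class (`AU`, `GC`, `GU`) a free-energy
#' increment in kcal/mol, plus a penalty per page-2 (pseudoknot) pair. The
#' open chain has energy zero. The model deliberately omits nearest-neighbor
#' loop terms so that the exhaustive ensemble enumerator stays exact and
#' cheap; the design algorithm itself is energy-model agnostic.
#'
#' @slot pairEnergy Named numeric, energies (kcal/mol) for `AU`, `GC`, `GU`.
#' @slot pkPenalty Numeric, kcal/mol added per page-2 pair.
#' @slot stackEnergy Numeric, kcal/mol added per pair of adjacent pairs
#'   (`(i, j)` and `(i+1, j-1)` both present) - the cooperative term that
#'   lets contiguous helices dominate register-scrambled pairings.
#' @slot temperature Numeric, Kelvin.
#' @slot thermalEnergy Numeric, k_B * T in kcal/mol.
#' @seealso [energyModel()]
#' @exportClass EnergyModel
setClass("EnergyModel",
    representation(
        pairEnergy = "numeric",
        pkPenalty = "numeric",
        stackEnergy = "numeric",
        temperature = "numeric",
        thermalEnergy = "numeric"
    )
)

setValidity("EnergyModel", function(object) {
    if (!all(c("AU", "GC", "GU") %in% names(object@pairEnergy)))
        return("pairEnergy must be named with AU, GC, GU")
    if (!all(is.finite(object@pairEnergy)) || !is.finite(object@pkPenalty) ||
        !is.finite(object@stackEnergy))
        return("all energies must be finite")
    if (!is.finite(object@thermalEnergy) || object@thermalEnergy <= 0)
        return("thermalEnergy must be positive")
    if (!is.finite(object@temperature) || object@temperature <= 0)
        return("temperature must be positive")
    TRUE
})

#' PairProbabilityMatrices: equilibrium base-pair probabilities
#'
#' The augmented pair-probability matrix `P` (`n` rows, `n + 1` columns;
#' the extra column holds unpaired probabilities, so every row sums to 1)
#' together with its split into nested (`P'`) and non-nested (`P''`)
#' components: `P' + P'' = P` elementwise on the first `n` columns. The
#' split follows each ensemble structure's deterministic two-page
#' assignment.
#'
#' @slot P Numeric `n x (n+1)` matrix (augmented).
#' @slot Pnested Numeric `n x n` matrix (page-1 contributions).
#' @slot Pnonnested Numeric `n x n` matrix (page-2 contributions).
#' @seealso [pairProbabilityMatrices()]
#' @exportClass PairProbabilityMatrices
setClass("PairProbabilityMatrices",
    representation(P = "matrix", Pnested = "matrix", Pnonnested = "matrix")
)

setValidity("PairProbabilityMatrices", function(object) {
    n <- nrow(object@P)
    if (ncol(object@P) != n + 1L)
        return("P must be n x (n+1) (augmented)")
    if (!all(dim(object@Pnested) == c(n, n)) ||
        !all(dim(object@Pnonnested) == c(n, n)))
        return("Pnested and Pnonnested must be n x n")
    if (any(object@P < -1e-9) || any(object@P > 1 + 1e-9))
        return("probabilities must lie in [0, 1]")
    TRUE
})

#' RnaEnsemble: summary of an exhaustively enumerated structure ensemble
#'
#' @slot sequence Character scalar, the RNA sequence.
#' @slot Q Numeric, partition function (open chain contributes 1).
#' @slot numStructures Numeric, number of structures in the ensemble.
#' @slot mfeStructure A [PairedStructure-class], the minimum-free-energy
#'   structure (ties broken by lexicographically smallest dot-bracket).
#' @slot mfeEnergy Numeric, kcal/mol.
#' @slot structures A data.frame with columns `dotbracket`, `energy`,
#'   `probability` (empty unless per-structure listing was requested).
#' @seealso [enumerateEnsemble()]
#' @exportClass RnaEnsemble
setClass("RnaEnsemble",
    representation(
        sequence = "character",
        Q = "numeric",
        numStructures = "numeric",
        mfeStructure = "PairedStructure",
        mfeEnergy = "numeric",
        structures = "data.frame"
    )
)

setValidity("RnaEnsemble", function(object) {
    if (object@Q < 1 - 1e-9)
        return("Q must be >= 1 (the open chain contributes exp(0))")
    TRUE
})

#' DesignConfig: parameters of a design run
#'
#' @slot fstop Numeric in (0, 1], target normalized ensemble defect; the
#'   run stops as soon as `N <= fstop`.
#' @slot maxIt Positive integer, iteration cap.
#' @slot gcContent Numeric in \[0, 1\] or `NA`; when `NA` each seed draws a
#'   GC fraction uniformly from \[0.20, 0.80\].
#' @slot adaptiveC Positive numeric, divisor C of the adaptive mutation
#'   size (`m' = N * n / C`).
#' @slot seed Integer or `NA`, RNG seed for the run.
#' @slot backend Character, `"exact"`, `"nested"` or `"nupack"`.
#' @slot adaptiveEnabled Logical, whether the adaptive m-mutation operator
#'   participates in operator selection.
#' @slot retryCap Numeric or `NA` (then `100 * n`), draw budget before a
#'   defect-gated operator falls back to ungated uniform selection.
#' @slot allNestedPairTypes Logical; `FALSE` restricts fully free nested
#'   pair mutations to the orientations A-U, G-C, G-U, `TRUE` allows all
#'   six.
#' @slot maxStructures Numeric, enumeration guard for the exact backend.
#' @seealso [designConfig()], [designSequence()]
#' @exportClass DesignConfig
setClass("DesignConfig",
    representation(
        fstop = "numeric",
        maxIt = "integer",
        gcContent = "numeric",
        adaptiveC = "numeric",
        seed = "integer",
        backend = "character",
        adaptiveEnabled = "logical",
        retryCap = "numeric",
        allNestedPairTypes = "logical",
        maxStructures = "numeric"
    )
)

setValidity("DesignConfig", function(object) {
    if (!(object@fstop > 0 && object@fstop <= 1))
        return("fstop must lie in (0, 1]")
    if (is.na(object@maxIt) || object@maxIt < 1L)
        return("maxIt must be >= 1")
    if (!is.na(object@gcContent) &&
        (object@gcContent < 0 || object@gcContent > 1))
        return("gcContent must lie in [0, 1] or be NA")
    if (object@adaptiveC <= 0) return("the adaptive divisor C must be positive")
    if (!object@backend %in% c("exact", "nested", "nupack"))
        return("backend must be 'exact', 'nested' or 'nupack'")
    TRUE
})

#' DesignResult: the outcome of one design trial
#'
#' Holds the best (lowest normalized ensemble defect) sequence observed
#' during the run together with its quality metrics and the per-iteration
#' trace.
#'
#' @slot targetId Character, identifier of the target.
#' @slot sequence Character, the designed RNA sequence.
#' @slot normalizedDefect Numeric, N in \[0, 1\].
#' @slot probabilityDefect Numeric, pi = 1 - p(target).
#' @slot freeEnergy Numeric, Delta G of the sequence folded into the
#'   target (kcal/mol).
#' @slot mfeDefect Numeric, structure Hamming distance between the MFE
#'   structure and the target (0 = successful design).
#' @slot boltzmannFrequency Numeric, the target's share of the ensemble.
#' @slot iterationsUsed Integer, mutation iterations performed.
#' @slot elapsedSeconds Numeric, wall-clock time of the run.
#' @slot reachedFstop Logical, whether `N <= fstop` was attained.
#' @slot trace data.frame with columns `iteration`, `operator`, `m`, `N`,
#'   `pi`; iteration 0 records the seed evaluation.
#' @seealso [designSequence()]
#' @exportClass DesignResult
setClass("DesignResult",
    representation(
        targetId = "character",
        sequence = "character",
        normalizedDefect = "numeric",
        probabilityDefect = "numeric",
        freeEnergy = "numeric",
        mfeDefect = "numeric",
        boltzmannFrequency = "numeric",
        iterationsUsed = "integer",
        elapsedSeconds = "numeric",
        reachedFstop = "logical",
        trace = "data.frame"
    )
)

# -- show methods -------------------------------------------------------

setMethod("show", "PairedStructure", function(object) {
    npk <- sum(object@pages == 2L)
    cat(sprintf("PairedStructure of %d nt: %d pairs (%d nested, %d pseudoknot)\n",
                object@n, nrow(object@pairs), nrow(object@pairs) - npk, npk))
    cat(" ", object@dotbracket, "\n")
})

setMethod("show", "DesignTemplate", function(object) {
    locked <- sum(strsplit(object@text, "")[[1L]] != "o")
    cat(sprintf("DesignTemplate of %d nt, %d locked position(s)\n",
                nchar(object@text), locked))
    cat(" ", object@text, "\n")
})

setMethod("show", "EnergyModel", function(object) {
    cat("EnergyModel (additive pair energies, kcal/mol)\n")
    cat(sprintf("  AU = %.2f, GC = %.2f, GU = %.2f; stack = %.2f; pseudoknot pair penalty = %+.2f\n",
                object@pairEnergy[["AU"]], object@pairEnergy[["GC"]],
                object@pairEnergy[["GU"]], object@stackEnergy,
                object@pkPenalty))
    cat(sprintf("  T = %.2f K, kT = %.4f kcal/mol\n",
                object@temperature, object@thermalEnergy))
})

setMethod("show", "PairProbabilityMatrices", function(object) {
    n <- nrow(object@P)
    cat(sprintf("PairProbabilityMatrices for %d nt (augmented P, P', P'')\n", n))
    cat(sprintf("  paired probability mass: %.4f (nested %.4f, non-nested %.4f)\n",
                sum(object@P[, seq_len(n)]) / 2, sum(object@Pnested) / 2,
                sum(object@Pnonnested) / 2))
})

setMethod("show", "RnaEnsemble", function(object) {
    cat(sprintf("RnaEnsemble: %s structures, Q = %.6g\n",
                format(object@numStructures, big.mark = ","), object@Q))
    cat(sprintf("  MFE %.3f kcal/mol: %s\n", object@mfeEnergy,
                object@mfeStructure@dotbracket))
})

setMethod("show", "DesignResult", function(object) {
    cat(sprintf("DesignResult '%s' (%s after %d iteration(s), %.2fs)\n",
                object@targetId,
                if (object@reachedFstop) "stop condition reached" else "iteration cap",
                object@iterationsUsed, object@elapsedSeconds))
    cat(" ", object@sequence, "\n")
    cat(sprintf("  N = %.4g, pi = %.4g, dG = %.3f, MFE defect = %d, Bf = %.4g\n",
                object@normalizedDefect, object@probabilityDefect,
                object@freeEnergy, as.integer(object@mfeDefect),
                object@boltzmannFrequency))
})
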