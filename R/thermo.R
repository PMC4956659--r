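# Energy model and equilibrium ensemble computation. The default backend
# ("exact") exhaustively enumerates the two-page ensemble in compiled code;
# "nested" is an O(n^3)/O(n^4) dynamic-programming fast path for
# pseudoknot-free ensembles; "nupack" delegates to an external folding
# engine when one is installed.

.BOLTZMANN_KCAL <- 0.0019872  # kcal/mol/K

#' Construct an additive pair-energy model with helix stacking
#'
#' Each base pair contributes its class energy (AU, GC or GU, orientation
#' ignored); each adjacent pair of pairs (`(i, j)` together with
#' `(i+1, j-1)`) contributes `stackEnergy`; each page-2 (pseudoknot) pair
#' additionally pays `pkPenalty`. The open chain has energy 0. Defaults:
#' AU = -2.0, GC = -3.0, GU = -1.0 kcal/mol, stackEnergy = -2.0,
#' pkPenalty = +0.5 kcal/mol, T = 310.15 K, so
#' kT = 0.0019872 * 310.15 ~ 0.6163 kcal/mol.
#'
#' The stacking term is the minimal cooperative ingredient: without it,
#' matchings that scramble the pairing register are isoenergetic with the
#' intended helix and the equilibrium ensemble stays diffuse, which makes
#' low-defect design impossible in principle. Its magnitude sits in the
#' range of measured nearest-neighbor stack free energies. Setting
#' `stackEnergy = 0` recovers the pairs-only model.
#'
#' @param pairEnergy Named numeric vector with entries `AU`, `GC`, `GU`
#'   (kcal/mol).
#' @param pkPenalty Energy added per page-2 pair (kcal/mol).
#' @param stackEnergy Energy added per adjacent pair of pairs (kcal/mol).
#' @param temperature Temperature in Kelvin.
#' @param thermalEnergy k_B * T (kcal/mol); computed from `temperature`
#'   when not supplied.
#' @return An [EnergyModel-class].
#' @examples
#' energyModel()
#' energyModel(stackEnergy = 0)  # pairs-only model
#' @export
energyModel <- function(pairEnergy = c(AU = -2.0, GC = -3.0, GU = -1.0),
                        pkPenalty = 0.5, stackEnergy = -2.0,
                        temperature = 310.15,
                        thermalEnergy = .BOLTZMANN_KCAL * temperature) {
    obj <- new("EnergyModel", pairEnergy = pairEnergy[c("AU", "GC", "GU")],
               pkPenalty = pkPenalty, stackEnergy = stackEnergy,
               temperature = temperature, thermalEnergy = thermalEnergy)
    validObject(obj)
    obj
}

.pairClass <- function(a, b) {
    key <- paste0(a, b)
    switch(key,
        AU = , UA = "AU",
        GC = , CG = "GC",
        GU = , UG = "GU",
        NA_character_)
}

#' Free energy of a sequence folded into a fixed structure
#'
#' Sum of pair-class energies over all pairs, plus `stackEnergy` per
#' adjacent pair of pairs, plus the pseudoknot penalty times the number of
#' page-2 pairs; the open chain scores 0.
#'
#' @param seq RNA sequence string.
#' @param structure A [PairedStructure-class].
#' @param model An [EnergyModel-class].
#' @return Free energy in kcal/mol.
#' @examples
#' freeEnergy("GGGAAACCC", parseDotBracket("(((...)))"), energyModel())
#' @export
freeEnergy <- function(seq, structure, model = energyModel()) {
    ch <- .checkRnaSequence(seq)
    stopifnot(is(structure, "PairedStructure"))
    if (length(ch) != structure@n)
        stop("sequence and structure lengths differ")
    p <- structure@pairs
    if (!nrow(p)) return(0)
    cls <- mapply(.pairClass, ch[p[, 1L]], ch[p[, 2L]])
    if (anyNA(cls)) {
        r <- which(is.na(cls))[1L]
        stop(sprintf("bases %s-%s at pair (%d, %d) do not form an allowed pair",
                     ch[p[r, 1L]], ch[p[r, 2L]], p[r, 1L], p[r, 2L]))
    }
    partner <- .partnerVector(structure)
    nStacks <- sum(vapply(seq_len(nrow(p)), function(r) {
        i <- p[r, 1L]; j <- p[r, 2L]
        i > 1L && j < structure@n && partner[i - 1L] == j + 1L
    }, logical(1L)))
    sum(model@pairEnergy[cls]) + model@stackEnergy * nStacks +
        model@pkPenalty * sum(structure@pages == 2L)
}

.enumGuard <- function(seq, maxLength) {
    n <- nchar(seq)
    if (n > maxLength)
        stop(sprintf("sequence length %d exceeds the enumeration length guard (%d); raise maxLength only if you accept the exponential cost",
                     n, maxLength))
}

#' Exhaustively enumerate the structure ensemble of a sequence
#'
#' Enumerates every structure whose pairs are sequence-allowed, satisfy
#' `j >= i + 3`, use each position at most once and (when `pkAllowed`)
#' whose crossing graph is bipartite (the two-page class). Boltzmann
#' weights give the partition function `Q = sum exp(-E / kT)` and
#' per-structure probabilities that sum to 1. The cost is proportional to
#' the number of structures, which grows exponentially with length:
#' comfortable to roughly 24 nt for arbitrary sequences (about 10^7
#' structures near 26 nt, over 10^8 by 30 nt), hence the guards.
#'
#' @param seq RNA sequence string.
#' @param model An [EnergyModel-class].
#' @param pkAllowed Include pseudoknotted (two-page) structures?
#' @param listStructures Return the per-structure table?
#' @param maxLength Length guard (configurable).
#' @param maxStructures Abort if the ensemble exceeds this many structures.
#' @return An [RnaEnsemble-class].
#' @examples
#' enumerateEnsemble("ACGU", listStructures = TRUE)
#' @export
enumerateEnsemble <- function(seq, model = energyModel(), pkAllowed = TRUE,
                              listStructures = FALSE, maxLength = 35,
                              maxStructures = 5e7) {
    .checkRnaSequence(seq)
    .enumGuard(seq, maxLength)
    r <- .Call_enumerate(seq, model@pairEnergy, model@pkPenalty,
                         model@stackEnergy, model@thermalEnergy, pkAllowed,
                         listStructures, maxStructures)
    structs <- if (listStructures) {
        data.frame(dotbracket = r$structures, energy = r$energies,
                   probability = r$probabilities, stringsAsFactors = FALSE)
    } else {
        data.frame(dotbracket = character(0), energy = numeric(0),
                   probability = numeric(0))
    }
    new("RnaEnsemble", sequence = seq, Q = r$Q,
        numStructures = r$numStructures,
        mfeStructure = parseDotBracket(r$mfeDotbracket),
        mfeEnergy = r$mfeEnergy, structures = structs)
}

# raw C++ evaluation; shared by several exported fronts
.exactEvaluate <- function(seq, model, pkAllowed = TRUE, maxLength = 35,
                           maxStructures = 5e7) {
    .checkRnaSequence(seq)
    .enumGuard(seq, maxLength)
    .Call_enumerate(seq, model@pairEnergy, model@pkPenalty,
                    model@stackEnergy, model@thermalEnergy, pkAllowed,
                    FALSE, maxStructures)
}

#' Equilibrium base-pair probability matrices P, P', P''
#'
#' `P[i, j]` is the equilibrium probability that pair `(i, j)` forms;
#' the augmented column `P[i, n + 1]` is the probability that `i` is
#' unpaired, so each row sums to 1. Every ensemble structure's pairs are
#' split by its deterministic two-page assignment: page-1 contributions
#' accumulate into `P'` (nested), page-2 into `P''` (non-nested), and
#' `P' + P'' = P` on the first `n` columns.
#'
#' @param seq RNA sequence string.
#' @param model An [EnergyModel-class].
#' @param backend `"exact"` (two-page enumeration), `"nested"`
#'   (pseudoknot-free dynamic programming; `P''` is zero) or `"nupack"`
#'   (external engine, if installed).
#' @param maxLength,maxStructures Guards for the exact backend.
#' @return A [PairProbabilityMatrices-class].
#' @export
pairProbabilityMatrices <- function(seq, model = energyModel(),
                                    backend = c("exact", "nested", "nupack"),
                                    maxLength = 35, maxStructures = 5e7) {
    backend <- match.arg(backend)
    if (backend == "exact") {
        r <- .exactEvaluate(seq, model, TRUE, maxLength, maxStructures)
        obj <- new("PairProbabilityMatrices", P = r$P, Pnested = r$Pnested,
                   Pnonnested = r$Pnonnested)
    } else if (backend == "nested") {
        obj <- .nestedPairProbabilities(seq, model)
    } else {
        obj <- nupackPairProbabilities(seq, model)
    }
    validObject(obj)
    obj
}

#' Equilibrium probability of folding into a target structure
#'
#' `p(phi, tau) = exp(-dG(phi, tau) / kT) / Q(phi)`. With the `"nested"`
#' backend the ensemble is pseudoknot-free and pseudoknotted targets are
#' rejected.
#'
#' @inheritParams pairProbabilityMatrices
#' @param target A [PairedStructure-class]; must be pair-compatible with
#'   `seq`.
#' @return Probability in `[0, 1]`.
#' @export
equilibriumProbability <- function(seq, target, model = energyModel(),
                                   backend = c("exact", "nested", "nupack"),
                                   maxLength = 35, maxStructures = 5e7) {
    backend <- match.arg(backend)
    dG <- freeEnergy(seq, target, model)  # also checks compatibility
    Q <- .backendQ(seq, target, model, backend, maxLength, maxStructures)
    exp(-dG / model@thermalEnergy) / Q
}

.backendQ <- function(seq, target, model, backend, maxLength, maxStructures) {
    if (backend == "nested") {
        if (any(target@pages == 2L))
            stop("the 'nested' backend only supports pseudoknot-free targets")
        nestedPartitionFunction(seq, model)
    } else if (backend == "exact") {
        .exactEvaluate(seq, model, TRUE, maxLength, maxStructures)$Q
    } else {
        nupackPartitionFunction(seq, model)
    }
}

#' Partition function of the pseudoknot-free ensemble (dynamic programming)
#'
#' O(n^3) recursion over all non-crossing structures with `j >= i + 3`;
#' identical in value to [enumerateEnsemble()] with `pkAllowed = FALSE`.
#'
#' @param seq RNA sequence string.
#' @param model An [EnergyModel-class].
#' @return The partition function (a positive number, >= 1).
#' @export
nestedPartitionFunction <- function(seq, model = energyModel()) {
    .nestedInside(seq, model)$Q
}

# Two-state McCaskill-style inside recursion with helix stacking:
#   Zb(i, j) = q(i, j) * (Z(i+1, j-1) + (s - 1) * Zb(i+1, j-1))
#   Z(i, j)  = Z(i+1, j) + sum_k Zb(i, k) * Z(k+1, j)
# where s = exp(-stackEnergy / kT) rewards a pair sitting directly on the
# pair (i+1, j-1). Empty and too-short intervals have Z = 1, Zb = 0.
.nestedInside <- function(seq, model) {
    ch <- .checkRnaSequence(seq)
    n <- length(ch)
    q <- .pairWeights(ch, model)
    s <- exp(-model@stackEnergy / model@thermalEnergy)
    Z <- matrix(1, n + 2L, n + 1L)
    Zb <- matrix(0, n + 2L, n + 1L)
    if (n >= 4L) {
        for (span in 3:(n - 1L)) for (i in seq_len(n - span)) {
            j <- i + span
            if (q[i, j] > 0) {
                inner <- if (span >= 5L) Zb[i + 1L, j - 1L] else 0
                Zb[i, j] <- q[i, j] * (Z[i + 1L, j - 1L] + (s - 1) * inner)
            }
            acc <- Z[i + 1L, j]
            for (k in (i + 3L):j)
                if (Zb[i, k] > 0) acc <- acc + Zb[i, k] * Z[k + 1L, j]
            Z[i, j] <- acc
        }
    }
    list(Q = Z[1L, n], Z = Z, Zb = Zb, q = q, s = s, n = n)
}

.pairWeights <- function(ch, model) {
    n <- length(ch)
    q <- matrix(0, n, n)
    if (n < 4L) return(q)
    for (i in seq_len(n - 3L)) for (j in (i + 3L):n) {
        cls <- .pairClass(ch[i], ch[j])
        if (!is.na(cls)) q[i, j] <- exp(-model@pairEnergy[[cls]] / model@thermalEnergy)
    }
    q
}

# Inside-outside pair probabilities for the pseudoknot-free ensemble.
# Zhat(i, j) sums over exterior configurations of a pair (i, j): either no
# pair encloses (i, j) (independent structures left and right), or an
# innermost enclosing pair (k, l) contributes q(k, l) times the two gap
# partition functions times its own exterior - with the stack factor when
# the enclosing pair sits directly on (i, j). P(i, j) = Zb * Zhat / Q.
# O(n^4), adequate at the lengths where a desk-scale designer operates.
.nestedPairProbabilities <- function(seq, model) {
    ins <- .nestedInside(seq, model)
    n <- ins$n; q <- ins$q; s <- ins$s; Q <- ins$Q
    Zin <- function(i, j) if (i > j) 1 else ins$Z[i, j]
    P <- matrix(0, n, n + 1L)
    if (n >= 4L) {
        cand <- which(q > 0, arr.ind = TRUE)
        if (nrow(cand)) {
            spans <- cand[, 2L] - cand[, 1L]
            cand <- cand[order(-spans), , drop = FALSE]
            Zhat <- matrix(0, n, n)
            for (r in seq_len(nrow(cand))) {
                i <- cand[r, 1L]; j <- cand[r, 2L]
                acc <- Zin(1L, i - 1L) * Zin(j + 1L, n)
                if (i > 1L && j < n) {
                    for (k in seq_len(i - 1L)) for (l in (j + 1L):n) {
                        if (q[k, l] > 0) {
                            adj <- if (k == i - 1L && l == j + 1L) s else 1
                            acc <- acc + q[k, l] * adj * Zin(k + 1L, i - 1L) *
                                   Zin(j + 1L, l - 1L) * Zhat[k, l]
                        }
                    }
                }
                Zhat[i, j] <- acc
                P[i, j] <- ins$Zb[i, j] * acc / Q
            }
            P[seq_len(n), seq_len(n)] <- P[seq_len(n), seq_len(n)] +
                t(P[seq_len(n), seq_len(n)])
        }
    }
    P[, n + 1L] <- pmax(0, 1 - rowSums(P[, seq_len(n), drop = FALSE]))
    new("PairProbabilityMatrices", P = P,
        Pnested = P[, seq_len(n), drop = FALSE],
        Pnonnested = matrix(0, n, n))
}

#' Minimum-free-energy structure
#'
#' The argmin of the energy over the backend's ensemble; exact ties (within
#' 1e-9 kcal/mol) are broken by the lexicographically smallest dot-bracket
#' string, which makes the result deterministic.
#'
#' @inheritParams pairProbabilityMatrices
#' @return A [PairedStructure-class].
#' @export
mfeStructure <- function(seq, model = energyModel(),
                         backend = c("exact", "nested", "nupack"),
                         maxLength = 35, maxStructures = 5e7) {
    backend <- match.arg(backend)
    if (backend == "nupack")
        stop("MFE retrieval through the external adapter is not implemented; use backend 'exact' or 'nested'")
    r <- .exactEvaluate(seq, model, pkAllowed = (backend == "exact"),
                        maxLength, maxStructures)
    parseDotBracket(r$mfeDotbracket)
}

# One-shot evaluation used by the design loop: everything Algorithm-style
# iterations need from a single enumeration of the candidate's ensemble.
.backendEvaluate <- function(seq, target, model, backend = "exact",
                             maxLength = 35, maxStructures = 5e7) {
    if (backend == "nested" && any(target@pages == 2L))
        stop("the 'nested' backend only supports pseudoknot-free targets")
    dG <- freeEnergy(seq, target, model)
    if (backend == "exact") {
        r <- .exactEvaluate(seq, model, TRUE, maxLength, maxStructures)
        P <- r$P; Pn <- r$Pnested; Pnn <- r$Pnonnested; Q <- r$Q
    } else if (backend == "nested") {
        m <- .nestedPairProbabilities(seq, model)
        P <- m@P; Pn <- m@Pnested; Pnn <- m@Pnonnested
        Q <- nestedPartitionFunction(seq, model)
    } else {
        m <- nupackPairProbabilities(seq, model)
        P <- m@P; Pn <- m@Pnested; Pnn <- m@Pnonnested
        Q <- nupackPartitionFunction(seq, model)
    }
    S <- structureMatrix(target)
    defect <- ensembleDefect(P, S)
    p <- exp(-dG / model@thermalEnergy) / Q
    list(P = P, Pnested = Pn, Pnonnested = Pnn, Q = Q, dG = dG,
         N = defect[["normalized"]], defect = defect[["defect"]],
         pi = 1 - p, p = p)
}
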