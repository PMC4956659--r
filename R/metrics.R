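# Sequence-quality measures at equilibrium: ensemble defect, probability
# defect, Boltzmann frequency, MFE defect, sequence identity.

#' Ensemble defect and normalized ensemble defect
#'
#' The ensemble-average number of incorrectly paired nucleotides,
#' `n(phi, tau) = n - sum_{i, j} P[i, j] * S[i, j]` over `1 <= i <= n`,
#' `1 <= j <= n + 1`, and its normalization `N = n(phi, tau) / n`.
#'
#' @param P A [PairProbabilityMatrices-class] or the augmented
#'   `n x (n + 1)` probability matrix itself.
#' @param S A [PairedStructure-class] or its augmented structure matrix
#'   (see [structureMatrix()]).
#' @return Named numeric vector with elements `defect` (in `[0, n]`) and
#'   `normalized` (in `[0, 1]`).
#' @examples
#' tgt <- parseDotBracket("((((...))))")
#' P <- pairProbabilityMatrices("GGGGAAACCCC")
#' ensembleDefect(P, tgt)
#' @export
ensembleDefect <- function(P, S) {
    if (is(P, "PairProbabilityMatrices")) P <- P@P
    if (is(S, "PairedStructure")) S <- structureMatrix(S)
    if (!all(dim(P) == dim(S)))
        stop("P and S dimensions differ")
    n <- nrow(P)
    defect <- n - sum(P * S)
    c(defect = defect, normalized = defect / n)
}

#' Probability defect
#'
#' The total equilibrium probability of all non-target structures,
#' `pi = 1 - p(phi, tau)`.
#'
#' @param p Equilibrium probability of the target, in `[0, 1]`.
#' @return `1 - p`.
#' @export
probabilityDefect <- function(p) {
    if (!is.numeric(p) || any(p < 0 | p > 1))
        stop("p must lie in [0, 1]")
    1 - p
}

#' Boltzmann frequency of a target structure
#'
#' `Bf = exp(-dG(phi, tau) / kT) / Q(phi)`: the target's share of the
#' Boltzmann ensemble. Algebraically this is the same expression as the
#' equilibrium probability of the target; it is exposed under its own name
#' because the two quantities are reported separately in design summaries.
#'
#' @inheritParams equilibriumProbability
#' @return Probability in `[0, 1]`.
#' @export
boltzmannFrequency <- function(seq, target, model = energyModel(),
                               backend = c("exact", "nested", "nupack"),
                               maxLength = 35, maxStructures = 5e7) {
    equilibriumProbability(seq, target, model, backend,
                           maxLength = maxLength,
                           maxStructures = maxStructures)
}

#' Structure Hamming distance
#'
#' The number of positions whose pairing partner (or unpaired status)
#' differs between two structures of equal length: unpaired vs paired
#' counts as a disagreement, and pairing with different partners counts
#' once per endpoint. `d = 0` iff the structures are identical.
#'
#' @param a,b [PairedStructure-class] objects of equal length.
#' @return Non-negative integer.
#' @export
structureDistance <- function(a, b) {
    stopifnot(is(a, "PairedStructure"), is(b, "PairedStructure"))
    if (a@n != b@n) stop("structures have different lengths")
    sum(.partnerVector(a) != .partnerVector(b))
}

#' MFE defect of a designed sequence
#'
#' The structure Hamming distance between the predicted MFE structure of
#' the sequence and the target. A design is called successful when the
#' MFE defect is 0.
#'
#' @inheritParams equilibriumProbability
#' @return Non-negative integer.
#' @export
mfeDefect <- function(seq, target, model = energyModel(),
                      backend = c("exact", "nested", "nupack"),
                      maxLength = 35, maxStructures = 5e7) {
    if (!isCompatible(seq, target))
        stop("sequence is not pair-compatible with the target")
    mfe <- mfeStructure(seq, model, backend, maxLength, maxStructures)
    structureDistance(mfe, target)
}

#' Sequence identity of a set of designed sequences
#'
#' The mean, over all unordered distinct pairs of sequences, of the
#' fraction of identical positions. 1 means all sequences are identical;
#' lower values mean a more diverse solution set. All sequences must have
#' equal length (designs for one target are gap-free by construction).
#'
#' @param seqs Character vector of at least two equal-length sequences.
#' @return Mean pairwise identity in `[0, 1]`.
#' @examples
#' sequenceIdentity(c("AAAA", "AACC"))  # 0.5
#' @export
sequenceIdentity <- function(seqs) {
    if (length(seqs) < 2L) stop("at least two sequences are required")
    if (length(unique(nchar(seqs))) != 1L)
        stop("sequences must have equal length")
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    total <- 0
    npairs <- 0L
    for (a in seq_len(nrow(m) - 1L)) for (b in (a + 1L):nrow(m)) {
        total <- total + mean(m[a, ] == m[b, ])
        npairs <- npairs + 1L
    }
    total / npairs
}
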