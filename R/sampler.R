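# The adaptive defect-weighted sampling designer: seed initialization, the
# three mutation operators, and the main design loop with stop condition
# and per-iteration trace.
#
# All operators draw from R's RNG stream; a design run seeds it once from
# the config, making every trial bit-reproducible.

.inapplicable <- function(msg) {
    cond <- simpleError(msg)
    class(cond) <- c("knotdesign_inapplicable_operator", class(cond))
    stop(cond)
}

#' Design run configuration
#'
#' Defaults mirror the reference protocol: `fstop = 0.01`,
#' `maxIt = 400`, adaptive divisor `C = 5`.
#'
#' @param fstop Target normalized ensemble defect in (0, 1].
#' @param maxIt Maximum number of mutation iterations.
#' @param gcContent GC fraction for seed initialization, or `NA` to draw
#'   one uniformly from \[0.20, 0.80\] per seed.
#' @param C Divisor of the adaptive mutation size `m' = N * n / C`.
#' @param seed RNG seed (integer) or `NA` to continue the current stream.
#' @param backend Folding backend: `"exact"`, `"nested"` or `"nupack"`.
#' @param adaptiveEnabled Include the adaptive m-mutation operator?
#'   Setting `FALSE` restricts sampling to the single-nucleotide and pair
#'   operators (the ablation configuration).
#' @param retryCap Draw budget before a defect-gated operator falls back
#'   to ungated uniform selection; `NA` means `100 * n`.
#' @param allNestedPairTypes Allow all six orientations when resampling a
#'   fully free nested pair (default keeps the A-U, G-C, G-U orientations
#'   only).
#' @param maxStructures Enumeration guard for the exact backend.
#' @return A [DesignConfig-class].
#' @export
designConfig <- function(fstop = 0.01, maxIt = 400L, gcContent = NA_real_,
                         C = 5, seed = NA_integer_, backend = "exact",
                         adaptiveEnabled = TRUE, retryCap = NA_real_,
                         allNestedPairTypes = FALSE, maxStructures = 5e7) {
    obj <- new("DesignConfig", fstop = fstop, maxIt = as.integer(maxIt),
               gcContent = as.numeric(gcContent), adaptiveC = C,
               seed = as.integer(seed), backend = backend,
               adaptiveEnabled = adaptiveEnabled,
               retryCap = as.numeric(retryCap),
               allNestedPairTypes = allNestedPairTypes,
               maxStructures = maxStructures)
    validObject(obj)
    obj
}

.templateChars <- function(template, n) {
    if (is.null(template)) rep("o", n)
    else strsplit(template@text, "", fixed = TRUE)[[1L]]
}

#' Initialize a random seed sequence compatible with the target
#'
#' Paired positions are drawn jointly as pair types so the seed always
#' satisfies the base-pairing rules of the target; locked template
#' positions are copied verbatim. Unconstrained positions approximate the
#' requested GC fraction; when `gcContent` is `NA`, a fraction is drawn
#' uniformly from \[0.20, 0.80\] for this seed.
#'
#' @param target A [PairedStructure-class].
#' @param template A [DesignTemplate-class] or `NULL` (no constraints).
#' @param gcContent Numeric in \[0, 1\] or `NA`.
#' @return An RNA sequence string compatible with `target`.
#' @export
initializeSeed <- function(target, template = NULL, gcContent = NA_real_) {
    stopifnot(is(target, "PairedStructure"))
    n <- target@n
    tch <- .templateChars(template, n)
    if (length(tch) != n) stop("template length differs from target length")
    gc <- if (is.na(gcContent)) runif(1L, 0.20, 0.80) else gcContent
    seqc <- rep(NA_character_, n)
    locked <- tch != "o"
    seqc[locked] <- tch[locked]
    p <- target@pairs
    for (r in seq_len(nrow(p))) {
        i <- p[r, 1L]; j <- p[r, 2L]
        if (locked[i] && locked[j]) next  # validated by designTemplate()
        if (locked[i] || locked[j]) {
            fixedPos <- if (locked[i]) i else j
            freePos <- if (locked[i]) j else i
            opts <- .ALLOWED_PARTNERS[[seqc[fixedPos]]]
            seqc[freePos] <- if (length(opts) == 1L) opts else {
                # honour the GC request where the wobble leaves a choice
                gcOpt <- intersect(opts, c("G", "C"))
                auOpt <- setdiff(opts, c("G", "C"))
                if (length(gcOpt) && runif(1L) < gc) sample(c(gcOpt, gcOpt), 1L)
                else if (length(auOpt)) sample(c(auOpt, auOpt), 1L)
                else sample(c(opts, opts), 1L)
            }
        } else {
            pairType <- if (runif(1L) < gc) sample(c("GC", "CG"), 1L)
                        else sample(c("AU", "UA"), 1L)
            seqc[i] <- substr(pairType, 1L, 1L)
            seqc[j] <- substr(pairType, 2L, 2L)
        }
    }
    free <- which(is.na(seqc))
    if (length(free)) {
        pickGC <- runif(length(free)) < gc
        seqc[free[pickGC]] <- sample(c("G", "C"), sum(pickGC), replace = TRUE)
        seqc[free[!pickGC]] <- sample(c("A", "U"), sum(!pickGC), replace = TRUE)
    }
    out <- paste(seqc, collapse = "")
    if (!isCompatible(out, target))
        stop("template and target are jointly unsatisfiable")
    out
}

.augmentedP <- function(P) {
    if (is(P, "PairProbabilityMatrices")) P@P else P
}

#' Single-nucleotide mutation operator (defect-weighted)
#'
#' Repeatedly draws a random unpaired position of the target; locked
#' positions are skipped; position `i` is accepted with probability
#' `1 - P[i, n + 1]` (its contribution to the ensemble defect) and its
#' base replaced by one of the three alternatives, uniformly. If the
#' acceptance gate rejects `retryCap` draws in a row (which happens when
#' the defect is already near zero), the position is chosen uniformly
#' without the gate so the operator stays bounded.
#'
#' @param seq Current sequence.
#' @param target A [PairedStructure-class].
#' @param P A [PairProbabilityMatrices-class] or augmented matrix.
#' @param template A [DesignTemplate-class] or `NULL`.
#' @param retryCap Draw budget before the ungated fallback.
#' @return A sequence differing from `seq` at exactly one unpaired,
#'   unlocked position.
#' @export
mutateSingleNucleotide <- function(seq, target, P, template = NULL,
                                   retryCap = 100 * nchar(seq)) {
    ch <- .checkRnaSequence(seq)
    n <- target@n
    P <- .augmentedP(P)
    tch <- .templateChars(template, n)
    unpaired <- unpairedPositions(target)
    mutable <- unpaired[tch[unpaired] == "o"]
    if (!length(mutable))
        .inapplicable("no unpaired, unlocked position to mutate")
    pos <- NA_integer_
    for (tries in seq_len(retryCap)) {
        i <- unpaired[sample.int(length(unpaired), 1L)]
        if (tch[i] != "o") next
        if (runif(1L) < 1 - P[i, n + 1L]) { pos <- i; break }
    }
    if (is.na(pos)) pos <- mutable[sample.int(length(mutable), 1L)]
    alternatives <- setdiff(c("A", "C", "G", "U"), ch[pos])
    ch[pos] <- alternatives[sample.int(3L, 1L)]
    paste(ch, collapse = "")
}

.NESTED_PAIR_TYPES <- c("AU", "GC", "GU")
.ALL_PAIR_TYPES <- c("AU", "GC", "GU", "UA", "CG", "UG")

# pair rows of `target` that the pair operator can modify, with their mode
.mutablePairRows <- function(target, tch, chSeq) {
    p <- target@pairs
    keep <- logical(nrow(p))
    for (r in seq_len(nrow(p))) {
        li <- tch[p[r, 1L]] != "o"; lj <- tch[p[r, 2L]] != "o"
        if (li && lj) next
        if (li || lj) {
            fixedPos <- if (li) p[r, 1L] else p[r, 2L]
            freePos <- if (li) p[r, 2L] else p[r, 1L]
            opts <- setdiff(.ALLOWED_PARTNERS[[chSeq[fixedPos]]], chSeq[freePos])
            keep[r] <- length(opts) > 0L  # a locked A or C end may leave none
        } else keep[r] <- TRUE
    }
    which(keep)
}

#' Base-pair mutation operator (defect-weighted)
#'
#' Draws a random target pair. Pairs locked at both ends are skipped.
#' Pairs locked at one end mutate only the free end, immediately and
#' without a probability gate, to a base that still forms an allowed pair
#' with the locked end. Fully free pairs pass a defect gate first: nested
#' (page 1) pairs are accepted with probability `1 - P'[i, j]` and
#' reassigned a type from A-U, G-C, G-U (all six orientations if
#' `allTypes`); non-nested (page 2) pairs are accepted with probability
#' `1 - P''[i, j]` and reassigned from all six orientations. The returned
#' sequence differs from the input in one or two positions, all within a
#' single target pair.
#'
#' @param seq Current sequence.
#' @param target A [PairedStructure-class].
#' @param Pnested,Pnonnested Nested / non-nested pair-probability matrices
#'   (or one [PairProbabilityMatrices-class] passed as `Pnested`).
#' @param template A [DesignTemplate-class] or `NULL`.
#' @param retryCap Draw budget before the ungated fallback.
#' @param allTypes Allow all six orientations for nested pairs.
#' @return The mutated sequence.
#' @export
mutateBasepair <- function(seq, target, Pnested, Pnonnested = NULL,
                           template = NULL, retryCap = 100 * nchar(seq),
                           allTypes = FALSE) {
    ch <- .checkRnaSequence(seq)
    if (is(Pnested, "PairProbabilityMatrices")) {
        Pnonnested <- Pnested@Pnonnested
        Pnested <- Pnested@Pnested
    }
    n <- target@n
    tch <- .templateChars(template, n)
    p <- target@pairs
    if (!nrow(p)) .inapplicable("target has no pairs")
    mutable <- .mutablePairRows(target, tch, ch)
    if (!length(mutable)) .inapplicable("no mutable pair")
    chosen <- NA_integer_
    for (tries in seq_len(retryCap)) {
        r <- sample.int(nrow(p), 1L)
        i <- p[r, 1L]; j <- p[r, 2L]
        li <- tch[i] != "o"; lj <- tch[j] != "o"
        if (li && lj) next
        if (li || lj) {
            if (!(r %in% mutable)) next
            chosen <- r; break  # one-end-locked: no gate, mutate immediately
        }
        gate <- if (target@pages[r] == 1L) 1 - Pnested[i, j] else 1 - Pnonnested[i, j]
        if (runif(1L) < gate) { chosen <- r; break }
    }
    if (is.na(chosen)) chosen <- mutable[sample.int(length(mutable), 1L)]
    r <- chosen
    i <- p[r, 1L]; j <- p[r, 2L]
    li <- tch[i] != "o"; lj <- tch[j] != "o"
    if (li || lj) {
        fixedPos <- if (li) i else j
        freePos <- if (li) j else i
        opts <- setdiff(.ALLOWED_PARTNERS[[ch[fixedPos]]], ch[freePos])
        ch[freePos] <- opts[sample.int(length(opts), 1L)]
    } else {
        types <- if (target@pages[r] == 2L || allTypes) .ALL_PAIR_TYPES
                 else .NESTED_PAIR_TYPES
        current <- paste0(ch[i], ch[j])
        opts <- setdiff(types, current)
        pick <- opts[sample.int(length(opts), 1L)]
        ch[i] <- substr(pick, 1L, 1L)
        ch[j] <- substr(pick, 2L, 2L)
    }
    paste(ch, collapse = "")
}

#' Adaptive mutation size m
#'
#' The adaptive operator mutates `m` positions per iteration, with
#' `m = floor(|Normal(m', m'/5)|)` clamped to at least 1, where
#' `m' = N * n / C`. Mutation intensity therefore shrinks as the design
#' approaches the target (`N = 0` always gives `m = 1`).
#'
#' @param N Current normalized ensemble defect in `[0, 1]`.
#' @param n Target length.
#' @param C Positive divisor (default 5).
#' @return A positive integer.
#' @export
computeM <- function(N, n, C = 5) {
    stopifnot(N >= 0, N <= 1, n >= 1, C > 0)
    mPrime <- N * n / C
    m <- floor(abs(rnorm(1L, mPrime, mPrime / 5)))
    max(1L, as.integer(m))
}

#' m-mutation operator
#'
#' Mutates exactly `m` counted positions by random calls to the
#' single-nucleotide and pair operators: a draw landing on an unpaired
#' position (or the guard at count `m - 1`) triggers a single-nucleotide
#' mutation (+1 to the count); a draw landing on a paired position
#' triggers a pair mutation (+2, even when only one base actually
#' changes). When one operator has no mutable site, the other is used in
#' its place (the count may then exceed `m` by one before the loop
#' stops).
#'
#' @param m Number of counted positions to mutate.
#' @param seq Current sequence.
#' @param target A [PairedStructure-class].
#' @param P A [PairProbabilityMatrices-class] (or augmented matrix when
#'   `Pnested`/`Pnonnested` are given separately).
#' @param Pnested,Pnonnested Optional separate matrices.
#' @param template A [DesignTemplate-class] or `NULL`.
#' @param retryCap Draw budget per operator call.
#' @param allTypes Allow all six orientations for nested pairs (passed to
#'   [mutateBasepair()]).
#' @return The mutated sequence, with attribute `mutationCount` holding
#'   the counted total.
#' @export
mMutation <- function(m, seq, target, P, Pnested = NULL, Pnonnested = NULL,
                      template = NULL, retryCap = 100 * nchar(seq),
                      allTypes = FALSE) {
    stopifnot(m >= 1)
    if (is(P, "PairProbabilityMatrices")) {
        Pnested <- P@Pnested; Pnonnested <- P@Pnonnested; P <- P@P
    }
    n <- target@n
    tch <- .templateChars(template, n)
    unp <- unpairedPositions(target)
    canSingle <- any(tch[unp] == "o")
    partner <- .partnerVector(target)
    count <- 0L
    while (count < m) {
        i <- sample.int(n, 1L)
        singleDraw <- partner[i] == 0L || count == m - 1L
        if (singleDraw && canSingle) {
            seq <- mutateSingleNucleotide(seq, target, P, template, retryCap)
            count <- count + 1L
        } else {
            canPair <- length(.mutablePairRows(
                target, tch, strsplit(seq, "", fixed = TRUE)[[1L]])) > 0L
            if (!canPair && !canSingle)
                .inapplicable("no mutable site for the m-mutation operator")
            if (!canPair) {
                seq <- mutateSingleNucleotide(seq, target, P, template, retryCap)
                count <- count + 1L
            } else {
                seq <- mutateBasepair(seq, target, Pnested, Pnonnested,
                                      template, retryCap, allTypes)
                count <- count + 2L
            }
        }
    }
    attr(seq, "mutationCount") <- count
    seq
}

.applicableOperators <- function(target, tch, chSeq, adaptiveEnabled) {
    unp <- unpairedPositions(target)
    op1 <- any(tch[unp] == "o")
    op2 <- length(.mutablePairRows(target, tch, chSeq)) > 0L
    ops <- c(if (op1) 1L, if (op2) 2L,
             if (adaptiveEnabled && (op1 || op2)) 3L)
    ops
}

#' Design an RNA sequence for a pseudoknotted target structure
#'
#' The adaptive defect-weighted sampling loop: initialize a compatible
#' seed, evaluate its equilibrium matrices, then iterate - select one of
#' the applicable mutation operators uniformly at random (the adaptive
#' operator first draws `m` via [computeM()]), mutate, re-evaluate - until
#' the normalized ensemble defect drops to `fstop` or `maxIt` iterations
#' are reached. The best (lowest-N) candidate observed anywhere in the run
#' is returned with its full metrics and the per-iteration trace.
#'
#' @param target A [PairedStructure-class] (within the backend's class).
#' @param template A [DesignTemplate-class] or `NULL`.
#' @param config A [DesignConfig-class].
#' @param model An [EnergyModel-class].
#' @param targetId Identifier stored in the result.
#' @param debug Assert template safety and target compatibility on every
#'   iteration.
#' @return A [DesignResult-class].
#' @examples
#' \donttest{
#' tgt <- parseDotBracket("((((....[[[.))))...]]]")
#' res <- designSequence(tgt, config = designConfig(fstop = 0.05, seed = 1L))
#' res
#' }
#' @export
designSequence <- function(target, template = NULL, config = designConfig(),
                           model = energyModel(), targetId = "target",
                           debug = FALSE) {
    stopifnot(is(target, "PairedStructure"))
    t0 <- proc.time()[["elapsed"]]
    if (!is.na(config@seed)) set.seed(config@seed)
    n <- target@n
    if (!is.null(template)) template <- designTemplate(template@text, target)
    tch <- .templateChars(template, n)
    if (all(tch != "o"))
        stop("template locks every position: nothing to mutate")
    retryCap <- if (is.na(config@retryCap)) 100L * n else as.integer(config@retryCap)
    lockedIdx <- which(tch != "o")

    evalSeq <- function(s)
        .backendEvaluate(s, target, model, config@backend,
                         maxStructures = config@maxStructures)
    phi <- initializeSeed(target, template, config@gcContent)
    ev <- evalSeq(phi)
    best <- list(seq = phi, N = ev$N, pi = ev$pi, dG = ev$dG)
    trace <- data.frame(iteration = 0L, operator = NA_integer_,
                        m = NA_integer_, N = ev$N, pi = ev$pi)
    iter <- 0L
    while (ev$N > config@fstop && iter < config@maxIt) {
        iter <- iter + 1L
        chNow <- strsplit(phi, "", fixed = TRUE)[[1L]]
        ops <- .applicableOperators(target, tch, chNow, config@adaptiveEnabled)
        if (!length(ops)) stop("no applicable mutation operator for this target/template")
        op <- ops[sample.int(length(ops), 1L)]
        m <- NA_integer_
        if (op == 1L) {
            phi <- mutateSingleNucleotide(phi, target, ev$P, template, retryCap)
        } else if (op == 2L) {
            phi <- mutateBasepair(phi, target, ev$Pnested, ev$Pnonnested,
                                  template, retryCap,
                                  allTypes = config@allNestedPairTypes)
        } else {
            m <- computeM(ev$N, n, config@adaptiveC)
            phi <- as.character(mMutation(m, phi, target, ev$P, ev$Pnested,
                                          ev$Pnonnested, template, retryCap,
                                          allTypes = config@allNestedPairTypes))
        }
        ev <- evalSeq(phi)
        if (debug) {
            stopifnot(isCompatible(phi, target))
            if (length(lockedIdx))
                stopifnot(identical(strsplit(phi, "")[[1L]][lockedIdx],
                                    tch[lockedIdx]))
        }
        trace <- rbind(trace, data.frame(iteration = iter, operator = op,
                                         m = m, N = ev$N, pi = ev$pi))
        if (ev$N < best$N)
            best <- list(seq = phi, N = ev$N, pi = ev$pi, dG = ev$dG)
    }
    mu <- mfeDefect(best$seq, target, model, config@backend,
                    maxStructures = config@maxStructures)
    new("DesignResult",
        targetId = targetId,
        sequence = best$seq,
        normalizedDefect = best$N,
        probabilityDefect = best$pi,
        freeEnergy = best$dG,
        mfeDefect = as.numeric(mu),
        boltzmannFrequency = 1 - best$pi,
        iterationsUsed = iter,
        elapsedSeconds = proc.time()[["elapsed"]] - t0,
        reachedFstop = best$N <= config@fstop,
        trace = trace)
}

#' Run several independent design trials for one target
#'
#' Trial `l` runs with RNG seed `config@seed + l`, making the whole set
#' reproducible from the base seed.
#'
#' @inheritParams designSequence
#' @param trials Number of independent trials.
#' @return List of [DesignResult-class] objects.
#' @export
runDesignTrials <- function(target, template = NULL,
                            config = designConfig(), trials = 30L,
                            model = energyModel(), targetId = "target") {
    if (is.na(config@seed))
        stop("runDesignTrials needs a base seed in the config for reproducibility")
    lapply(seq_len(trials), function(l) {
        cfg <- config
        cfg@seed <- config@seed + l
        designSequence(target, template, cfg, model, targetId = targetId)
    })
}
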