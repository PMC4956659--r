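# Synthetic two-page targets and sequences: every other module is testable
# without any external dataset. The generator emulates the structural
# character of natural pseudoknot collections (H-type-like: a crossing
# helix against a nested scaffold) at lengths where the exact enumeration
# backend is comfortable.

.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

#' Generate a random two-page target structure (H-type-like)
#'
#' Builds the dominant natural pseudoknot topology: the nested pairs form
#' one or two contiguous helices and the page-2 pairs form a single
#' contiguous helix whose pairs all cross the first nested helix (the
#' classic H-type arrangement, e.g. `((..[[..))..]]`). Unpaired positions
#' are distributed randomly over the 5' tail, the loops and the 3' tail.
#' Contiguous helices matter: isolated base pairs carry no stacking
#' energy, so structures made of scattered single pairs are thermo-
#' dynamically unrealistic as design targets. The crossing graph is
#' bipartite by construction; deterministic given the RNG state.
#'
#' @param n Structure length (nucleotides).
#' @param numNestedPairs Number of page-1 pairs (>= 2; split into two
#'   helices when 6 or more and space allows).
#' @param numPkPairs Number of page-2 pairs (0 gives a nested-only
#'   structure; otherwise >= 2).
#' @param maxTries Bounded rejection-sampling budget; an infeasible
#'   specification errors out.
#' @return A [PairedStructure-class].
#' @export
randomTwoPageStructure <- function(n, numNestedPairs, numPkPairs = 0L,
                                   maxTries = 200L) {
    n <- as.integer(n)
    h1 <- as.integer(numNestedPairs)
    h2 <- as.integer(numPkPairs)
    if (h1 < 2L) stop("at least two nested pairs are required for a helix")
    if (h2 == 1L) stop("a pseudoknot helix needs at least two pairs")
    nUnpaired <- n - 2L * (h1 + h2)
    if (nUnpaired < 2L)
        stop("more pair endpoints requested than positions available")
    splitLens <- function(total, parts, minima) {
        # random composition of `total` over `parts` cells with minima
        extra <- total - sum(minima)
        if (extra < 0L) return(NULL)
        cuts <- sort(sample.int(extra + parts - 1L, parts - 1L))
        lens <- diff(c(0L, cuts, extra + parts)) - 1L
        minima + lens
    }
    for (tryi in seq_len(maxTries)) {
        if (h2 == 0L) {
            # one or two hairpin helices
            two <- h1 >= 6L && n >= 2L * h1 + 4L && runif(1L) < 0.5
            if (two) {
                hA <- sample(3L:(h1 - 3L), 1L)
                hB <- h1 - hA
                lens <- splitLens(nUnpaired, 5L, c(0L, 2L, 0L, 2L, 0L))
                if (is.null(lens)) next
                ch <- c(rep(".", lens[1L]), rep("(", hA), rep(".", lens[2L]),
                        rep(")", hA), rep(".", lens[3L]), rep("(", hB),
                        rep(".", lens[4L]), rep(")", hB), rep(".", lens[5L]))
            } else {
                lens <- splitLens(nUnpaired, 3L, c(0L, 2L, 0L))
                if (is.null(lens)) next
                ch <- c(rep(".", lens[1L]), rep("(", h1), rep(".", lens[2L]),
                        rep(")", h1), rep(".", lens[3L]))
            }
        } else {
            # H-type: 5'tail, stem1, loop1, pk-open, loop2, stem1', loop3,
            # pk-close, 3'tail
            lens <- splitLens(nUnpaired, 5L, c(0L, 0L, 0L, 0L, 0L))
            if (is.null(lens)) next
            ch <- c(rep(".", lens[1L]), rep("(", h1), rep(".", lens[2L]),
                    rep("[", h2), rep(".", lens[3L]), rep(")", h1),
                    rep(".", lens[4L]), rep("]", h2), rep(".", lens[5L]))
        }
        db <- paste(ch, collapse = "")
        obj <- tryCatch(parseDotBracket(db), error = function(e) NULL)
        if (!is.null(obj)) return(obj)
    }
    stop("could not realize the requested pair counts (infeasible spec?)")
}

#' Random pair-compatible sequence for a structure
#'
#' A thin front over [initializeSeed()] with an unconstrained template:
#' paired positions are drawn jointly as pair types, unpaired positions
#' approximate the requested GC fraction.
#'
#' @param structure A [PairedStructure-class].
#' @param gcContent GC fraction in \[0, 1\] or `NA` (then drawn uniformly
#'   from \[0.20, 0.80\]).
#' @return An RNA sequence string compatible with `structure`.
#' @export
randomSequenceFor <- function(structure, gcContent = NA_real_) {
    initializeSeed(structure, template = NULL, gcContent = gcContent)
}

# 85-nt Hammerhead ribozyme fixture. The conserved-motif template string is
# taken verbatim from the source describing the mouse-gut-metagenome
# cis-acting Hammerhead; the secondary structure is a RECONSTRUCTION (the
# published dot-bracket rendering has ambiguous unpaired run lengths):
# stem 1 (5 bp) closing the molecule, a 5-bp pseudoknot helix starting at
# position 3, an inner 3-bp and a 7-bp stem, with all conserved motif
# blocks (CCUGAUGAG at 17-25, GCGAAA at 41-46, UCG at 69-71) unpaired.
.HH_TEMPLATE <- paste0("oooooooooooooooo", "CCUGAUGAG", "ooooooooooooooo",
                       "GCGAAA", "oooooooooooooooooooooo", "UCG",
                       "oooooooooooooo")
.HH_DOTBRACKET <- paste0("..", "[[[[[", "....", "(((((", ".........",
                         "(((", "..", "]]]]]", "...........", ")))", "..",
                         "(((((((", "...", ")))))))", "...", ")))))",
                         ".........")

#' The bundled Hammerhead ribozyme design fixture (synthetic structure)
#'
#' An 85-nt cis-acting Hammerhead ribozyme target with its conserved-motif
#' design template: 18 locked nucleotides in three blocks (CCUGAUGAG,
#' GCGAAA, UCG) that the designer must carry untouched through every
#' mutation. The base-pair layout is a synthetic reconstruction consistent
#' with the template and the described stem/pseudoknot architecture.
#'
#' @return A record list with `id`, `structure`, `template`.
#' @export
hammerheadTarget <- function() {
    structure <- parseDotBracket(.HH_DOTBRACKET)
    list(id = "HH_synthetic",
         structure = structure,
         template = designTemplate(.HH_TEMPLATE, structure))
}

#' Named, reproducible fixture suites
#'
#' `"toy"` bundles hand-built cases, including the 85-nt Hammerhead
#' template fixture. `"paperlike"` holds 20 random two-page targets of
#' 21-35 nt emulating a natural pseudoknot collection at reduced length;
#' contents are byte-identical across runs (fixed internal seed).
#'
#' @param name `"toy"` or `"paperlike"`.
#' @return List of records (`id`, `structure`, `template`).
#' @export
fixtureSuite <- function(name = c("toy", "paperlike")) {
    name <- match.arg(name)
    if (name == "toy") {
        hp <- parseDotBracket("(((...)))")
        ht <- parseDotBracket("((..[[..))..]]")
        pk22 <- parseDotBracket("((((....[[[.))))...]]]")
        return(list(
            list(id = "hairpin9", structure = hp, template = NULL),
            list(id = "htype14", structure = ht, template = NULL),
            list(id = "pk22", structure = pk22, template = NULL),
            hammerheadTarget()))
    }
    .withSeed(20160722L, {
        lapply(seq_len(20L), function(k) {
            n <- sample(21:35, 1L)
            nNested <- sample(4:6, 1L)
            nPk <- sample(2:3, 1L)
            list(id = sprintf("pseudo_like_%02d", k),
                 structure = randomTwoPageStructure(n, nNested, nPk),
                 template = NULL)
        })
    })
}

#' Generate the desk-scale convergence study targets
#'
#' Twenty random H-type two-page targets at 15-17 nt with a 3-4 bp nested
#' stem and a 3 bp pseudoknot helix: the dominant natural topology, at
#' lengths where the exact enumeration backend evaluates each candidate in
#' a few tens of milliseconds (a 400-iteration trial stays in the seconds
#' range even when the stop condition is never met). Used by the
#' convergence and adaptive-ablation studies.
#'
#' @param count Number of targets.
#' @param lengths Integer vector of admissible lengths.
#' @param seed RNG seed.
#' @return List of records (`id`, `structure`, `template = NULL`).
#' @export
convergenceSuite <- function(count = 20L, lengths = 15:17, seed = 20160723L) {
    .withSeed(seed, {
        lapply(seq_len(count), function(k) {
            n <- lengths[sample.int(length(lengths), 1L)]
            nPk <- 3L
            nOpts <- 3:min(5L, (n - 2L * nPk - 2L) %/% 2L)
            nNested <- nOpts[sample.int(length(nOpts), 1L)]
            list(id = sprintf("conv_%02d", k),
                 structure = randomTwoPageStructure(n, nNested, nPk),
                 template = NULL)
        })
    })
}
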