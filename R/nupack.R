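# Optional adapter for an external pseudoknot-capable folding engine
# (NUPACK's `prob`/`pairs`/`pfunc` programs run with their pseudoknot
# option). The adapter is feature-gated on the binaries being installed;
# the output parser is usable on its own.

#' Is the external folding engine available?
#'
#' @param program Binary to look for.
#' @return Logical scalar.
#' @export
nupackAvailable <- function(program = "pairs") {
    nzchar(Sys.which(program))
}

#' Parse pair-probability output of the external engine
#'
#' Accepts the whitespace-separated triple format `i j p` (1-based
#' indices; `j = n + 1` marks the unpaired column), preceded by an
#' optional line holding `n`; `%` and `#` lines are comments. An optional
#' fourth column may carry the page (1 nested / 2 non-nested); without
#' it the paired mass is reported in the nested matrix and the
#' non-nested matrix stays zero (the triple format does not distinguish
#' the pages - an adapter limitation).
#'
#' @param lines Character vector of output lines.
#' @param n Sequence length.
#' @return A [PairProbabilityMatrices-class].
#' @export
parseNupackPairs <- function(lines, n) {
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "%") &
                   !startsWith(lines, "#")]
    P <- matrix(0, n, n + 1L)
    Pn <- matrix(0, n, n)
    Pnn <- matrix(0, n, n)
    for (ln in lines) {
        fields <- strsplit(ln, "[[:space:]]+")[[1L]]
        if (length(fields) == 1L) next  # leading record holding n
        if (length(fields) < 3L)
            stop(sprintf("unparseable pair-probability line: '%s'", ln))
        i <- as.integer(fields[1L]); j <- as.integer(fields[2L])
        p <- as.numeric(fields[3L])
        if (is.na(i) || is.na(j) || is.na(p) || i < 1L || i > n ||
            j < 1L || j > n + 1L)
            stop(sprintf("pair-probability entry out of range: '%s'", ln))
        P[i, j] <- p
        if (j <= n) {
            P[j, i] <- p
            page <- if (length(fields) >= 4L) as.integer(fields[4L]) else 1L
            if (page == 2L) { Pnn[i, j] <- p; Pnn[j, i] <- p }
            else { Pn[i, j] <- p; Pn[j, i] <- p }
        }
    }
    unfilled <- P[, n + 1L] == 0
    P[unfilled, n + 1L] <- pmax(0, 1 - rowSums(P[unfilled, seq_len(n),
                                                 drop = FALSE]))
    obj <- new("PairProbabilityMatrices", P = P, Pnested = Pn,
               Pnonnested = Pnn)
    validObject(obj)
    obj
}

.nupackRun <- function(program, seq, extra = character(0)) {
    if (!nupackAvailable(program))
        stop(sprintf("external folding engine '%s' is not installed; use backend 'exact' or 'nested'",
                     program))
    dir <- tempfile("nupack")
    dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE))
    prefix <- file.path(dir, "job")
    writeLines(seq, paste0(prefix, ".in"))
    status <- system2(program, c("-pseudo", extra, prefix),
                      stdout = TRUE, stderr = TRUE)
    outFile <- list.files(dir, pattern = "^job\\.(ppairs|pairs|prob)$",
                          full.names = TRUE)
    if (!length(outFile))
        stop(sprintf("'%s' produced no pair-probability output", program))
    readLines(outFile[1L], warn = FALSE)
}

#' Pair probabilities through the external engine
#'
#' @param seq RNA sequence string.
#' @param model Ignored by the external engine (it applies its own
#'   nearest-neighbor parameters); accepted for interface parity.
#' @return A [PairProbabilityMatrices-class].
#' @export
nupackPairProbabilities <- function(seq, model = energyModel()) {
    .checkRnaSequence(seq)
    parseNupackPairs(.nupackRun("pairs", seq), nchar(seq))
}

#' Partition function through the external engine
#'
#' @inheritParams nupackPairProbabilities
#' @return The partition function value.
#' @export
nupackPartitionFunction <- function(seq, model = energyModel()) {
    .checkRnaSequence(seq)
    out <- .nupackRun("pfunc", seq)
    vals <- suppressWarnings(as.numeric(out))
    vals <- vals[!is.na(vals)]
    if (!length(vals)) stop("could not parse a partition function value")
    vals[length(vals)]  # pfunc prints the free energy then Q; take the last
}
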