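# Parsing, validation and classification of pseudoknotted secondary
# structures and design templates. Coordinates are 1-based and inclusive
# throughout.

.PAIR_SET <- c("AU", "UA", "GC", "CG", "GU", "UG")

# partners that form an allowed pair with the given base
.ALLOWED_PARTNERS <- list(
    A = "U", C = "G", G = c("C", "U"), U = c("A", "G")
)

.anyCrossing <- function(pairs) {
    k <- nrow(pairs)
    if (k < 2L) return(FALSE)
    for (a in seq_len(k - 1L)) for (b in seq((a + 1L), k)) {
        i <- pairs[a, 1L]; j <- pairs[a, 2L]
        k1 <- pairs[b, 1L]; l1 <- pairs[b, 2L]
        if ((i < k1 && k1 < j && j < l1) || (k1 < i && i < l1 && l1 < j))
            return(TRUE)
    }
    FALSE
}

.checkRnaSequence <- function(seq) {
    if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
        stop("sequence must be a single non-empty character string")
    ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
    bad <- setdiff(unique(ch), c("A", "C", "G", "U"))
    if (length(bad)) {
        hint <- if ("T" %in% bad) " (DNA 'T' is rejected, not converted)" else ""
        stop(sprintf("illegal base(s) in sequence: %s%s",
                     paste(bad, collapse = ", "), hint))
    }
    ch
}

#' Parse a dot-bracket string into a PairedStructure
#'
#' Supports two bracket layers: round brackets encode page-1 (nested)
#' pairs, square brackets page-2 (non-nested, pseudoknot) pairs, dots are
#' unpaired. Every pair must close at least three positions after it opens
#' (`j >= i + 3`, i.e. hairpin loops hold at least two unpaired bases).
#' Additional bracket layers (`{}`, letters) are rejected: the supported
#' structure class is exactly the set of two-page structures.
#'
#' @param text Dot-bracket string over `.()[]`.
#' @return A [PairedStructure-class].
#' @examples
#' parseDotBracket("((..[[..))..]]")
#' @export
parseDotBracket <- function(text) {
    if (!is.character(text) || length(text) != 1L || !nzchar(text))
        stop("text must be a single non-empty string")
    ch <- strsplit(text, "", fixed = TRUE)[[1L]]
    bad <- setdiff(unique(ch), c(".", "(", ")", "[", "]"))
    if (length(bad))
        stop(sprintf("illegal structure character(s): %s (only two bracket layers '.()[]' are supported)",
                     paste(bad, collapse = ", ")))
    n <- length(ch)
    stack1 <- integer(0)
    stack2 <- integer(0)
    pi <- integer(0); pj <- integer(0); pg <- integer(0)
    for (k in seq_len(n)) {
        c0 <- ch[k]
        if (c0 == "(") stack1 <- c(stack1, k)
        else if (c0 == "[") stack2 <- c(stack2, k)
        else if (c0 == ")") {
            if (!length(stack1)) stop(sprintf("unbalanced ')' at position %d", k))
            i <- stack1[length(stack1)]; stack1 <- stack1[-length(stack1)]
            if (k < i + 3L)
                stop(sprintf("pair (%d, %d) violates j >= i + 3", i, k))
            pi <- c(pi, i); pj <- c(pj, k); pg <- c(pg, 1L)
        } else if (c0 == "]") {
            if (!length(stack2)) stop(sprintf("unbalanced ']' at position %d", k))
            i <- stack2[length(stack2)]; stack2 <- stack2[-length(stack2)]
            if (k < i + 3L)
                stop(sprintf("pair (%d, %d) violates j >= i + 3", i, k))
            pi <- c(pi, i); pj <- c(pj, k); pg <- c(pg, 2L)
        }
    }
    if (length(stack1) || length(stack2))
        stop(sprintf("unbalanced open bracket at position %d",
                     c(stack1, stack2)[1L]))
    ord <- order(pi, pj)
    pairs <- cbind(i = pi[ord], j = pj[ord])
    storage.mode(pairs) <- "integer"
    obj <- new("PairedStructure", n = n, pairs = pairs,
               pages = pg[ord], dotbracket = text)
    validObject(obj)
    obj
}

#' Write a PairedStructure back to dot-bracket notation
#'
#' Inverse of [parseDotBracket()]: page-1 pairs as `()`, page-2 as `[]`,
#' unpaired positions as `.`.
#'
#' @param structure A [PairedStructure-class].
#' @return Dot-bracket string.
#' @export
writeDotBracket <- function(structure) {
    stopifnot(is(structure, "PairedStructure"))
    .renderDotBracket(structure@n, structure@pairs, structure@pages)
}

.renderDotBracket <- function(n, pairs, pages) {
    ch <- rep(".", n)
    if (nrow(pairs)) {
        ch[pairs[, 1L]] <- ifelse(pages == 1L, "(", "[")
        ch[pairs[, 2L]] <- ifelse(pages == 1L, ")", "]")
    }
    paste(ch, collapse = "")
}

#' Assign base pairs to two non-crossing pages
#'
#' Two pairs `(i, j)` and `(k, l)` cross iff `i < k < j < l`. The crossing
#' graph is 2-colored so that each color class is internally non-crossing;
#' the assignment is deterministic: pairs are visited in lexicographic
#' order and the 5'-most pair of each connected component receives page 1.
#' Structures whose crossing graph is not bipartite lie outside the
#' supported two-page pseudoknot class and are rejected with an error of
#' class `knotdesign_page_error` (mirroring the class filter a two-page
#' folding engine imposes on input datasets).
#'
#' @param pairs Two-column matrix of 1-based index pairs, `i < j`.
#' @param n Structure length.
#' @return Integer vector of pages (1 or 2), one per row of `pairs`.
#' @examples
#' twoPageSplit(cbind(c(1, 3), c(5, 8)), 8) # single crossing: pages 1, 2
#' @export
twoPageSplit <- function(pairs, n) {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    k <- nrow(pairs)
    if (k == 0L) return(integer(0))
    if (any(pairs < 1L) || any(pairs > n))
        stop("pair indices out of range")
    if (any(pairs[, 2L] < pairs[, 1L] + 3L))
        stop("every pair must satisfy j >= i + 3")
    if (anyDuplicated(as.vector(pairs)))
        stop("a position may occur in at most one pair")
    ord <- order(pairs[, 1L], pairs[, 2L])
    p <- pairs[ord, , drop = FALSE]
    crossing <- function(a, b) {
        (p[a, 1L] < p[b, 1L] && p[b, 1L] < p[a, 2L] && p[a, 2L] < p[b, 2L]) ||
        (p[b, 1L] < p[a, 1L] && p[a, 1L] < p[b, 2L] && p[b, 2L] < p[a, 2L])
    }
    page <- rep(NA_integer_, k)
    for (root in seq_len(k)) {
        if (!is.na(page[root])) next
        page[root] <- 1L  # 5'-most pair of this component
        queue <- root
        while (length(queue)) {
            a <- queue[1L]; queue <- queue[-1L]
            for (b in seq_len(k)) {
                if (b == a || !crossing(a, b)) next
                if (is.na(page[b])) {
                    page[b] <- 3L - page[a]
                    queue <- c(queue, b)
                } else if (page[b] == page[a]) {
                    cond <- simpleError(
                        "structure is outside the supported two-page pseudoknot class (crossing graph is not bipartite)")
                    class(cond) <- c("knotdesign_page_error", class(cond))
                    stop(cond)
                }
            }
        }
    }
    page[order(ord)]
}

#' Test whether a pair set belongs to the two-page class
#'
#' @inheritParams twoPageSplit
#' @return `TRUE` if [twoPageSplit()] accepts the pair set.
#' @export
isTwoPage <- function(pairs, n) {
    !inherits(tryCatch(twoPageSplit(pairs, n),
                       knotdesign_page_error = function(e) e),
              "knotdesign_page_error")
}

#' Build a PairedStructure from a bare pair list
#'
#' Pages are assigned deterministically by [twoPageSplit()].
#'
#' @inheritParams twoPageSplit
#' @return A [PairedStructure-class].
#' @export
pairedStructure <- function(pairs, n) {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    pages <- twoPageSplit(pairs, n)
    ord <- order(pairs[, 1L], pairs[, 2L])
    pairs <- pairs[ord, , drop = FALSE]
    pages <- pages[ord]
    obj <- new("PairedStructure", n = as.integer(n), pairs = pairs,
               pages = pages,
               dotbracket = .renderDotBracket(as.integer(n), pairs, pages))
    validObject(obj)
    obj
}

#' Augmented structure matrix S(tau)
#'
#' An `n x (n + 1)` 0/1 matrix: entry `(i, j)` is 1 iff `(i, j)` or
#' `(j, i)` is a pair of the structure; entry `(i, n + 1)` is 1 iff
#' position `i` is unpaired. Every row sums to exactly 1.
#'
#' @param structure A [PairedStructure-class].
#' @return Integer matrix, `n` rows and `n + 1` columns.
#' @export
structureMatrix <- function(structure) {
    stopifnot(is(structure, "PairedStructure"))
    n <- structure@n
    S <- matrix(0L, n, n + 1L)
    p <- structure@pairs
    if (nrow(p)) {
        S[cbind(p[, 1L], p[, 2L])] <- 1L
        S[cbind(p[, 2L], p[, 1L])] <- 1L
    }
    unpaired <- setdiff(seq_len(n), as.vector(p))
    S[cbind(unpaired, rep(n + 1L, length(unpaired)))] <- 1L
    S
}

#' Validate a design template against a target structure
#'
#' Checks length, alphabet (`A`, `C`, `G`, `U`, `o`; DNA `T` is rejected)
#' and locked-pair compatibility: if both ends of a target pair are locked,
#' the two locked bases must form an allowed pair (A-U, G-C or G-U in
#' either orientation).
#'
#' @param text Template string.
#' @param target A [PairedStructure-class].
#' @return A [DesignTemplate-class].
#' @export
designTemplate <- function(text, target) {
    stopifnot(is(target, "PairedStructure"))
    obj <- new("DesignTemplate", text = text)
    validObject(obj)
    if (nchar(text) != target@n)
        stop(sprintf("template length %d differs from target length %d",
                     nchar(text), target@n))
    ch <- strsplit(text, "", fixed = TRUE)[[1L]]
    p <- target@pairs
    for (r in seq_len(nrow(p))) {
        a <- ch[p[r, 1L]]; b <- ch[p[r, 2L]]
        if (a != "o" && b != "o" && !(paste0(a, b) %in% .PAIR_SET))
            stop(sprintf("template locks target pair (%d, %d) to %s-%s, which is not an allowed base pair",
                         p[r, 1L], p[r, 2L], a, b))
    }
    obj
}

#' Is a sequence pair-compatible with a target structure?
#'
#' `TRUE` iff every target pair's bases form one of the six allowed pairs
#' A-U, G-C, G-U, U-A, C-G, U-G.
#'
#' @param seq RNA sequence string.
#' @param structure A [PairedStructure-class].
#' @return Logical scalar.
#' @export
isCompatible <- function(seq, structure) {
    stopifnot(is(structure, "PairedStructure"))
    ch <- .checkRnaSequence(seq)
    if (length(ch) != structure@n)
        stop(sprintf("sequence length %d differs from structure length %d",
                     length(ch), structure@n))
    p <- structure@pairs
    if (!nrow(p)) return(TRUE)
    all(paste0(ch[p[, 1L]], ch[p[, 2L]]) %in% .PAIR_SET)
}

# -- accessors ----------------------------------------------------------

#' @describeIn parseDotBracket Number of nucleotides of a structure.
#' @param structure A [PairedStructure-class].
#' @export
structureLength <- function(structure) structure@n

#' @describeIn parseDotBracket Base-pair matrix (columns `i`, `j`).
#' @export
basePairs <- function(structure) structure@pairs

#' @describeIn parseDotBracket Page (1 or 2) of each pair.
#' @export
pairPages <- function(structure) structure@pages

#' @describeIn parseDotBracket The dot-bracket string.
#' @export
dotBracket <- function(structure) structure@dotbracket

#' @describeIn parseDotBracket Indices of unpaired positions.
#' @export
unpairedPositions <- function(structure)
    setdiff(seq_len(structure@n), as.vector(structure@pairs))

# partner vector: partner index per position, 0 if unpaired
.partnerVector <- function(structure) {
    partner <- integer(structure@n)
    p <- structure@pairs
    if (nrow(p)) {
        partner[p[, 1L]] <- p[, 2L]
        partner[p[, 2L]] <- p[, 1L]
    }
    partner
}

#' Locked positions of a design template
#'
#' @param template A [DesignTemplate-class] or `NULL`.
#' @param n Structure length (used when `template` is `NULL`).
#' @return Integer vector of locked (non-`o`) positions.
#' @export
lockedPositions <- function(template, n = NULL) {
    if (is.null(template)) return(integer(0))
    which(strsplit(template@text, "", fixed = TRUE)[[1L]] != "o")
}

#' @describeIn lockedPositions The template text.
#' @export
templateText <- function(template) template@text
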