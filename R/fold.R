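## Deterministic base-pair maximisation folding.
##
## The structure-similarity statistic used by the acceptor-hairpin screen
## consumes only the dot-bracket string, so the default folding engine is
## a Nussinov-style maximiser of the number of base pairs (Watson-Crick
## plus, optionally, G.U wobble) under a minimum hairpin-loop constraint,
## with a fully deterministic traceback.  An externally computed structure
## (e.g. an MFE fold) can be injected instead wherever a dot-bracket
## column is accepted.

canPairMatrix <- function(allowGU) {
    pairs <- c("AU", "UA", "GC", "CG")
    if (allowGU) pairs <- c(pairs, "GU", "UG")
    pairs
}

#' Fold an RNA sequence by base-pair maximisation
#'
#' Computes a secondary structure with the maximum number of base pairs
#' (Watson-Crick, plus G.U when `allowGU = TRUE`) subject to a minimum
#' hairpin-loop length, and returns it in dot-bracket notation.  When
#' several structures attain the maximum, the traceback is deterministic:
#' a position is left unpaired only if no pairing achieves the optimum,
#' and otherwise pairs with the smallest admissible partner that does.
#'
#' @param seq Character scalar or [Biostrings::RNAString] over A, C, G, U.
#' @param minLoop Minimum number of unpaired bases enclosed by a pair
#'   (default 3).
#' @param allowGU Allow G.U wobble pairs (default TRUE).
#' @return Character scalar: dot-bracket structure, same length as `seq`.
#' @examples
#' foldNussinov("GGGGAAAACCCC")
#' @export
foldNussinov <- function(seq, minLoop = 3L, allowGU = TRUE) {
    s <- toupper(as.character(seq))
    if (length(s) != 1L) stop("seq must be a single sequence")
    ch <- strsplit(s, "")[[1L]]
    if (!all(ch %in% c("A", "C", "G", "U")))
        stop("invalid alphabet in sequence (need A/C/G/U): ", s)
    n <- length(ch)
    if (n == 0L) return("")
    ok <- canPairMatrix(allowGU)
    canPair <- function(i, j) paste0(ch[i], ch[j]) %in% ok

    ## M[i,j] = max pairs within i..j (1-based, i > j meaning empty = 0)
    M <- matrix(0L, n, n)
    if (n > minLoop + 1L) {
        for (span in (minLoop + 1L):(n - 1L)) {
            for (i in seq_len(n - span)) {
                j <- i + span
                best <- M[i + 1L, j]          # i unpaired
                for (k in (i + minLoop + 1L):j) {
                    if (!canPair(i, k)) next
                    inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
                    outer <- if (k + 1L <= j) M[k + 1L, j] else 0L
                    cand <- 1L + inner + outer
                    if (cand > best) best <- cand
                }
                M[i, j] <- best
            }
        }
    }

    db <- rep(".", n)
    ## iterative traceback over a stack of intervals; pair i with the
    ## smallest admissible k achieving the optimum, else leave i unpaired
    stack <- list(c(1L, n))
    while (length(stack)) {
        iv <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        i <- iv[1L]; j <- iv[2L]
        while (i < j) {
            if (j - i < minLoop + 1L) break
            target <- M[i, j]
            paired <- FALSE
            for (k in (i + minLoop + 1L):j) {
                if (!canPair(i, k)) next
                inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
                outer <- if (k + 1L <= j) M[k + 1L, j] else 0L
                if (1L + inner + outer == target) {
                    db[i] <- "("; db[k] <- ")"
                    if (k + 1L <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
                    j <- k - 1L; i <- i + 1L
                    paired <- TRUE
                    break
                }
            }
            if (!paired) i <- i + 1L
        }
    }
    paste(db, collapse = "")
}

#' Count paired positions of a dot-bracket string
#'
#' @param structure Dot-bracket character scalar.
#' @return Integer: number of positions that are '(' or ')'.
#' @export
pairedPositions <- function(structure) {
    ch <- strsplit(structure, "")[[1L]]
    if (!all(ch %in% c("(", ")", ".")))
        stop("not a dot-bracket string")
    sum(ch != ".")
}

#' Structure similarity score between two dot-bracket strings
#'
#' The score is the number of nucleotide positions that are paired
#' (i.e. '(' or ')') in *both* structures.  It is symmetric, bounded by
#' the paired-position count of either argument, and equals that count
#' when a structure is compared with itself.
#'
#' @param candidate,reference Dot-bracket strings of equal length.
#' @return Non-negative integer similarity score.
#' @examples
#' structureSimilarity("..(...)..", "(((...)))")  # 2
#' @export
structureSimilarity <- function(candidate, reference) {
    a <- strsplit(candidate, "")[[1L]]
    b <- strsplit(reference, "")[[1L]]
    if (length(a) != length(b))
        stop("structures differ in length (", length(a), " vs ",
             length(b), ")")
    if (!all(a %in% c("(", ")", ".")) || !all(b %in% c("(", ")", ".")))
        stop("not a dot-bracket string")
    sum(a != "." & b != ".")
}
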