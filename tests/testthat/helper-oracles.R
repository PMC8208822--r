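## Independent oracles used by the folding tests.

.pairSet <- function(allowGU) {
    p <- c("AU", "UA", "GC", "CG")
    if (allowGU) p <- c(p, "GU", "UG")
    p
}

## Memoised maximum-pair oracle, recursing on the *rightmost* position
## (the implementation runs a bottom-up DP on the leftmost), so the two
## routes share only the problem definition.
oracleMaxPairs <- function(seq, minLoop = 3L, allowGU = TRUE) {
    ch <- strsplit(toupper(as.character(seq)), "")[[1L]]
    ok <- .pairSet(allowGU)
    memo <- new.env(parent = emptyenv())
    rec <- function(i, j) {
        if (j - i < minLoop + 1L) return(0L)
        key <- paste(i, j)
        if (!is.null(memo[[key]])) return(memo[[key]])
        best <- rec(i, j - 1L)                     # j unpaired
        for (k in i:(j - minLoop - 1L)) {          # j paired with k
            if (!paste0(ch[k], ch[j]) %in% ok) next
            cand <- 1L + (if (k > i) rec(i, k - 1L) else 0L) +
                rec(k + 1L, j - 1L)
            if (cand > best) best <- cand
        }
        memo[[key]] <- best
        best
    }
    if (length(ch) == 0L) return(0L)
    rec(1L, length(ch))
}

## Exhaustive enumeration of every non-crossing structure (no memo, no
## shared recurrence-pruning): only usable for short sequences.
enumMaxPairs <- function(seq, minLoop = 3L, allowGU = TRUE) {
    ch <- strsplit(toupper(as.character(seq)), "")[[1L]]
    ok <- .pairSet(allowGU)
    rec <- function(idx) {
        if (length(idx) == 0L) return(0L)
        i <- idx[1L]
        best <- rec(idx[-1L])                      # i unpaired
        for (jpos in seq_along(idx)[-1L]) {
            j <- idx[jpos]
            if (j - i - 1L < minLoop) next
            if (!paste0(ch[i], ch[j]) %in% ok) next
            inside <- idx[idx > i & idx < j]
            outside <- idx[idx > j]
            cand <- 1L + rec(inside) + rec(outside)
            if (cand > best) best <- cand
        }
        best
    }
    rec(seq_along(ch))
}

randomRna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                      replace = TRUE), collapse = "")

countPairs <- function(db) {
    sum(strsplit(db, "")[[1L]] == "(")
}
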