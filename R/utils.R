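#' @importFrom methods new validObject is setClass setGeneric setMethod setValidity show
#' @importFrom stats model.matrix optimize p.adjust pchisq pf dnbinom
#'   rnbinom rmultinom runif setNames
#' @importFrom utils read.delim write.table
NULL

## Coordinate conventions
##
## Annotation (GTF) coordinates are 1-based fully-closed throughout the
## package; bedGraph files are 0-based half-open.  Every cross-format
## conversion goes through the two helpers below so that the off-by-one
## logic lives in exactly one place.

#' Convert a 1-based closed interval to 0-based half-open (BED) coordinates
#'
#' @param start,end Integer vectors, 1-based inclusive.
#' @return A list with elements `start` (0-based) and `end` (exclusive).
#' @keywords internal
closedToBed0 <- function(start, end) {
    stopifnot(all(start >= 1L), all(end >= start))
    list(start = start - 1L, end = end)
}

#' Convert 0-based half-open (BED) coordinates to a 1-based closed interval
#'
#' @param start,end Integer vectors, 0-based half-open.
#' @return A list with elements `start` and `end`, 1-based inclusive.
#' @keywords internal
bed0ToClosed <- function(start, end) {
    stopifnot(all(start >= 0L), all(end > start))
    list(start = start + 1L, end = end)
}

## Evaluate an expression under a fixed RNG state, restoring the caller's
## stream afterwards.  All stochastic code in the package funnels through
## this helper so that a master seed yields byte-identical outputs.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}

#' Derive a reproducible child seed from a master seed and a label
#'
#' Each output stream (one file, one simulation stage) draws from its own
#' seed derived from the master seed and a stable text label, so adding a
#' new output never perturbs existing ones.
#'
#' @param seed Integer master seed.
#' @param label Character scalar naming the stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, label) {
    stopifnot(length(seed) == 1L, length(label) == 1L)
    h <- as.double(seed) %% 2147483647
    for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483647
    as.integer(h)
}

## condition constructors: distinct classes so callers can tell a window
## that runs off the contig from a structurally invalid site
windowBoundsError <- function(msg) {
    stop(errorCondition(msg, class = c("windowBoundsError", "spliceMethError")))
}
invalidSiteError <- function(msg) {
    stop(errorCondition(msg, class = c("invalidSiteError", "spliceMethError")))
}
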