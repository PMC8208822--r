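#' @import methods
#' @importClassesFrom GenomicRanges GRangesList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

setClassUnion("dfOrNULL", c("data.frame", "NULL"))

#' TranscriptSet: a set of transcript models
#'
#' Holds exon structures (1-based closed genomic coordinates), gene
#' assignments and optional CDS spans for a set of transcripts.  Exons of
#' each transcript are sorted by start and must not overlap; a CDS span,
#' when present, must start and end inside exons of its transcript.
#'
#' @slot exons A [GenomicRanges::GRangesList], one element per transcript,
#'   named by transcript id.
#' @slot geneId Character vector parallel to `exons`: gene id per transcript.
#' @slot cdsStart,cdsEnd Numeric vectors parallel to `exons`; `NA` when the
#'   transcript has no annotated CDS.
#' @exportClass TranscriptSet
setClass("TranscriptSet",
    slots = c(
        exons = "GRangesList",
        geneId = "character",
        cdsStart = "numeric",
        cdsEnd = "numeric"
    )
)

setValidity("TranscriptSet", function(object) {
    n <- length(object@exons)
    msgs <- character()
    if (length(object@geneId) != n || length(object@cdsStart) != n ||
        length(object@cdsEnd) != n)
        msgs <- c(msgs, "slot lengths disagree")
    if (n > 0L && (is.null(names(object@exons)) ||
                   anyDuplicated(names(object@exons))))
        msgs <- c(msgs, "transcript ids must be unique and non-empty")
    for (i in seq_len(n)) {
        ex <- object@exons[[i]]
        id <- names(object@exons)[i]
        st <- GenomicRanges::start(ex)
        en <- GenomicRanges::end(ex)
        if (length(ex) == 0L) {
            msgs <- c(msgs, sprintf("transcript %s has no exons", id))
            next
        }
        if (is.unsorted(st, strictly = TRUE) && length(ex) > 1L)
            msgs <- c(msgs, sprintf("exons of %s not sorted by start", id))
        if (length(ex) > 1L && any(st[-1L] <= en[-length(ex)]))
            msgs <- c(msgs, sprintf("overlapping exons in transcript %s", id))
        if (length(unique(as.character(GenomicRanges::strand(ex)))) != 1L)
            msgs <- c(msgs, sprintf("mixed strand in transcript %s", id))
        cs <- object@cdsStart[i]; ce <- object@cdsEnd[i]
        if (!is.na(cs)) {
            if (is.na(ce) || ce < cs)
                msgs <- c(msgs, sprintf("bad CDS span in %s", id))
            else if (!any(cs >= st & cs <= en) || !any(ce >= st & ce <= en))
                msgs <- c(msgs, sprintf("CDS of %s not inside its exons", id))
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' @describeIn TranscriptSet Number of transcripts.
#' @param x,object A `TranscriptSet`.
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@exons))

#' Accessors for TranscriptSet
#'
#' `transcriptIds()` and `geneIds()` return the identifier vectors,
#' `exonsByTranscript()` the exon `GRangesList`, and `cdsSpans()` a
#' data.frame of genomic CDS spans (NA where absent).
#'
#' @param x A `TranscriptSet`.
#' @return See each description.
#' @export
transcriptIds <- function(x) names(x@exons)

#' @rdname transcriptIds
#' @export
geneIds <- function(x) stats::setNames(x@geneId, names(x@exons))

#' @rdname transcriptIds
#' @export
exonsByTranscript <- function(x) x@exons

#' @rdname transcriptIds
#' @export
cdsSpans <- function(x) {
    data.frame(
        transcript_id = names(x@exons),
        cds_start = x@cdsStart,
        cds_end = x@cdsEnd,
        row.names = NULL
    )
}

setMethod("show", "TranscriptSet", function(object) {
    cat("TranscriptSet with", length(object), "transcripts (",
        length(unique(object@geneId)), "genes );",
        sum(!is.na(object@cdsStart)), "with CDS\n")
})

#' MethIPCounts: gene x sample counts for an m6A-IP/input design
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose `colData` carries
#' the factorial m6A-IP-seq design: `assay` (input or ip), `genotype`
#' (WT or KO) and `replicate`, plus optional `librarySize`.  The assay
#' matrix `counts` may be fractional after multimapper weighting.
#'
#' @exportClass MethIPCounts
setClass("MethIPCounts", contains = "SummarizedExperiment")

setValidity("MethIPCounts", function(object) {
    cd <- SummarizedExperiment::colData(object)
    msgs <- character()
    if (!all(c("assay", "genotype", "replicate") %in% colnames(cd)))
        return("colData needs columns assay, genotype, replicate")
    if (!all(cd$assay %in% c("input", "ip")))
        msgs <- c(msgs, "assay must be 'input' or 'ip'")
    if (!all(cd$genotype %in% c("WT", "KO")))
        msgs <- c(msgs, "genotype must be 'WT' or 'KO'")
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msgs <- c(msgs, "assay matrix must be named 'counts'")
    else if (any(SummarizedExperiment::assay(object, "counts") < 0))
        msgs <- c(msgs, "counts must be non-negative")
    if (length(msgs)) msgs else TRUE
})

#' Construct a MethIPCounts object
#'
#' @param counts Numeric gene x sample matrix (fractional values allowed,
#'   e.g. after [weightMultimapped()]).
#' @param sampleData data.frame with one row per sample and columns
#'   `assay` ("input"/"ip"), `genotype` ("WT"/"KO"), `replicate`, and
#'   optionally `librarySize`.
#' @return A `MethIPCounts` object.
#' @examples
#' m <- matrix(rpois(40, 20), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
#' sd <- data.frame(assay = rep(c("input", "ip"), each = 4),
#'                  genotype = rep(c("WT", "KO"), 4),
#'                  replicate = rep(1:2, each = 2))
#' MethIPCounts(m, sd)
#' @export
MethIPCounts <- function(counts, sampleData) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(sampleData)
    )
    new("MethIPCounts", se)
}

setMethod("show", "MethIPCounts", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat("MethIPCounts:", nrow(object), "genes x", ncol(object), "samples\n")
    cat("  design: ", paste(sprintf(
        "%s/%s n=%d", rep(c("input", "ip"), each = 2),
        rep(c("WT", "KO"), 2),
        as.vector(table(cd$assay, cd$genotype)[
            cbind(rep(c("input", "ip"), each = 2), rep(c("WT", "KO"), 2))])
    ), collapse = ", "), "\n")
})

#' IsoformQuant: rpm-normalised isoform abundances at one locus
#'
#' Result container of [quantifyIsoforms()]: reads-per-million abundances
#' of the protein-coding (PC, canonical acceptor), alternatively spliced
#' (AS, cryptic upstream acceptor) and intron-retained (IR) isoforms.
#'
#' @slot pcRpm,asRpm,irRpm Numeric scalars, reads per million.
#' @slot librarySize Numeric scalar, total mapped reads used for scaling.
#' @slot nearMiss data.frame of junction records within 1 nt of either
#'   quantified intron but not exactly matching it (QC for dialect
#'   off-by-one errors), or NULL.
#' @exportClass IsoformQuant
setClass("IsoformQuant",
    slots = c(
        pcRpm = "numeric", asRpm = "numeric", irRpm = "numeric",
        librarySize = "numeric", nearMiss = "dfOrNULL"
    )
)

setValidity("IsoformQuant", function(object) {
    v <- c(object@pcRpm, object@asRpm, object@irRpm)
    if (any(v < 0)) return("rpm values must be non-negative")
    if (object@librarySize <= 0) return("librarySize must be positive")
    TRUE
})

#' @rdname IsoformQuant-class
#' @param x An `IsoformQuant`.
#' @export
pcRpm <- function(x) x@pcRpm

#' @rdname IsoformQuant-class
#' @export
asRpm <- function(x) x@asRpm

#' @rdname IsoformQuant-class
#' @export
irRpm <- function(x) x@irRpm

#' @rdname IsoformQuant-class
#' @export
nearMissJunctions <- function(x) x@nearMiss

setMethod("show", "IsoformQuant", function(object) {
    cat(sprintf(
        "IsoformQuant (library %g): PC %.3f  AS %.3f  IR %.3f rpm\n",
        object@librarySize, object@pcRpm, object@asRpm, object@irRpm))
    if (!is.null(object@nearMiss) && nrow(object@nearMiss))
        cat("  ", nrow(object@nearMiss), "near-miss junction record(s)\n")
})

#' MetaProfile: binned metagene coverage profile
#'
#' Holds per-region binned mean coverage (5'UTR, CDS, 3'UTR split into
#' `nBins` bins each) and, optionally, a 1-nt resolution profile around
#' the stop codon.  Bins with no contributing transcript are `NA`, never
#' zero-filled.
#'
#' @slot regions data.frame with columns `region`, `bin`, `mean`, `n`.
#' @slot stopWindow data.frame with columns `offset`, `mean`, `n`, or NULL.
#' @slot nBins Integer, bins per region.
#' @slot halfWindow Integer, half-width of the stop-codon window (nt).
#' @exportClass MetaProfile
setClass("MetaProfile",
    slots = c(
        regions = "dfOrNULL", stopWindow = "dfOrNULL",
        nBins = "integer", halfWindow = "integer"
    )
)

#' @rdname MetaProfile-class
#' @param x A `MetaProfile`.
#' @export
regionProfile <- function(x) x@regions

#' @rdname MetaProfile-class
#' @export
stopWindowProfile <- function(x) x@stopWindow

setMethod("show", "MetaProfile", function(object) {
    cat("MetaProfile:")
    if (!is.null(object@regions))
        cat(" regions [", paste(unique(object@regions$region), collapse = ", "),
            "] x", object@nBins, "bins;")
    if (!is.null(object@stopWindow))
        cat(" stop-codon window +/-", object@halfWindow, "nt;")
    cat("\n")
})
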