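#' Read a splice-junction count table
#'
#' Parses the tab-separated junction dialect emitted by spliced aligners
#' (e.g. `SJ.out.tab`): at least 7 columns — contig, intron start, intron
#' end (both 1-based inclusive), strand code (0 undefined / 1 '+' / 2
#' '-'), splice-motif code, annotated flag, and uniquely-mapping read
#' count.  Columns beyond the seventh are ignored.
#'
#' @param path Path to the junction table.
#' @return data.frame with columns `contig`, `start`, `end`,
#'   `strandCode`, `strand`, `motifCode`, `annotated`, `count`.
#' @export
readJunctionTable <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    empty <- data.frame(
        contig = character(), start = integer(), end = integer(),
        strandCode = integer(), strand = character(),
        motifCode = integer(), annotated = integer(), count = numeric())
    if (!length(lines)) return(empty)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    out <- vector("list", length(fields))
    for (i in seq_along(fields)) {
        f <- fields[[i]]
        if (length(f) < 7L)
            stop(sprintf("line %d: expected >= 7 tab-separated columns", i))
        num <- suppressWarnings(as.numeric(f[c(2L, 3L, 4L, 5L, 6L, 7L)]))
        if (anyNA(num) || any(num[1:2] != floor(num[1:2])))
            stop(sprintf("line %d: malformed numeric field", i))
        out[[i]] <- data.frame(
            contig = f[1L], start = as.integer(num[1L]),
            end = as.integer(num[2L]),
            strandCode = as.integer(num[3L]),
            strand = c("*", "+", "-")[as.integer(num[3L]) + 1L],
            motifCode = as.integer(num[4L]),
            annotated = as.integer(num[5L]),
            count = num[6L])
    }
    df <- do.call(rbind, out)
    if (any(df$start > df$end))
        stop("junction with start > end")
    if (any(df$count < 0))
        stop("negative junction count")
    df
}

#' Read a bedGraph coverage track
#'
#' bedGraph intervals are 0-based half-open on disk; they are converted
#' to the package's 1-based closed convention at this boundary and
#' returned as a per-contig run-length coverage.
#'
#' @param path Path to a bedGraph file.
#' @return An [IRanges::RleList] of per-base depth, one element per contig.
#' @export
readBedGraph <- function(path) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (any(gr$score < 0)) stop("negative depth in bedGraph: ", path)
    GenomicRanges::coverage(gr, weight = gr$score)
}

#' Write a coverage track as bedGraph
#'
#' @param cov An [IRanges::RleList] of per-base depth.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(cov, path) {
    rows <- character()
    for (ctg in names(cov)) {
        r <- cov[[ctg]]
        rl <- S4Vectors::runLength(r)
        rv <- S4Vectors::runValue(r)
        en1 <- cumsum(rl)              # 1-based closed run ends
        st1 <- en1 - rl + 1L
        keep <- rv != 0
        if (!any(keep)) next
        b <- closedToBed0(st1[keep], en1[keep])
        rows <- c(rows, sprintf("%s\t%d\t%d\t%s", ctg, b$start, b$end,
                                format(rv[keep], trim = TRUE,
                                       scientific = FALSE)))
    }
    writeLines(rows, path)
    invisible(path)
}

#' Length of an intron from 1-based inclusive coordinates
#'
#' @param start,end Genomic coordinates, 1-based inclusive.
#' @return `end - start + 1`.
#' @examples
#' intronLength(5848949, 5849317)  # 369
#' @export
intronLength <- function(start, end) {
    stopifnot(all(start <= end))
    end - start + 1
}

#' Reads-per-million normalisation
#'
#' @param count Read count (or per-base depth; any linear quantity).
#' @param librarySize Total mapped reads in the library.
#' @return `count * 1e6 / librarySize`.
#' @export
rpm <- function(count, librarySize) {
    stopifnot(librarySize > 0)
    count * 1e6 / librarySize
}

#' Define the isoform-quantification locus
#'
#' @param contig Contig name.
#' @param canonicalIntron Length-2 numeric: canonical intron (start, end),
#'   1-based inclusive. Spliced reads spanning it support the
#'   protein-coding (PC) isoform.
#' @param alternativeIntron Length-2 numeric: the cryptic upstream
#'   acceptor's intron; must share the donor with, or nest inside, the
#'   canonical intron.  Supports the alternatively spliced (AS) isoform.
#' @param trim Nucleotides removed from each canonical-intron end before
#'   averaging coverage for the intron-retained (IR) isoform (default 10;
#'   avoids splice-junction edge artifacts).
#' @param pcAmpliconLen Optional: fully spliced RT-PCR product length for
#'   this locus, used by [ampliconLength()] cross-checks.
#' @return A validated list of class `LocusDefinition`.
#' @export
locusDefinition <- function(contig, canonicalIntron, alternativeIntron,
                            trim = 10L, pcAmpliconLen = NULL) {
    stopifnot(length(canonicalIntron) == 2L, length(alternativeIntron) == 2L,
              canonicalIntron[1L] <= canonicalIntron[2L],
              alternativeIntron[1L] <= alternativeIntron[2L])
    if (alternativeIntron[1L] < canonicalIntron[1L] ||
        alternativeIntron[2L] > canonicalIntron[2L])
        stop("alternative intron must nest within the canonical intron")
    if (2L * trim >= intronLength(canonicalIntron[1L], canonicalIntron[2L]))
        stop("trim too large for the canonical intron")
    structure(list(contig = contig,
                   canonicalIntron = as.numeric(canonicalIntron),
                   alternativeIntron = as.numeric(alternativeIntron),
                   trim = as.integer(trim),
                   pcAmpliconLen = pcAmpliconLen),
              class = "LocusDefinition")
}

#' Quantify PC / AS / IR isoform abundances at a locus
#'
#' The protein-coding (PC) isoform is quantified by the count of spliced
#' reads spanning exactly the canonical intron, the alternatively spliced
#' (AS) isoform by the count spanning exactly the alternative intron, and
#' the intron-retained (IR) isoform as the mean per-base coverage of the
#' canonical intron trimmed by `trim` nt on both sides.  All three are
#' rpm-normalised.  Junction matching requires exact equality of both
#' intron ends; records within 1 nt of either intron are reported in the
#' `nearMiss` QC slot instead of being merged.
#'
#' @param junctions data.frame from [readJunctionTable()].
#' @param coverage [IRanges::RleList] from [readBedGraph()].
#' @param locus A [locusDefinition()].
#' @param librarySize Total mapped reads of the sample (supplied
#'   explicitly; junction tables undercount the library).
#' @return An [IsoformQuant-class] object.
#' @export
quantifyIsoforms <- function(junctions, coverage, locus, librarySize) {
    stopifnot(inherits(locus, "LocusDefinition"))
    ci <- locus$canonicalIntron; ai <- locus$alternativeIntron
    onCtg <- junctions[junctions$contig == locus$contig, , drop = FALSE]
    exact <- function(iv)
        sum(onCtg$count[onCtg$start == iv[1L] & onCtg$end == iv[2L]])
    near <- function(iv) {
        d1 <- abs(onCtg$start - iv[1L]); d2 <- abs(onCtg$end - iv[2L])
        onCtg[(d1 + d2) > 0 & d1 <= 1 & d2 <= 1, , drop = FALSE]
    }
    pc <- exact(ci); as_ <- exact(ai)
    nm <- unique(rbind(near(ci), near(ai)))

    lo <- ci[1L] + locus$trim; hi <- ci[2L] - locus$trim
    if (lo > hi) stop("trimmed IR interval is empty")
    depth <- if (locus$contig %in% names(coverage)) {
        r <- coverage[[locus$contig]]
        if (hi > length(r)) {
            r <- c(r, S4Vectors::Rle(0, hi - length(r)))
        }
        mean(as.numeric(S4Vectors::window(r, lo, hi)))
    } else 0
    q <- new("IsoformQuant",
             pcRpm = rpm(pc, librarySize),
             asRpm = rpm(as_, librarySize),
             irRpm = rpm(depth, librarySize),
             librarySize = librarySize,
             nearMiss = if (nrow(nm)) nm else NULL)
    validObject(q)
    q
}

#' RT-PCR amplicon length for a retention product
#'
#' The intron-retained amplicon is the fully spliced product plus the
#' retained segment: e.g. a 133-bp spliced product across a 369-nt intron
#' yields a 502-bp retention product.
#'
#' @param baseProductLen Fully spliced product length (bp).
#' @param retainedLen Retained segment length (nt), e.g. from
#'   [intronLength()].
#' @return `baseProductLen + retainedLen`.
#' @examples
#' ampliconLength(133, intronLength(5848949, 5849317))  # 502
#' @export
ampliconLength <- function(baseProductLen, retainedLen) {
    stopifnot(baseProductLen >= 0, retainedLen >= 0)
    baseProductLen + retainedLen
}

#' Write per-locus isoform quantification to TSV
#'
#' @param quants Named list of [IsoformQuant-class] objects (names =
#'   locus ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeIsoformTsv <- function(quants, path) {
    df <- data.frame(
        locus = names(quants),
        pc_rpm = vapply(quants, pcRpm, numeric(1)),
        as_rpm = vapply(quants, asRpm, numeric(1)),
        ir_rpm = vapply(quants, irRpm, numeric(1)),
        library_size = vapply(quants, function(q) q@librarySize, numeric(1)),
        row.names = NULL
    )
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
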