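#' METTL16/METT-10 methylation motifs
#'
#' The default motif set recognised by the METTL16/METT-10 family at 3'
#' splice sites: `UACAGAGA` and `UACAGAAA`, with the methylated adenosine
#' at position 4 (so that the motif's `AG` at positions 4-5 coincides with
#' the acceptor AG).
#'
#' @return Named list with elements `sequences` (character vector) and
#'   `methylIndex` (integer, 1-based position of the methylated A).
#' @export
defaultMotifs <- function() {
    list(sequences = c("UACAGAGA", "UACAGAAA"), methylIndex = 4L)
}

validateMotifs <- function(motifs) {
    stopifnot(is.list(motifs),
              all(c("sequences", "methylIndex") %in% names(motifs)))
    mi <- motifs$methylIndex
    for (m in motifs$sequences) {
        ch <- strsplit(m, "")[[1L]]
        if (!all(ch %in% c("A", "C", "G", "U")))
            stop("motif not over A/C/G/U: ", m)
        if (mi < 1L || mi + 1L > length(ch))
            stop("methylIndex outside motif: ", m)
        if (ch[mi] != "A" || ch[mi + 1L] != "G")
            stop("motif must carry the acceptor AG at methylIndex..+1: ", m)
    }
    motifs
}

#' Scan acceptor sites for anchored methylation motifs
#'
#' A site matches a motif iff the sense-strand window centred on the
#' acceptor adenosine carries the motif in the single register that puts
#' the motif's AG on the acceptor AG (no sliding): motif position
#' `methylIndex` sits on the window centre.  Sites whose window cannot be
#' extracted (runs off the contig) or contains ambiguous bases are
#' skipped and reported in the `skipped` attribute of the result.
#'
#' @param sites GRanges from [enumerateAcceptorSites()].
#' @param genome A [Biostrings::DNAStringSet].
#' @param motifs Motif set as from [defaultMotifs()].
#' @param flank Window half-width in nt (default 20, i.e. 41-nt windows).
#' @return A [S4Vectors::DataFrame] with one row per (site, motif) hit:
#'   columns `contig`, `strand`, `targetA`, `geneId`, `transcriptId`,
#'   `motif`, `window`.  Metadata: `sitesExamined`, `skipped` (data.frame
#'   of site index + reason).
#' @export
scanMotifs <- function(sites, genome, motifs = defaultMotifs(), flank = 20L) {
    motifs <- validateMotifs(motifs)
    if (length(motifs$sequences) &&
        flank < max(nchar(motifs$sequences)))
        stop("flank must be at least the motif length")
    hits <- list()
    skipped <- data.frame(site = integer(), reason = character())
    mi <- motifs$methylIndex
    for (j in seq_along(sites)) {
        w <- tryCatch(as.character(fetchWindow(genome, sites[j], flank)),
                      windowBoundsError = function(e) NA_character_)
        if (is.na(w)) {
            skipped <- rbind(skipped,
                             data.frame(site = j, reason = "out_of_bounds"))
            next
        }
        if (grepl("[^ACGU]", w)) {
            skipped <- rbind(skipped,
                             data.frame(site = j, reason = "ambiguous_base"))
            next
        }
        for (m in motifs$sequences) {
            startPos <- flank + 2L - mi   # motif position mi on window centre
            if (startPos < 1L || startPos + nchar(m) - 1L > nchar(w)) next
            if (substr(w, startPos, startPos + nchar(m) - 1L) == m) {
                hits[[length(hits) + 1L]] <- data.frame(
                    contig = as.character(GenomeInfoDb::seqnames(sites))[j],
                    strand = as.character(GenomicRanges::strand(sites))[j],
                    targetA = sites$targetA[j],
                    geneId = sites$geneId[j],
                    transcriptId = sites$transcriptId[j],
                    motif = m, window = w,
                    stringsAsFactors = FALSE)
            }
        }
    }
    out <- if (length(hits)) S4Vectors::DataFrame(do.call(rbind, hits))
           else S4Vectors::DataFrame(
               contig = character(), strand = character(),
               targetA = numeric(), geneId = character(),
               transcriptId = character(), motif = character(),
               window = character())
    S4Vectors::metadata(out) <- list(sitesExamined = length(sites),
                                     skipped = skipped)
    out
}

#' Fold motif hits and rank them by similarity to a reference hairpin
#'
#' Each hit window is folded (or looked up in `foldTable` when supplied)
#' and scored against the reference structure with
#' [structureSimilarity()].  Candidates are sorted by similarity
#' descending, ties broken by (contig, coordinate) ascending, and given
#' 1-based competition ranks (ties share the better rank).  Motif-positive
#' but structure-poor sites are retained with their low scores; no score
#' cutoff is applied.
#'
#' @param hits DataFrame from [scanMotifs()].
#' @param reference Dot-bracket string of the reference hairpin, same
#'   length as the windows.
#' @param minLoop,allowGU Folding parameters, see [foldNussinov()].
#' @param foldTable Optional named character vector mapping window
#'   sequence to an externally computed dot-bracket structure.
#' @return The hits DataFrame with added columns `structure`,
#'   `similarity`, `rank`, sorted by rank.
#' @export
rankCandidates <- function(hits, reference, minLoop = 3L, allowGU = TRUE,
                           foldTable = NULL) {
    if (nrow(hits) == 0L) {
        hits$structure <- character(0)
        hits$similarity <- integer(0)
        hits$rank <- integer(0)
        return(hits)
    }
    if (any(nchar(hits$window) != nchar(reference)))
        stop("reference structure length must equal window length")
    fold1 <- function(w) {
        if (!is.null(foldTable) && w %in% names(foldTable)) foldTable[[w]]
        else foldNussinov(w, minLoop = minLoop, allowGU = allowGU)
    }
    uw <- unique(hits$window)
    structs <- vapply(uw, fold1, character(1))
    hits$structure <- unname(structs[hits$window])
    hits$similarity <- vapply(hits$structure, structureSimilarity,
                              integer(1), reference = reference,
                              USE.NAMES = FALSE)
    o <- order(-hits$similarity, hits$contig, hits$targetA)
    hits <- hits[o, ]
    ## competition ranking: 1 + number of strictly better candidates
    hits$rank <- vapply(hits$similarity,
                        function(s) 1L + sum(hits$similarity > s),
                        integer(1))
    hits
}

#' Genome-wide screen for methylatable stem-loop acceptor sites
#'
#' Full composition of the screen: enumerate unique 3' splice sites,
#' scan for anchored methylation motifs, fold each 41-nt window, score
#' against the reference hairpin structure and rank.  Output is
#' deterministic (byte-identical across runs) and invariant to the order
#' of annotation records.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param transcripts A [TranscriptSet] (or path to a GTF file).
#' @param motifs Motif set, see [defaultMotifs()].
#' @param reference Reference hairpin: either a dot-bracket string or an
#'   RNA sequence (then folded with the same engine).
#' @param flank Window half-width (default 20).
#' @param minLoop,allowGU Folding parameters.
#' @param foldTable Optional externally computed structures, see
#'   [rankCandidates()].
#' @return Ranked candidate [S4Vectors::DataFrame]; metadata records
#'   `sitesExamined` and `motifHits`.
#' @export
runScreen <- function(genome, transcripts, motifs = defaultMotifs(),
                      reference, flank = 20L, minLoop = 3L, allowGU = TRUE,
                      foldTable = NULL) {
    if (is.character(transcripts) && length(transcripts) == 1L)
        transcripts <- readTranscriptGtf(transcripts)
    refStruct <- if (grepl("^[().]+$", reference)) reference
                 else foldNussinov(reference, minLoop = minLoop,
                                   allowGU = allowGU)
    if (nchar(refStruct) != 2L * flank + 1L)
        stop("reference structure length must be 2*flank + 1")
    sites <- enumerateAcceptorSites(transcripts, genome)
    hits <- scanMotifs(sites, genome, motifs = motifs, flank = flank)
    ranked <- rankCandidates(hits, refStruct, minLoop = minLoop,
                             allowGU = allowGU, foldTable = foldTable)
    S4Vectors::metadata(ranked) <- c(
        S4Vectors::metadata(hits),
        list(motifHits = nrow(hits)))
    ranked
}

#' Write a ranked candidate table to TSV
#'
#' Columns: BED6 of the acceptor intron is not reproduced here; the table
#' carries contig, 0-based window start/end, name, similarity as score,
#' strand, then window sequence, dot-bracket structure, similarity and
#' rank.
#'
#' @param candidates DataFrame from [runScreen()] / [rankCandidates()].
#' @param path Output path.
#' @param flank Window half-width used in the screen (default 20).
#' @return `path`, invisibly.
#' @export
writeScreenTsv <- function(candidates, path, flank = 20L) {
    b <- closedToBed0(candidates$targetA - flank, candidates$targetA + flank)
    df <- data.frame(
        chrom = candidates$contig,
        start = b$start, end = b$end,
        name = paste0(candidates$geneId, ":", candidates$transcriptId),
        score = candidates$similarity,
        strand = candidates$strand,
        window = candidates$window,
        structure = candidates$structure,
        similarity = candidates$similarity,
        rank = candidates$rank
    )
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
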