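#' Read a genome FASTA file
#'
#' Wraps [Biostrings::readDNAStringSet()] with the checks this package
#' relies on: unique record names and at least one record.  Sequences are
#' upper-cased on read.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A [Biostrings::DNAStringSet], one element per contig.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ACGT"), fa)
#' readGenomeFasta(fa)
#' @export
readGenomeFasta <- function(path) {
    x <- Biostrings::readDNAStringSet(path)
    if (length(x) == 0L)
        stop("no sequences in FASTA file: ", path)
    nm <- names(x)
    ## readDNAStringSet keeps everything after the first space; use the
    ## full header line as the contig name
    if (anyDuplicated(nm))
        stop("duplicate FASTA header(s): ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    x
}

#' Write a genome to FASTA
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
    Biostrings::writeXStringSet(genome, path)
    invisible(path)
}

#' Read transcript models from a GTF file
#'
#' Parses `exon` (and, when present, `CDS`) features into a
#' [TranscriptSet].  Exons are grouped per transcript and sorted by start;
#' the CDS span of a transcript is the min/max over its CDS features.
#'
#' @param path Path to a GTF file (attributes must carry `gene_id` and
#'   `transcript_id`).
#' @return A [TranscriptSet].
#' @export
readTranscriptGtf <- function(path) {
    g <- rtracklayer::import(path, format = "gtf")
    ex <- g[g$type == "exon"]
    if (length(ex) == 0L)
        stop("no exon features in GTF: ", path)
    if (is.null(ex$transcript_id) || any(is.na(ex$transcript_id)) ||
        any(ex$transcript_id == ""))
        stop("exon feature without transcript_id in ", path)
    if (is.null(ex$gene_id) || any(is.na(ex$gene_id)) ||
        any(ex$gene_id == ""))
        stop("exon feature without gene_id in ", path)
    exl <- GenomicRanges::split(ex, ex$transcript_id)
    exl <- S4Vectors::endoapply(exl, function(e) GenomicRanges::sort(e))
    geneId <- vapply(exl, function(e) e$gene_id[1L], character(1))

    cdsStart <- rep(NA_real_, length(exl))
    cdsEnd <- rep(NA_real_, length(exl))
    cds <- g[g$type == "CDS"]
    if (length(cds)) {
        byTx <- split(seq_along(cds), cds$transcript_id)
        idx <- match(names(byTx), names(exl))
        if (anyNA(idx))
            stop("CDS feature for unknown transcript: ",
                 paste(names(byTx)[is.na(idx)], collapse = ", "))
        cdsStart[idx] <- vapply(byTx, function(i)
            min(GenomicRanges::start(cds)[i]), numeric(1))
        cdsEnd[idx] <- vapply(byTx, function(i)
            max(GenomicRanges::end(cds)[i]), numeric(1))
    }
    ts <- new("TranscriptSet", exons = exl, geneId = unname(geneId),
              cdsStart = cdsStart, cdsEnd = cdsEnd)
    validObject(ts)
    ts
}

#' Write a TranscriptSet to GTF
#'
#' Emits one `exon` line per exon and, for transcripts with a CDS span,
#' one `CDS` line per exon segment overlapping the span.
#'
#' @param transcripts A [TranscriptSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTranscriptGtf <- function(transcripts, path) {
    rows <- character()
    ids <- transcriptIds(transcripts)
    for (i in seq_along(ids)) {
        ex <- transcripts@exons[[i]]
        gid <- transcripts@geneId[i]
        attr <- sprintf('gene_id "%s"; transcript_id "%s";', gid, ids[i])
        chr <- as.character(GenomeInfoDb::seqnames(ex))
        str <- as.character(GenomicRanges::strand(ex))
        rows <- c(rows, sprintf("%s\tspliceMeth\texon\t%d\t%d\t.\t%s\t.\t%s",
                                chr, GenomicRanges::start(ex),
                                GenomicRanges::end(ex), str, attr))
        cs <- transcripts@cdsStart[i]; ce <- transcripts@cdsEnd[i]
        if (!is.na(cs)) {
            s <- pmax(GenomicRanges::start(ex), cs)
            e <- pmin(GenomicRanges::end(ex), ce)
            keep <- s <= e
            rows <- c(rows, sprintf(
                "%s\tspliceMeth\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                chr[keep], s[keep], e[keep], str[keep], attr))
        }
    }
    writeLines(rows, path)
    invisible(path)
}

#' Enumerate unique annotated 3' splice sites
#'
#' Every intron of every multi-exon transcript contributes one acceptor
#' (3' splice) site; sites are then de-duplicated on (contig, strand,
#' acceptor position) and returned in deterministic (contig, coordinate,
#' strand) order.  The methylatable adenosine of the acceptor AG
#' (`targetA`) sits at `intron_end - 1` on '+' and `intron_start + 1` on
#' '-' transcripts.  When `genome` is supplied, sites whose sense intron
#' does not end in AG are flagged `canonical = FALSE` (kept, not dropped:
#' annotation noise should not abort a genome-wide run).
#'
#' @param transcripts A [TranscriptSet].
#' @param genome Optional [Biostrings::DNAStringSet] used to flag
#'   non-AG acceptors.
#' @return A [GenomicRanges::GRanges] of introns with metadata columns
#'   `targetA`, `geneId`, `transcriptId` (first contributing transcript),
#'   `nTranscripts`, and `canonical` (NA without a genome).  The metadata
#'   list carries `nRedundant`, the pre-deduplication site count.
#' @export
enumerateAcceptorSites <- function(transcripts, genome = NULL) {
    chr <- character(); st <- integer(); en <- integer(); strd <- character()
    gid <- character(); tid <- character()
    ids <- transcriptIds(transcripts)
    for (i in seq_along(ids)) {
        ex <- transcripts@exons[[i]]
        if (length(ex) < 2L) next
        s <- GenomicRanges::start(ex); e <- GenomicRanges::end(ex)
        ist <- e[-length(e)] + 1L
        ien <- s[-1L] - 1L
        if (any(ien - ist + 1L < 4L))
            invalidSiteError(sprintf("intron shorter than 4 nt in %s", ids[i]))
        k <- length(ist)
        chr <- c(chr, rep(as.character(GenomeInfoDb::seqnames(ex))[1L], k))
        strd <- c(strd, rep(as.character(GenomicRanges::strand(ex))[1L], k))
        st <- c(st, ist); en <- c(en, ien)
        gid <- c(gid, rep(transcripts@geneId[i], k))
        tid <- c(tid, rep(ids[i], k))
    }
    if (!length(st)) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::metadata(gr) <- list(nRedundant = 0L)
        return(gr)
    }
    targetA <- ifelse(strd == "+", en - 1L, st + 1L)
    key <- paste(chr, strd, targetA)
    nRedundant <- length(key)
    grp <- match(key, unique(key))
    first <- !duplicated(grp)
    nTx <- as.integer(table(grp)[as.character(grp[first])])
    gr <- GenomicRanges::GRanges(
        seqnames = chr[first],
        ranges = IRanges::IRanges(st[first], en[first]),
        strand = strd[first],
        targetA = targetA[first],
        geneId = gid[first], transcriptId = tid[first],
        nTranscripts = nTx,
        canonical = NA
    )
    if (!is.null(genome)) {
        gr$canonical <- vapply(seq_along(gr), function(j) {
            ctg <- as.character(GenomeInfoDb::seqnames(gr))[j]
            if (!ctg %in% names(genome)) return(NA)
            if (as.character(GenomicRanges::strand(gr))[j] == "+") {
                dint <- substr(as.character(
                    genome[[ctg]]), GenomicRanges::end(gr)[j] - 1L,
                    GenomicRanges::end(gr)[j])
                identical(dint, "AG")
            } else {
                dint <- substr(as.character(
                    genome[[ctg]]), GenomicRanges::start(gr)[j],
                    GenomicRanges::start(gr)[j] + 1L)
                identical(dint, "CT")   # sense AG read on the minus strand
            }
        }, logical(1))
    }
    o <- order(as.character(GenomeInfoDb::seqnames(gr)), gr$targetA,
               as.character(GenomicRanges::strand(gr)))
    gr <- gr[o]
    S4Vectors::metadata(gr) <- list(nRedundant = nRedundant)
    gr
}

#' Extract a sense-strand RNA window around the acceptor adenosine
#'
#' Returns the `2*flank + 1` nt sequence centred on the methylatable
#' acceptor adenosine of one splice site, in the RNA alphabet and in
#' transcription order (reverse-complemented for '-' strand sites).  The
#' target A sits at position `flank + 1`.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param site A length-1 [GenomicRanges::GRanges] as produced by
#'   [enumerateAcceptorSites()] (metadata column `targetA` required).
#' @param flank Integer number of nucleotides on each side of the target A.
#' @return A [Biostrings::RNAString] of length `2*flank + 1`.
#' @export
fetchWindow <- function(genome, site, flank = 20L) {
    if (length(site) != 1L)
        invalidSiteError("fetchWindow expects a single site")
    ctg <- as.character(GenomeInfoDb::seqnames(site))
    if (!ctg %in% names(genome))
        invalidSiteError(paste("unknown contig:", ctg))
    ta <- site$targetA
    if (is.null(ta) || is.na(ta))
        invalidSiteError("site lacks a targetA coordinate")
    lo <- ta - flank; hi <- ta + flank
    if (lo < 1L || hi > Biostrings::nchar(genome[[ctg]]))
        windowBoundsError(sprintf(
            "window [%d, %d] outside contig %s (length %d)",
            lo, hi, ctg, Biostrings::nchar(genome[[ctg]])))
    d <- Biostrings::subseq(genome[[ctg]], lo, hi)
    if (as.character(GenomicRanges::strand(site)) == "-")
        d <- Biostrings::reverseComplement(d)
    Biostrings::RNAString(d)
}

#' Export acceptor sites as BED6
#'
#' Writes the intron intervals in 6-column BED (0-based half-open) with
#' name `gene:transcript-index`, score 0 and strand.
#'
#' @param sites GRanges from [enumerateAcceptorSites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
exportSitesBed <- function(sites, path) {
    b <- closedToBed0(GenomicRanges::start(sites), GenomicRanges::end(sites))
    df <- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(sites)),
        start = b$start, end = b$end,
        name = sprintf("%s:%s-%d", sites$geneId, sites$transcriptId,
                       seq_along(sites)),
        score = 0L,
        strand = as.character(GenomicRanges::strand(sites))
    )
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}
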