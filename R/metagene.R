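## Metagene coverage profiles: per-transcript projection of genomic
## coverage into transcript coordinates, fractional binning of the
## 5'UTR / CDS / 3'UTR regions, and a 1-nt profile around the stop codon.

#' Project genomic coverage onto one transcript
#'
#' Concatenates per-exon depth in transcription order (reversed for '-'
#' strand transcripts); intronic positions do not appear in the result.
#'
#' @param transcripts A [TranscriptSet].
#' @param txId Transcript id to project.
#' @param coverage [IRanges::RleList] of per-base genomic depth.
#' @return Numeric vector of length = total exonic length.
#' @export
projectCoverage <- function(transcripts, txId, coverage) {
    i <- match(txId, transcriptIds(transcripts))
    if (is.na(i)) stop("unknown transcript: ", txId)
    ex <- transcripts@exons[[i]]
    ctg <- as.character(GenomeInfoDb::seqnames(ex))[1L]
    st <- GenomicRanges::start(ex); en <- GenomicRanges::end(ex)
    r <- if (ctg %in% names(coverage)) coverage[[ctg]] else S4Vectors::Rle(0, 0)
    if (length(r) < max(en)) r <- c(r, S4Vectors::Rle(0, max(en) - length(r)))
    v <- unlist(lapply(seq_along(st), function(k)
        as.numeric(S4Vectors::window(r, st[k], en[k]))), use.names = FALSE)
    if (as.character(GenomicRanges::strand(ex))[1L] == "-") v <- rev(v)
    v
}

## Map a genomic position to 1-based transcript coordinates (NA if
## intronic / outside the exons).
genomicToTxPos <- function(ex, pos) {
    st <- GenomicRanges::start(ex); en <- GenomicRanges::end(ex)
    cum <- cumsum(en - st + 1L)
    k <- which(pos >= st & pos <= en)
    if (!length(k)) return(NA_integer_)
    plusPos <- (if (k > 1L) cum[k - 1L] else 0L) + (pos - st[k] + 1L)
    if (as.character(GenomicRanges::strand(ex))[1L] == "-")
        cum[length(cum)] - plusPos + 1L
    else plusPos
}

## 5'UTR / CDS / 3'UTR spans of one transcript in transcript coordinates;
## NULL when the transcript has no CDS.
txRegionSpans <- function(transcripts, i) {
    cs <- transcripts@cdsStart[i]; ce <- transcripts@cdsEnd[i]
    if (is.na(cs)) return(NULL)
    ex <- transcripts@exons[[i]]
    a <- genomicToTxPos(ex, cs); b <- genomicToTxPos(ex, ce)
    if (is.na(a) || is.na(b)) return(NULL)
    cdsLo <- min(a, b); cdsHi <- max(a, b)
    txLen <- sum(GenomicRanges::width(ex))
    list(`5UTR` = c(1L, cdsLo - 1L),
         CDS = c(cdsLo, cdsHi),
         `3UTR` = c(cdsHi + 1L, txLen))
}

## Fractional-overlap bin means of a depth vector: bin k of nBins covers
## the continuous interval [k*L/n, (k+1)*L/n); the bin mean is the
## integral of the step function over the interval divided by its width.
binMeansFractional <- function(v, nBins) {
    L <- length(v)
    cs <- c(0, cumsum(v))                 # integral of depth up to x
    S <- function(x) {                    # x in [0, L], continuous
        i <- floor(x)
        frac <- x - i
        cs[i + 1L] + ifelse(i < L, frac * v[pmin(i + 1L, L)], 0)
    }
    edges <- seq(0, L, length.out = nBins + 1L)
    (S(edges[-1L]) - S(edges[-(nBins + 1L)])) / (L / nBins)
}

#' Binned metagene profile over 5'UTR, CDS and 3'UTR
#'
#' For every transcript with an annotated CDS, the three regions are cut
#' into `nBins` equal-width bins (fractional-overlap weighting, so region
#' lengths need not divide evenly) and per-transcript bin means are
#' averaged across transcripts.  Regions shorter than `minLen` are
#' excluded (that region only; the transcript's other regions still
#' contribute).  Bins with no contributing transcript are `NA`.
#'
#' @param transcripts A [TranscriptSet].
#' @param coverage [IRanges::RleList] of genomic depth.
#' @param nBins Bins per region (default 100).
#' @param minLen Minimum region length in nt (default 100).
#' @param geneWhitelist Optional character vector of gene ids to restrict
#'   to (e.g. genes with significant m6A-IP enrichment).
#' @return A [MetaProfile-class] with the `regions` slot filled.
#' @export
binnedRegionProfile <- function(transcripts, coverage, nBins = 100L,
                                minLen = 100L, geneWhitelist = NULL) {
    regions <- c("5UTR", "CDS", "3UTR")
    sums <- matrix(0, nrow = 3L, ncol = nBins, dimnames = list(regions))
    ns <- matrix(0L, nrow = 3L, ncol = nBins, dimnames = list(regions))
    ids <- transcriptIds(transcripts)
    for (i in seq_along(ids)) {
        if (!is.null(geneWhitelist) &&
            !(transcripts@geneId[i] %in% geneWhitelist)) next
        spans <- txRegionSpans(transcripts, i)
        if (is.null(spans)) next
        v <- projectCoverage(transcripts, ids[i], coverage)
        for (rg in regions) {
            sp <- spans[[rg]]
            len <- sp[2L] - sp[1L] + 1L
            if (len < minLen) next
            bm <- binMeansFractional(v[sp[1L]:sp[2L]], nBins)
            sums[rg, ] <- sums[rg, ] + bm
            ns[rg, ] <- ns[rg, ] + 1L
        }
    }
    if (all(ns == 0L))
        warning("no qualifying transcript for any region")
    df <- data.frame(
        region = rep(regions, each = nBins),
        bin = rep(seq_len(nBins), times = 3L),
        mean = as.vector(t(sums / ifelse(ns == 0L, NA, ns))),
        n = as.vector(t(ns))
    )
    new("MetaProfile", regions = df, stopWindow = NULL,
        nBins = as.integer(nBins), halfWindow = NA_integer_)
}

#' Mean coverage around the stop codon
#'
#' Position-wise mean depth over a window of `+/- halfWindow` nt centred
#' on the first base of the stop codon (taken as the last 3 nt of the
#' annotated CDS) in transcript coordinates.  Window positions outside a
#' transcript are clipped, so the contributor count `n` can drop towards
#' the window edges.
#'
#' @param transcripts A [TranscriptSet].
#' @param coverage [IRanges::RleList] of genomic depth.
#' @param halfWindow Half-width in nt (default 500).
#' @param geneWhitelist Optional gene-id restriction.
#' @return data.frame with columns `offset` (-halfWindow..halfWindow),
#'   `mean`, `n`.
#' @export
stopCodonProfile <- function(transcripts, coverage, halfWindow = 500L,
                             geneWhitelist = NULL) {
    width <- 2L * halfWindow + 1L
    sums <- numeric(width)
    ns <- integer(width)
    ids <- transcriptIds(transcripts)
    for (i in seq_along(ids)) {
        if (!is.null(geneWhitelist) &&
            !(transcripts@geneId[i] %in% geneWhitelist)) next
        spans <- txRegionSpans(transcripts, i)
        if (is.null(spans)) next
        center <- spans$CDS[2L] - 2L       # first base of the stop codon
        if (center < 1L) next
        v <- projectCoverage(transcripts, ids[i], coverage)
        pos <- (center - halfWindow):(center + halfWindow)
        inside <- pos >= 1L & pos <= length(v)
        sums[inside] <- sums[inside] + v[pos[inside]]
        ns[inside] <- ns[inside] + 1L
    }
    data.frame(offset = -halfWindow:halfWindow,
               mean = sums / ifelse(ns == 0L, NA, ns),
               n = ns)
}

#' Full metagene profile (regions + stop-codon window)
#'
#' Convenience wrapper combining [binnedRegionProfile()] and
#' [stopCodonProfile()] into one [MetaProfile-class].
#'
#' @inheritParams binnedRegionProfile
#' @param halfWindow Stop-codon window half-width (default 500).
#' @return A [MetaProfile-class].
#' @export
metaProfile <- function(transcripts, coverage, nBins = 100L, minLen = 100L,
                        halfWindow = 500L, geneWhitelist = NULL) {
    mp <- binnedRegionProfile(transcripts, coverage, nBins = nBins,
                              minLen = minLen, geneWhitelist = geneWhitelist)
    mp@stopWindow <- stopCodonProfile(transcripts, coverage,
                                      halfWindow = halfWindow,
                                      geneWhitelist = geneWhitelist)
    mp@halfWindow <- as.integer(halfWindow)
    mp
}

#' Write a metagene profile as long-format TSV
#'
#' @param profile A [MetaProfile-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMetaProfileTsv <- function(profile, path) {
    df <- regionProfile(profile)
    if (is.null(df)) stop("profile has no region data")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
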