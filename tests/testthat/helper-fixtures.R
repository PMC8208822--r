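## In-code fixtures shared across test files.

## A two-gene genome built by hand: g1 on '+', g2 on '-', both with a
## known intron so window extraction can be checked against planted
## sequences.
makeTinyAnnotation <- function() {
    exl <- GenomicRanges::GRangesList(
        t1 = GenomicRanges::GRanges("c1", IRanges::IRanges(
            c(1, 201), c(100, 300)), strand = "+"),
        t2 = GenomicRanges::GRanges("c1", IRanges::IRanges(
            c(401, 601), c(500, 700)), strand = "-")
    )
    new("TranscriptSet", exons = exl, geneId = c("gA", "gB"),
        cdsStart = c(NA_real_, NA_real_), cdsEnd = c(NA_real_, NA_real_))
}

## Genome in which both introns end (sense-strand) in AG.
makeTinyGenome <- function(seed = 5) {
    g <- spliceMeth:::withSeed(seed, {
        s <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE),
                   collapse = "")
        ## canonical acceptors: '+' intron 101..200 ends AG
        substr(s, 199, 200) <- "AG"
        ## '-' intron 501..600: sense AG means genomic CT at 501..502
        substr(s, 501, 502) <- "CT"
        s
    })
    Biostrings::DNAStringSet(c(c1 = g))
}

## Single-exon transcripts with CDS, convenient for metagene tests:
## each 1000 nt, 5'UTR 200 / CDS 500 / 3'UTR 300.
makeMetageneAnnotation <- function(n = 3, strand = "+") {
    exl <- list()
    cdsStart <- cdsEnd <- numeric(n)
    for (i in seq_len(n)) {
        a <- (i - 1) * 1200 + 1
        exl[[paste0("mt", i)]] <- GenomicRanges::GRanges(
            "cM", IRanges::IRanges(a, a + 999), strand = strand)
        if (strand == "+") {
            cdsStart[i] <- a + 200; cdsEnd[i] <- a + 699
        } else {
            cdsStart[i] <- a + 300; cdsEnd[i] <- a + 799
        }
    }
    new("TranscriptSet", exons = GenomicRanges::GRangesList(exl),
        geneId = paste0("mg", seq_len(n)),
        cdsStart = cdsStart, cdsEnd = cdsEnd)
}

flatCoverage <- function(contig, len, depth) {
    stats::setNames(IRanges::RleList(S4Vectors::Rle(depth, len)), contig)
}
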