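test_that("FASTA reading normalises case, rejects duplicates and empties", {
    fa <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">c1", "acgt"), fa)
    g <- readGenomeFasta(fa)
    expect_equal(as.character(g[["c1"]]), "ACGT")

    writeLines(c(">c1", "ACGT", ">c1", "GGGG"), fa)
    expect_error(readGenomeFasta(fa), "c1")

    writeLines(character(), fa)
    expect_error(readGenomeFasta(fa), "no sequences")
})

test_that("FASTA round-trips through write + read unchanged", {
    g <- Biostrings::DNAStringSet(c(c1 = "ACGTACGT", c2 = "TTTTCCCC"))
    fa <- withr::local_tempfile(fileext = ".fa")
    writeGenomeFasta(g, fa)
    g2 <- readGenomeFasta(fa)
    expect_identical(as.character(g2), as.character(g))
})

test_that("GTF parsing groups, sorts and derives CDS spans", {
    gtf <- withr::local_tempfile(fileext = ".gtf")
    attr1 <- 'gene_id "g1"; transcript_id "t1";'
    writeLines(c(
        sprintf("c1\tx\texon\t201\t300\t.\t+\t.\t%s", attr1),  # out of order
        sprintf("c1\tx\texon\t1\t100\t.\t+\t.\t%s", attr1),
        sprintf("c1\tx\tCDS\t50\t100\t.\t+\t0\t%s", attr1),
        sprintf("c1\tx\tCDS\t201\t260\t.\t+\t0\t%s", attr1)
    ), gtf)
    ts <- readTranscriptGtf(gtf)
    expect_equal(length(ts), 1L)
    ex <- exonsByTranscript(ts)[["t1"]]
    expect_equal(GenomicRanges::start(ex), c(1, 201))
    cds <- cdsSpans(ts)
    expect_equal(cds$cds_start, 50)
    expect_equal(cds$cds_end, 260)

    writeLines(sprintf("c1\tx\texon\t1\t100\t.\t+\t.\t%s",
                       'gene_id "g1";'), gtf)
    expect_error(readTranscriptGtf(gtf), "transcript_id")

    writeLines(c(
        sprintf("c1\tx\texon\t1\t100\t.\t+\t.\t%s", attr1),
        sprintf("c1\tx\texon\t50\t150\t.\t+\t.\t%s", attr1)
    ), gtf)
    expect_error(readTranscriptGtf(gtf), "overlap")
})

test_that("acceptor enumeration follows the strand convention and de-duplicates", {
    ts <- makeTinyAnnotation()
    sites <- enumerateAcceptorSites(ts)
    expect_equal(length(sites), 2L)
    plus <- sites[as.character(GenomicRanges::strand(sites)) == "+"]
    minus <- sites[as.character(GenomicRanges::strand(sites)) == "-"]
    ## '+': intron 101-200, target A one base before the terminal G
    expect_equal(GenomicRanges::start(plus), 101)
    expect_equal(GenomicRanges::end(plus), 200)
    expect_equal(plus$targetA, 199)
    ## '-': intron 501-600, mirror convention
    expect_equal(minus$targetA, 502)

    ## two transcripts sharing an acceptor collapse to one site
    exl <- GenomicRanges::GRangesList(
        a = GenomicRanges::GRanges("c1", IRanges::IRanges(
            c(1, 201), c(100, 300)), strand = "+"),
        b = GenomicRanges::GRanges("c1", IRanges::IRanges(
            c(31, 201), c(100, 320)), strand = "+")
    )
    ts2 <- new("TranscriptSet", exons = exl, geneId = c("g", "g"),
               cdsStart = c(NA_real_, NA_real_),
               cdsEnd = c(NA_real_, NA_real_))
    s2 <- enumerateAcceptorSites(ts2)
    expect_equal(length(s2), 1L)
    expect_equal(s2$nTranscripts, 2L)
    expect_equal(S4Vectors::metadata(s2)$nRedundant, 2L)

    ## single-exon transcripts contribute nothing
    ts3 <- new("TranscriptSet",
               exons = GenomicRanges::GRangesList(
                   s = GenomicRanges::GRanges(
                       "c1", IRanges::IRanges(1, 100), strand = "+")),
               geneId = "g", cdsStart = NA_real_, cdsEnd = NA_real_)
    expect_equal(length(enumerateAcceptorSites(ts3)), 0L)
})

test_that("enumeration is idempotent and independent of transcript order", {
    cfg <- syntheticConfig(seed = 19, nGenes = 12)
    toy <- buildToyGenome(cfg)
    s1 <- enumerateAcceptorSites(toy$transcripts)
    ids <- rev(transcriptIds(toy$transcripts))
    perm <- new("TranscriptSet",
                exons = toy$transcripts@exons[ids],
                geneId = rev(toy$transcripts@geneId),
                cdsStart = rev(toy$transcripts@cdsStart),
                cdsEnd = rev(toy$transcripts@cdsEnd))
    s2 <- enumerateAcceptorSites(perm)
    expect_equal(GenomicRanges::start(s1), GenomicRanges::start(s2))
    expect_equal(s1$targetA, s2$targetA)
})

test_that("window extraction is strand-aware, centred, and flags bounds", {
    g <- makeTinyGenome()
    ts <- makeTinyAnnotation()
    sites <- enumerateAcceptorSites(ts, g)
    expect_true(all(sites$canonical))
    plus <- sites[as.character(GenomicRanges::strand(sites)) == "+"]
    minus <- sites[as.character(GenomicRanges::strand(sites)) == "-"]

    w <- fetchWindow(g, plus, flank = 20)
    expect_equal(length(w), 41L)
    expect_equal(as.character(Biostrings::subseq(w, 21, 22)), "AG")
    ## equals the planted genomic slice, transcribed
    slice <- as.character(Biostrings::subseq(g[["c1"]], 179, 219))
    expect_equal(as.character(w), chartr("T", "U", slice))

    ## flank 0: just the acceptor adenosine
    expect_equal(as.character(fetchWindow(g, plus, flank = 0)), "A")

    ## minus strand: reverse complement of the genomic slice
    wm <- fetchWindow(g, minus, flank = 5)
    rc <- Biostrings::reverseComplement(
        Biostrings::subseq(g[["c1"]], 497, 507))
    expect_equal(as.character(wm), chartr("T", "U", as.character(rc)))
    expect_equal(as.character(Biostrings::subseq(wm, 6, 7)), "AG")

    ## out-of-bounds window raises the dedicated condition
    far <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 40),
                                  strand = "+", targetA = 10)
    expect_error(fetchWindow(g, far, flank = 20),
                 class = "windowBoundsError")
    bad <- GenomicRanges::GRanges("c9", IRanges::IRanges(1, 40),
                                  strand = "+", targetA = 10)
    expect_error(fetchWindow(g, bad, flank = 2),
                 class = "invalidSiteError")
})

test_that("windows from a synthetic genome reproduce the planted sequences", {
    cfg <- syntheticConfig(seed = 23, nGenes = 8)
    toy <- buildToyGenome(cfg)
    sites <- enumerateAcceptorSites(toy$transcripts, toy$genome)
    expect_true(all(sites$canonical))
    man <- toy$manifest$genes
    for (i in seq_len(nrow(man))) {
        s <- sites[sites$geneId == man$geneId[i]]
        w <- fetchWindow(toy$genome, s, flank = 20)
        expect_equal(as.character(w), man$window[i])
    }
})

test_that("BED export uses 0-based half-open coordinates", {
    ts <- makeTinyAnnotation()
    sites <- enumerateAcceptorSites(ts)
    bed <- withr::local_tempfile(fileext = ".bed")
    exportSitesBed(sites, bed)
    df <- read.delim(bed, header = FALSE)
    expect_equal(df$V2, GenomicRanges::start(sites) - 1L)
    expect_equal(df$V3, GenomicRanges::end(sites))
    expect_equal(df$V5, c(0L, 0L))
})
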