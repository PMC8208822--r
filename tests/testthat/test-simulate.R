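test_that("synthetic configs validate their weights and sizes", {
    expect_error(syntheticConfig(isoformWeights = list(
        WT = c(pc = 0.5, as = 0.5, ir = 0.5),
        KO = c(pc = 0.8, as = 0.1, ir = 0.1))), "sum to 1")
    expect_error(syntheticConfig(nGenes = 2, nPlantedStructured = 3))
    expect_s3_class(syntheticConfig(), "SyntheticConfig")
})

test_that("toy genomes are reproducible and carry the planted design", {
    cfg <- syntheticConfig(seed = 131, nGenes = 14)
    t1 <- buildToyGenome(cfg)
    t2 <- buildToyGenome(cfg)
    expect_identical(as.character(t1$genome), as.character(t2$genome))
    man <- t1$manifest$genes
    expect_equal(sum(man$class == "structured"), 3L)
    expect_equal(sum(man$class == "unstructured"), 3L)
    ## every planted window carries a motif at the anchored register;
    ## background windows do not
    motifs <- defaultMotifs()$sequences
    expect_true(all(substr(man$window[man$class != "background"],
                           18, 25) %in% motifs))
    expect_false(any(substr(man$window[man$class == "background"],
                            18, 25) %in% motifs))
    ## unstructured controls share < 4 paired positions with the reference
    refStruct <- t1$manifest$referenceStructure
    for (w in man$window[man$class == "unstructured"])
        expect_lt(structureSimilarity(foldNussinov(w), refStruct), 4)

    ## empty genome still yields valid containers
    t0 <- buildToyGenome(syntheticConfig(seed = 1, nGenes = 0,
                                         nPlantedStructured = 0,
                                         nPlantedUnstructured = 0))
    expect_equal(length(t0$transcripts), 0L)
    expect_equal(length(t0$genome), 1L)
})

test_that("generated files validate against every reader", {
    cfg <- syntheticConfig(seed = 137, nGenes = 10)
    dir <- withr::local_tempdir()
    expect_no_warning(ds <- writeSimulatedData(cfg, dir))
    expect_no_warning(g <- readGenomeFasta(file.path(dir, "genome.fa")))
    expect_equal(as.character(g), as.character(ds$genome))
    expect_no_warning(ts <- readTranscriptGtf(file.path(dir, "annotation.gtf")))
    expect_setequal(transcriptIds(ts), transcriptIds(ds$transcripts))
    expect_no_warning(j <- readJunctionTable(
        file.path(dir, "junctions_WT_1.tsv")))
    expect_true(all(j$count > 0))
    expect_no_warning(cov <- readBedGraph(
        file.path(dir, "coverage_WT_1.bedGraph")))
    expect_equal(as.numeric(cov[["chrS"]]),
                 as.numeric(ds$splicing$WT_1$coverage[["chrS"]])[
                     seq_len(length(cov[["chrS"]]))])
    man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                               simplifyVector = TRUE)
    expect_equal(nrow(man$genes), 10L)
    ## same seed, byte-identical files
    dir2 <- withr::local_tempdir()
    writeSimulatedData(cfg, dir2)
    for (f in list.files(dir))
        expect_identical(readLines(file.path(dir, f)),
                         readLines(file.path(dir2, f)), label = f)
})

test_that("degenerate isoform weights zero the right outputs", {
    cfg <- syntheticConfig(seed = 139, nGenes = 3, nPlantedStructured = 1,
                           nPlantedUnstructured = 0,
                           isoformWeights = list(
                               WT = c(pc = 1, as = 0, ir = 0),
                               KO = c(pc = 1, as = 0, ir = 0)))
    toy <- buildToyGenome(cfg)
    spl <- simulateSplicingData(cfg, toy$manifest)
    g <- toy$manifest$genes[1, ]
    j <- spl$WT_1$junctions
    alt <- j[j$start == g$alternativeStart & j$end == g$alternativeEnd, ]
    expect_equal(nrow(alt), 0L)
    loc <- locusDefinition(g$contig, c(g$canonicalStart, g$canonicalEnd),
                           c(g$alternativeStart, g$alternativeEnd))
    q <- quantifyIsoforms(j, spl$WT_1$coverage, loc, 1e6)
    expect_equal(asRpm(q), 0)
    expect_equal(irRpm(q), 0)
    expect_equal(pcRpm(q), cfg$junctionDepth)
})

test_that("IP count simulation is reproducible with genotype-dependent enrichment", {
    cfg <- syntheticConfig(seed = 149, nGenes = 40, nPlantedStructured = 8)
    ip1 <- simulateIpCounts(cfg)
    ip2 <- simulateIpCounts(cfg)
    expect_identical(SummarizedExperiment::assay(ip1, "counts"),
                     SummarizedExperiment::assay(ip2, "counts"))
    truth <- S4Vectors::metadata(ip1)$truth
    cd <- SummarizedExperiment::colData(ip1)
    cts <- SummarizedExperiment::assay(ip1, "counts")
    depth <- S4Vectors::metadata(ip1)$depthFactors
    norm <- sweep(cts, 2, depth, "/")
    wtIp <- cd$assay == "ip" & cd$genotype == "WT"
    koIp <- cd$assay == "ip" & cd$genotype == "KO"
    mRatio <- rowMeans(norm[, wtIp]) / rowMeans(norm[, koIp])
    ## methylated genes are enriched in WT IP only (factor ~4)
    expect_gt(mean(mRatio[truth$methylated]), 2.5)
    expect_lt(abs(mean(mRatio[!truth$methylated]) - 1), 0.3)
})

test_that("whole pipeline recovers the planted truths end to end", {
    cfg <- syntheticConfig(seed = 151, nGenes = 30,
                           nPlantedStructured = 3, nPlantedUnstructured = 3)
    toy <- buildToyGenome(cfg)
    man <- toy$manifest$genes

    ## (a) screen: planted structured acceptors above all controls
    sc <- runScreen(toy$genome, toy$transcripts,
                    reference = referenceStructure())
    structured <- man$geneId[man$class == "structured"]
    expect_setequal(sc$geneId[1:3], structured)

    ## (b) isoforms within sampling error (checked in detail elsewhere):
    ## PC fold change KO/WT near the planted 8x
    spl <- simulateSplicingData(cfg, toy$manifest)
    g <- man[man$class == "structured", ][1, ]
    loc <- locusDefinition(g$contig, c(g$canonicalStart, g$canonicalEnd),
                           c(g$alternativeStart, g$alternativeEnd))
    pcW <- mean(sapply(1:3, function(r) pcRpm(quantifyIsoforms(
        spl[[paste0("WT_", r)]]$junctions, spl[[paste0("WT_", r)]]$coverage,
        loc, 1e6))))
    pcK <- mean(sapply(1:3, function(r) pcRpm(quantifyIsoforms(
        spl[[paste0("KO_", r)]]$junctions, spl[[paste0("KO_", r)]]$coverage,
        loc, 1e6))))
    planted <- cfg$isoformWeights$KO[["pc"]] / cfg$isoformWeights$WT[["pc"]]
    expect_lt(abs(pcK / pcW - planted) / planted, 0.1)

    ## (c) differential methylation recovers the planted genes, right sign
    ip <- simulateIpCounts(cfg, toy$manifest)
    res <- nbLrtInteraction(ip)
    called <- callTargets(res, threshold = 0.1, direction = "decrease")
    expect_true(all(structured %in% called))
})
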