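## Synthetic-data generator.
##
## Emits desk-scale toy datasets that mirror the study design this
## package analyses: a genome + annotation with methylatable stem-loop
## acceptors planted among background genes, condition-dependent
## PC/AS/IR isoform mixtures realised as junction counts + coverage in
## biological triplicates, and NB-distributed IP/input count matrices in
## which methylated genes are enriched in WT IP only (modelling loss of
## the mark in the KO).  Every output stream derives its own seed from
## the master seed via a stable label, so outputs are byte-identical
## under a fixed seed and adding a stream never perturbs the others.

#' Configuration of a synthetic dataset
#'
#' Defaults mirror the study design analysed by this package: biological
#' triplicates of a WT and a methyltransferase-KO genotype; in the WT
#' the methylated acceptor is mostly blocked (PC weight 0.1, AS 0.3, IR
#' 0.6) while in the KO the site is used freely (PC 0.8, AS 0.1, IR
#' 0.1, an 8-fold PC gain); m6A-IP enrichment factor 4 for methylated
#' genes in WT IP; NB dispersion 0.05 with base means in 100-1000.
#'
#' @param seed Master integer seed.
#' @param nGenes Total genes in the toy genome.
#' @param nPlantedStructured Genes whose acceptor window carries the
#'   methylation motif inside a designed perfect stem-loop.
#' @param nPlantedUnstructured Control genes carrying the motif with
#'   pair-poor flanks that do not fold with the reference.
#' @param isoformWeights Named list of length-3 numeric vectors
#'   (`pc`, `as`, `ir`, each summing to 1) for conditions `WT` and `KO`.
#' @param junctionDepth Multinomial read depth per gene and sample.
#' @param nbMeanRange Length-2 range of NB base means for IP/input counts.
#' @param nbDispersion NB dispersion (1/size).
#' @param ipEnrichment IP/input enrichment factor of methylated genes in
#'   the WT (lost in the KO).
#' @param replicates Replicates per (assay, genotype) cell.
#' @param intronLengthRange Length-2 range the intron lengths are drawn
#'   from (nt).
#' @param altOffset Distance (nt) between the cryptic and the canonical
#'   acceptor (the AS-retained segment length).
#' @return A validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(seed = 1L,
                            nGenes = 50L,
                            nPlantedStructured = 3L,
                            nPlantedUnstructured = 3L,
                            isoformWeights = list(
                                WT = c(pc = 0.1, as = 0.3, ir = 0.6),
                                KO = c(pc = 0.8, as = 0.1, ir = 0.1)),
                            junctionDepth = 1e4,
                            nbMeanRange = c(100, 1000),
                            nbDispersion = 0.05,
                            ipEnrichment = 4,
                            replicates = 3L,
                            intronLengthRange = c(200L, 800L),
                            altOffset = 93L) {
    stopifnot(nGenes >= nPlantedStructured + nPlantedUnstructured,
              nbDispersion > 0, ipEnrichment > 0, replicates >= 1L,
              junctionDepth >= 1, seed == floor(seed),
              all(c("WT", "KO") %in% names(isoformWeights)))
    for (w in isoformWeights) {
        stopifnot(length(w) == 3L, all(w >= 0), all(w <= 1))
        if (abs(sum(w) - 1) > 1e-8)
            stop("isoform weights must sum to 1 per condition")
    }
    structure(list(
        seed = as.integer(seed), nGenes = as.integer(nGenes),
        nPlantedStructured = as.integer(nPlantedStructured),
        nPlantedUnstructured = as.integer(nPlantedUnstructured),
        isoformWeights = isoformWeights,
        junctionDepth = junctionDepth,
        nbMeanRange = nbMeanRange, nbDispersion = nbDispersion,
        ipEnrichment = ipEnrichment, replicates = as.integer(replicates),
        intronLengthRange = as.integer(intronLengthRange),
        altOffset = as.integer(altOffset)
    ), class = "SyntheticConfig")
}

## Designed 41-nt acceptor window (RNA): positions 1..22 are intronic,
## 23..41 exonic, the acceptor AG sits at 21-22 and the motif at 18-25.
## Structured windows place the motif in the loop of a perfect 8-bp
## G/C stem (positions 9-16 paired with 27-34); fillers come from the
## pair-poor {A, C} alphabet so no competing helix can form.
STEM5 <- "GGCAGGCC"
STEM3 <- "GGCCUGCC"   # reverse complement of STEM5

designWindow <- function(motif, fillers) {
    stopifnot(nchar(motif) == 8L, length(fillers) == 17L)
    paste0(paste(fillers[1:8], collapse = ""), STEM5, fillers[9L],
           motif, fillers[10L], STEM3,
           paste(fillers[11:17], collapse = ""))
}

#' Reference hairpin for screens of synthetic genomes
#'
#' `referenceHairpin()` returns the canonical designed stem-loop window
#' (see the package vignette): the `UACAGAAA` motif in the loop of a
#' perfect 8-bp stem with A/C fillers.  `referenceStructure()` returns
#' the designed structure itself in dot-bracket notation — the 8-bp
#' stem pairing window positions 9-16 with 27-34 and everything else
#' unpaired.  The structure form is the recommended screen reference:
#' a base-pair maximiser decorates any folded sequence with
#' opportunistic filler pairs, whereas the designed stem is exactly the
#' feature the planted acceptors share.
#'
#' @return Character scalar: a 41-nt RNA sequence
#'   (`referenceHairpin`) or a 41-character dot-bracket string
#'   (`referenceStructure`).
#' @export
referenceHairpin <- function() {
    designWindow("UACAGAAA", strsplit("ACACACACAAACACACA", "")[[1L]])
}

#' @rdname referenceHairpin
#' @export
referenceStructure <- function() {
    paste0(strrep(".", 8), strrep("(", 8), strrep(".", 10),
           strrep(")", 8), strrep(".", 7))
}

rnaToDna <- function(x) chartr("U", "T", x)
dnaToRna <- function(x) chartr("T", "U", x)

randSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## Draw an unstructured (pair-poor) motif window: flanks over {A, C},
## verified not to share >= 4 paired positions with the reference
## structure once folded.
drawUnstructuredWindow <- function(motif, refStruct, maxTries = 100L) {
    for (t in seq_len(maxTries)) {
        fillers <- sample(c("A", "C"), 33L, replace = TRUE)
        w <- paste0(paste(fillers[1:17], collapse = ""), motif,
                    paste(fillers[18:33], collapse = ""))
        if (structureSimilarity(foldNussinov(w), refStruct) < 4L)
            return(w)
    }
    stop("could not draw an unstructured motif window in ", maxTries,
         " attempts")
}

## Draw a background acceptor window: random sequence, intron forced to
## end in AG, no anchored motif match.
drawBackgroundWindow <- function(motifs, maxTries = 100L) {
    for (t in seq_len(maxTries)) {
        w <- dnaToRna(randSeq(41L))
        substr(w, 21L, 22L) <- "AG"
        if (!substr(w, 18L, 25L) %in% motifs$sequences) return(w)
    }
    stop("could not draw a background window")
}

#' Build a toy genome with planted methylatable acceptors
#'
#' Generates `nGenes` two-exon genes (exon1 200 nt, intron drawn from
#' `intronLengthRange`, exon2 300 nt, CDS leaving 150-nt UTRs) laid out
#' on one contig with random strands.  The first `nPlantedStructured`
#' genes carry the methylation motif at the acceptor inside a designed
#' perfect stem-loop, the next `nPlantedUnstructured` carry the motif in
#' a pair-poor context, and the rest are motif-free background.  Every
#' gene also has a cryptic acceptor `altOffset` nt upstream of the
#' canonical one.
#'
#' @param config A [syntheticConfig()].
#' @param motifs Motif set, see [defaultMotifs()].
#' @return List with elements `genome` ([Biostrings::DNAStringSet]),
#'   `transcripts` ([TranscriptSet]) and `manifest` (list; see
#'   [writeSimulatedData()] for the serialised form).
#' @export
buildToyGenome <- function(config, motifs = defaultMotifs()) {
    stopifnot(inherits(config, "SyntheticConfig"))
    refStruct <- referenceStructure()
    nS <- config$nPlantedStructured
    nU <- config$nPlantedUnstructured
    nG <- config$nGenes
    withSeed(deriveSeed(config$seed, "genome"), {
        classes <- c(rep("structured", nS), rep("unstructured", nU),
                     rep("background", nG - nS - nU))
        strands <- if (nG) sample(c("+", "-"), nG, replace = TRUE) else character()
        intronLens <- if (nG) sample(seq(config$intronLengthRange[1L],
                                         config$intronLengthRange[2L]),
                                     nG, replace = TRUE) else integer()
        windows <- character(nG)
        for (i in seq_len(nG)) {
            windows[i] <- switch(classes[i],
                structured = designWindow(
                    sample(motifs$sequences, 1L),
                    sample(c("A", "C"), 17L, replace = TRUE)),
                unstructured = drawUnstructuredWindow(
                    sample(motifs$sequences, 1L), refStruct),
                background = drawBackgroundWindow(motifs))
        }

        spacer <- 50L
        contigParts <- character()
        pos <- 1L
        geneRows <- list()
        exl <- list(); geneId <- character()
        cdsStart <- numeric(); cdsEnd <- numeric()
        for (i in seq_len(nG)) {
            L <- intronLens[i]
            glen <- 200L + L + 300L
            ## sense-strand gene sequence with the designed acceptor window
            ## occupying intron[-21..] + exon2[1..19]
            ex1 <- randSeq(200L)
            intr <- randSeq(L)
            ex2 <- randSeq(300L)
            wdna <- rnaToDna(windows[i])
            substr(intr, L - 21L, L) <- substr(wdna, 1L, 22L)
            substr(ex2, 1L, 19L) <- substr(wdna, 23L, 41L)
            sense <- paste0(ex1, intr, ex2)
            a <- pos + spacer          # gene segment start on the contig
            seg <- if (strands[i] == "+") sense else
                as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(sense)))
            contigParts <- c(contigParts, randSeq(spacer), seg)
            pos <- a + glen
            ## sense-coordinate intervals -> genomic
            toGenomic <- function(p1, p2) {
                if (strands[i] == "+") c(a + p1 - 1L, a + p2 - 1L)
                else c(a + glen - p2, a + glen - p1)
            }
            e1 <- toGenomic(1L, 200L)
            e2 <- toGenomic(200L + L + 1L, glen)
            ci <- toGenomic(201L, 200L + L)
            ai <- toGenomic(201L, 200L + L - config$altOffset)
            cds <- toGenomic(151L, 200L + L + 150L)
            exStarts <- sort(c(e1[1L], e2[1L]))
            exEnds <- sort(c(e1[2L], e2[2L]))
            gid <- sprintf("g%03d", i)
            exl[[gid]] <- GenomicRanges::GRanges(
                seqnames = "chrS",
                ranges = IRanges::IRanges(exStarts, exEnds),
                strand = strands[i])
            geneId <- c(geneId, gid)
            cdsStart <- c(cdsStart, min(cds))
            cdsEnd <- c(cdsEnd, max(cds))
            geneRows[[i]] <- data.frame(
                geneId = gid, class = classes[i], strand = strands[i],
                contig = "chrS", intronLength = L,
                canonicalStart = min(ci), canonicalEnd = max(ci),
                alternativeStart = min(ai), alternativeEnd = max(ai),
                targetA = if (strands[i] == "+") max(ci) - 1L else min(ci) + 1L,
                window = windows[i],
                methylated = classes[i] == "structured",
                stringsAsFactors = FALSE)
        }
        contigParts <- c(contigParts, randSeq(spacer))
        genome <- Biostrings::DNAStringSet(
            stats::setNames(paste(contigParts, collapse = ""), "chrS"))
        transcripts <- new("TranscriptSet",
                           exons = GenomicRanges::GRangesList(exl),
                           geneId = geneId,
                           cdsStart = cdsStart, cdsEnd = cdsEnd)
        if (nG) validObject(transcripts)
        manifest <- list(
            config = unclass(config),
            referenceStructure = refStruct,
            genes = if (nG) do.call(rbind, geneRows) else data.frame())
        list(genome = genome, transcripts = transcripts, manifest = manifest)
    })
}

#' Simulate junction counts and coverage per sample
#'
#' For each genotype and replicate, per-gene reads are split
#' Multinomial(`junctionDepth`, weights) between the canonical junction
#' (PC), the cryptic junction (AS) and intron retention (IR, realised as
#' uniform per-base intron coverage); exon coverage equals the total so
#' expression is condition-independent.  Methylated genes use the WT
#' weight set in WT samples only; all other (gene, genotype) pairs use
#' the KO (unblocked) weights.
#'
#' @param config A [syntheticConfig()].
#' @param manifest Manifest from [buildToyGenome()].
#' @return Named list of samples (`WT_1`, ...), each with elements
#'   `junctions` (data.frame in the 7-column dialect), `coverage`
#'   ([IRanges::RleList]), `librarySize`, `genotype`, `replicate`.
#' @export
simulateSplicingData <- function(config, manifest) {
    genes <- manifest$genes
    out <- list()
    for (geno in c("WT", "KO")) {
        for (r in seq_len(config$replicates)) {
            id <- sprintf("%s_%d", geno, r)
            out[[id]] <- withSeed(deriveSeed(config$seed,
                                             paste0("splicing/", id)), {
                jrows <- list(); covGr <- list()
                for (i in seq_len(nrow(genes))) {
                    g <- genes[i, ]
                    wset <- if (g$methylated && geno == "WT") "WT" else "KO"
                    w <- config$isoformWeights[[wset]]
                    nn <- as.vector(rmultinom(1L, config$junctionDepth, w))
                    strandCode <- if (g$strand == "+") 1L else 2L
                    jrows[[length(jrows) + 1L]] <- data.frame(
                        contig = g$contig,
                        start = c(g$canonicalStart, g$alternativeStart),
                        end = c(g$canonicalEnd, g$alternativeEnd),
                        strandCode = strandCode, motifCode = 1L,
                        annotated = 1L, count = nn[1:2])
                    total <- sum(nn)
                    ## exons at total depth, intron at IR depth; exon
                    ## widths depend on strand (exon1 200 nt, exon2 300)
                    upW <- if (g$strand == "+") 200L else 300L
                    downW <- if (g$strand == "+") 300L else 200L
                    covGr[[length(covGr) + 1L]] <- GenomicRanges::GRanges(
                        seqnames = g$contig,
                        ranges = IRanges::IRanges(
                            start = c(g$canonicalStart - upW,
                                      g$canonicalEnd + 1L,
                                      g$canonicalStart),
                            end = c(g$canonicalStart - 1L,
                                    g$canonicalEnd + downW,
                                    g$canonicalEnd)),
                        score = c(total, total, nn[3L]))
                }
                jdf <- do.call(rbind, jrows)
                jdf <- jdf[jdf$count > 0, , drop = FALSE]
                allGr <- do.call(c, covGr)
                cov <- GenomicRanges::coverage(allGr, weight = allGr$score)
                list(junctions = jdf, coverage = cov,
                     librarySize = 1e6, genotype = geno, replicate = r)
            })
        }
    }
    out
}

#' Simulate an NB IP/input count matrix
#'
#' Counts follow `NB(mean = base x depth x enrichment, dispersion)` where
#' `enrichment = ipEnrichment` for methylated genes in WT IP samples and
#' 1 otherwise, modelling loss of the mark in the KO.  Per-sample depth
#' factors are drawn from U(0.5, 1.5).
#'
#' @param config A [syntheticConfig()].
#' @param manifest Optional manifest from [buildToyGenome()]; when NULL,
#'   `nGenes` generic genes are simulated with the first
#'   `nPlantedStructured` marked methylated.
#' @return A [MethIPCounts-class]; its metadata carries `truth`
#'   (data.frame gene/methylated/baseMean) and `depthFactors`.
#' @export
simulateIpCounts <- function(config, manifest = NULL) {
    if (!is.null(manifest)) {
        geneId <- manifest$genes$geneId
        methylated <- manifest$genes$methylated
    } else {
        geneId <- sprintf("g%03d", seq_len(config$nGenes))
        methylated <- seq_len(config$nGenes) <= config$nPlantedStructured
    }
    nG <- length(geneId)
    cd <- expand.grid(replicate = seq_len(config$replicates),
                      genotype = c("WT", "KO"), assay = c("input", "ip"),
                      stringsAsFactors = FALSE)[, 3:1]
    sampleNames <- sprintf("%s_%s_%d", cd$assay, cd$genotype, cd$replicate)
    withSeed(deriveSeed(config$seed, "ipcounts"), {
        base <- runif(nG, config$nbMeanRange[1L], config$nbMeanRange[2L])
        depth <- runif(nrow(cd), 0.5, 1.5)
        counts <- matrix(0, nG, nrow(cd),
                         dimnames = list(geneId, sampleNames))
        for (s in seq_len(nrow(cd))) {
            enr <- ifelse(methylated & cd$assay[s] == "ip" &
                          cd$genotype[s] == "WT", config$ipEnrichment, 1)
            mu <- base * depth[s] * enr
            counts[, s] <- rnbinom(nG, mu = mu, size = 1 / config$nbDispersion)
        }
        cd$librarySize <- round(1e6 * depth)
        rownames(cd) <- sampleNames
        obj <- MethIPCounts(counts, cd)
        S4Vectors::metadata(obj) <- list(
            truth = data.frame(gene = geneId, methylated = methylated,
                               baseMean = base),
            depthFactors = depth)
        obj
    })
}

#' Write a complete synthetic dataset to disk
#'
#' Emits `genome.fa`, `annotation.gtf`, per-sample `junctions_<s>.tsv`
#' and `coverage_<s>.bedGraph`, `counts.tsv`, `samples.tsv`, and
#' `manifest.json` (the machine-readable truth manifest) under `outdir`.
#'
#' @param config A [syntheticConfig()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the in-memory dataset (list with `genome`,
#'   `transcripts`, `manifest`, `splicing`, `ipCounts`).
#' @export
writeSimulatedData <- function(config, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    toy <- buildToyGenome(config)
    writeGenomeFasta(toy$genome, file.path(outdir, "genome.fa"))
    writeTranscriptGtf(toy$transcripts, file.path(outdir, "annotation.gtf"))
    spl <- simulateSplicingData(config, toy$manifest)
    for (s in names(spl)) {
        write.table(spl[[s]]$junctions,
                    file.path(outdir, sprintf("junctions_%s.tsv", s)),
                    sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
        writeBedGraph(spl[[s]]$coverage,
                      file.path(outdir, sprintf("coverage_%s.bedGraph", s)))
    }
    ip <- simulateIpCounts(config, toy$manifest)
    cts <- SummarizedExperiment::assay(ip, "counts")
    write.table(data.frame(gene = rownames(cts), cts, check.names = FALSE),
                file.path(outdir, "counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cd <- as.data.frame(SummarizedExperiment::colData(ip))
    write.table(data.frame(sample = rownames(cd), cd, row.names = NULL),
                file.path(outdir, "samples.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- toy$manifest
    manifest$ipTruth <- S4Vectors::metadata(ip)$truth
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    invisible(list(genome = toy$genome, transcripts = toy$transcripts,
                   manifest = manifest, splicing = spl, ipCounts = ip))
}
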