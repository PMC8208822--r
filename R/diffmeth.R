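#' Weight multimapped reads and summarise to gene level
#'
#' Each read contributes `1/n` to each of the `n` transcripts it maps to;
#' transcript contributions are then summed per gene, yielding fractional
#' gene-level counts.
#'
#' @param assignments data.frame with columns `read` and `transcript`
#'   (one row per read-to-transcript mapping), or a list of character
#'   vectors of transcript ids, one element per read.
#' @param txToGene Named character vector mapping transcript id to gene id.
#' @return Named numeric vector of gene-level counts.
#' @examples
#' a <- data.frame(read = c("r1", "r1", "r2"),
#'                 transcript = c("t1", "t2", "t1"))
#' weightMultimapped(a, c(t1 = "g1", t2 = "g1"))  # g1 = 2
#' @export
weightMultimapped <- function(assignments, txToGene) {
    if (is.list(assignments) && !is.data.frame(assignments)) {
        n <- lengths(assignments)
        if (any(n == 0L)) stop("read with zero target transcripts")
        assignments <- data.frame(
            read = rep(paste0("r", seq_along(assignments)), n),
            transcript = unlist(assignments, use.names = FALSE))
    }
    stopifnot(all(c("read", "transcript") %in% colnames(assignments)))
    if (nrow(assignments) == 0L) return(stats::setNames(numeric(0), character(0)))
    nPerRead <- table(assignments$read)
    w <- 1 / as.numeric(nPerRead[assignments$read])
    gene <- txToGene[assignments$transcript]
    if (anyNA(gene))
        stop("transcript(s) missing from txToGene: ",
             paste(unique(assignments$transcript[is.na(gene)]), collapse = ", "))
    tapply(w, gene, sum)
}

#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors computed against the geometric-mean
#' pseudo-reference over genes with all-positive counts (the DESeq
#' median-of-ratios estimator).  If no gene is positive in every sample,
#' the estimator is undefined and the function falls back to library-size
#' factors (column sums scaled to geometric mean 1) with a warning.
#'
#' @param counts Numeric gene x sample matrix, or a [MethIPCounts-class].
#' @return Named numeric vector of positive factors, one per sample.
#' @export
sizeFactorsMedianRatio <- function(counts) {
    if (is(counts, "MethIPCounts"))
        counts <- SummarizedExperiment::assay(counts, "counts")
    counts <- as.matrix(counts)
    allPos <- rowSums(counts > 0) == ncol(counts)
    if (!any(allPos)) {
        warning("no gene with positive counts in all samples; ",
                "falling back to library-size factors")
        ls <- colSums(counts)
        if (any(ls == 0)) stop("sample with zero total counts")
        return(ls / exp(mean(log(ls))))
    }
    sf <- DESeq2::estimateSizeFactorsForMatrix(counts)
    stats::setNames(as.numeric(sf), colnames(counts))
}

## Negative-binomial log-likelihood for fixed dispersion alpha
nbLogLik <- function(y, mu, alpha) {
    if (alpha < 1e-8) alpha <- 1e-8
    sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

## Fit an NB GLM with log link at fixed dispersion; returns fit or NULL
nbFit <- function(y, X, offset, alpha) {
    fam <- MASS::negative.binomial(theta = 1 / max(alpha, 1e-8))
    tryCatch(
        suppressWarnings(stats::glm.fit(X, y, family = fam, offset = offset,
                                        control = list(maxit = 50))),
        error = function(e) NULL)
}

## Cox-Reid adjusted profile log-likelihood of the dispersion under the
## design X: the adjustment -0.5 * log det(X' W X) corrects the downward
## small-sample bias of plain ML dispersion estimates.
crAdjProfile <- function(logAlpha, y, X, offset) {
    alpha <- exp(logAlpha)
    fit <- nbFit(y, X, offset, alpha)
    if (is.null(fit) || !fit$converged) return(-Inf)
    mu <- fit$fitted.values
    w <- mu / (1 + alpha * mu)          # working weights at the log link
    xtwx <- crossprod(X, X * w)
    d <- determinant(xtwx, logarithm = TRUE)
    if (d$sign <= 0) return(-Inf)
    nbLogLik(y, mu, alpha) - 0.5 * as.numeric(d$modulus)
}

## Estimate per-gene dispersion by maximising the (Cox-Reid adjusted)
## profile likelihood under the full design; floor 1e-8.
estimateDispersion <- function(y, X, offset, adjust = TRUE) {
    f <- function(la) {
        if (adjust) crAdjProfile(la, y, X, offset)
        else {
            fit <- nbFit(y, X, offset, exp(la))
            if (is.null(fit) || !fit$converged) return(-Inf)
            nbLogLik(y, fit$fitted.values, exp(la))
        }
    }
    opt <- stats::optimize(f, interval = c(log(1e-8), log(30)),
                           maximum = TRUE, tol = 1e-3)
    max(exp(opt$maximum), 1e-8)
}

#' Per-gene interaction likelihood-ratio test for differential m6A
#'
#' For each gene, fits a negative-binomial GLM of the counts on the
#' factorial m6A-IP-seq design with log size-factor offsets and compares
#' the full model `~ assay + genotype + assay:genotype` with the reduced
#' model `~ assay + genotype` by a likelihood-ratio test on 1 degree of
#' freedom.  The interaction coefficient is the log2 change of the
#' IP/input enrichment ratio in KO relative to WT; a methylation target
#' lost in the KO has a negative interaction.
#'
#' The per-gene dispersion is estimated once under the full model by
#' maximising the Cox-Reid adjusted profile likelihood (floored at
#' `1e-8`) and shared by both fits, preserving the nested-model
#' reference distribution.  Because the dispersion is estimated rather
#' than known, the statistic is referred by default to an
#' `F(1, n - p)` distribution (`n` samples, `p` full-model
#' coefficients), the usual small-sample correction for tests with a
#' plug-in dispersion; `test = "chisq"` gives the asymptotic 1-df
#' chi-squared reference instead, which is anticonservative at typical
#' replicate numbers.  Genes with total count below `minCount` are
#' excluded before testing; non-converged fits are flagged and excluded
#' from the multiple-testing correction.
#'
#' @param object A [MethIPCounts-class].
#' @param sizeFactors Optional per-sample factors; default
#'   [sizeFactorsMedianRatio()] of the counts.
#' @param minCount Minimum total count across samples for a gene to be
#'   tested (default 10).
#' @param crAdjust Use the Cox-Reid adjustment when estimating
#'   dispersion (default TRUE; plain profile ML is anticonservative at
#'   typical replicate numbers).
#' @param test Reference distribution for the likelihood-ratio
#'   statistic: `"F"` (default, `F(1, n - p)`) or `"chisq"`
#'   (asymptotic 1-df chi-squared).
#' @return data.frame with one row per gene: `gene`, `log2Interaction`,
#'   `lr`, `pvalue`, `padj`, `direction` ("decrease"/"increase"/NA),
#'   `status` ("ok", "low_count", "failed").
#' @export
nbLrtInteraction <- function(object, sizeFactors = NULL, minCount = 10,
                             crAdjust = TRUE, test = c("F", "chisq")) {
    test <- match.arg(test)
    stopifnot(is(object, "MethIPCounts"))
    cd <- SummarizedExperiment::colData(object)
    cells <- table(cd$assay, cd$genotype)
    if (any(cells < 2L))
        stop("each (assay, genotype) cell needs >= 2 replicates")
    counts <- SummarizedExperiment::assay(object, "counts")
    if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatio(counts)
    stopifnot(length(sizeFactors) == ncol(counts), all(sizeFactors > 0))
    offset <- log(sizeFactors)

    assayF <- factor(cd$assay, levels = c("input", "ip"))
    genoF <- factor(cd$genotype, levels = c("WT", "KO"))
    Xfull <- model.matrix(~ assayF + genoF + assayF:genoF)
    Xred <- model.matrix(~ assayF + genoF)
    intCol <- which(colnames(Xfull) == "assayFip:genoFKO")

    n <- nrow(counts)
    log2Int <- lr <- p <- rep(NA_real_, n)
    status <- rep("ok", n)
    for (g in seq_len(n)) {
        y <- round(as.numeric(counts[g, ]))
        if (sum(y) < minCount) { status[g] <- "low_count"; next }
        alpha <- tryCatch(
            estimateDispersion(y, Xfull, offset, adjust = crAdjust),
            error = function(e) NA_real_)
        if (is.na(alpha)) { status[g] <- "failed"; next }
        fitF <- nbFit(y, Xfull, offset, alpha)
        fitR <- nbFit(y, Xred, offset, alpha)
        if (is.null(fitF) || is.null(fitR) ||
            !fitF$converged || !fitR$converged) {
            status[g] <- "failed"; next
        }
        llF <- nbLogLik(y, fitF$fitted.values, alpha)
        llR <- nbLogLik(y, fitR$fitted.values, alpha)
        stat <- max(2 * (llF - llR), 0)
        lr[g] <- stat
        p[g] <- if (test == "F")
            stats::pf(stat, 1, ncol(counts) - ncol(Xfull),
                      lower.tail = FALSE)
        else pchisq(stat, df = 1, lower.tail = FALSE)
        log2Int[g] <- fitF$coefficients[intCol] / log(2)
    }
    res <- data.frame(
        gene = rownames(counts),
        log2Interaction = log2Int,
        lr = lr,
        pvalue = p,
        padj = bhAdjust(p),
        direction = ifelse(is.na(log2Int), NA_character_,
                           ifelse(log2Int < 0, "decrease", "increase")),
        status = status,
        row.names = NULL
    )
    res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' missing p-values are excluded (the number of tests is the number of
#' observed p-values) and returned as `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`, `NA` allowed.
#' @return Numeric vector of adjusted p-values, same length as `p`.
#' @export
bhAdjust <- function(p) {
    stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
    out <- rep(NA_real_, length(p))
    obs <- !is.na(p)
    out[obs] <- p.adjust(p[obs], method = "BH")
    out
}

#' Call differential-methylation targets
#'
#' @param results data.frame from [nbLrtInteraction()].
#' @param threshold Adjusted p-value cutoff (default 0.1).
#' @param direction "decrease" (loss of IP/input enrichment in KO, the
#'   signature of a methylation target) or "increase".
#' @return Character vector of gene ids.
#' @export
callTargets <- function(results, threshold = 0.1, direction = "decrease") {
    direction <- match.arg(direction, c("decrease", "increase"))
    ok <- !is.na(results$padj) & results$padj <= threshold &
        results$direction == direction
    results$gene[ok]
}

#' Relative 3' splice-site usage normalised to gene expression
#'
#' Per-sample usage of a splice site is the rpm of reads spliced at the
#' site divided by the rpm of its host gene; per-genotype means and the
#' KO - WT difference rank sites by gain of usage.  Sites whose host gene
#' has zero expression in any sample are flagged undefined and excluded
#' from the ranking.
#'
#' @param junctionCounts Numeric site x sample matrix of junction read
#'   counts.
#' @param geneCounts Numeric gene x sample matrix of gene-level counts.
#' @param siteToGene Named character vector mapping site id (rownames of
#'   `junctionCounts`) to host gene id.
#' @param sampleData data.frame with columns `genotype` ("WT"/"KO") and
#'   `librarySize`, rows parallel to the count columns.
#' @return data.frame with one row per site: per-genotype mean usage,
#'   `delta` (KO - WT), `direction`, `undefined` flag; defined sites
#'   sorted by decreasing delta, undefined sites last.
#' @export
relativeSsUsage <- function(junctionCounts, geneCounts, siteToGene,
                            sampleData) {
    junctionCounts <- as.matrix(junctionCounts)
    geneCounts <- as.matrix(geneCounts)
    stopifnot(ncol(junctionCounts) == nrow(sampleData),
              ncol(geneCounts) == nrow(sampleData),
              all(c("genotype", "librarySize") %in% colnames(sampleData)))
    gene <- siteToGene[rownames(junctionCounts)]
    if (anyNA(gene)) stop("site(s) without host gene in siteToGene")
    ls <- sampleData$librarySize
    jr <- sweep(junctionCounts, 2, ls, function(x, l) rpm(x, l))
    gr <- sweep(geneCounts[gene, , drop = FALSE], 2, ls,
                function(x, l) rpm(x, l))
    undefined <- apply(gr, 1, function(x) any(x == 0))
    usage <- jr / gr
    usage[gr == 0] <- NA
    isKO <- sampleData$genotype == "KO"
    meanWT <- rowMeans(usage[, !isKO, drop = FALSE])
    meanKO <- rowMeans(usage[, isKO, drop = FALSE])
    delta <- meanKO - meanWT
    out <- data.frame(
        site = rownames(junctionCounts),
        gene = unname(gene),
        meanUsageWT = meanWT, meanUsageKO = meanKO,
        delta = delta,
        direction = ifelse(is.na(delta), NA_character_,
                           ifelse(delta >= 0, "increase", "decrease")),
        undefined = unname(undefined),
        row.names = NULL
    )
    out[order(out$undefined, -ifelse(is.na(out$delta), -Inf, out$delta)), ]
}

#' Read a gene x sample count matrix and sample sheet into MethIPCounts
#'
#' @param countsPath TSV with gene ids in the first column and one column
#'   per sample.
#' @param samplesPath TSV sample sheet with columns `sample`, `assay`,
#'   `genotype`, `replicate`, and optionally `librarySize`.
#' @return A [MethIPCounts-class].
#' @export
readCountMatrix <- function(countsPath, samplesPath) {
    cts <- read.delim(countsPath, row.names = 1, check.names = FALSE)
    ss <- read.delim(samplesPath)
    stopifnot("sample" %in% colnames(ss))
    if (!all(ss$sample %in% colnames(cts)))
        stop("sample sheet and count matrix disagree on sample names")
    cts <- as.matrix(cts[, ss$sample, drop = FALSE])
    rownames(ss) <- ss$sample
    MethIPCounts(cts, ss)
}
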