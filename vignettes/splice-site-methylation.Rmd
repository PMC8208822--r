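---
title: "Methods: screening, quantifying and testing m6A at 3' splice sites"
author: "spliceMeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, quantifying and testing m6A at 3' splice sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceMeth)
```

# Background

N6-methyladenosine written by the METTL16/METT-10 methyltransferase
family is unusual among mRNA marks in that it can sit directly on the
adenosine of a 3' splice site. The enzyme requires two features at
once: the sequence motif (`UACAGAGA` or `UACAGAAA`, methylated A at
position 4, so that motif positions 4-5 coincide with the acceptor AG)
and a stem-loop that presents the motif in its loop. When the acceptor
adenosine is methylated, U2AF35 can no longer read the AG and splicing
of the host intron is suppressed: the transcript pool shifts from the
protein-coding (PC) isoform towards an alternatively spliced (AS)
isoform using a cryptic upstream acceptor and an intron-retained (IR)
isoform. `spliceMeth` implements the full computational workflow
around this biology; this vignette records the models, parameters and
design decisions.

# Coordinate conventions

Annotation coordinates are 1-based fully-closed (GTF convention)
throughout the package; bedGraph input/output is 0-based half-open,
converted at the module boundary by a single pair of named helpers.
The choice is forced by the locus arithmetic the package must
reproduce: a canonical intron printed as chrIV:5,848,949-5,849,317 has
length `369` only under the inclusive reading, which is exactly the
segment that converts a 133-bp fully spliced RT-PCR product into the
502-bp retention product (`ampliconLength(133, 369)`); the same holds
for the 148/517-bp transgene pair. The cryptic-acceptor product
arithmetic is deliberately *not* exposed as a validated identity: under
the inclusive convention the printed AS coordinates are off by one
base against the published AS product lengths, so the AS amplicon is
not part of the package's validated surface.

On the `+` strand the methylatable adenosine of an acceptor is
`intron_end - 1`; on the `-` strand it is `intron_start + 1`, and all
windows are reported sense-strand (reverse-complemented, T→U).
Non-AG acceptors are retained and flagged rather than dropped —
annotation noise should not abort a genome-wide run — and the anchored
motif match excludes them naturally. Windows containing ambiguous
bases (N) are excluded from folding and reported with the reason
`ambiguous_base`, since folding over N is undefined.

# The motif + structure screen

`runScreen()` composes four steps: enumerate unique acceptors
(de-duplicated on contig/strand/acceptor position; both redundant and
unique counts are reported because annotation releases differ in
transcript redundancy), scan the 41-nt window centred on the target
adenosine for motifs, fold each hit window, and rank by structural
similarity to a reference hairpin.

**Anchoring.** A motif matches only in the single register that places
its AG on the acceptor AG. Sliding matches are not biologically
meaningful here: the screen targets the splice-site adenosine
specifically.

**Folding.** The similarity statistic consumes only a dot-bracket
string, so the default engine is a deterministic base-pair maximiser
(Nussinov recursion) rather than a thermodynamic folder: Watson-Crick
plus G·U pairs, minimum hairpin loop 3 nt. When several structures
attain the maximum pair count the traceback is fixed — a position is
left unpaired only if no pairing achieves the optimum, and otherwise
pairs with its smallest admissible partner — so reruns are
byte-identical. An externally computed structure (e.g. an MFE fold)
can be injected per window sequence via `foldTable`, which replaces
the internal engine without touching the rest of the pipeline. Tests
verify the engine against two independent oracles: exhaustive
enumeration of all non-crossing structures for short sequences and a
memoised right-to-left recursion for 20-mers.

**Similarity and ranking.** `structureSimilarity()` counts positions
paired in both the candidate and the reference structure. It is
symmetric, bounded by each structure's paired-position count, and
equals that count on self-comparison. Candidates are sorted by
similarity (ties broken by contig then coordinate) and given 1-based
competition ranks. Motif-positive but structure-poor sites are kept
with their low scores; no similarity cutoff is imposed, because none
is biologically established — rank order is the product.

# Isoform quantification

For a locus with a canonical intron and a nested cryptic intron
sharing the donor:

* PC rpm = count of junction reads matching the canonical intron
  exactly (both ends) × 10⁶ / library size;
* AS rpm = the same for the cryptic intron;
* IR rpm = mean per-base coverage over the canonical intron trimmed by
  `trim = 10` nt at each end (avoiding splice-junction edge
  artifacts), rpm-scaled.

Junction matching is exact; records within ±1 nt of either intron are
surfaced in a `nearMiss` QC slot instead of being merged, so aligner
dialect off-by-ones are visible rather than silently absorbed. The
library size is always supplied explicitly (junction tables undercount
the library). All three quantities are linear in counts and depth at
fixed library size, which the tests exercise directly.

# The interaction likelihood-ratio test

Differential methylation between genotypes is tested per gene on the
2×2 factorial design (assay input/IP × genotype WT/KO, ≥2 replicates
per cell) with a negative-binomial GLM and log size-factor offsets:

* full model: `~ assay + genotype + assay:genotype`
* reduced model: `~ assay + genotype`

The interaction coefficient is the log₂ change of the IP/input ratio
in KO relative to WT; a methylation target lost in the KO has a
negative interaction, and `callTargets()` applies the padj ≤ 0.1
decrease rule.

**Dispersion.** Each gene's dispersion is estimated once under the
full model by maximising the Cox-Reid-adjusted profile likelihood
(floored at 10⁻⁸) and shared by both fits, preserving the nested-model
structure. The Cox-Reid term corrects the downward bias of plain ML
dispersion at small replicate numbers; without it the test is badly
anticonservative (null rejection near 0.16 at nominal 0.05 with
triplicates).

**Reference distribution.** Even with bias-corrected dispersion, the
asymptotic χ²₁ reference stays anticonservative with 12 samples
because the dispersion is a noisy plug-in. The default therefore
refers the LR statistic to `F(1, n − p)` (`n` samples, `p` full-model
coefficients), the usual convention for tests with an estimated
dispersion (the same motivation as quasi-likelihood F-tests in count
GLMs). On null simulations at the package's study conditions (2,000
genes, triplicates, means 100-1000, dispersion 0.05) this reference is
calibrated within Monte-Carlo error and p-values are near-uniform,
which the acceptance suite verifies; `test = "chisq"` restores the
asymptotic reference for comparison with tools that use it. The cost
is conservatism when very few genes are non-null; at 10% non-null the
power against a 4-fold enrichment loss remains above 0.9, which the
suite also measures. Fractional (multimapper-weighted) counts are
rounded for the likelihood. Genes with total count < 10 are excluded
before testing (a configurable stability filter, reported in the
`status` column); failed fits are excluded from the BH correction,
reducing the number of tests accordingly.

**Normalisation.** Size factors are median-of-ratios against the
geometric-mean pseudo-reference (delegated to DESeq2's estimator) with
an explicit library-size fallback, used when no gene has positive
counts in every sample. The LR statistic is invariant to rescaling
all size factors by a constant, which is tested. Median-of-ratios
assumes most genes are unaffected; parameter-recovery tests that
simulate 100% non-null genes therefore pass the true depths instead.

**Relative usage.** `relativeSsUsage()` divides junction rpm by host
gene rpm per sample, averages within genotype and ranks by the KO-WT
difference; sites whose gene has zero expression in any sample are
flagged undefined and excluded from ranking rather than producing
infinities.

# Metagene profiles

Coverage is projected exon-wise into transcript coordinates
(reverse-complement order for minus-strand transcripts). For
transcripts with an annotated CDS, the 5'UTR, CDS and 3'UTR are each
cut into 100 bins with fractional-overlap weighting — a region of
length L contributes to bin k the average of the step function over
`[kL/100, (k+1)L/100)` — so region lengths need not divide evenly; the
bin means are checked against closed-form integrals of a linear ramp
to 10⁻⁶. Regions shorter than `minLen = 100` nt are excluded; the
filter applies uniformly to all three regions (length filters are
sometimes stated only for 3'UTRs, but a uniform rule is cleaner, and
the parameter is configurable). Bins with no contributors are `NA`, never
zero-filled. The stop-codon profile is a ±500-nt window at 1-nt
resolution centred, by fixed convention, on the first base of the stop
codon taken as the last 3 nt of the annotated CDS; transcript ends
clip the window and the per-position contributor count drops
accordingly. An optional gene whitelist restricts profiles to, e.g.,
genes with significant IP enrichment.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults encode the
study conditions the package targets:

| parameter | default | rationale |
|---|---|---|
| replicates | 3 per (assay, genotype) cell | biological triplicates |
| WT isoform weights (PC, AS, IR) | 0.1, 0.3, 0.6 | methylated acceptor mostly blocked |
| KO isoform weights | 0.8, 0.1, 0.1 | site released; 8-fold PC gain |
| junction depth | 10⁴ per gene and sample | desk-scale, ~1% binomial error |
| NB base means | U(100, 1000) | typical meRIP gene counts |
| NB dispersion | 0.05 | typical bulk RNA-seq biological CV |
| IP enrichment (methylated, WT IP) | 4 | strong methylation signal, lost in KO |
| intron lengths | U(200, 800) nt | desk-scale but exercises coordinates |
| cryptic-acceptor offset | 93 nt | mirrors the canonical/alternative intron gap |

Toy genes have two exons (200 + 300 nt) with a CDS leaving 150-nt
UTRs, random strands, and acceptors forced to end in AG. Planted
structured genes carry the motif in the loop of a designed perfect
8-bp G/C stem; their flanking filler positions are drawn from the
pair-poor {A, C} alphabet. Unstructured controls carry the same motif
with all-{A, C} flanks and are verified to share fewer than 4 paired
positions with the reference structure once folded (resampled up to
100 times); a naive shuffle of structured flanks would almost always
re-pair somewhere and fail that check, which is why the generator
draws from the pair-poor alphabet instead. Background genes are
verified not to match any motif at the anchored register. The
`referenceHairpin()` window is the canonical designed stem-loop, and
`referenceStructure()` is its designed dot-bracket (8 stem pairs,
everything else unpaired), which is the reference used when screening
synthetic genomes: folding the reference *sequence* would decorate it
with opportunistic filler pairs and blur the contrast the controls are
checked against. Tests never depend on any unpublished natural
sequence.

Splicing data are Multinomial(depth, weights) per gene and sample:
canonical-junction count (PC), cryptic-junction count (AS), and IR
realised as uniform per-base intron coverage equal to the IR draw,
with exons at total depth so expression is condition-independent.
Methylated genes use the WT weight set only in WT samples. IP/input
counts are NB with per-sample depth factors U(0.5, 1.5) and the
enrichment rule above. Every output stream (each file, each
simulation stage) takes its own seed derived from the master seed and
a stable label, so outputs are byte-identical under a fixed seed and
adding a stream never perturbs existing ones.

**What the generator does not emulate:** read-level sequencing error,
fragment-length and positional coverage biases, AS-isoform coverage
over its retained segment (intron coverage is pure IR), overlapping
genes, multi-intron transcripts, and dispersion trends across the mean.
Passing recovery tests therefore demonstrate correctness of the
estimators under the stated model, not robustness to every artifact of
real libraries.

# Problem sizes and runtimes

The shipped tests and the acceptance script use desk-scale sizes
chosen to keep a full run in the low minutes on one CPU while leaving
no estimator untested at meaningful size: 50-gene genomes for the
screen, 2,000 genes for null calibration, 500 genes (10% non-null) for
power, 10⁴ junction reads per locus for isoform recovery, and
exhaustive folding oracles up to length 12 plus 200 sampled 20-mers.

# Known limitations

* The folding engine maximises pair count, not free energy; stems of
  marginal stability rank the same as stable ones. Injecting external
  folds recovers thermodynamic behaviour where needed.
* The similarity score is positional, not topological: a candidate
  pairing the same positions through a different helix scores fully.
* The F-referenced LRT is conservative in nearly-all-null regimes with
  very few discoveries; users wanting asymptotic behaviour can select
  `test = "chisq"` explicitly.
* Per-gene dispersion is estimated without information sharing across
  genes; with fewer than two replicates per cell the test refuses to
  run rather than produce unstable fits.
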