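# spliceMeth

Analysis of N6-methyladenosine (m⁶A) at 3′ splice sites.

The METTL16/METT-10 family of methyltransferases can methylate the
adenosine of a 3′ splice site — the acceptor `AG` dinucleotide — when
that adenosine sits in a `UACAGAGA`/`UACAGAAA` consensus motif presented
in the loop of a stem-loop structure. The mark blocks binding of the
splicing factor U2AF35 to the acceptor and thereby suppresses splicing
of the host intron, shifting the transcript output from the
protein-coding (PC) isoform towards alternatively spliced (AS) and
intron-retained (IR) variants. `spliceMeth` implements the computational
toolkit for studying this regulation from standard RNA-seq and
m⁶A-IP-seq (meRIP) data:

* **Acceptor enumeration** — parse a genome FASTA and transcript GTF,
  enumerate unique annotated 3′ splice sites with their methylatable
  adenosine (`intron_end − 1` on `+`, `intron_start + 1` on `−`).
* **Motif + structure screen** — find acceptors carrying a methylation
  motif anchored on the acceptor AG, fold the 41-nt window centred on
  the target adenosine by deterministic base-pair maximisation
  (Nussinov-style, Watson–Crick + G·U, minimum hairpin loop 3), and rank
  candidates by a dot-bracket similarity score against a reference
  hairpin: the number of positions paired (`(` or `)`) in both the
  candidate and the reference structure.
* **Isoform quantification** — PC abundance from spliced reads spanning
  exactly the canonical intron, AS from reads spanning the cryptic
  upstream intron, IR as mean per-base coverage of the canonical intron
  trimmed by 10 nt on each side; all in reads per million
  (rpm = count × 10⁶ / library size).
* **Differential methylation** — per-gene negative-binomial GLM
  likelihood-ratio test comparing
  `~ assay + genotype + assay:genotype` against
  `~ assay + genotype` (assay ∈ {input, m⁶A-IP}; genotype ∈ {WT, KO}),
  with median-of-ratios size factors as offsets and Cox–Reid-adjusted
  profile-likelihood dispersion shared between the nested fits. The
  interaction coefficient is the log₂ change of the IP/input enrichment
  ratio in KO versus WT; methylation targets show a significant
  (padj ≤ 0.1) decrease. Relative splice-site usage (junction rpm /
  gene rpm) ranks acceptors gaining usage in the KO.
* **Metagene profiles** — coverage projected into transcript
  coordinates, 5′UTR/CDS/3′UTR each split into 100 fractional bins, and
  a ±500-nt profile around the stop codon.
* **Synthetic data** — fully seeded toy genomes with stem-loop acceptors
  planted among motif-only and background genes, condition-dependent
  PC/AS/IR junction + coverage data in triplicate, and NB IP/input count
  matrices with genotype-dependent enrichment, all accompanied by a
  machine-readable truth manifest.

## Worked example

```r
library(spliceMeth)

cfg <- syntheticConfig(seed = 42, nGenes = 20)   # 3 stem-loop + 3 motif-only acceptors
toy <- buildToyGenome(cfg)

## 1. screen acceptors for methylatable stem-loops
scr <- runScreen(toy$genome, toy$transcripts, reference = referenceStructure())
head(as.data.frame(scr)[, c("geneId", "targetA", "motif", "similarity", "rank")])
#>   geneId targetA    motif similarity rank
#> 1   g001     786 UACAGAGA         15    1
#> 2   g002    1439 UACAGAGA         15    1
#> 3   g003    2278 UACAGAGA         12    3
#> 4   g005    4063 UACAGAGA          2    4
#> 5   g004    3149 UACAGAGA          1    5
#> 6   g006    5315 UACAGAGA          1    5
```

The three planted stem-loop acceptors (`g001`–`g003`) share 12–15 paired
positions with the reference hairpin structure and occupy the top three
rows; the motif-only controls score at most 2.

```r
## 2. quantify splice isoforms at the first planted locus
spl <- simulateSplicingData(cfg, toy$manifest)
g <- toy$manifest$genes[1, ]
loc <- locusDefinition(g$contig, c(g$canonicalStart, g$canonicalEnd),
                       c(g$alternativeStart, g$alternativeEnd))
quantifyIsoforms(spl$WT_1$junctions, spl$WT_1$coverage, loc, spl$WT_1$librarySize)
#> IsoformQuant (library 1e+06): PC 1048.000  AS 2994.000  IR 5958.000 rpm
quantifyIsoforms(spl$KO_1$junctions, spl$KO_1$coverage, loc, spl$KO_1$librarySize)
#> IsoformQuant (library 1e+06): PC 7947.000  AS 1022.000  IR 1031.000 rpm
```

With the acceptor methylated in WT, the protein-coding isoform is
suppressed (PC ≈ 1000 rpm against AS + IR ≈ 9000 rpm); removing the
methyltransferase releases the site (PC ≈ 7900 rpm, an ≈8-fold gain).

```r
## 3. differential methylation between genotypes
ip <- simulateIpCounts(cfg, toy$manifest)
res <- nbLrtInteraction(ip)
callTargets(res, threshold = 0.1, direction = "decrease")
#> [1] "g001" "g002" "g003"
```

The interaction LRT recovers exactly the genes whose acceptors lose
m⁶A-IP enrichment in the KO, with negative log₂ interaction effects
(planted value −log₂ 4 = −2).

The classic coordinate arithmetic is also exposed directly: the
canonical *sams-3* intron 2 spans chrIV:5,848,949–5,849,317, so

```r
intronLength(5848949, 5849317)        # 369 nt
ampliconLength(133, 369)              # 502 bp intron-retained RT-PCR product
ampliconLength(148, 369)              # 517 bp transgene retention product
```

## Package layout

* `R/genome.R` – FASTA/GTF input, acceptor enumeration, window extraction
* `R/fold.R`, `R/screen.R` – folding engine, similarity score, screen
* `R/isoform.R` – junction/bedGraph input, PC/AS/IR quantification
* `R/diffmeth.R` – size factors, interaction LRT, BH, target calls, usage
* `R/metagene.R` – transcript-coordinate projection and binned profiles
* `R/simulate.R` – synthetic datasets with truth manifests
* `vignettes/` – methods vignette describing the models and choices
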