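# consensusGSA

Consensus gene-set enrichment for bulk RNA-seq via the harmonic mean
p-value.

## What it is for

Transcriptome studies of single-gene mutants in sibling cohorts often find
almost no individually differentially expressed genes, yet whole pathways
shift coherently by small amounts. consensusGSA is a downstream analysis
pipeline for exactly that regime. From transcript-level abundances it

1. aggregates mature transcripts to gene counts (omitting unspliced,
   intron-retaining rows), filters undetectable genes (CPM < 0.66 in at
   least half the libraries) and TMM-normalises;
2. estimates one factor of unwanted variation with RUVg: an initial
   negative-binomial GLM fit picks the 5000 genes least affected by
   genotype as negative controls, and the first singular vector of their
   centred log-counts becomes the latent factor `W_1`;
3. refits per-gene NB GLMs (genotype + sex + tank + `W_1`, wild type as
   intercept) with likelihood-ratio tests per genotype contrast, BH-FDR
   at 0.05;
4. tests every gene set with three independent algorithms — a
   self-contained Monte-Carlo **rotation** test, a **competitive** test
   adjusted for inter-gene correlation (`VIF = 1 + (m-1)·ρ̄`), and
   preranked **GSEA** (weighted Kolmogorov–Smirnov running sum on
   `sign(logFC)·(−log10 p)`, gene-sampling null, leading-edge
   extraction);
5. combines the three p-values per set by the harmonic mean p-value,
   `HMP = 1 / Σ(wᵢ/pᵢ)`, BH-adjusts across sets, and flags sets at
   `FDR(HMP) < 0.05`;
6. validates the consensus by permuting gene labels (breaking set
   membership while keeping every per-gene statistic) and counting
   significant sets under that null.

A truth-known negative-binomial simulator emulating the 24-sample,
four-genotype sibling design (n = 8 wild type, 6 + 4 heterozygous mutants,
6 transheterozygous; library-size-correlated latent factor; subtle planted
set shifts) makes every stage testable offline, and diagnostic helpers
(`pcaDiagnostic`, `markerDistribution`, `leadingEdgeOverlap`) cover the
accompanying sanity checks.

Standard steps run through the established machinery (edgeR for TMM,
dispersion estimation and NB GLMs; limma's variance shrinkage inside the
enrichment tests); the enrichment algorithms, RUVg factor analysis, HMP
consensus and permutation validation are implemented in this package and
verified against brute-force oracles and, where available, reference
implementations.

## Worked example

```r
library(consensusGSA)

cfg <- simConfig(nGenes = 4000, nSets = 25, setSizeRange = c(60, 120),
                 seed = 1)
sim <- simulateExperiment(cfg)
fit <- runPipeline(sim$se, sim$sets, nControls = 1600, nRot = 999,
                   nPermGsea = 999, seed = 2)
```

```
aggregated to 4000 genes
detection filter kept 3851 of 4000 genes; library sizes 520905 - 1050754
  eofad: 6 DE genes at FDR < 0.05
  null: 6 DE genes at FDR < 0.05
  trans: 2 DE genes at FDR < 0.05
testing 25 gene sets on a universe of 3851 genes
  eofad: 2 consensus-significant sets
  null: 2 consensus-significant sets
  trans: 2 consensus-significant sets
```

The simulator planted coordinated ±0.3 log2 shifts in 80% of the members
of two sets per genotype contrast. The consensus table for the `eofad`
contrast recovers exactly those two sets:

```r
head(fit$consensus$eofad[, c("set", "p_rotation", "p_competitive",
                             "p_gsea", "hmp", "fdr_hmp", "significant")], 4)
```

```
      set p_rotation p_competitive      p_gsea          hmp     fdr_hmp significant
1  set001      0.001  2.220328e-05 0.001930502 6.443798e-05 0.001610949        TRUE
2  set002      0.001  6.322934e-04 0.002036660 9.763895e-04 0.012204869        TRUE
23 set023      0.025  4.358311e-02 0.067567568 3.858786e-02 0.321565464       FALSE
3  set003      0.108  1.239796e-01 0.132936508 1.207365e-01 0.585039882       FALSE
```

Each row shows the three methods' p-values, their harmonic mean, and the
BH-adjusted consensus used for the significance call. The per-contrast DE
tables (`deTable(fit$de, "eofad")`), the latent factor (`fit$W`), GSEA
leading edges (`fit$consensus$eofad$leadingEdge`) and the permutation
validation (`permuteLabelValidation(fit, nPerm = 100, seed = 3)`) hang off
the same object. Real data enter through `readKallisto()` (per-sample
kallisto `abundance.tsv` plus a tx2gene map and metadata) or
`readCountMatrix()`, with GMT collections via `readGMT()` and identifier
translation via `mapSetIds()`.

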