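---
title: "Consensus gene-set enrichment for bulk RNA-seq: methods and design"
author: "consensusGSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus gene-set enrichment for bulk RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Studies of single-gene mutants in inbred or sibling cohorts often produce
transcriptomes in which almost no individual gene passes a genome-wide
differential-expression threshold, yet whole pathways shift coherently by
small amounts. consensusGSA implements a downstream analysis built for that
regime: negative-binomial differential expression to characterise the few
individually responsive genes, and gene-set level inference that combines
three enrichment algorithms with complementary nulls into a single
consensus p-value per set, validated by a gene-label permutation
experiment. The reference design it targets — and the design its simulator
emulates — is a four-genotype family of 24 sibling zebrafish (wild type
n = 8 as baseline, one heterozygous mutant n = 6, a second heterozygous
mutant n = 4, and the transheterozygote n = 6), with sex and rearing tank
as nuisance covariates and one strong latent factor of unwanted variation
correlated with library size.

# Preprocessing

Transcript-level estimated counts (kallisto-style `abundance.tsv`) are
summed over each gene's *mature* transcripts; unspliced, intron-retaining
transcript rows (identifier suffix `.unspliced`, configurable pattern) are
excluded at aggregation. Counts stay fractional throughout, as usual for
pseudo-aligner output; the NB likelihood machinery in edgeR accepts them
as-is.

A gene is called undetectable when its CPM falls below 0.66 in at least
half the libraries (12 of 24 in the reference design); CPM for the filter
uses the raw, pre-normalisation library sizes because filtering precedes
normalisation in the protocol. Library sizes are then recomputed on the
retained genes, and TMM scaling factors (30% M-trim, 5% A-trim, inverse
asymptotic-variance weights, geometric mean one) are computed via
`edgeR::calcNormFactors`; the test suite checks those factors against a
naive double-loop implementation of the published definition.

# Unwanted variation (RUVg)

A first-pass NB GLM is fitted without latent factors, and the 5000 genes
with the largest p-value in the joint (ANOVA-type) likelihood-ratio test
over all genotype coefficients are taken as negative controls — genes least
plausibly affected by genotype. The control genes' `log(count + 1)` matrix
is row-centred and its first `k` sample-side singular vectors (default
`k = 1`) become the latent factor scores `W`. Columns of `W` have unit norm
(the regression absorbs the scale) and the sign is fixed so the
largest-magnitude loading is positive, making results reproducible across
linear-algebra backends. The pseudo-count of 1 is the method's published
default; results are insensitive to it for the moderate-to-high counts that
drive the leading singular vector. The two-pass protocol is packaged as one
operation (`estimateUnwantedVariation`) so the control genes can never
accidentally be selected from a fit that already contains `W`.

# Differential expression

The design matrix places the wild-type genotype on the intercept, one
coefficient per mutant genotype, sex (female reference) and tank (tank 1
reference), plus the `W` columns. Gene-wise dispersions are estimated by
Cox-Reid adjusted profile likelihood with empirical-Bayes shrinkage towards
the mean-dispersion trend (prior degrees of freedom 10, configurable), and
each genotype coefficient is tested by a likelihood-ratio test, with the
joint test over all genotype coefficients retained for control-gene
selection. LRT is the default because it is the simpler, exactly
reproducible choice; quasi-likelihood F-tests are available behind
`test = "ql"`. Genes are flagged DE at Benjamini-Hochberg FDR < 0.05.
Non-convergent fits are reported with p = 1 (conservative).

# The three enrichment tests

All three are implemented in this package and are checked in the test suite
against independent oracles (and, where an established implementation
exists, against it):

**Self-contained rotation test.** For one tested coefficient, the QR
decomposition of the design splits each gene's data into an effect
component and `d` residual components; under the null this
`(d + 1)`-vector is spherically symmetric, so multiplying all genes'
vectors by a common random unit vector generates a null sample that
preserves the fitted nuisance structure and the inter-gene correlation.
The set statistic is the mean of members' moderated t (variance shrinkage
hyperparameters frozen at their observed values across rotations), and the
two-sided p-value is `(b + 1) / (nRot + 1)`. Monte-Carlo rotations were
chosen over the analytic infinite-rotation approximation because they can
be verified against a brute-force oracle that builds explicit random
orthogonal matrices and refits; an analytic mode is a possible extension.

**Competitive test with inter-gene correlation adjustment.** Moderated t
statistics are converted to z; a set's mean inter-gene residual
correlation is estimated from the row-standardised residual effects and
inflates the variance of the set-versus-rest comparison through
`VIF = 1 + (m - 1) * rho`. The inflation factor is applied as estimated —
a negative estimated correlation may deflate it below one — because the
plain formula is what holds its nominal size under independence; clipping
the VIF at one (`allowNegCor = FALSE`) is available and mildly
conservative. The implementation reproduces `limma::camera` (with
estimated correlation and the matching clipping choice) to ten decimal
places in the test suite, and
the calibration study in the acceptance tests shows the defining property:
with within-set correlation 0.1 the unadjusted test is anti-conservative
while the VIF-adjusted test holds its nominal size.

**Preranked GSEA.** Genes are ranked by `sign(logFC) * -log10(p)` (the
ranking metric the pipeline displays; a signed-statistic alternative is a
configuration away), with ties broken by gene identifier so the order is
total and deterministic, and zero p-values capped at magnitude 300. The
enrichment score is the maximal signed deviation of the weighted
Kolmogorov-Smirnov running sum (weight 1 by default); the null is
generated by drawing random same-size gene sets from the ranked list
(gene sampling, 10^4 draws by default), the p-value is two-tailed by ES
sign with the +1 correction, and NES divides ES by the mean |ES| of
same-sign null draws. Null sets are drawn in a canonical gene order so
that negating every statistic exactly negates all null scores — mirrored
analyses give identical p-values. The leading edge contains the members at
or before (after, for negative ES) the running-sum extremum. The
multilevel refinement of the fast GSEA implementation is out of scope; at
the default number of draws the p-value floor of about 10^-4 is far below
the consensus significance boundary.

# Consensus and validation

Per set and contrast the three p-values are combined by the harmonic mean
p-value, `HMP = 1 / sum(w_i / p_i)` with equal weights by default. The raw
HMP is used — no asymptotic (Landau-distribution) recalibration — because
the value is immediately FDR-adjusted across all sets tested in the
contrast and the threshold applied to the adjusted value; the asymptotic
transform would be a documented optional mode. BH adjustment pools all
collections passed in one `buildConsensus` call; targeted small families
(e.g. IRE or pathway-regulator sets) should be analysed in their own call
so they form their own adjustment family, mirroring how targeted analyses
are usually presented.

The validation experiment permutes gene labels: identifiers are reassigned
to expression rows, which breaks gene-set membership while leaving the
expression matrix — and therefore every per-gene statistic — intact.
Shuffles are drawn uniformly over non-identity permutations. Because the
per-gene statistics do not move, the rotation null matrix, the moderated
z-scores and the GSEA null distributions are computed once per contrast
and reused across permutations; only set membership changes. A calibrated
consensus leaves (essentially) no FDR-significant sets under this null.
Both readings of "permuting gene labels" — shuffling the identifier column
or shuffling expression rows — induce the same membership null; the
implementation uses the identifier-side formulation.

# The simulator

`simulateExperiment` draws gene counts from
`NB(mu_ij, phi_i)` with `mu_ij = p_i * L_j * 2^(x_j' beta_i + w_j a_i)`:
lognormal relative abundances `p_i`, library sizes `L_j` uniform on a
configurable range (scaled down to 0.5-1 M by default for speed;
`realisticLibSizes = TRUE` restores 13-23 M totals), genotype/sex/tank
effects `beta_i`, and a latent factor `w` standardised with correlation
0.8 to log library size. The latent loadings (N(0, 0.4^2) log2 units on
half the genes by default) are calibrated so that, as in the motivating
study's diagnostics, PC1 of the logCPM matrix tracks library size before
adjustment and stops doing so once `W_1` is removed. Gene counts are split
multinomially over 1-3 mature transcripts, and every gene also receives a
low-abundance unspliced transcript row (5% of the gene mean) so the
aggregation rule is genuinely exercised. Planted signal follows the
"subtle" regime: a few sets receive coordinated log2 shifts of +/-0.3 in
80% of their members, plus a handful of individually large-effect genes
(|log2FC| = 2) placed outside any set at detectably expressed levels
(expected CPM >= 50). Effect sizes for the planted regime are not
estimable from any published table; the defaults were chosen once to
reproduce "few DE genes, detectable set-level signal" and are part of the
study conditions the tests run under.

The simulator does **not** model GC or length bias, read-level error,
alternative splicing, or compositional (cell-type mixture) change; passing
tests therefore demonstrate statistical correctness and calibration of the
pipeline under its stated model, not robustness to those artefacts — the
`pcaDiagnostic` and `markerDistribution` helpers exist to check the last
two on real data.

# Numerical choices

* Genes whose joint effect-plus-residual energy is at numerical-noise
  level relative to their data are assigned a zero statistic in both the
  observed and rotated fits (a constant gene carries no evidence).
* All Monte-Carlo p-values use the `(b + 1)/(n + 1)` form, so no method
  ever returns exactly zero; competitive-test p-values are clamped away
  from zero at the smallest positive double.
* Ties in every ordering (ranking statistic, control selection) are broken
  by gene identifier.
* IRLS convergence and dispersion estimation follow the edgeR defaults
  apart from the explicit prior degrees of freedom.
* Every stage derives its RNG stream from the master seed plus a fixed
  offset, so stages are individually reproducible and reordering one does
  not perturb another.

# Problem sizes in the test suite

The acceptance tests exercise the study-scale fixture (24 samples, 12000
genes, 100 sets) for the permutation-null and latent-factor-recovery
checks, 500 null sets for the calibration study, and 50 replicate
simulations of 4000 genes with 25 sets of 60-120 members for the
planted-signal recall study; rotation and GSEA null draws are set to
499-999 in these loops. These sizes are the package's choices for a
default-hardware test run; all of them are parameters the user can raise.

# Known limitations

* The rotation test's p-value granularity is bounded by `1/(nRot + 1)`;
  for very small targeted families at stringent thresholds, raise `nRot`.
* Gene-sampling GSEA ignores inter-gene correlation by construction; that
  is precisely why it is only one vote in the consensus.
* The harmonic mean p-value is used as a pragmatic consensus, not with its
  full closed-testing multilevel procedure; family-wise error control
  beyond BH on the HMP is out of scope.
* `RUVg` with `k = 1` removes one direction of unwanted variation; designs
  with several independent technical factors need larger `k` and their own
  diagnostics.
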