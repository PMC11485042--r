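---
title: "Methods: gene-level multi-omics integration by correlated meta-analysis"
author: "omicsfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-level multi-omics integration by correlated meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A single cohort can carry three distinct lines of gene-level evidence about a
quantitative trait: common-variant association (GWAS), association between
*measured* gene expression and the trait (TWAS, in the measured — not
predicted — sense), and rare-variant set association (RVA). Each line is
underpowered on its own at cohort sizes of a few thousand, and each has a
characteristic failure mode: GWAS hits tag genes through linkage
disequilibrium (LD), expression-trait association is vulnerable to reverse
causation and confounding, and rare-variant signals are sparse. Pooling the
three at the gene level concentrates the evidence on the gene (expression is
not propagated by LD) while any two sources computed on overlapping samples
may be correlated — so a naive Stouffer/Fisher combination would inflate
type-I error. The pipeline implemented here prepares trait residuals, builds
the three gene scores under family relatedness, combines them with a
correlated meta-analysis (CMA), and interrogates the results at the pathway
level through protein-interaction-module enrichment and GO
over-representation, with replication logic for a second cohort.

# Models and procedures

## Trait preparation

Traits are residualized on their covariates by OLS, adjusted forward-stepwise
for the top 10 genetic principal components (a PC is retained iff its
marginal slope p-value against the *current* residual is below 0.05, walking
PC1..PC10 in order, with a final joint re-fit on the retained set), and then
rank-inverse-normal transformed with the Blom offset,
$z_i = \Phi^{-1}((r_i - 3/8)/(n + 1/4))$, average ranks for ties. "Stepwise"
is not a uniquely defined procedure; the forward single-pass reading in index
order is the simplest reproducible one and is recorded in the output.
Trait-specific covariate sets and log-transforms are configuration, not code.

## GWAS gene scores

Per-variant summary statistics come from a mixed-model Wald scan
(`gwas_scan`) or any external GWAS. Variants with MAF ≥ 5% within 50 kb of
the gene body (1-based inclusive intervals, strand ignored, a variant may
serve multiple overlapping windows) contribute
$T = \sum_i z_i^2$ with $|z_i| = \Phi^{-1}(1 - p_i/2)$ capped at 37. Under
the null $z \sim N(0, R)$ with $R$ the LD correlation matrix, so
$T \sim \sum_j \lambda_j \chi^2_1$ with $\lambda_j$ the eigenvalues of $R$.
$R$ is estimated from the cohort's own genotypes (mean-imputed dosages,
Pearson), shrunk as $(1-\varepsilon)R + \varepsilon I$ with
$\varepsilon = 10^{-3}$ to guarantee positive semi-definiteness. Genes with
more than 3,000 variants are thinned to the highest-MAF 3,000 before the
eigen-decomposition. Only the sum statistic is implemented.

We examined replacing the raw-dosage LD with kinship-whitened dosage
correlations (the exact correlation of the GLS z-scores); on sib-pair
cohorts it did not improve, and slightly worsened, the null calibration of
the gene p-values, so the plain in-cohort LD is used.

## The mixture-of-chi-squares tail

$P(\sum_j \lambda_j \chi^2_1 > T)$ is evaluated by Imhof's exact inversion
integral. Because the integrand oscillates with wavelength bounded below by
$4\pi/(T + \sum\lambda)$, the integral is computed on half-wavelength panels
with 12-point Gauss–Legendre quadrature, accumulated in vectorized blocks
until the truncation bound — the smaller of Imhof's envelope bound and an
integration-by-parts cancellation bound — falls below $10^{-9}$. Equal
weights reduce to a scaled chi-square evaluated in closed form. Below
$p \approx 10^{-6}$ the quadrature's absolute error floor dominates and the
Liu moment-matching tail takes over (standard practice for rare-variant
tests); the method used is recorded in an attribute. Verified against
$10^6$–$10^7$-draw Monte-Carlo oracles in the test suite.

## TWAS

Genes with counts-per-million below 3 in more than 98.5% of samples are
dropped; samples with an intergenic read fraction above 8% (when supplied)
are dropped. Counts are transformed as $\log_2(\mathrm{CPM} + 0.5)$ — a
deliberately simple variance-stabilizing stand-in, since the package's
claims concern association calibration rather than count modeling —
residualized on base covariates, and adjusted stepwise (same rule as the
trait) for batch and the top 10 expression PCs computed once on the
transformed, base-adjusted matrix. The per-gene association is a GLS slope
test of the trait residual on the expression residual under
$V = \sigma_g^2\, 2K + \sigma_e^2 I$, where the variance components are fit
once per trait by profile REML on the eigen-decomposition of $2K$; with
$K = 0$ the test reduces exactly to the OLS t-test. When the genomic
inflation factor (GIF, median chi-square over 0.4549) of the TWAS p-values
exceeds 1.1, z-scores are recalibrated by the empirical null described next.

## Empirical null (inflation/bias correction)

A three-component normal mixture is fit by EM: a dominant null component
seeded at the median with MAD scale, and two wide, low-weight (1% each)
signal components at ±4 MAD. A component whose expected membership drops
below two observations is removed and the EM continues — a signal-free input
degenerates cleanly to a single-normal fit. Bias and inflation are the mean
and sd of the dominant (largest-weight) component;
$z_{corr} = (z - \text{bias})/\text{inflation}$, two-sided p. If the EM hits
a true degeneracy the estimator falls back to median/MAD with a warning.
Limitation: under strong, heavily bimodal signal contamination (tens of
percent of genes) the null component can absorb signal and over-estimate the
inflation — a conservative failure direction; at realistic contamination
(≤10%) the estimator tracks the truth (see the test suite's seeded checks).
This estimator plays the role of a full Bayesian bias/inflation sampler in a
lighter, deterministic form; the trigger rule (GIF > 1.1) is preserved.

## Rare-variant tests

Bi-allelic variants with MAF < 5% and a functional category label are
assigned to genes with the same ±50 kb windowing. The ten categories are
synonymous, missense, plof, promoter CAGE, promoter DHS, enhancer CAGE,
enhancer DHS, upstream, downstream, UTR. Within each gene-category set with
at least two polymorphic variants, functional annotation scores are
standardized and the first principal component — sign-oriented to correlate
positively with the standardized row-mean, making weights deterministic — is
Phred-scaled through its upper-tail percentile,
$aPC_i = -10\log_{10}(1 - r_i/(n+1))$. The SKAT weight combines this with
the classic MAF kernel: $w_j^2 = \mathrm{Beta}(\mathrm{MAF}_j; 1, 25)^2
\cdot aPC_j/\overline{aPC}$ (whether the MAF-beta factor is retained
alongside annotation weights is a convention choice; both factors are kept
and reported). The statistic is
$Q = r'V^{-1}GW^2G'V^{-1}r$ with $r$ first centred by its GLS intercept, and
the null tail uses the eigenvalues of $WG'P_0GW$,
$P_0 = V^{-1} - V^{-1}\mathbf{1}(\mathbf{1}'V^{-1}\mathbf{1})^{-1}\mathbf{1}'V^{-1}$,
through the same quadrature. The aPC is computed per tested variant set
(keeping weights comparable within a test); genome-wide standardization is
an alternative the data would also support. Scaling all weights by a
constant provably leaves p unchanged. Burden and ACAT-style tests are
deliberately absent, and the ten category p-values are never collapsed into
one omnibus value.

The mixture-chi-square null matches the conditional permutation null in its
first two moments exactly, but not in higher moments; at $n = 200$ the
residual discrepancy is below 1.5% relative, visible only beyond roughly
$3\times10^4$ permutations.

## Correlated meta-analysis

Gene p-values are mapped to direction-free upper-tail z-scores
$z = \Phi^{-1}(1-p)$ (clipped to ±37; signs are not commensurable across the
three sources, and TWAS effect directions are reported separately). For each
of the ten categories, a gene × {GWAS, TWAS, RVA-category} matrix is formed —
genes missing the RVA column combine the other two — and the inter-source
correlation $\Sigma$ is estimated per run from the null subset of genes
(complete cases with every p > 1e-4; if fewer than 50 remain the estimator
falls back to all complete cases, then to pairwise-complete estimation).
Estimators: Pearson (default) or tetrachoric; the latter dichotomizes each
z column at its median, where the bivariate-normal quadrant probability has
the closed form $1/4 + \arcsin(\rho)/2\pi$, and maximizes the 2×2 multinomial
likelihood in one dimension. Off-diagonals are clipped to ±0.99 and the
matrix is made PSD by eigenvalue clipping. The combination over the observed
subset $S$ is $p = 1 - \Phi\!\left(\sum_{i\in S} z_i \big/
\sqrt{\mathbf{1}'\Sigma_{SS}\mathbf{1}}\right)$: exactly the input p when one
source is observed, exactly Stouffer when $\Sigma = I$, and exactly the
common p for two fully correlated identical inputs. Significance is
Bonferroni at $\alpha = 0.05$ over the test count aggregated across all ten
runs; a gene is significant if any of its category p-values beats that
threshold.

## Module enrichment and GO over-representation

Genes with p-values from fewer than two sources are removed from every
module (modules dropping below 2 genes are discarded). Each module's fusion
statistic over its member genes' minimum-category CMA p-values is
$T = \sum_g F^{-1}_{\chi^2_1}(1 - p_g)$, referenced to $\chi^2_k$
($k$ = module size); Fisher's $-2\sum\log p$ is available as a sensitivity
flag. Because the inputs are minima over ten runs — anti-conservative against
a uniform reference — the recommended (and pipeline-default) reference is an
empirical null of `n_random` size-matched random gene sets drawn from the
same p table; the analytic tail is retained for speed and unit testing. The
corrected p floor under the empirical null is `n_modules / n_random`, which
is why `run_all` defaults to 10,000 draws. Correction over modules is
Bonferroni by default with BH available (both are defensible; the choice is
exposed, defaulting to the stricter). GO terms are tested against the
background of all genes entering the CMA (the tested universe) by upper-tail
hypergeometric with BH FDR at 0.05, then pruned greedily: walking terms by
ascending p, a term is kept iff its gene-overlap Jaccard index with every
kept term is ≤ 0.5 — a transparent replacement for clustering-based
redundancy removal.

## Replication

Discovery-significant units are re-tested in the second cohort at
$0.05/m$, where $m$ counts significant genes (GWAS, TWAS) or significant
gene-category pairs (CMA, RVA); TWAS calls also report the sign concordance
of the betas. Modules replicate at $0.05/(\text{number of
discovery-enriched modules})$.

# The synthetic cohort generator

The generator exists so that every stage — and the end-to-end pipeline — can
be exercised, calibrated, and power-tested without restricted individual
data. It emulates:

* **Genotypes** by a latent-threshold model: per gene, common variants share
  an exchangeable latent correlation per haplotype, with the latent value
  solved numerically so the *dosage* correlation realizes the configured
  `ld_rho`; rare variants (MAF 0.005–0.05) are independent. Sib-pair
  relatedness is realized by children drawing one haplotype from each of four
  parental haplotypes (no recombination), giving expected kinship 0.25
  between sibs; the pedigree kinship matrix accompanies the genotypes.
* **A trait** with covariate effects (age, sex, centre), a polygenic
  component with variance 0.2 drawn along the kinship, planted effects, and
  unit residual noise.
* **Expression** as negative-binomial counts (dispersion 0.1, lognormal
  baselines including forced-low genes so the CPM filter fires, library-size
  variation, a mild batch shift) loaded on a latent per-gene signal; planted
  TWAS genes feed that latent signal into the trait (expression→trait
  direction).
* **Annotations** as standard-normal scores shifted upward by 1.5 for causal
  rare variants, so annotation-PC weights are informative.
* **Modules and GO sets** as random gene sets plus one planted module/term
  containing the causal genes.

Planted effect sizes default to `gwas_h2 = 0.025` (per-gene variance
fraction of one common causal variant), `twas_beta = 0.3` per sd of latent
expression with loading 0.5 on the counts, and `rva_effect = 0.25` per
carried rare allele on 60% of the gene's plof variants. These were chosen
once so that, at the default planted-cohort scale (800 samples, 400 with
RNA), each source contributes comparable moderate evidence (z ≈ 3): the
multi-source recovery property of the meta-analysis — combined p smaller
than every single source — is a statement about genes with balanced support,
and grossly unbalanced planting (one z ≈ 9 source) would instead measure the
trivial dominance of the strongest source.

What the generator does **not** emulate: realistic human LD maps and allele
frequency spectra, population stratification, genotyping error, sequence
content, cell-type composition, or trait-to-expression reverse causation.
Passing tests therefore demonstrate statistical correctness and calibration
of the machinery under the assumed generating model, not robustness to every
artefact of real cohort data.

# Numerical choices and degenerate inputs

* p-values are clipped to $[10^{-300}, 1]$ on ingestion; z conversions are
  capped at ±37.
* MAF is computed on observed dosages only; missing dosages are mean-imputed
  inside test statistics, never in MAF.
* Zero-variance variants are dropped from LD with a warning; all-constant
  annotation matrices yield uniform weights with a warning; non-PSD kinship
  or correlation matrices are eigenvalue-clipped at zero.
* Rank-deficient covariate designs drop collinear columns with a warning.
* One variant in a category returns a missing RVA result (not an error);
  a single observed source in the CMA returns that source's p exactly.
* Tetrachoric tables are fit on (−0.999, 0.999) and clipped to ±0.99.

# Problem sizes used in the checks

The calibration checks run the full pipeline on null cohorts of 2,000 genes
× 1,000 sib-paired samples (500 with RNA), three seeds; recovery and module
ranking use ten planted cohorts of 300 genes × 800 samples; oracle
comparisons use $10^6$-draw Monte-Carlo and $2\times10^4$-permutation
references on instances with $k \le 10$ variants and $n \le 200$ samples.
These sizes keep a complete run in the minutes range on one CPU while
leaving the binomial/KS bounds tight enough to detect miscalibration of a
few percent.

# Known limitations

* The empirical-null EM can over-estimate inflation under extreme bimodal
  signal contamination (conservative direction).
* The SKAT tail is asymptotic; against exact permutation references it is
  accurate to ~1% relative at n = 200, which is visible at very high
  permutation resolutions.
* Sum-statistic gene scores are direction-free; a gene driven by two
  opposing-direction sources is treated the same as one with concordant
  sources.
* The per-run correlation matrix is estimated from a few hundred
  complete-case genes when an RVA category is sparse; its sampling noise
  (±0.05) propagates into mild per-run calibration wobble, which the
  aggregated Bonferroni accounting absorbs.
* Replication assumes the same trait and comparable gene universes in both
  cohorts; no cross-cohort effect-size calibration is attempted.
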