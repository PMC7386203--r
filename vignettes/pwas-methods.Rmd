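---
title: "Gene-level association testing on protein functional effect scores"
author: "pwasR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level association testing on protein functional effect scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwasR)
```

## The model

A proteome-wide association study (PWAS) asks, for every protein-coding
gene, whether the predicted functional damage to its protein product
varies between individuals in a way that correlates with a phenotype.
Instead of testing each variant separately, all non-synonymous variants
affecting a gene are aggregated into two per-sample gene scores and those
scores are regressed on the phenotype. This recovers signal spread across
many (possibly rare) variants and, uniquely, models recessive inheritance
at the gene level, where compound heterozygosity — two different variants
damaging the two gene copies — is visible.

### Variant effect scores

Every protein-affecting variant gets an effect score $s \in [0, 1]$,
read as the probability that the protein retains its function given the
variant ($0$ = complete loss of function, $1$ = no damage). Nonsense,
frameshift, and canonical splice-site variants are treated as complete
loss of function ($s = 0$). Missense scores come from an external
predictor and enter through the input table (or a pluggable scorer
function); `pwasR` deliberately does not re-implement any particular
machine-learning predictor — the aggregation contract only needs a number
in $[0,1]$. In-frame indels are scored by a rule,
$s = \max(0,\, 1 - (n_\mathrm{sub} w_\mathrm{sub} + n_\mathrm{ins}
w_\mathrm{ins} + n_\mathrm{del} w_\mathrm{del}))$, monotone in the
numbers of substituted, inserted and deleted residues, equal to 1 when no
residue is affected. The per-residue weights default to $0.05$ and are
exposed (`indelWeights`); the default is a deliberately mild, configurable
choice — damage grows with the size of the in-frame lesion and saturates
at complete loss after 20 affected residues.

### From variant scores to gene scores

For variant $i$ of a gene in a given sample, with genotype probabilities
$(p_0^{(i)}, p_1^{(i)}, p_2^{(i)})$ of carrying the alternate allele 0, 1
or 2 times, the probability that the gene retains function considering
that variant alone is

$$x_i = p_0^{(i)} + p_1^{(i)} s_i + p_2^{(i)}\bigl(\mu s_i +
(1-\mu)s_i^2\bigr),$$

where $\mu \in [0,1]$ interpolates between independent ($\mu = 0$, the
two homozygous hits multiply) and fully dependent ($\mu = 1$, the
homozygote behaves like the heterozygote) homozygous damage. The
probability that variant $i$ damages *exactly one* copy is

$$y_i = p_1^{(i)} (1 - s_i) + p_2^{(i)} (1-\mu)\, 2 s_i (1 - s_i);$$

a fully dependent homozygote cannot damage exactly one copy, hence the
$(1-\mu)$ factor.

The **dominant score** is
$D = \exp\!\bigl(-\lVert(\log \tfrac1{x_1}, \dots, \log
\tfrac1{x_k})\rVert_p\bigr)$: at $p = 1$ the variants act independently
($D = \prod_i x_i$), at $p = \infty$ only the most damaging variant
matters ($D = \min_i x_i$). The **recessive score** is
$R = (1 + \zeta_q) D_p$ with
$\zeta_q = \lVert(y_1/x_1, \dots, y_k/x_k)\rVert_q$ — the probability of
at most one damaging hit, so that $1 - R$ is the probability of the
two-hit event recessive conditions require. When some $x_i = 0$ the
product form is undefined and the limit of the expression is used: two or
more zeros give $R = 0$; a single zero at position $i$ gives $y_i$ for
$p > 1$ and $y_i \prod_{j \neq i} x_j$ for $p = 1$.

Defaults are the published fitted values $\mu_D = 1$, $p_D = 1.25$,
$\mu_R = 0.5$, $p_R = \infty$, $q_R = 3$ (`AggregationParams()`); the
strings `"inf"` are accepted in configuration files. The dominant and
recessive matrices use their own $\mu$ ($x$ is computed with $\mu_D$ for
$D$ and recomputed with $\mu_R$ for $R$; $y$ always uses $\mu_R$): the
two schemes share a functional form but are independently parameterized.
Genotypes are assumed unphased, and distinct variants are assumed to hit
distinct gene copies — the modeling choice that makes compound
heterozygosity count as two hits. Missing genotype calls become
$(1,0,0)$: an ungenotyped damaged gene is mistaken for intact, which
loses power but cannot create false positives.

### Association testing

Each gene is tested by covariate-adjusted regression — ordinary least
squares for continuous phenotypes, logistic regression for binary ones
(categorical phenotypes are split one-vs-rest into binary phenotypes
first). Three models are fitted: dominant ($H_0\!: \beta_D = 0$, Wald
test), recessive ($H_0\!: \beta_R = 0$), and generalized
($H_0\!: \beta_D = \beta_R = 0$, a 2-df nested-model F-test for linear
models and a 2-df likelihood-ratio test for logistic ones — the standard
joint tests in these families). Benjamini–Hochberg q-values are computed
separately within each model's p-value column, since each model reports
its own q-values. Effect sizes are Cohen's d between cases and controls
on the score column (binary) or the partial Pearson correlation "r"
between the covariate-residualized score and phenotype (continuous),
sign-matched to the regression coefficient: negative values mean
the gene is more damaged in cases.

### Power simulation

`estimatePower()` reproduces the simulation design used to characterize
the method: a phenotype $y = \beta x + \sigma$, $\sigma \sim N(0,1)$,
where $x$ is a gene's dominant column, recessive column, or (additive
inheritance) the standardized sum of the two standardized columns, itself
standardized to mean 0 and sd 1 across the cohort. Binary phenotypes
threshold the same liability at the upper `prevalence` quantile of its
theoretical $N(0, 1+\beta^2)$ distribution (default prevalence 0.1), the
standard liability-threshold convention. Each replicate picks a random
gene from the pool, subsamples the cohort, perturbs the gene's variant
scores with clipped Gaussian noise of sd $\epsilon$, rebuilds the gene's
scores from the perturbed variant scores, simulates the phenotype, and
runs the matching test (dominant/recessive inheritance use their own
model; additive uses the generalized model) at a per-test $\alpha$
(default 0.05, the single-gene design of the original simulations;
configurable). Power is the significant fraction with a Wilson 95%
interval, and the whole table is deterministic given one seed.

## The synthetic cohort generator

`simulateCohort()` emulates the genetic architecture the method is meant
for, without any external data:

* **Variants per gene**: log-normal, default `meanlog = log(36) - 0.5`,
  `sdlog = 1` (mean ≈ 36 variants per gene, matching the typical count of
  non-synonymous variants per protein-coding gene in a biobank-scale
  imputed cohort), floored at 1.
* **Allele frequencies**: log-uniform on $(0.001, 0.05)$ by default —
  non-synonymous variants are predominantly rare, and the log-uniform
  shape puts most variants at the rare end while keeping a few common
  ones. Genotypes are Hardy–Weinberg draws, Binomial(2, f).
* **Consequence mix**: missense 85%, nonsense 5%, frameshift 5%,
  canonical splice 3%, in-frame indel 2% — missense is the vast majority
  of non-synonymous variation, with a realistic loss-of-function tail.
* **Missense scores**: Beta(0.5, 0.5), a bimodal distribution with mass
  near both 0 (damaging) and 1 (benign), the qualitative shape of
  predicted effect-score distributions.
* **Covariates**: independent standard normals (an intercept is added at
  test time).

What the generator does *not* emulate: linkage disequilibrium (variants
are independent), population structure and relatedness,
imputation-quality artifacts, sex and mitochondrial chromosomes, and any
correlation between allele frequency and effect score (real damaging
variants are shifted toward rarity by selection). Tests passing on these
cohorts therefore validate the statistical machinery and its
calibration, not robustness to confounding — on real data the covariate
set, not the generator, has to carry that burden.

## Numerical choices

* **Stable p-norms.** $\lVert v\rVert_p$ is evaluated as
  $m\,(\sum (v_i/m)^p)^{1/p}$ with $m = \max v$, so the $p \to \infty$
  behaviour is correct to $10^{-6}$ even at $p = 10^6$ and no
  intermediate overflows occur; $x_i = 0$ is short-circuited before any
  logarithm, so no IEEE infinities enter the norms.
* **Clipping $R$.** With finite $q$, $(1+\zeta_q)D_p$ can exceed 1 (many
  mildly damaging heterozygous variants inflate the correction); since
  scores are interpreted as probabilities, $R$ is clipped to $[0,1]$ and
  the aggregation reports how many values were clipped. Whether to clip
  or renormalize is not dictated by the model; clipping preserves the
  probability contract.
* **Snap-to-one.** Values of $R$ within $10^{-12}$ of 1 are set to
  exactly 1. A single heterozygous variant gives $R =
  (1 + \frac{1-s}{s})s = 1$ analytically, but floating-point evaluation
  leaves it short by ~$10^{-16}$; without snapping, genes with no true
  recessive variability would look non-constant and leak numerical noise
  into simulations.
* **Degenerate score columns.** A score vector with no variance left
  after covariate adjustment cannot be tested; it is flagged
  `"degenerate"` and reported at $p = 1$. Logistic fits are IRLS-capped
  at 100 iterations; non-convergence, a perfectly fitted model, or a
  coefficient shifting the log-odds by more than 30 per score-sd is
  flagged `"separation"` and likewise reported at $p = 1$ — conservative
  fallbacks that protect FDR validity.
* **Collinearity.** Covariate matrices are reduced to full column rank by
  pivoted QR with a warning; when the dominant and recessive columns of a
  gene are collinear, the generalized test degrades to the corresponding
  1-df test (flag `"collinear"`).
* **Genotype triplets** are renormalized to sum to exactly 1 on ingest;
  raw sums outside $[0.99, 1.01]$ are rejected as malformed.

## Problem sizes used by the test-suite

The packaged checks run entirely on generated cohorts, sized so the
properties they probe are sharp: the aggregation core is verified
exactly (to $10^{-12}$) against a brute-force enumeration oracle for all
genes of up to 3 variants on a score grid; type-I calibration uses 500
genes × 2000 samples with 5 covariates; planted-signal recovery and the
score-shuffle control use 200 genes × 5000 samples with a recessive
effect of $\beta = 0.5$ over 20 phenotype replicates; power curves use
cohort sizes 500/2000/8000 at $\beta \in \{0.1, 0.3\}$ and
$\epsilon \in \{0, 0.25\}$ with 50 replicates per cell. The same
quantities are recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

* **The shuffle control is only a partial negative control at high
  effect sizes.** Shuffling variant scores before aggregation destroys
  the score–variant correspondence but *not* the carrier structure: a
  gene whose recessive column deviates from 1 at a handful of multi-hit
  carriers keeps deviating at the same samples under any score
  assignment, so a sufficiently strong planted signal ($\beta = 0.5$ at
  $n = 5000$) remains detectable through the shuffled scores. Our tests
  compute this directly: the shuffled scan still flags about one gene
  per replicate versus ~0.1 under a true null. Score shuffling
  demonstrates the *contribution* of score content (power drops), not
  its necessity; the $\epsilon$-noise arm of the power simulation is the
  cleaner probe of score-content value.
* Recessive logic assumes autosomal biallelic inheritance; sex and
  mitochondrial chromosomes, structural and copy-number variants, and
  non-canonical splicing are out of scope.
* Multi-allelic sites must be decomposed to bi-allelic records upstream
  (e.g. `bcftools norm -m-`); phased genotypes are not exploited.
* Relatedness is not modeled — remove kin before testing rather than
  relying on a mixed model.

## A minimal run

```{r example, eval = FALSE}
cohort <- simulateCohort(nSamples = 1000, nGenes = 50, seed = 1)
scores <- buildGeneScores(cohort$genotypes)          # AggregationParams()
planted <- plantAssociation(scores, "GENE0007", "recessive",
                            beta = 0.5, seed = 2)
res <- runPWAS(scores, planted$phenotype, covariates = cohort$covariates)
head(res)
```
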