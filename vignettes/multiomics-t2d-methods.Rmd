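---
title: "Statistical methods of the triomics pipeline"
author: "triomics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods of the triomics pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomics)
```

# Scope

`triomics` implements an integrated case/control analysis of blood DNA
methylation, whole-genome genotypes and serum metabolomics in type 2
diabetes (T2D): epigenome-wide association (EWAS) with a two-way
discovery/replication design, kinship-aware methylation-QTL (meQTL)
mapping, a metabolome-wide association study (MWAS), a two-batch
CpG-metabolite meta-analysis with heterogeneity exclusion, two-sample
Mendelian randomization (2SMR) from summary statistics, and assembly of a
tripartite SNP-CpG-metabolite network. This vignette documents the models,
their assumptions, the tunable parameters, and the design decisions taken
where the methodology left genuine freedom.

# The association stages

## EWAS with two-way discovery/replication

Each CpG's beta value (methylation fraction, bounded in $[0,1]$) is the
dependent variable of an ordinary least-squares model with T2D status as
the predictor of interest and, as covariates: sex, the first two principal
components of the five measured leukocyte counts, plate, batch, a
batch-by-sex interaction, the well-row position, the smoking-surrogate CpG
cg05575921 (AHRR), and three genomic principal components. BMI is included
in one of the two parallel models (`ewas_BMI`) and omitted in the other
(`ewas_noBMI`), because random cohort assembly can leave BMI differently
distributed between cases and controls.

**Age** is deliberately not a design column. In cohorts assembled the way
these were, cases are substantially older than controls, so age and
disease status are nearly collinear and a joint fit would split the signal
arbitrarily. Instead each CpG is first regressed on age *in controls
only*, and the fitted line $\beta_0 + \beta_1\,\mathrm{age}$ is subtracted
from all samples (`fitAgeModel()` / `ageResidualize()`). Plates are
nested in batches in practice, so the design builder lets the plate
indicators absorb the batch main effect and codes the batch-by-sex
interaction explicitly against the reference batch; factors constant on
the analysed subset are dropped, and any remaining collinearity is a hard
error naming the offending columns.

Selection is two-way: CpGs with discovery $p < 5.8\times10^{-8}$ (the
epigenome-wide threshold for the 850K array; configurable) in one cohort
are kept if their p-value in the other cohort is below $0.05/k$, with $k$
the number of discovery hits in the discovering cohort; the roles are then
swapped and the union taken. The two BMI models are combined by union and
the result filtered to CpGs whose effect has the same sign in both cohorts
under the model that discovered them — the direction-consistency step is
applied once, at the end, reproducing the published funnel shape
(74 selected, 66 direction-consistent in the source design).

## Kinship-aware meQTL mapping

Relatedness is summarized by the genomic relationship matrix (GRM)
$K = m^{-1} Z^\top Z$ over $m$ variants with
$Z_{ij} = (g_{ij} - 2p_i)/\sqrt{2p_i(1-p_i)}$; its diagonal is $\approx 1$
and full siblings sit near $0.5$. Negative eigenvalues (possible when
samples outnumber variants) are bent to $10^{-6}$.

For each CpG the polygenic mixed model
$y \sim N(X\beta,\ \sigma^2_g\, 2K + \sigma^2_e I)$ is fitted by **maximum
likelihood** with a one-dimensional profile search over
$h^2 = \sigma^2_g/(\sigma^2_g+\sigma^2_e)$ on the spectral decomposition
of $2K$: given $h^2$, the GLS coefficients and total variance are closed
form, so `optimize()` over $h^2 \in [0, 0.99]$ suffices; the endpoints are
always evaluated as well, and near-ties resolve to the *smallest* $h^2$ so
that an uninformative kinship ($K = I$) reduces exactly to OLS. ML (not
REML) was chosen because it matches the default behavior of the classical
`polygenic` fit this stage emulates and is directly checkable against a
grid oracle.

Each variant is then tested with an **efficient score test** on the
polygenic residuals $r$:
$$T = \frac{(\tilde g^\top V^{-1} r)^2}{\tilde g^\top V^{-1} \tilde g},
\qquad p = P(\chi^2_1 > T),$$
where $\tilde g$ is the genotype centered *and projected off the
fixed-effect design in the $V$-metric*. The projection matters: with a
merely centered genotype the reported effect
$b = \tilde g^\top V^{-1} r / \tilde g^\top V^{-1}\tilde g$ is attenuated
by a factor $1 - R^2(g \mid X)$ whenever the variant correlates with the
covariates — which ancestry-differentiated variants do through the genomic
PCs — while the efficient score leaves the estimate unbiased; under the
null, and for variants orthogonal to the design, the two versions
coincide. Since the GLS residuals already satisfy $X^\top V^{-1} r = 0$,
only the denominator changes.

Pairs below $8.7\times10^{-10}$ (configurable) are retained. A pair is
*cis* when SNP and CpG share a chromosome at a distance strictly below
1 Mb, *trans* otherwise — including same-chromosome pairs beyond 1 Mb,
because the cis definition is exclusive. Replication is locus-based: a
discovery pair replicates if the replication cohort shows the same CpG
with the identical SNP, or with any SNP within 500 kb on the same
chromosome, at $p < 0.05/n_\mathrm{discovery\,pairs}$ (the replication
threshold is not pinned down by the source design and is configurable).
The variant MAF filter defaults to 0.01.

## MWAS and the CpG-metabolite meta-analysis

Metabolite QC (`metaboliteQC()`) follows log transform → single-pass
outlier removal (values beyond mean ± 3 SD over all samples set missing)
→ re-standardization to mean 0, SD 1 over the non-missing values.
Natural log is used (the base only rescales z-scores); the outlier pass is
single-shot, not iterated; metabolites with zero variance or more than 20%
missingness (configurable) are dropped. Removal precedes the z-scoring —
the one reading under which the published "936 metabolites remained"
bookkeeping is reproducible.

The MWAS regresses each metabolite on T2D with age, sex, BMI and three
genomic PCs, splits samples 70/30 at random, keeps discovery hits at
$p < 0.05/m_\mathrm{total}$ and replications at $p < 0.05/m_\mathrm{sig}$
with the same sign. CpG-metabolite associations then reuse the EWAS model
(CpG dependent, metabolite as predictor, BMI excluded, age residualized)
within each of two metabolomics batches, and the batches are combined by
**fixed-effect inverse-variance meta-analysis** with weights
$w_i = 1/\mathrm{SE}_i^2$ — the STDERR scheme, chosen over sample-size
weighting because the published per-pair effect sizes and the coupling of
the heterogeneity p-value with I² match the inverse-variance formulation.
Pairs with Cochran's $Q$ p-value below 0.05 are excluded rather than
down-weighted. With two batches this exclusion rule is *exactly* a
threshold on I²: for df = 1,
$Q > \chi^2_{1,0.95} = 3.841 \iff I^2 = 100\,(Q-1)/Q > 73.97\%$ — the
"heterogeneity corresponded to I² > 74" observation is a theorem of the
df = 1 case, and the test suite asserts the equivalence on random inputs.
Final pairs must pass $p < 0.05/(n_\mathrm{CpGs}\times n_\mathrm{mets})$.

## Two-sample Mendelian randomization

Per instrument the inputs are $(B_x, \mathrm{SE}_x)$ — the variant's
effect on the exposure (CpG methylation, from the meQTL stage) — and
$(B_y, \mathrm{SE}_y)$ — its effect on the outcome (HbA1c, from external
GWAS summary statistics). The single-SNP estimator maximizes the
bivariate-normal likelihood $B_x \sim N(\xi, \mathrm{SE}_x^2)$,
$B_y \sim N(\theta\xi, \mathrm{SE}_y^2)$ numerically; its point estimate
is identically the Wald ratio $B_y/B_x$ and its Fisher-information SE
equals the closed form
$\sqrt{(\mathrm{SE}_y/B_x)^2 + (B_y\,\mathrm{SE}_x/B_x^2)^2}$, an identity
the test suite verifies to 1% on a 1000-case random grid. The multi-SNP
IVW estimator combines ratios with **first-order** weights
$s_j = \mathrm{SE}_{y,j}/|B_{x,j}|$ (second-order weights do not reproduce
the published combined SE of $1.8\times10^{-5}$ for the three-variant HK1
analysis), reports $Q$, its $\chi^2_{J-1}$ p-value, and I². Confidence
intervals are $\pm 1.96\,\mathrm{SE}$ with two-sided normal p-values. The
published heterogeneity figure labeled "I²" (90.34) is treated as
Cochran's $Q$, since $e^{-90.34/2} = 2.4\times10^{-20}$ matches the
printed heterogeneity p-value exactly; the proper I² is reported
alongside.

## Partial-correlation network

Metabolites are residualized against the MWAS covariate set (the
natural reading of "all covariates mentioned previously"; configurable)
and the metabolite Gaussian graphical model is estimated from the
residuals: the sample correlation matrix is shrunk towards the identity
with the Schäfer-Strimmer analytic intensity
$\lambda^* = \sum_{i<j}\widehat{\mathrm{Var}}(r_{ij}) / \sum_{i<j} r_{ij}^2$
(clipped to $[0,1]$ with a warning and recorded on the result), partial
correlations come from the inverse
($\rho_{ij} = -P_{ij}/\sqrt{P_{ii}P_{jj}}$), and each pair is tested by
Fisher z with effective sample size $n - p - 1$ against a Bonferroni
threshold over all $p(p-1)/2$ pairs. This replaces the empirical-Bayes
local-fdr edge test of the GeneNet package with a verifiable
z-approximation — the Bonferroni cut is the published rule, and the
z-based version admits an exact unregularized oracle. The Bonferroni
denominator counts all pairs among included metabolites.

The network unions meQTL, CpG-metabolite and metabolite-metabolite edges
into a typed tripartite graph; duplicate edges collapse to the smaller
p-value, conflicting layer assignments are an error, and components,
SIF/GraphML exports and node/edge TSVs are provided.

# The synthetic-data generator

`simulationConfig()` / `simulateCohort()` produce cohorts with the
dependence structure every stage assumes, with ground truth recorded for
recovery testing. Defaults mirror the study conditions the pipeline
targets: 1026 samples in three cohorts (454/381/191), 43.5% T2D cases
(cases defined by self-report or HbA1c ≥ 6.5 with onset above 30 years),
cases ~17 years older than controls in the EWAS cohorts, BMI imbalanced in
cohort 1 only, a genotyping split of ~703/323 and a metabolomics batch
split of ~364/344. Feature spaces are scaled down — 1000 CpGs, 5000 SNPs,
150 metabolites by default; tests use 300-2000 samples with hundreds of
features — so a full synthetic run takes seconds to minutes on one core.

* **Genotypes**: explicit sibships (four parental haplotypes, Mendelian
  segregation per SNP) rather than a covariance draw, so kinship
  *estimation* is genuinely exercised (expected sibling GRM entry 0.5);
  two ancestry components under a Balding-Nichols $F_{st}$ of 0.02 feed
  the genomic PCs; variants span two chromosomes over 250 Mb so cis and
  trans labels both occur.
* **Methylation**: each CpG's logit is linear in its covariates (age,
  sex, batch, batch-by-sex, plate, well row, cell composition, planted
  SNP and T2D effects) plus Gaussian noise, then inverse-logit — beta
  values stay strictly inside $(0,1)$ while effects remain exactly linear
  on the logit scale. One designated CpG (cg05575921) is driven by a
  latent smoking variable.
* **Metabolites**: latent z-scores from a multivariate normal whose
  correlation matrix is the standardized inverse of a sparse precision
  matrix constructed directly from the planted partial correlations
  ($P = I - \rho$, rescaled towards zero until safely positive definite,
  so the planted $\rho$ *are* the true partial correlations); planted T2D
  and CpG effects shift the means; exponentiation produces the positive
  raw scale the QC log-transform expects.

Planted effects live on the scale the generator is linear in: logit
methylation for SNP→CpG and T2D→CpG effects, latent-SD units for
metabolite effects. The association stages default to beta values, as the
emulated design did, and expose `transform = "logit"`; recovery tests use
the logit scale so that estimates and generative parameters are
commensurable. The recovery checks pool a small number of replicate
cohorts (3-5) and compare the mean deviation against the pooled SE — a
sharper unbiasedness check than a single draw at the same nominal 2-SE
level. Because the QC z-scoring divides by a data-dependent SD (which
includes planted between-group variance), metabolite recovery checks undo
that per-metabolite affine scale before comparing.

What passing these tests shows — and does not. The generator emulates
additive genetics, linear covariate structure, family relatedness, batch
nesting and a sparse conditional-dependence metabolome; it does not
emulate realistic linkage disequilibrium (planted pairs aside, variants
are independent), cell-type heterogeneity beyond a Dirichlet composition,
non-linear age trajectories, or assay artefacts such as probe
cross-hybridization. Calibration and recovery on these cohorts therefore
validate the estimators and the plumbing, not robustness to everything
real arrays produce.

# Numerical choices and degenerate inputs

* Profile ML over $h^2\in[0,0.99]$ with `optimize()` (tolerance $10^{-6}$)
  plus explicit endpoint evaluation; ties within $10^{-6}$ log-likelihood
  resolve to the smallest $h^2$.
* GRM eigen-bending only engages when a Cholesky test fails; bent
  eigenvalues are floored at $10^{-6}$.
* The score test's quadratic form is floored at zero against roundoff;
  monomorphic variants are skipped with a message rather than an error.
* Shrinkage intensities outside $[0,1]$ are clipped with a warning.
* Designs are pruned of constant columns (a batch inside a single-batch
  subset); genuine rank deficiency errors with column names.
* Missing ages exclude the sample from residualization with a warning;
  missing metabolite cells are tolerated per-feature (complete-case fits)
  and may be mean-imputed (z = 0) for the GGM, which requires complete
  data.
* Single-record VCFs, GT and DS fields, phased separators and missing
  genotypes are all handled; multiallelic records are skipped or error by
  choice.
* Coordinates are 1-based inclusive (VCF convention); distances in bp.

# Known limitations

The two-step age-residual adjustment is not exactly calibrated when age
and disease are strongly collinear: the per-CpG age slope is estimated in
finitely many controls, and the estimation noise multiplies age, which
differs between cases and controls. The resulting chi-square inflation is
scale-free — approximately
$1 + f\,\Delta_\mathrm{age}^2/\mathrm{Var}_\mathrm{controls}(\mathrm{age})$
with $f$ the case fraction — about $\lambda \approx 1.4$ under a 17-year
age gap, *independent of sample size and of methylation noise*. This is a
property of the adjustment itself, not of this implementation. Null
calibration is therefore assessed on a global null in which age is
exchangeable with disease (`ageCollinearT2d = FALSE`); under the
age-imbalanced design the adjustment trades the collinearity bias for this
variance leak, and discovery p-values near the significance boundary
should be read accordingly.

Other limitations: the GGM edge test is a z-approximation, slightly
conservative at small $n - p$; the locus-replication threshold is a
package default, not a published value; the pipeline analyses whole-blood
methylation only, and no medication adjustment is attempted.
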