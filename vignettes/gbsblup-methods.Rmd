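---
title: "Models and methods in gbsblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in gbsblup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbsblup)
```

gbsblup implements genomic prediction for polyploid populations genotyped
by sequencing when allele dosages cannot be called — the situation of
hexaploid timothy (*Phleum pratense* L.) and many other outcrossing
polyploids without a reference genome. This vignette explains the models,
the tunable parameters, and the numerical and design choices behind the
implementation.

## Continuous genotypes

With genotyping-by-sequencing, each individual $i$ and biallelic marker
$j$ yields reference and alternate read counts $R_{A_{ij}}$ and
$R_{B_{ij}}$. Instead of calling an integer dosage in $0..k$ (ploidy $k$),
the genotype is taken to be the continuous allele frequency

$$f_{ij} = \frac{R_{A_{ij}}}{R_{A_{ij}} + R_{B_{ij}}},$$

missing when no reads were observed. `read_vcf_depths()` extracts the
counts from a VCF (AD, or RO/AO, fields; multi-allelic records are skipped
and counted), `continuous_genotypes()` forms $f$, and
`merge_repeated_samples()` averages the frequencies of repeated samples of
the same individual — the merged read counts are summed, so depth
statistics and dispersion likelihoods downstream use all reads supporting
an individual.

Markers are then filtered conjunctively on minor allele frequency
(computed from the mean observed $f$ before imputation, so imputation
cannot alter selection), mean total read depth, and call rate
(`filter_markers()`), and remaining missing cells are imputed with the
marker mean (`impute_missing()`), which preserves per-marker means
exactly. The per-marker mean depth is averaged over individuals *with*
reads; averaging over all individuals is the other defensible convention,
and the choice matters only for sparsely called markers.

## The relationship matrix and its scaling

With $\mathbf F$ the $n \times m$ matrix of (imputed) continuous genotypes
and $\bar{\mathbf f}$ its column means,

$$\mathbf G = \frac{(\mathbf F - \mathbf 1\bar{\mathbf f}')
  (\mathbf F - \mathbf 1\bar{\mathbf f}')'}{h}.$$

Because $\bar{\mathbf f}$ is recomputed from the imputed matrix, each row
of $\mathbf G$ sums to zero exactly. Three scalings $h$ are provided:

* **naive** — $h = \frac1k \sum_j \bar f_j (1-\bar f_j)$, the Binomial
  variance of a dosage ratio under ploidy $k$;
* **debiased** — the naive $\mathbf G$ with diagonal elements multiplied
  by $1 - w_i$, $w_i = (k-1)/(\bar R_{T_i} + k - 1)$, correcting the
  read-sampling inflation of self-relationships at each individual's mean
  depth ($w_i \to 0$ as depth grows). This intentionally breaks the
  row-sum-zero property;
* **Beta-Binomial** — $h = \sum_j \bar f_j (1-\bar f_j)\,\omega_j$ with
  the heterogeneity factor
  $\omega_j = [1 + (\bar R_{T_j} - 1)\hat\tau_j] / \bar R_{T_j}$. No
  ploidy term appears: the read-sampling model replaces it.

The Beta-Binomial scaling treats the latent allele-sampling probability at
marker $j$ as $p_{ij} \sim \mathrm{Beta}(\mu_j, \tau_j)$ in the
location/dispersion parameterisation
($\alpha = \mu(1-\tau)/\tau$, $\beta = (1-\mu)(1-\tau)/\tau$), with
$R_{A_{ij}} \mid p_{ij} \sim \mathrm{Binomial}(R_{T_{ij}}, p_{ij})$, so
that

$$\mathbb{V}\mathrm{ar}[f_{ij}] =
  \mu_j(1-\mu_j)\,\frac{1 + (R_{T_{ij}}-1)\tau_j}{R_{T_{ij}}}.$$

$\tau_j = 0$ recovers pure Binomial sampling; overdispersion
($\tau_j > 0$) keeps the genotype variance bounded away from zero even at
high depth, which is why the naive scaling inflates the diagonal of
$\mathbf G$ on overdispersed data and the Beta-Binomial scaling does not.

$\hat\tau_j$ maximises the Beta-Binomial log-likelihood of the marker's
read counts with $\mu_j$ fixed at $\bar f_j$ (`estimate_tau()`). Numerical
choices: bounded L-BFGS-B on $[10^{-6}, 1-10^{-6}]$ from a moment-based
start, with a dense grid search as fallback when the optimiser does not
converge (the result is then flagged); cells with zero reads are excluded
because imputed values carry no read evidence. Since the naive and
Beta-Binomial scalings differ only by the scalar $h$, the two
$\mathbf G$ matrices are exact scalar multiples, and GBLUP with
co-rescaled genetic variances returns identical breeding values — a
property the test suite asserts to $10^{-10}$. The debiased matrix is not
a scalar multiple, so its predictions genuinely differ.

## The mixed model

Phenotypic records of progeny are modelled per trait stack as

$$\mathbf y = \mathbf X\mathbf b + \mathbf Z_m\mathbf m +
  \mathbf Z_c\mathbf c + \mathbf e,$$

with trial-by-year contemporary groups as fixed effects, mother (genetic)
effects $\mathbf m \sim N(\mathbf 0, \mathbf V_M \otimes \mathbf G)$,
progeny-within-trial permanent-environment effects
$\mathbf c \sim N(\mathbf 0, \mathbf V_C \otimes \mathbf I)$, and
residuals correlated across the traits observed on the same record
through $\mathbf V_E$. `solve_gblup()` solves the sparse mixed-model
equations; mothers without records obtain GEBV through their genomic
relationships with recorded mothers. Fixed effects use cell-means coding
(one indicator per trial-by-year level per trait, no intercept), which
fits the same model as reference-level coding without an arbitrary
reference choice. In single-trait mode each trait uses the corresponding
diagonal elements of $\mathbf V_M$, $\mathbf V_C$, $\mathbf V_E$.
A singular $\mathbf G$ receives a small configurable ridge
($10^{-6}$ by default, logged) before inversion.

Records with some traits unobserved enter the multi-trait equations
through the inverse of the observed sub-block of $\mathbf V_E$,
equivalent to zero-weighting the missing traits.

## EM-REML

Variance components are estimated by deterministic
Expectation–Maximisation REML (`em_reml()`): each round solves the
mixed-model equations, forms the exact conditional expectations
(quadratic forms in the solutions plus trace terms from the inverted
coefficient matrix), and updates $\mathbf V_M$, $\mathbf V_C$,
$\mathbf V_E$. Missing trait measurements are integrated out with the
usual multivariate-normal conditional moments. The restricted
log-likelihood is non-decreasing across iterations — asserted by the test
suite — and converged solutions coincide with the maximiser of an
independently coded dense restricted likelihood. Exact traces are
feasible because the package targets evaluations of hundreds of mothers
and a few thousand records; Monte-Carlo trace approximations, useful at
national-evaluation scale, are deliberately not implemented, and
sampling-based standard errors of the estimates are out of scope
(`reml_standard_errors()` says so explicitly; reports carry `NA`).

Convergence is declared when the maximum relative round-to-round change
of any component falls below `tol`. EM approaches the optimum
geometrically and slows near convergence; with a single trait the
permanent-environment equations (a diagonal block) are absorbed exactly
into the fixed-plus-mother system, so several hundred iterations cost
seconds and desk-scale fits run at `tol` of $10^{-6}$–$10^{-8}$.
Parameter-recovery simulations in the tests use $10^{-6}$ with a
1000-iteration cap.

## Genetic parameters

Because the mother (half-sib family) variance captures one quarter of the
additive variance, $\sigma^2_{A} = 4\sigma^2_{M}$, and because
$\mathbf G$ is not rescaled to unit mean inbreeding, the mean diagonal
$\overline{\mathrm{diag}(\mathbf G)}$ enters the parameter formulas:

$$h^2 = \frac{\overline{\mathrm{diag}(\mathbf G)}\,\sigma^2_A}
  {\sigma^2_M\,\overline{\mathrm{diag}(\mathbf G)} + \sigma^2_C +
   \sigma^2_e},
\qquad
c^2 = \frac{\overline{\mathrm{diag}(\mathbf G)}\,\sigma^2_A + \sigma^2_C}
  {\sigma^2_M\,\overline{\mathrm{diag}(\mathbf G)} + \sigma^2_C +
   \sigma^2_e}.$$

$h^2$ is returned unclamped — with negligible permanent-environment and
residual variance the formula exceeds 1 (it tends to 4), and hiding that
would mask upstream problems. $c^2 - h^2 = \sigma^2_C/\mathrm{denominator}
\ge 0$ holds exactly. Genetic correlations are the correlations of
$4\mathbf V_M$ (the factor cancels); phenotypic correlations those of
$\mathbf V_P = \mathbf V_M + \mathbf V_C + \mathbf V_E$. Report rounding
is half away from zero at two decimals, matching how such tables are
printed.

## Validation

Two splitting strategies are provided. *Family cross-validation*
(`family_cv_splits()`) holds out, per half-sib family meeting a size
floor, all progeny records of that family's mothers. *Forward prediction*
(`forward_split()`) holds out all records from a cutoff year onward. In
both cases the genomic data of every mother stays in the evaluation; only
phenotypes are masked.

Accuracy is summarised by (i) predictive ability — the correlation
between reduced-fit GEBV and progeny means adjusted for fixed and
permanent-environment effects — and (ii) the Legarra–Reverter statistics:
correlation, regression slope, and $R^2$ of full-evaluation GEBV on
reduced-evaluation GEBV over the validation mothers, with slope below 1
read as over-prediction. Following the convention adopted here, the
regression runs full on reduced (the original method regresses partial on
whole; with nested evaluations both center the slope on 1 for an unbiased
evaluator, which the tests verify over replicate simulations).
Adjustments of validation phenotypes default to the full-data fit because
validation-only trial-years have no estimable effects in the reduced fit;
`adjust_with = "reduced"` is available for the stricter convention where
estimable.

## The synthetic-data generator

Nothing in the pipeline requires real data: `simulate_population()`,
`simulate_reads()` and `simulate_phenotypes()` generate populations with
exactly the structure the pipeline assumes, and `simulate_dataset()`
writes them as VCF + phenotype + sample-map files. Defaults were chosen
once to emulate a timothy-like GBS breeding population and are not
re-tuned:

* ploidy 6; 18 half-sib families; mothers share one simulated parent per
  family (half the gametes drawn at the family parent's realised
  frequency, half at the base frequency), which makes half-sibs more
  related than non-sibs without disturbing marginal frequencies;
* base allele frequencies $\sim$ Beta(2.64, 0.79) — mean 0.77, SD 0.20,
  matching the right-shifted reference-allele frequency spectrum typical
  of GBS reference panels built from the same population;
* per-marker $\tau \sim$ Beta(1.3, 3.7) — mean 0.26, SD about 0.16,
  spanning roughly 0–0.8 as estimated on real GBS data;
* total depth $\sim$ zero-inflated negative binomial, mean 38 and size
  1.4 (right-skewed, SD about 33), with an extra dropout probability of
  0.2 producing the missingness; a zero total depth is the *only* source
  of missing genotypes;
* degenerate Beta draws at $\mu \in \{0, 1\}$ return $\mu$ exactly, since
  the Beta distribution is undefined at the boundary;
* single-trait phenotype defaults use first-cut-yield magnitudes
  (mother 15085.7, permanent environment 79075.3, residual 482725.8, in
  (kg DM/ha)$^2$); trial-by-year effects default to half the residual SD;
* the crossing design linking mothers to progeny is not modelled
  (top-/poly-cross pollination details are unknowable from data of this
  kind); progeny per mother and records per progeny are free parameters,
  with records per progeny $\ge 2$ required for the permanent-environment
  variance to separate from the residual.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data — includes linkage disequilibrium and
marker correlation, allelic bias and sequencing error (systematic, not
just overdispersed, deviations of read ratios), selection and drift over
generations, and genotype-by-environment interaction. Every stage is
bit-reproducible given the configuration seed (the three stages derive
their streams from `seed`, `seed + 1`, `seed + 2`).

## Problem sizes and runtimes

The package targets desk-scale evaluations: hundreds of mothers, a few
thousand records, $10^2$–$10^5$ markers. The test suite simulates at
40–500 mothers; parameter-recovery checks use 300 mothers with two
progeny each and three records per progeny (1800 records), 20 replicates,
which completes in minutes on one core. Dense trace computations in
EM-REML scale as the cube of the number of equations, so national-scale
data would require the Monte-Carlo machinery this package intentionally
omits.

## Known limitations

* Genotype-likelihood dosage calling, haplotype phasing, and
  relationship- or LD-based imputation are out of scope; imputation is
  marker-mean only.
* Sequencing error, allelic bias and outlier modelling are not part of
  the read model.
* Dominance and epistasis, spatial field-trend correction (assumed done
  upstream), reaction-norm GxE models, and broad-sense heritability are
  not provided.
* Every mother with records must be genotyped; ungenotyped parents are
  rejected rather than imputed through a pedigree.
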