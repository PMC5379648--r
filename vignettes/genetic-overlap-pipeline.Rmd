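---
title: "Modelling shared genetic influences between longitudinal behavioural traits"
author: "gcovpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling shared genetic influences between longitudinal behavioural traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Behavioural dimensions such as ADHD symptoms and social-communication
difficulties are measured repeatedly during childhood and adolescence with
short questionnaires (integer scores on 0–10 or 0–24 scales, strongly
right-skewed). Three questions recur in population genetics studies of such
traits:

1. How much of each measure's variance is tagged by common genotyped SNPs
   (SNP heritability), and how strongly do measures share genetic influences
   within and across traits over development (genetic correlation and
   covariance)?
2. Do specific biological gene sets account for part of that genetic
   variance, consistently across correlated, repeatedly measured traits?
3. Do polygenic scores built from clinical case/control discovery GWAS
   predict the population traits — and when they do not, was there power to
   detect a plausible trait–disorder genetic covariance in the first place?

gcovpipe implements this full pipeline — variance-component estimation,
gene-set partitioning with correlated-measure meta-analysis, and polygenic
scoring with a closed-form power/covariance model — together with synthetic
data generators that emulate the study design with known ground truth, so
every stage is testable without access to restricted cohort data.

## Phenotype transformations

Raw questionnaire scores are adjusted by OLS for sex, exact age and two
ancestry-informative principal components, and the residuals are mapped to
normality by the rank-based inverse-normal transform with Blom offsets,
`qnorm((rank - 3/8)/(n + 1/4))`, using average ranks for ties. Integer
scores guarantee heavy ties, so the average-rank convention is load-bearing:
tied raw scores receive identical transformed values. Blom offsets are a
declared default (any offset pair in (0, 1/2) would be defensible); they are
configurable only by editing the transform, because nothing downstream is
sensitive to the offset choice.

The multiple-testing budget uses the eigenvalue-spectrum estimate of the
effective number of independent measures, `Meff = 1 + (M-1)(1 - var(lambda)/M)`
rounded to the nearest integer, followed by the Šidák step
`alpha_e = 1 - (1 - alpha)^(1/Meff)`. With five effective measures and a
family alpha of 0.05 this yields 0.0102, the value the pipeline treats as its
experiment-wise error rate. Whether to exclude near-zero-heritability
measures from the budget is left to the caller (the `exclude` argument);
the package takes no position beyond exposing the choice.

## GRM and REML estimation

The genetic relationship matrix uses the standard standardised-dosage
cross-product with in-sample allele frequencies,
`A_jk = (1/M_jk) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`,
with missing dosages excluded pairwise (per-pair SNP counts are kept and
serialised in the GCTA binary dialect). Monomorphic SNPs are skipped with a
warning. Relatedness screening greedily removes the individual involved in
the most pairs above the cutoff, breaking ties by the lexicographically
smallest id — a declared convention; the 0.025 screening practice fixes
only the cutoff, not which member of a pair is dropped. Note that 0.025 is meaningful for chip-scale
GRMs (~500k SNPs, pairwise noise ~0.0014); synthetic panels with a few
thousand SNPs have pairwise noise of order `1/sqrt(m)` and need a cutoff
above that noise floor, which is why the bundled analyses screen at 0.1.

Variance components are estimated by average-information (AI) REML for
`y ~ N(X b, sum_k theta_k V_k)`, with step-halving, a per-coordinate Newton
fallback, and an EM-like scaled-gradient fallback when an AI step would
leave the feasible region; convergence is declared when the restricted
log-likelihood changes by less than 1e-8 (at most 100 iterations; a
non-converged fit is flagged, never silent). Three backends share this loop:

* univariate fits rotate into the GRM eigenbasis, making every iteration
  O(n);
* bivariate fits with complete sample overlap rotate both traits into the
  shared eigenbasis, where the covariance is block-diagonal with 2×2 blocks
  (six parameters, O(n) iterations);
* gene-set partitioned fits (set-GRM + noset-GRM + residual) and
  partial-overlap bivariate fits use a dense backend.

Variance components are constrained non-negative (floored at 1e-6 of the
phenotypic variance); covariance parameters are clamped so the implied
correlations stay in `(-1, 1)` with margin 1e-4, which keeps the covariance
matrix positive definite even for degenerate inputs such as the same trait
entered twice (the fit then runs to the clamp and reports correlations of
~1). Standard errors come from the inverse AI matrix by the delta method.
Fixed effects inside REML are intercepts only, because covariates are
removed beforehand by the transform step.

Because transformed traits have unit variance, `Var_g = s2_g/(s2_g + s2_e)`
is the SNP heritability, and the reported standardised genetic covariance
satisfies `Cov_g = r_g * sqrt(h2_1 * h2_2)` exactly by construction.

Testing a single variance component on its boundary uses the 50:50
`chi2_0/chi2_1` mixture; the reported p-value follows the GCTA convention
`0.5 * P(chi2_1 > LRT)`, so a zero statistic yields p = 0.5. The bivariate
test of `r_g = 0` refits with the genetic covariance pinned to zero and uses
a plain `chi2_1`, since a covariance is unbounded in sign. The pipeline
tests `r_g = 0` (not `r_g = 1`); the constrained-refit hook makes other
nulls easy to add.

## Gene-set scans and correlated-measure meta-analysis

For each pathway, SNPs within member genes ±50 kb (1-based, inclusive
arithmetic; BED I/O converts at the boundary) form the set-GRM, the
remainder the noset-GRM, and the set component is tested by LRT against the
noset-only model, measure by measure.

Per-measure evidence is combined by a homogeneity statistic: one-sided
z-scores are combined as `Q = z' R^{-1} z` with `R` the phenotypic
correlation matrix among measures (eigenvalue-floored at 1e-6 before
inversion), referred to `chi2` with one degree of freedom per measure. `R`
is a working approximation to the correlation of the per-measure test
statistics — exact only to the extent that test-statistic dependence
tracks phenotypic dependence — chosen because it accounts for inter-measure
correlation and yields a chi-squared reference; the combination rule is a
single pluggable function. `R` is built from transformed scores (the same
scores the REML fits consume), which we consider the consistent choice
given that the raw-vs-transformed correlations differ only in the third
decimal.

Two conventions matter for calibration:

* the z recovered from a stored boundary-mixture p-value is
  `z = qnorm(1 - p)` — the exact inverse of the mixture survival function
  for p ≤ 1/2 — not `qnorm(1 - p/2)`, which would conflate the mixture
  with a two-sided p;
* scans run the set component unconstrained by default (the GCTA
  `--reml-no-constrain` idea), carrying the signed root
  `z = sign(s2_set) * sqrt(LRT)` into the combination. Constrained fits
  truncate negative evidence at zero, which makes the combined statistic
  conservative under the null; with signed roots, `Q` is exactly
  `chi2`-distributed when the working correlation is right, and the null
  calibration tests hold to Kolmogorov–Smirnov tolerance.

The Bonferroni adjustment defaults to 50 pathways (the hallmark-collection
size). Matched permutations draw random gene sets with the same gene count
per gene-length decile bin and a total length within ±10%, scan and combine
them identically, and report the add-one empirical p,
`(1 + #{Q_perm >= Q_obs})/(n_perm + 1)` — floored at 1/201 for the
conventional 200 permutations, never zero. "Similar size" is unspecified in
the source; count-per-decile-bin plus total-length tolerance is the declared
matching rule.

The age/trait meta-regression fits per-measure set variances with fixed
effects for age and trait (0/1 coding), a random intercept per measure
(`tau2` by REML via metafor), and known sampling covariance `V = D R D`
where `D = diag(SE)` — the same working approximation as above, in the
spirit of phylogenetically correlated meta-analyses. No attempt is made to
derive the exact sampling covariance of REML variance shares. The
trait×age interaction is tested by an ML likelihood-ratio test between
nested fixed-effect specifications. At `tau2 = 0` the fit reduces to
closed-form GLS, which the tests verify to 1e-8.

## Polygenic scoring

Discovery summary statistics are clumped greedily in p-value order (ties by
chromosome, then position): each index SNP claims all unclaimed SNPs within
±500 kb whose squared dosage correlation exceeds 0.25. Duplicate ids keep
the smaller p. Scores at each threshold `P_T` sum effect-allele-aligned
dosages weighted by log-odds; a flipped allele label complements the dosage
(`2 - x`), making scores exactly invariant to label flips, and missing
dosages contribute `2 * freq * effect`. Scores are Z-standardised per
threshold. The default grid {0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 1}
respects the open interval (0.001, 1]; the source never lists its grid.

Cross-sectional association is OLS of the transformed trait on the score
(adjusted R² reported). Longitudinal association uses lme4: a Gaussian
mixed model with fixed PGS, sex and age and random intercepts and age
slopes for the 0–10 trait, and a Poisson log-link model with random
intercepts only for the 0–24 trait (Laplace approximation; adaptive
quadrature is out of scope). Score×age interactions are tested by ML LRT.
Confidence intervals are individual-level bootstrap (resampling individuals
with all their occasions; default 500 replicates), reported as
estimate ± 1.96 × bootstrap SD — the "parametric bootstrap CI" reading —
with percentile intervals behind a flag. The marginal R² is the
fixed-effects share of total variance,
`var_fixed / (var_fixed + var_random + var_residual)`.

## The closed-form polygenic-score model

The power and covariance calculations implement the standard polygenic-score
model. Among `m` independent score SNPs, `m1 = n_causal` carry normal
effects with per-SNP variance `vg1/m1`; estimates add sampling noise with
variance `Var(y1)/n1`. A binary discovery trait is mapped from the
liability to the observed case/control scale by the threshold-model factor
`z P(1-P) / (K(1-K))` at prevalence `K` and case fraction `P` (applied
squared to `vg1`, linearly to the genetic covariance). Selecting SNPs with
`p <= P_T` truncates the estimate distribution at `u = qnorm(1 - P_T/2)`
z-units, and with `e(u) = E[Z^2; |Z| > u]` the expected target-sample R² is

```
R2 = (cov12 * e(u_eff))^2 / (m1 s2 e(u_eff) + m0 err e(u_thr))
```

with `s2` the marginal estimate variance at effect SNPs and `err` the null
sampling variance. Power follows from the non-centrality
`n_target R2 / (1 - R2)` of the 1-df association test; with zero covariance
the power equals alpha exactly. The inversion from an observed R² to the
implied genetic covariance is closed-form because the score variance does
not involve the covariance; its CI propagates the non-central-chi-squared
sampling variance of R² at the target n and becomes one-sided at the zero
floor.

Two modelling choices deserve comment.

* **Score-SNP count.** The reference scenarios fix 100,000 causal SNPs
  but not the number of independent SNPs entering the score. The package
  default is `n_snp = 150000` — a realistic post-clumping count for
  1000-Genomes-imputed chip data at r² > 0.25, ±500 kb — with all 100,000
  causal SNPs among them. The covariance inversion moves by only ~±0.008
  across 125k–175k score SNPs, so conclusions are insensitive within the
  plausible range.
* **"Half the uni-dimensional covariance".** The cross-dimensional power
  scenarios set the covariance to half of a printed uni-dimensional value;
  two candidates exist (0.10 for the ADHD dimension, 0.072 for the ASD
  dimension). Under the model, 0.10/2 reproduces both reference power
  values (0.237 vs 0.23 for the ASD-discovery scenario and 0.198 vs 0.21
  for the ADHD-discovery scenario) at the default score-SNP count, while
  0.072/2 cannot reproduce either for any score-SNP count at or above the
  causal count. The pipeline therefore adopts the 0.10/2 reading
  throughout.

## The synthetic cohort: what it does and does not emulate

The generators reproduce the design features the methods are sensitive to:
cohort-scale samples with two traits measured at ages 7/10/12/13/17 and
8/11/14/17; per-measure SNP heritabilities spanning 0.05–0.45; genetic and
residual correlation matrices that decay exponentially with age gap (valid
kernels, hence positive semi-definite by construction); right-skewed integer
scores via monotone binomial quantile maps (Binomial(10, 0.25) and
Binomial(24, 0.12)), which match the marginal shape without item-level
modelling; a gene-set-enriched genetic variance component; and case/control
discovery GWAS generated analytically under the liability-threshold model
(true effect plus Gaussian noise at the design-implied SE — discovery
genotypes are never simulated because scoring consumes only effects and
p-values). Residual correlation magnitudes are not pinned by the emulated
design; the defaults (0.5 scale, 10-year decay) are configurable and
deliberately uncalibrated.

Deliberately absent are linkage disequilibrium (SNPs are independent draws,
so clumping removes essentially nothing and set/noset partitions do not leak
through LD), population stratification and cryptic relatedness (individuals
are i.i.d.; the attached PCs are pure noise covariates), genotyping error,
X-chromosome SNPs, informative attrition, and item-level response behaviour.
Passing tests therefore demonstrate the estimators' correctness and
calibration under the intended sampling models — not robustness to LD
structure, stratification, or missingness mechanisms found in real cohorts.

Two scale effects of the small synthetic panels are worth remembering when
reading test output: GRM off-diagonals have noise ~`1/sqrt(m_SNPs)`, so
heritability SEs are much smaller than chip-scale equivalents at the same n;
and relatedness cutoffs must sit above that noise (see above).

## Problem sizes and numerical choices in the test-suite

The suite exercises the study-like conditions at sizes chosen to keep a full
run comfortably inside a few minutes of CPU: parameter recovery runs at
n = 2000 individuals × 5000 SNPs (univariate h² = 0.4; bivariate
r_g ∈ {0, 0.5, 1} with h² = 0.4/0.4), the partitioned recovery at
n = 1200 × 2500 with a 30% set share of h² = 0.4 and a gene set spanning
enough SNPs (~200) that the intended 150 causal set SNPs fit inside it,
boundary-LRT calibration on 200 replicates of n = 120 × 160, permutation
calibration with the full 200 matched sets at n = 220 × 400, and the
end-to-end score pipeline on 20 replicates of n = 2000 × 2000. Oracles are
independent implementations: a double-loop GRM, a dense restricted-likelihood
grid search, a re-scanning clumping reference, and closed-form GLS.

Other conventions: REML convergence 1e-8 in log-likelihood, 100-iteration
cap; variance floors at 1e-6 of phenotypic variance; correlation clamps at
1 − 1e-4; eigenvalue floors of 1e-6 when inverting working correlation
matrices; clumping ties broken by (chromosome, position); permutation
matching retried up to 200 times before reporting the unmatched bins.

## Known limitations

* More than one homogeneity statistic could meet this setting's needs; the
  quadratic-form combination here is a declared implementation with the two
  properties required (correlation-adjusted, chi-squared reference) and is
  pluggable.
* The working covariance `V = D R D` understates dependence when genetic
  (not phenotypic) overlap drives the correlation of estimates, and the
  meta-regression inherits that approximation.
* The polygenic model assumes independent score SNPs; applying it with a
  post-clumping count treats residual LD as negligible.
* Bivariate fits with partial overlap use the dense backend, which scales as
  O((n1+n2)³) per iteration and is intended for moderate samples.
* Sex-stratified bivariate GREML and its power analysis, LD-aware scoring
  against external reference panels, and multivariate (joint) decomposition
  of genetic covariance are out of scope.
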