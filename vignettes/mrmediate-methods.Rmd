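---
title: "Methods: two-sample MR estimation and two-step mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR estimation and two-step mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The model

Two-sample Mendelian randomization works entirely on GWAS summary
statistics. For each instrument $j$ we observe an estimated per-allele
effect on the exposure, $\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$,
and on the outcome, $\hat\beta_{Yj} \sim N(\Gamma_j, \sigma_{Yj}^2)$, from
non-overlapping samples. Under the instrumental-variable assumptions
(relevance, independence from confounders, and effect on the outcome only
through the exposure), $\Gamma_j = \theta\,\gamma_j$ and every Wald ratio
$\hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the causal effect $\theta$.
For binary outcomes the effects are log odds ratios and $\theta$ is a
log-OR per unit of exposure.

The estimators differ in how they pool the ratios and which violations
they tolerate:

* **IVW** regresses $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ through the
  origin with weights $1/\sigma_{Yj}^2$. The random-effects variant (the
  primary model here, as in most applied two-sample MR work) inflates the
  fixed-effect standard error by $\sqrt{\max(1, Q/(J-1))}$, the
  multiplicative residual model with the inflation floored at one.
* **MR-Egger** adds an intercept, which estimates the average directional
  pleiotropy; the slope stays consistent under the InSIDE assumption
  (instrument strength independent of direct effects). Instruments are
  first oriented so $\hat\beta_{Xj} \ge 0$, since the intercept is not
  invariant to allele orientation. Slope and intercept are referred to a
  $t_{J-2}$ distribution.
* **Weighted median** takes the 0.5 point of the cumulative IVW-weight
  distribution of sorted ratios (midpoint convention, linear
  interpolation); it is consistent while instruments carrying at least
  half the weight are valid. Its standard error comes from a seeded
  parametric bootstrap (default 1000 draws).
* **Profile maximum likelihood** treats each $\gamma_j$ as a nuisance
  parameter in the bivariate normal likelihood, profiles it analytically,
  and optimizes $\theta$ numerically from the IVW start; the standard
  error is the curvature of the profile likelihood at the optimum.

Heterogeneity is quantified by Cochran's
$Q=\sum_j w_j(\hat\theta_j-\hat\theta_{IVW})^2$ on $\chi^2_{J-1}$.
**MR-PRESSO** turns the leave-one-out weighted residual sum of squares
into a global pleiotropy test by parametric bootstrap, flags per-variant
outliers (Bonferroni across instruments), and reports a distortion
p-value for the change between raw and outlier-corrected IVW estimates.
**Radial MR** refits the model in radial coordinates with modified
second-order weights
$w_j = (\sigma_{Yj}^2/\hat\beta_{Xj}^2 +
\hat\beta_{Yj}^2\sigma_{Xj}^2/\hat\beta_{Xj}^4)^{-1}$; each variant's
contribution $Q_j$ is $\chi^2_1$ under homogeneity, and variants with
upper-tail $p < \alpha$ are removed before a single re-estimation (an
iterated mode exists but is off by default, matching the
detect-once-then-reanalyse convention).

The **Steiger test** guards against reverse causation: instruments should
explain more variance in the exposure than in the outcome. Per-variant
$R^2 = \beta^2\,2f(1-f)\,/\,(\beta^2\,2f(1-f)+se^2 n\,2f(1-f))$, which
reduces algebraically to $z^2/(z^2+n)$ — the allele-frequency terms
cancel, so the estimator is computable even when EAF is missing. The
directional p-value compares Fisher-transformed correlation magnitudes
with variance $1/(n_X-3)+1/(n_Y-3)$.

**Multivariable MR** replaces the single exposure column by a matrix,
estimating each exposure's direct effect conditional on the others:
MV-IVW (weighted multivariable regression through the origin, the primary
model), MVMR-Egger (adds an intercept after orienting rows on the first
exposure), MVMR-median (weighted least absolute deviations, bootstrap
SEs), and MVMR-Lasso (per-variant indicator intercepts under an L1
penalty; variants whose indicator is shrunk to zero are "valid", and the
final estimate is MV-IVW on the valid set). The Lasso penalty is tuned by
a heterogeneity criterion: among penalties whose valid-set Q stays below
the $\chi^2$ 95th percentile of its degrees of freedom, the one retaining
the most instruments is used. The instrument set for multivariable fits is
the union of each exposure's independent genome-wide-significant variants,
re-clumped jointly (a `first_exposure` policy is available to keep an
adjusted effect on the same instrument frame as its univariable
counterpart).

## Two-step mediation

For a candidate mediator $M$ on the path $X \to M \to Y$:
$\beta_1$ is the univariable IVW effect of $X$ on $M$ (exposure
instruments), $\beta_2$ the MV-IVW effect of $M$ on $Y$ adjusted for $X$,
and $\beta_0$ the univariable total effect of $X$ on $Y$. The mediating
effect is the product $\beta_1\beta_2$ with first-order delta standard
error $\sqrt{\beta_1^2 se_2^2+\beta_2^2 se_1^2}$ (the two steps use
disjoint outcome datasets and are treated as independent); the mediated
proportion is $\beta_1\beta_2/\beta_0$, with the components again treated
as independent. A Monte-Carlo percentile interval
(`mediated_proportion_mc()`) is provided as a sensitivity alternative,
since $\beta_0$ shares instruments with $\beta_1$ and the independence
approximation is not exact. Proportion intervals are additionally
truncated to $[0,1]$ for reporting; raw values are always retained.

Candidates pass a five-criterion screen before quantification: (1) a
causal $X \to M$ effect; (2) an $M \to Y$ effect without adjustment;
(3) an $M \to Y$ effect with adjustment for $X$; (4) no reverse $M \to X$
effect; (5) the sign of $\beta_1\beta_2$ agrees with $\beta_0$. A
directional-pleiotropy flag (Egger intercept of the $X \to M$ fit at
$\alpha$) excludes candidates regardless of the five criteria. The screen
level `alpha_screen` defaults to 0.05 — looser than the Bonferroni gate
used for the primary exposures, which published screens apply only to the
exposure family, not to each mediator test. When multiple criteria fail,
the recorded exclusion reason is the first in the order pleiotropy,
(1)–(5); the full logical vector is always returned, so no information is
lost to the ordering.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `p_instrument` | 5e-8 | genome-wide instrument threshold |
| `p_reverse` | 5e-7 | lenient threshold for reverse-direction instruments |
| `clump_r2`, `window_kb` | 0.001, 10000 | LD clumping cutoff and window |
| `f_min` | 10 | weak instruments (F strictly below) dismissed |
| `outcome_p` | 5e-8 | outcome-association exclusion threshold |
| `proxy_r2` | 0.8 | minimum LD for a proxy variant |
| `palindrome_eaf_window` | [0.42, 0.58] | "intermediate" EAF band for dropping palindromic variants |
| `alpha`, `family_size` | 0.05, 4 | diagnostic level and Bonferroni family (gate 0.0125) |
| `alpha_screen` | 0.05 | mediator-screen level |
| `n_boot`, `presso_n_sim` | 1000, 1000 | bootstrap sizes (seeded) |

The palindrome window and the drop-on-missing-EAF policy are conventions,
not published constants; both are configurable
(`action_on_missing_eaf = "keep"` assumes both GWAS report the forward
strand). The proxy threshold of 0.8 is likewise the common convention.
The weak-instrument boundary is strict: F = 10 exactly is retained.

## The synthetic generator

`simulate_triplet()` draws minor-allele frequencies uniformly (default
0.05–0.5), true instrument effects $\gamma_j \sim N(0, \texttt{gamma\_sd}^2)$
for the exposure, mediator effects $\beta_1\gamma_j$ plus an independent
set of mediator-specific instruments $\delta_j$, and outcome effects
$(\theta_{direct}+\beta_1\beta_2)\gamma_j+\beta_2\delta_j$ with optional
balanced or directional pleiotropy and planted outliers. Observed effects
add independent noise with $se = 1/\sqrt{2f(1-f)\,n}$ per trait — the
standard error of a per-allele regression coefficient for a unit-variance
trait — so z-scores, p-values, $R^2$ and F statistics are mutually
consistent. The three noise draws are independent, matching the
two-sample, no-overlap design. Defaults mirror the motivating study
conditions: a UK-Biobank-scale continuous exposure (n = 450,243), a large
binary mediator GWAS (n = 184,305), a MEGASTROKE-scale outcome
(n = 440,328), and path coefficients $\beta_1=-0.176$, $\beta_2=0.177$,
$\theta_{direct}=-0.047$, giving a total log-OR of about $-0.078$
(OR ≈ 0.925) with ~40 % mediated — magnitudes typical of the lean-mass /
coronary-heart-disease / ischemic-stroke pathway.

What the generator does *not* emulate: realistic LD (blocks are
constant-r² tiles, equilibrium by default), MAF–effect-size coupling,
case-control ascertainment, winner's curse beyond what thresholding
induces, or sample overlap. Passing tests therefore demonstrate
correctness of the estimators under the linear structural model they
assume, not robustness to every artefact of real consortium data.
Simulated variants use non-palindromic allele pairs so that harmonization
is information-preserving; palindromic handling is exercised by dedicated
constructed fixtures instead.

## Numerical choices

* Weighted least squares is solved via the analytic normal equations with
  the fixed-effect covariance computed directly, so exact-fit data (zero
  residual variance) keep finite standard errors; the multiplicative
  inflation multiplies by $\max(1,\hat\sigma)$.
* IVW and Wald p-values use the normal reference; Egger slope and
  intercept use $t$ with $J-2$ (univariable) or $J-k-1$ (multivariable)
  degrees of freedom.
* Wald-ratio standard errors are first-order ($|\sigma_Y/\beta_X|$) so the
  IVW identities hold exactly; a second-order option propagates the
  exposure-side error.
* Bootstrap and simulation-based methods take a mandatory seed and restore
  the caller's RNG state, so pipeline runs are bit-reproducible and
  reordering analyses cannot change results.
* Clumping and proxy selection break p-value and r² ties by lexicographic
  variant id, making instrument selection order-independent.
* Zero p-values on input are clamped to the smallest positive double;
  computed p-values are floored the same way.
* Degenerate inputs error early with the offending quantity named:
  single-instrument random-effects IVW, fewer than three instruments for
  Egger/median, fewer than four for MR-PRESSO, rank-deficient
  multivariable designs (collinear columns are listed), zero usable
  instruments after harmonization.

## Validation problem sizes

The test suite and `scripts/acceptance.R` validate calibration at sizes
chosen to keep Monte-Carlo noise well below the tolerances being checked:
1000 null replicates for IVW type-I error; 200 replicates for bias and
coverage at $\theta=0.1$ ($J=50$, $n=5\times10^4$); 100 seeded replicates
for planted-outlier detection ($J=30$, displacement 10 standard errors,
after instrument selection); 500 replicates for the weighted-median
breakdown design (100 equal-strength instruments, 49 invalid); and
200 replicates per cell for mediated-proportion recovery at true
proportions 10/25/50 % ($J=50$ instruments per trait, $n=10^5$,
`gamma_sd = 0.1` so instruments are strong, F ≈ 300). In that last grid
the total effect at the 50 % cell is small ($|\beta_0| \approx 0.062$);
with weak instruments the ratio estimator's Jensen bias alone would
exceed the recovery tolerance, which is why the strong-instrument regime
is the meaningful one for checking the mediation algebra. Delta-method
proportion standard errors are compared to the Monte-Carlo spread through
pooled standardized errors across the grid, restricted to replicates with
$|\beta_0|/se_0 > 5$ where the first-order expansion is trusted.

## Known limitations

* Only one mediator is quantified at a time (product-of-coefficients per
  mediator); joint multi-mediator decomposition is out of scope.
* The proportion's delta-method SE ignores the correlation between
  $\beta_0$ and $\beta_1$ induced by shared instruments; the Monte-Carlo
  interval is the recommended sensitivity check when $|\beta_0|/se_0$ is
  small.
* No winner's-curse correction: instrument selection and effect estimation
  use the same exposure GWAS, as in the workflow this package mirrors.
* LD handling is table-driven; the package does not compute LD from
  reference genotypes, and clumping without positional data treats all
  pairs as in-window.
* Binary traits are handled on the log-odds scale throughout; no
  liability-scale conversion is attempted.
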