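---
title: "Models and methods behind itqnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind itqnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itqnet)
```

itqnet implements the full analysis workflow used to validate the
International Trauma Questionnaire (ITQ) in community samples: the ICD-11
PTSD/complex-PTSD screening algorithm, ordinal confirmatory factor analysis
of the competing ITQ factor structures, regularized partial-correlation
networks over the twelve symptom items, and the trauma-exposure
epidemiology built on the 21-item International Trauma Exposure Measure
(ITEM) checklist. Because item-level data from validation cohorts are
rarely deposited, the package pairs every stage with a calibrated synthetic
cohort generator, so each method can be exercised and checked end to end.
This vignette records the models, the tunable parameters, and the design
decisions that were genuinely open.

## The diagnostic algorithm

The ITQ scores six symptom items (two per cluster: re-experiencing,
avoidance, sense of current threat; affective dysregulation, negative
self-concept, relational disturbance) and six functional-impairment items
on a 0--4 Likert scale. An item is *endorsed* at a score of 2 or more.
PTSD requires trauma exposure, one endorsed item in each of the three core
clusters, and one endorsed PTSD-impairment item; cPTSD additionally
requires one endorsed item in each DSO cluster and one endorsed
DSO-impairment item. The diagnoses are mutually exclusive: meeting the
full cPTSD criteria yields cPTSD only.

Two decisions were open here. First, the exposure gate: the checklist
records event endorsements but no index event, so `itq_diagnose()` gates
on a `trauma_exposed` flag that defaults to *any* checklist endorsement,
with `require_exposure = FALSE` available for sensitivity analyses.
Second, missingness: a record missing any diagnostic item receives a
missing diagnosis and leaves the prevalence denominator, even when the
observed items already fail a criterion — the conservative reading of
"complete cases analyzed".

## The synthetic cohort generator

The generator is a graded-response (cumulative-probit) measurement model:
subject latent scores for the six symptom factors and two impairment
composites are multivariate normal; item $j$'s latent response is
$\lambda_j Z_{f(j)} + \sqrt{1-\lambda_j^2}\,\varepsilon$, discretized at
four thresholds. This matches the assumptions under which polychoric
correlations and WLS factor analysis are consistent, which is exactly what
the downstream stages assume.

Exposure is drawn first: independent Bernoulli flags per checklist item
and developmental period, with gender-specific probabilities. Per-item
lifetime rates are anchored to a published Italian late-adolescent cohort
(`item_exposure_reference()`); because real exposures co-occur while the
generator draws independently, the per-class rates are rescaled by a
root-solved multiplier so the *aggregate* lifetime any-intentional and
any-unintentional rates match the reference values by gender (67.5%/53.7%
intentional for females/males; 84.5%/80.6% unintentional). Exposure then
shifts the latent means: by default +0.30 SD per intentional-exposure
period on the core factors and +0.35 SD on the DSO factors, +0.08 SD for
unintentional exposure — intentional trauma is the exposure class
associated with complex presentations, and the asymmetry gives the
multinomial regression a realistic signal to recover.

The default configuration was calibrated once, and the values are frozen:

* symptom-item thresholds come from the reference cohort's printed
  category counts (normal quantiles of the cumulative proportions);
* impairment items share a moderate marginal (45/25/15/10/5%);
* two block offsets added to the thresholds (+0.48 on the core-PTSD items
  and PTSD impairment, +0.30 on the DSO side) were grid-searched at
  n = 30,000--40,000 so that generated cohorts screen at roughly 9% PTSD
  and 4% cPTSD under the default exposure process, the rates reported for
  late-adolescent community samples;
* loadings of 0.87 put the PTSD-subscale Cronbach's alpha near 0.88, the
  reference reliability;
* factor correlations are deliberately *heterogeneous* (0.70--0.84 within
  the PTSD and DSO blocks, 0.42--0.60 across). With block-exchangeable
  correlations the two-factor second-order model is the true structure and
  correctly wins the BIC comparison; the heterogeneous default reproduces
  the situation community samples keep reporting, where the six
  correlated-factor model is decisively preferred.

What the generator does **not** emulate: school/geographic clustering,
item-level missingness patterns (a configurable MCAR rate stands in),
event co-occurrence beyond the aggregate calibration, and any
earthquake-specific exposure structure. Tests passing on synthetic cohorts
therefore certify the *methods* — estimator consistency, selection
behaviour, interval coverage — not distributional fidelity to any real
cohort.

## Polychoric correlations and the WLS weight matrix

Polychoric estimation is two-step: thresholds from the marginal cumulative
proportions (boundary proportions clamped to a finite sentinel of 8.2 on
the latent scale, which is exact to double precision), then the latent
correlation maximizing the bivariate-normal rectangle likelihood,
optimized on (-0.999, 0.999). The bivariate normal CDF uses 48-node
Gauss--Legendre quadrature of the classical single-integral identity and is
accurate to ~1e-13; it is vectorized over the threshold grid, which makes
the 66-pair matrix for 12 items cost well under a second at any n.
Pairwise matrices that come out indefinite are repaired by eigenvalue
clipping (flagged in the result).

The weight matrix for weighted least squares is the bootstrap covariance
of the correlation vector over subjects (B = 200 by default, seeded),
rescaled by n so that `chi2 = (n-1) * F_min` follows the usual convention;
a ridge of 1e-6 times the mean diagonal is recorded. Full 66x66 weights
are near-singular below n of about 500, so a diagonal-weights option
exists, and `fit_wls()` also accepts identity weights (unweighted least
squares). The recovery simulations use identity weights: BIC-based model
selection does not involve W, and ULS keeps 100-replicate studies cheap.
Absolute chi-square values under identity weights are not interpretable as
test statistics and are not treated as such anywhere.

## Factor models, fit indices, and comparison

Four standard structures for the 12 symptom items: one factor (df 54), six
correlated factors (df 39), six factors with one second-order factor
(df 48), and six factors with correlated second-order PTSD and DSO factors
(df 47). Identification fixes all factor variances at 1, so second-order
loadings are correlations between first-order factors and their
second-order factor. The implied matrix is $\Lambda\Phi\Lambda^\top$ with
the diagonal fixed at 1 by unique variances. During optimization the
six-factor $\Phi$ is kept positive semidefinite by eigenvalue bending plus
a penalty; the optimizer is bounded L-BFGS-B with one deterministic start
and seeded random restarts (five starts by default), tie-broken by lowest
discrepancy.

Fit indices follow the standard normal-theory formulas (RMSEA, CFI, TLI
against the zero-correlation independence baseline under the same weights,
SRMR over the 66 unique residuals). CD is the determinant ratio
$1-\det\hat\Theta/\det\hat\Sigma$ — the source reports give no formula, so
this convention is adopted and stated. BIC is
$-2\ell_G+q\ln n$ with $\ell_G$ the Gaussian pseudo-log-likelihood of the
sample correlation matrix under the implied one; only BIC *differences*
are meaningful (additive constants cancel; asserted in the tests), and a
gap above 10 is flagged decisive. The published RMSEA values for the
better-fitting models reproduce from their (chi-square, df, n) triples to
three decimals; the poorer models' printed values sit 0.002--0.004 above
the formula reconstruction (source-software conventions unknown), which is
the tolerance the checks use.

## The symptom network

The EBIC graphical lasso: correlations (polychoric by default — the items
are five-category ordinal — with a Pearson option) enter a graphical lasso
solved by block coordinate descent with the diagonal unpenalized, along a
grid of 100 penalties log-spaced from $\lambda_{max}$ (the largest
absolute correlation; empty network) down to $0.01\lambda_{max}$, with
warm starts along the path. Each solution is scored by
$\mathrm{EBIC} = -2\ell + E\ln n + 4\gamma E\ln p$ with $E$ the edge
count and $\gamma = 0.5$, and the minimizer is reported as a
partial-correlation network ($\rho_{ij} = -K_{ij}/\sqrt{K_{ii}K_{jj}}$).
Solutions satisfy the stationarity conditions to ~1e-8 and match a direct
numerical optimizer of the penalized objective at small p.

Centrality follows the symptom-network conventions: distances are
reciprocal absolute weights; betweenness uses Brandes counting with
fractional credit for tied shortest paths; closeness is the reciprocal of
summed distances, restricted to reachable nodes with a disconnection flag
(the verbal definition does not cover disconnected graphs); strength and
expected influence are the absolute and signed weight sums. Indices are
reported raw and z-standardized across the twelve nodes, the scale on
which such values are conventionally printed.

A note on the recovery study shipped with the package: with very strong
true partial correlations (~0.27) the EBIC criterion keeps trading
spurious edges for shrinkage-bias reduction and over-selects; at the
moderate magnitudes typical of symptom networks (~0.12, used in the
study) it recovers essentially all true edges with a false-edge rate well
under 10%. This is a property of EBIC-glasso worth knowing, not an
implementation artifact.

## Epidemiology

Gender contrasts use the uncorrected Pearson chi-square: rebuilding the
reference cohort's 2x2 tables from printed counts and percentages
reproduces its published statistics to ~0.001 *only* without continuity
correction, which settles that convention empirically. Denominators are
reconstructed as `round(100*count/percent)`; rows sharing a denominator
(the two prevalence rows per gender) are reconstructed jointly by
minimizing the summed squared percent mismatch, which resolves
rounding-boundary cases. Prevalence intervals are 95% Wilson score
intervals; the reference report's printed intervals match no standard
binomial method, so they are documented as non-reproducible and never used
as checks.

The diagnosis regression is a baseline-category multinomial logit
("none" as reference) fitted by full Newton--Raphson with step-halving, so
the log-likelihood is non-decreasing across iterations; the Wald
covariance is the inverse observed information, and quasi-separation
(diverging coefficients) is flagged rather than hidden. The design matrix
carries the six exposure-class indicators (intentional/unintentional x
childhood/adolescence/last 6 months) jointly, optionally adjusted for
gender, non-Italian nationality, and parental education coded as a single
ordinal covariate (its original coding is not documented; stated choice).

## Problem sizes and numerical conventions

The packaged simulation studies use: 100 replicates at n = 2,000 for CFA
model recovery (two optimizer starts per fit); 20 seeds at n = 5,000 for
network edge recovery; 100 replicates at n = 3,000 for multinomial
interval coverage — large enough that Wald intervals operate in their
asymptotic regime; n = 20,000 for consistency checks of the polychoric
estimators (sampling error ~0.01); n = 2,000 for the reliability
calibration check. Degenerate inputs (single-category items, zero
margins, zero total-score variance, non-positive-definite inputs) raise
typed errors naming the offending object rather than propagating NaNs.

## Known limitations

Polyserial/mixed correlations, robust (mean- and variance-adjusted)
chi-square variants, modification indices, measurement invariance,
bootstrapped edge- or centrality-stability intervals, and survey-design
corrections are out of scope. Absolute BIC values are software-specific
and only comparisons are reported. The synthetic generator's independence
assumptions are listed above; conclusions about real cohorts should rest
on the method guarantees, not on the generator's resemblance to any
particular sample.
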