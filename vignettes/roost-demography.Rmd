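---
title: "Seasonal decomposition and demographic estimation from stratified roost counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal decomposition and demographic estimation from stratified roost counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roostdemog)
```

## The data model

The atomic observation is one dusk count at one roost in one month,
stratified by the size of the arriving flocks: singletons, pairs (dyads
of paired birds), family flocks of three to six birds, and large flocks
of more than six. Two columns describe the family-flock stratum:
`family_flock_birds`, all individuals arriving in such flocks, and
`fledglings`, the same birds after discounting the two parental birds of
each flock. The number of family flocks is therefore derived, never
stored:

$$n_{\mathrm{flocks}} = \frac{\text{family flock birds} - \text{fledglings}}{2},$$

which must be a non-negative integer for a record to be consistent. When
every stratum is recorded the strata tile the total,

$$\text{all parrots} = \text{singles} + 2\,\text{pairs} +
  \text{family flock birds} + \text{large flock birds}.$$

`validate_counts()` reports violations of these identities per record.
The three-to-six-birds and one-to-four-young bounds per flock are checked
only under `strict = TRUE`: field protocols can legitimately produce
records with, say, fewer than one fledgling per implied flock when young
have joined other flocks between counts, so the bounds are a data-quality
screen rather than a hard invariant.

Missing strata are `NA` and never contribute zero to a sum: pooling over
roosts (`pool_roosts()`) sums whatever roosts report in a month, and a
pooled stratum is missing only when no roost reports it. This mirrors how
multi-roost monitoring data behave when monitoring windows differ — and
it also means a pooled series steps down when a roost's window ends,
which is a property of the data, not an artifact to correct.

Because counts and percentages of counts are rarely normal, all
descriptive summaries are median/IQR (`median_iqr()`), with quartiles
from linear-interpolation sample quantiles at plotting position
$h = (n-1)p$. That convention is not arbitrary: it is the one under which
the published five-roost annual summary tables (shipped as
`published_annual_summaries()`) are reproduced digit-for-digit from their
yearly values, which the acceptance tests verify.

## Seasonal–trend decomposition

`stl_decompose()` splits a monthly series into additive seasonal, trend
and remainder components by alternating two steps:

1. **Seasonal:** the sub-series mean of each calendar month of the
   detrended series (mean of all Januaries, …), centred to sum to zero
   over the twelve months. Without centring, part of the series level
   would leak into the seasonal and confound the trend, so the zero-sum
   constraint is imposed by construction.
2. **Trend:** a loess smooth (`loess_smooth()`, tricube weights over the
   $q = \lceil \text{span} \cdot n\rceil$ nearest neighbours, local
   degree 1) of the deseasonalized series.

Defaults: the trend window targets 19 neighbours — the conventional
trend window for period-12 series with a periodic seasonal — and the
iteration runs twice starting from a flat trend at the series mean. Two
passes remove the bulk of the trend leakage into the sub-series means at
the series lengths this package targets (28–61 months); the loop
converges geometrically (error roughly × 0.2 per pass), so the noiseless
sanity checks in the test suite iterate to convergence (`n_iter = 15`)
when they assert recovery to $10^{-6}$, while the default remains cheap.
No robustness (outlier down-weighting) pass is applied, and the
decomposition is strictly additive — count series with strong
mean–variance coupling could argue for a multiplicative variant, which
is out of scope.

Missing months interior to a series are linearly interpolated before
decomposition and flagged; the remainder is reported missing there, so
interpolated points never masquerade as observed residuals. Leading and
trailing gaps are dropped, never extrapolated. A series must have at
least 24 observations and at least one observation in every calendar
month; otherwise the decomposition refuses rather than degrade silently.

For cross-roost comparison the twelve seasonal effects are
range-standardized to $[0,1]$ (`range_standardize()`): the quietest month
maps to 0, the busiest to 1. A constant seasonal has no shape to show and
raises a degenerate-profile error rather than returning 0/0.

## Permutation inference

`fit_linear_model()` is ordinary least squares with treatment-coded
factors and *sequential* (type-I) sums of squares in the declared term
order, matching the decomposition conventional in permutation-ANOVA
software; the seasonal models are declared as roost, then month, then
their interaction. `permutation_test()` attaches resampling p-values:

* single-term models permute the raw response;
* multi-term models use Freedman–Lane permutation — each term's null is
  built by permuting the residuals of the model containing all *other*
  terms and re-fitting the full model — the standard
  exchangeability-preserving choice when nuisance terms are present.

p-values are $(1 + \#\{F^* \ge F_{\mathrm{obs}}\})/(n_{\mathrm{perm}}+1)$,
so they floor at $1/(n_{\mathrm{perm}}+1)$ and ties count against the
hypothesis (conservative). The default is 4999 permutations; a fixed
permutation count with a seed was chosen over sequential stopping rules
because bit-reproducibility of every p-value under a recorded seed is
worth more in a monitoring pipeline than adaptive efficiency.
Consequently, permuted p-values from other implementations are expected
to agree only in category (significant at $\alpha$ or not), not
digit-for-digit.

`ancova_with_parallelism()` operationalizes the usual ANCOVA discipline:
fit the covariate-by-factor interaction first; only if it is
non-significant at $\alpha$ (default 0.05) drop it and interpret the
common slope, flagged `"parallel-slopes"`; otherwise return the
interaction model flagged `"non-parallel"`, in which a single slope is
not meaningful. `grouped_trend()` applies this to the two family-flock
responses (flock counts and mean fledglings per flock), with time as
months elapsed since the first included record, shared across roosts so
that per-year slopes are exactly twelve times per-month slopes. Records
with no family flocks have an undefined mean brood size and are dropped
from that response, shrinking the residual degrees of freedom — the
honest treatment, not zero-imputation.

No autocorrelation correction or mixed-effects structure is applied:
month-to-month roost counts are treated as exchangeable under the null.
This matches standard practice for these designs but will anti-conserve
p-values if strong serial correlation remains in the remainder.

## Demographic estimators

The annual summaries fix two windows from the breeding cycle: June–July
(pre-reproductive attendance maximum, the denominator `all_parrots`) and
August–September (incubation; singletons). For a roost-year,
percentages are window means of the stratum divided by the window mean
total. With two-month windows the mean and the median of the window
coincide, which resolves the wording ambiguity between "average" and
"median" descriptions of these summaries. Years with no June–July
observation have no denominator and are excluded from medians, not
zero-filled.

* `breeding_attempt_proportion()`: the August–September singleton share
  of the June–July maximum is a *minimum* estimate of the proportion of
  the roosting population attempting to breed, valid when one member of
  each incubating pair returns nightly to the roost. It is a minimum
  because failed early breeders and non-detected singletons both bias it
  down.
* `expected_recruits(pct, N, r)`: `round(pct/100 * N * r)` in whole birds
  (half-up — 164.57 young is 165 birds, and commercial rounding keeps
  0.5 from rounding down). The fledging rate `r` defaults to 1.0 because
  the available field estimates (0.9–0.95 young per laying female per
  year) are treated as approximately one when converting breeding
  attempts to fledged young; it is configurable precisely because that
  approximation is the estimator's weakest link.
* `post_fledging_loss()`: the proportional shortfall of fledgling-based
  recruitment relative to singleton-based recruitment, attributed to
  mortality (or dispersal out of the monitored roosts) between fledging
  and the mid-year counts. It is clamped to $[0,1]$ with a warning when
  the fledgling-based estimate is larger, which can happen by sampling
  noise in small systems.

## The synthetic generator

`synthetic_config()` / `generate_roost_counts()` emulate the structure
the estimators assume, so the whole pipeline can be validated by
parameter recovery without any external data:

* five roosts with windows of 61, 61, 61, 38 and 28 months starting
  July/September 2004 — 249 scheduled counts with no missing months by
  default, matching a programme in which every scheduled count was
  completed (missingness is configurable per roost);
* per roost × stratum, counts are negative binomial with mean
  $\exp(a + b\,t + s_{m})$: log-level $a$, log-linear trend $b$ per
  month, and a zero-sum 12-month template $s$. Defaults: June–July peaks
  for pairs and large flocks, a post-fledging (Nov–Feb) peak for family
  flocks, a flat singleton baseline, a declining family-flock stratum
  ($b = -0.02$ per month on the log scale), and a collapsing fifth roost
  ($b = -0.08$ for every stratum). Template values are pairwise distinct
  so the template's month rank order is well defined for recovery
  checks;
* dispersion $\theta = 8$ by default — roost counts are aggregates of
  social groups and are strongly overdispersed; $\theta = \infty$ gives
  Poisson, and `noise = "none"` gives deterministic expected values for
  noise-free recovery checks. The NB choice is a modelling decision of
  this package, not a property inherited from any field protocol;
* the breeding signal: in August and September the singleton count gains
  a binomial draw with success $\varphi$ (default 0.05) out of the
  roost's *expected* June–July total, so the singleton-based estimator
  targets $\varphi$ up to the small flat singleton baseline
  (≈ 0.3–0.7 % of totals at the default levels — the reason the
  noise-free recovery tolerance is ±0.01, not 0);
* family flocks: a flock count is drawn, then each flock's young are
  i.i.d. on $\{1,2,3,4\}$ with probabilities $(0.6, 0.3, 0.08, 0.02)$
  (mean 1.52 young per flock, matching the magnitude reported for wild
  broods); `family_flock_birds` is assembled as $2n + \text{young}$ and
  the total by the stratification identity, so every generated table
  passes validation by construction.

What the generator does **not** emulate: movement of birds between
roosts (inter-roost exchange appears only as independent level shifts),
observer error that breaks the stratification identity, serial
correlation beyond the seasonal and trend structure, and
year-to-year variation in breeding phenology. Passing recovery tests
therefore show the estimators work when their assumptions hold; they do
not certify robustness to misclassified flocks or double-counted birds.

`recovery_experiment()` runs the full pipeline over seeded replicates and
reports slope sign recovery, trend-test rejection rate, seasonal template
correlation, and bias/RMSE of the breeding-fraction estimate. Because
exact rank equality of all twelve months is brittle for near-flat months
under realistic dispersion, seasonal recovery is judged by months within
one rank position of the template plus Spearman correlation, which is
what "the profile has the right shape" means operationally.

## Numerical conventions and degenerate inputs

* Quantiles: type-7 (linear interpolation, $h=(n-1)p$) everywhere.
* Rounding to printed precision uses half-up (`round_half_up()`);
  comparisons against printed six-value total rows allow ±1 because
  those rows were evidently computed from unrounded monthly means.
* Loess: the farthest of the $q$ included neighbours has tricube weight
  exactly zero, so the effective window is $q - 1$ points; $q$ is
  clamped to at least degree + 2. Local fits are solved per point by
  weighted least squares; a degenerate all-ties window falls back to a
  weighted mean.
* Permutation ties: counted as exceedances (with a $10^{-8}$ relative
  tolerance against floating-point equality), never in the hypothesis's
  favour; saturated fits define $F = 0$ when a term has no sum of
  squares and $F = \infty$ otherwise.
* All stochastic entry points take explicit seeds, restore the caller's
  RNG state, and the pipeline derives per-module child seeds from one
  master seed, so partial reruns reproduce the full run's artifacts.

## Problem sizes

The validation suite works at the scale the package targets: series of
24–61 months, tables of ≈ 250 records, 99–9999 permutations per test,
20-replicate recovery experiments, and a 200-replicate type-I-error
calibration of the permutation trend test (nominal 0.05; accepted band
0.03–0.08). These sizes were chosen as the smallest at which the
monitored properties are statistically meaningful.

## Known limitations

* The breeding-attempt estimator is identified only where the
  one-singleton-per-incubating-pair behaviour holds; for species without
  it the singleton share measures something else.
* Percentages use the same year's June–July denominator; recruitment
  attributable to a cohort spans a year boundary, and no cohort
  bookkeeping is attempted.
* The ANCOVA's roost factor absorbs level differences only; if roosts
  differ in seasonal amplitude the common-slope summary can mislead even
  when the parallelism check passes, since the check concerns the time
  slope, not the seasonal shape.
* Counts are analysed on the raw scale for comparability with the
  published summaries; a log-scale analysis would be natural for the
  multiplicative generator and is left to the user.
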