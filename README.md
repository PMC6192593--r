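# roostdemog

Demographic analysis of flock-size-stratified counts at communal parrot
roosts.

Many parrots — including the heavily traded Blue-fronted Amazon
(*Amazona aestiva*) — spend the night in large communal roosts that are
spatially separate from their nesting cavities. Monthly dusk counts of the
flocks arriving at a roost, classified by flock size, are one of the
cheapest ways to monitor such populations, and the flock-size strata carry
demographic information:

* **singletons** peak during incubation (August–September in the southern
  Pantanal), because one member of each breeding pair overnights at the
  nest while the other returns to the roost alone;
* **pairs** (dyads of two paired birds) dominate roost structure
  year-round;
* **family flocks** of 3–6 birds are a parental pair plus its 1–4 fledged
  young, so discounting two parents per flock counts the **fledglings**;
* total attendance peaks in the pre-reproductive June–July window, which
  serves as the population denominator.

`roostdemog` is aimed at field ornithologists and population ecologists
who have such stratified count tables and want seasonal profiles,
long-term trends and recruitment estimates out of them, with resampling
inference that does not lean on normality.

## What it computes

For a monthly series \(y_t\) the package fits the additive decomposition

\(y_t = T_t + S_{m(t)} + R_t\),

where the seasonal component \(S_m\) is the centred sub-series mean of
month \(m\) (mean of all Januaries, all Februaries, …), the trend \(T_t\)
is a tricube-weighted local linear (loess) smooth of the deseasonalized
series, and the two steps are iterated; the seasonal is range-standardized
to \([0,1]\) for comparison across roosts. Hypotheses about seasonality
and roost differences are tested with permutation ANOVA/ANCOVA: sequential
(type-I) F statistics with p-values from raw-response permutation
(one-term models) or Freedman–Lane residual permutation (multi-term
models), with a parallel-slopes check before any ANCOVA is interpreted.

The demographic estimators follow from the strata. With \(N\) the median
June–July count, \(s\) the median August–September singleton percentage
and \(f\) the median June–July fledgling percentage:

* minimum proportion of pairs attempting to breed: \(\hat\varphi = s/100\);
* expected recruits: \(\mathrm{round}(p/100 \cdot N \cdot r)\) for a
  stratum percentage \(p\) and fledging rate \(r\) (default 1.0 young per
  laying female per year);
* post-fledging loss: \(1 - E_f / E_s\), the shortfall of the
  fledgling-based recruitment estimate \(E_f\) relative to the
  singleton-based one \(E_s\).

A negative-binomial generator (`synthetic_config()`,
`generate_roost_counts()`) produces study-shaped tables — five roosts
monitored 61/61/61/38/28 months, June–July attendance peaks, an
incubation-season singleton pulse with breeding fraction φ, a declining
family-flock stratum and a collapsing fifth roost — so every stage of the
pipeline can be validated by parameter recovery (`recovery_experiment()`).

## Worked example

```r
library(roostdemog)

## Published annual summaries ship with the package
tot <- median_iqr(published_annual_values("pooled", "all_parrots"))
fl  <- median_iqr(published_annual_values("pooled", "fledglings_pct"))
tot$median                                  # 4571.5 birds (Jun-Jul median)
fl$median                                   # 3.6 % fledglings
expected_recruits(fl$median, tot$median)    # 165 six-month-old young/year

## Synthetic five-roost system, full pipeline
counts <- generate_roost_counts(synthetic_config(), seed = 1)
pooled <- pool_roosts(counts)
dec <- stl_decompose(monthly_series(pooled, "pooled", "all_parrots"))
round(range_standardize(dec), 2)
#>  Jan  Feb  Mar  Apr  May  Jun  Jul  Aug  Sep  Oct  Nov  Dec
#> 0.20 0.06 0.00 0.04 0.32 1.00 0.96 0.28 0.16 0.49 0.22 0.10

linear_trend(monthly_series(pooled, "pooled", "fledglings"),
             permute = TRUE, n_perm = 999, seed = 2)
#> Linear trend: slope -1.301 per month (-15.62 per year),
#>   F(1, 59) = 96.4, r2 = 0.620, n = 61
#>   p (classical) = 5.091e-14; p (permutation, 999 perms) = 0.001
```

The standardized profile peaks in June–July (pre-reproductive gathering)
and bottoms out in late summer, and the fledgling stratum declines — the
generator's default configuration builds in exactly the kind of
recruitment erosion the estimators are designed to flag: stable totals,
shrinking fledgling counts.

A command-line wrapper over the same pipeline is installed at
`inst/scripts/roost-pipeline.R`:

```sh
Rscript inst/scripts/roost-pipeline.R all \
    --input counts.csv --out results --seed 1 --nperm 999 \
    --trend-roosts 1,2,3,4
```

It writes the annual summary table, monthly medians, decomposition
components and profiles, trend and permutation-test JSON, demography
estimates, and a hash-stamped manifest.

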