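---
title: "Smoothing poaching rates: the binomial state-space model behind sPIKE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smoothing poaching rates: the binomial state-space model behind sPIKE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ranger patrols at elephant monitoring sites report, each year, the total
number of elephant carcasses found ($C_{i,t}$ for site $i$, year $t$) and how
many of them were killed illegally ($K_{i,t}$). The ratio $K/C$ — PIKE, the
Proportion of Illegally Killed Elephants — is the standard index of poaching
pressure, but it is a noisy one: many sites find only a handful of carcasses
a year, about a quarter of site-years are not reported at all, and a
proportion estimated from 5 carcasses is treated by a naive analysis exactly
like one estimated from 150.

`spikessm` separates the signal from the sampling noise with a per-site
state-space model, aggregates the smoothed site states into
population-weighted regional series, and tests for temporal trends.

## The model

For each site, the latent "true" poaching rate $s_{i,t}$ (sPIKE) evolves as
a random walk on the logit scale,

$$\mathrm{logit}(s_{i,t}) = \mathrm{logit}(s_{i,t-1}) + \epsilon_{i,t},
  \qquad \epsilon_{i,t} \sim N(0, \sigma^2_i),$$

and the observed counts are a binomial sample from it,

$$K_{i,t} \sim \mathrm{Binomial}(C_{i,t}, s_{i,t}).$$

The process error $\sigma^2_i$ — estimated separately per site by maximum
likelihood — controls how fast the latent rate may move: large values let
sPIKE "wiggle", small values force it flat so that year-to-year variation is
attributed to binomial sampling. Because the binomial variance shrinks with
$C$, sites and years with many carcasses are smoothed lightly and
small-sample ones heavily, which is exactly the error structure a proportion
deserves. Missing years are handled naturally: the filter simply propagates
the state through them, and the smoother fills them with
interpolation-like estimates whose variance reflects the gap length.

### Fitting: a Gaussian approximation done carefully

The filter is in the extended-Kalman-filter family: the posterior of the
logit state is propagated as a Gaussian. Two numerical choices matter and
are worth explaining, because the naive textbook recursion fails on this
data class.

1. **Measurement updates are moment-matched by quadrature.** The one-year
   posterior $\mathrm{Binom}(K \mid C, \mathrm{logit}^{-1}(x)) \cdot
   N(x \mid m_{\mathrm{pred}}, P_{\mathrm{pred}})$ is log-concave in $x$; we
   locate its mode with a safeguarded Newton search, then integrate on a
   grid centred there (161 points over $\pm 12$ posterior SDs) to obtain the
   exact normalizing constant, mean and variance. The filtered Gaussian
   therefore matches the exact one-year posterior's first two moments, and
   the accumulated normalizing constants are the exact predictive
   log-likelihood $\sum_t \log p(K_t \mid K_{1:t-1})$ under the Gaussian
   closure. A single first-order linearization around the predicted state
   (the textbook EKF update, available via
   `ssm_config(update = "predicted")`) is unstable here: when the predicted
   state sits in a saturated region of the inverse logit, the linearization
   slope $C\,\hat p(1-\hat p)$ collapses and the update can overshoot by tens
   of logit units.

2. **The likelihood is the predictive likelihood, not the Gaussian
   innovation density.** The innovation-density form
   $-\tfrac12(\log 2\pi S + v^2/S)$ is unbounded: for a site whose every
   observation is $K=0$ (or $K=C$), the fitted probability approaches the
   boundary, the innovation variance $S$ collapses, and the "likelihood"
   grows without limit as $\sigma^2$ increases — an artifact that drags
   every boundary site's $\hat\sigma^2$ to the search bound. The quadrature
   predictive likelihood is bounded above by the exact binomial log-pmf, so
   no such blow-up exists. (The innovation-form value is still returned as
   `loglik_gaussian` for comparison.)

Smoothing uses the standard RTS backward recursion on the filtered
Gaussians. On short series the smoothed means agree with an exact
discretized-grid smoother (`grid_oracle()`, a brute-force forward-backward
recursion over a fine mesh of logit values with exact binomial likelihoods)
to about $10^{-2}$ logit units in the moderate-count regime; the worst
cases — strongly skewed posteriors produced by near-boundary counts in the
first year of a series — can reach $\approx 0.2$ logit units, a known
limitation of any Gaussian-closure smoother.

$\hat\sigma^2_i$ is found by a coarse scan of the bounded log-variance
interval (13 points, guarding against the plateaus discussed below)
followed by Brent refinement. The diffuse initial state uses a large finite
variance ($10^7$); after the first informative observation its influence is
below $10^{-4}$ logit units.

### Degenerate inputs

* Years with $C = 0$ reported are *observed* (they count toward inclusion
  rules) but information-free for the proportion: the binomial likelihood is
  constant, so the update is skipped. This deliberately does not distinguish
  "searched and found nothing" from "searched little"; the raw data cannot.
* Boundary observations ($K = 0$ or $K = C$) need no continuity correction:
  the exact binomial likelihood handles them, and the reported probability
  scale state is clamped to $[10^{-6}, 1 - 10^{-6}]$ only at output.
* A site observed in a single year gets a constant sPIKE trajectory at that
  year's posterior, with variance growing away from it.

## Aggregation and trend tests

Regional (or continental) sPIKE is the weighted mean
$r_t = \sum_i w_{i,t} s_{i,t}$ with weights
$w_{i,t} = E_{i,t} / \sum_i E_{i,t}$ proportional to the estimated number of
live elephants at each site — not to carcasses found, which reflect search
effort and mortality as much as population. Survey estimates $E_{i,t}$ are
linearly interpolated between survey years and held constant outside them.
The variance is carried on the logit scale,
$V(\mathrm{logit}(r_t)) = \sum_i w_{i,t}^2 V(\mathrm{logit}(s_{i,t}))$, with
95% intervals formed on the logit scale and back-transformed, which keeps
them inside $(0,1)$ without truncation. This variance formula applies
probability-scale weights to logit-scale variances — a deliberate mixing of
scales, kept because it is how the quantity is defined for this analysis;
the delta-method conversion to the probability scale is used only inside
the trend test's weighting.

Trends are tested separately for 2003–2010 and 2011–2018 (2011 being the
reported inflection of poaching rates; the year belongs to both inclusion
sub-periods but opens the second regression period). The regression of
$r_t$ on year uses two-step feasible GLS: OLS supplies a residual variance,
each year's total variance is that plus the delta-method sampling variance
$V(\mathrm{logit}(r_t)) \cdot [r_t(1-r_t)]^2$, and the final fit is weighted
least squares with inverse total variances — equivalent to OLS when the
sampling variances are equal. Slopes are reported on the probability scale
per year (`scale = "logit"` is available), with $t$ tests on $n-2$ degrees
of freedom and Bonferroni correction at family size $m = 10$ (five scopes —
continent plus four regions — times two periods), chosen so the family-wise
error rate is 0.05.

For comparison, `fit_ls_means()` reproduces the legacy carcass-weighted
linear model $\mathrm{PIKE}_{i,t} = \mathrm{region}_i + \mathrm{year}_t +
\epsilon_{i,t}$ with weights $C_{i,t}$ and least-squares means by year. Its
known pathologies are on display by construction: multiplying every count
by ten changes neither the estimates nor the intervals (the model never
sees sample size), intervals must be truncated to $[0,1]$, and a year with
no reports has no estimate at all.

## The synthetic data generator

Real carcass tables are downloaded from the monitoring programme; the
package, however, is fully testable offline because `generate_mike_like_template()`
draws a sampling frame with the same structure: 38 sites split 12/10/9/7
across the Central/Eastern/Southern/West regions over 2003–2018; per-site
carcass rates lognormal with region means 17.8/51.0/46.1/7.5 and ranges
matching the monitoring programme's per-region summaries; live-elephant populations
lognormal with region means 3,529/6,559/8,078/492; and a missingness
pattern hitting the programme's mean reported-years per region (7.3–8.3 of
the nine pre-2011 years, 6.6–8.0 of the eight post-2011 years, the split
year itself reported with probability 0.9 so the period counts reconcile
with the 13.7-year overall mean). Every generated site satisfies the
default 4-years-per-period inclusion rule, as every analysed real site
does. Lognormal rates are the natural choice for positive, right-skewed
abundance-like quantities; rates and populations are clamped to the
programme's observed ranges.

What the template does *not* emulate: spatial correlation between sites,
reporting bias at sites that investigate intelligence reports (observed as
PIKE pinned near 1), year-to-year correlation of search effort, and any
relationship between poaching level and carcass counts. Passing simulation
tests therefore demonstrates correct recovery under the model's own
assumptions plus realistic sample sizes and missingness — not robustness to
biased reporting.

Two truth schemes ride on the template, mirroring the estimator's original
validation design:

* **trend** — per-site logit-linear trajectories,
  $\mathrm{logit}(a_{i,1}) \sim U(-4,4)$, slope $\beta_i \sim U(-1,1)$ per
  year, annual deviations $N(0,1)$;
* **random** — $a_{i,t} \sim U(0,1)$ independently, no structure at all.

Counts are drawn $K \sim \mathrm{Binomial}(C, a)$ on the template's observed
cells; truth is clamped to $[10^{-6}, 1-10^{-6}]$ before drawing. Accuracy
is scored as RMSE of sPIKE against truth — per replicate over all
site-years, and for the population-weighted continental series over years —
averaged over 100 replicates (`run_simulation_study()`; one template is
held fixed across a study's replicates, as the original validation design reused
its single real sampling frame).

## A reproducibility caveat found by this implementation

Under the trend scheme a non-trivial fraction of sites saturate: a slope of
$-0.9$/year starting at logit $+2$ reaches logit $-11$ by year 16, so the
site reports $K=0$ for a decade. For such sites the *exact* marginal
likelihood of $\sigma^2$ — computable by the grid oracle — is maximized at
very large values (a jump-then-flat state path explains the data slightly
better than any smooth one) while being nearly flat above $\sigma^2
\approx 2$. Bounded maximum likelihood therefore produces a heavy right
tail in $\hat\sigma^2$, and the cross-site *mean* process error under the
trend scheme lands at several logit$^2$ units rather than below 1; the
reference value for this quantity, 0.8, cannot be reproduced by maximizing
the likelihood (the per-site *median*, a typical site, does
show the expected contrast: roughly 1.5 under trends versus 4–6 under
structureless truth). The RMSE results are insensitive to this tail —
saturated sites are fitted at the boundary they actually occupy — and are
reproduced at the reference levels. `sim_score` objects report both the
mean and the median so the distinction stays visible.

## Problem sizes and defaults

| Quantity | Default | Why |
|---|---|---|
| study window | 2003–2018 | the monitoring programme's consistent reporting period |
| inclusion rule | ≥4 observed years per sub-period | trend estimation needs support on both sides of 2011 |
| $\sigma^2$ search interval | $[10^{-8}, 10^{2}]$ | brackets "flat" to "jump anywhere in a year" |
| diffuse prior variance | $10^7$ | logit scale; effectively no prior information |
| probability clamp | $10^{-6}$ | keeps reported states interior |
| quadrature grid | 161 points, $\pm 12$ SD | exact to plotting precision, cheap |
| oracle mesh | 2001 points on $[-10,10]$ | spacing 0.01, refinement-stable to $10^{-4}$ |
| simulation replicates | 100 | matches the original validation design |
| Bonferroni family | $m = 10$ | 5 scopes × 2 periods |

The test suite runs the full 100-replicate studies (about four minutes per
scheme on one core) plus the oracle-equivalence and parameter-recovery
checks; unit tests use smaller templates. All randomness flows through
explicit seeds; identical seeds give bit-identical datasets and analyses.

## Known limitations

* The model cannot correct biased reporting, only sampling noise: a site
  that preferentially reports illegal carcasses will have a biased sPIKE
  with an honest-looking interval.
* Cross-site correlation of disturbances is deliberately not modelled
  (independent-disturbance models were preferred by information criteria in
  the analysis this package implements).
* Population weights treat interpolated survey values as known; their
  uncertainty is not propagated into $V(\mathrm{logit}(r_t))$.
* The Gaussian closure leaves rare $\sim0.2$ logit-unit discrepancies from
  the exact smoother at strongly skewed early-series posteriors.
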