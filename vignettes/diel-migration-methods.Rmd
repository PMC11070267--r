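---
title: "Quantifying the diel timing of insect migration from vertical-looking radar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the diel timing of insect migration from vertical-looking radar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielflux)
```

## The problem

Vertical-looking entomological radars record individual targets passing
through a narrow upward-pointing beam, together with classifier
probabilities (insect, bird subgroups, non-biological), the altitude above
the radar, and a low-pass-filtered maximum radar cross section (RCSmax, in
cm², a proxy for body mass). `dielflux` turns such echo tables into
quantities that describe *when in the diel (24 h) cycle* migratory insects
fly: hourly migration traffic rates, per-phase daily aggregates, daily
proportional measures, and cross-site statistical comparisons.

Because day, twilight and night lengths vary strongly with latitude and
season, clock-time comparisons across a continental network are
uninformative. The package therefore segments every day into four diel
phases defined by the geometric (unrefracted) centre of the sun:

* **crepuscular morning** — nautical dawn (sun at −12°) to sunrise (0°),
* **day** — sunrise to sunset,
* **crepuscular evening** — sunset to nautical dusk (−12°),
* **night** — nautical dusk to the next nautical dawn.

## Solar geometry

Solar elevation uses a standard low-accuracy ephemeris (NOAA/Meeus class:
apparent solar longitude, corrected obliquity, equation of time). Its error
is well below 0.2°, and event times found by root refinement are accurate
to well under a minute — ample, since the shortest phases span tens of
minutes. The test suite cross-checks elevations against an independent
right-ascension/sidereal-time formulation and a Fourier-series ephemeris,
and crossing times against 1 s brute-force scans.

A *diel day* runs from nautical dawn to the next nautical dawn, so the
night interval stays contiguous and is attributed to the anchor date of the
dawn that opens it. This mirrors the natural phase ordering
(morning → day → evening → night) and avoids splitting the night at
midnight. All timestamps are UTC; local solar time enters only through the
site longitude. This sidesteps daylight-saving ambiguity across a network
spanning roughly 2° W to 24° E.

**High-latitude summers.** North of about 55° N, the sun may stay above
−12° all night. On such dates no night interval exists; the whole
sunset→next-sunrise span is twilight and is split at its *clock-time*
midpoint: the first half is crepuscular evening, the second half opens the
next diel day as crepuscular morning. The alternative — splitting at solar
midnight — differs by at most tens of seconds at these longitudes because
sunset and sunrise are nearly symmetric about solar midnight; clock
midpoint was chosen because it is exactly reproducible from the emitted
interval table. Polar day (never below 0°) collapses to a single `day`
interval; the crepuscular-only regime (sun between −12° and 0° all day)
splits its twilight span at the midpoint analogously. Neither regime occurs
at 43–61° N, but the geometry is handled so the partition invariant holds
everywhere.

Phase intervals are half-open `[start, end)`: a boundary instant belongs to
the later phase. Interval bounds of consecutive diel days are computed by
the same rule from the same solar events, so phase durations sum *exactly*
to the diel-day length and consecutive days chain without gaps.

## From echoes to traffic rates

An echo is retained as an insect if its insect probability exceeds 0.4
**and** exceeds every other class probability, and it flew between 50 and
500 m above the radar (all configurable via `dielflux_config()`).

The radar beam has a nominal −3 dB width of 17.5°, so at altitude $h$ a
crossing target is visible over a transect of width

$$w(h) = 2\,h\tan(17.5^\circ/2),$$

about 61.6 m at 200 m altitude. Each echo contributes $1/w(h_i)$ (in
km⁻¹) to its time bin, converting counts into a non-directional migration
traffic rate (MTR, insects·km⁻¹·h⁻¹):

$$\widehat{\mathrm{MTR}} = \frac{60}{\text{effective min}}
  \sum_i \frac{1}{w(h_i)}.$$

This deliberately simple geometric normalisation ignores the 2° antenna
nutation offset and any size-dependence of the detection volume; the
synthetic generator applies the *same* $w(h)$ when thinning detections, so
the estimator is exactly unbiased for the simulated flux and estimator
arithmetic can be validated independently of beam physics (a constant-$w$
hook is provided for tests).

Two protocol rules apply. (1) *Monitoring time*: an hour monitored for less
than 20% (12 min) of its span under the short-pulse protocol is reported as
`NA`; otherwise the echo sum is scaled by the monitored fraction.
(2) *Rain*: echoes inside rain intervals are discarded while the time still
counts as monitored, so rain reads as zero traffic, not as missing data.
Treating rain as non-monitored would instead inflate missingness during
rain, contradicting the zero-traffic interpretation.

Per diel phase and day, `phase_aggregates()` computes the **mean traffic
rate** (echo contributions divided by effective monitored hours) and the
**total traffic** (mean rate × phase duration, insects·km⁻¹ per phase).
These are computed at echo level against exact phase boundaries rather than
by resampling hourly bins, which avoids allocating fractional hours at
phase edges. The same 20% monitoring floor is applied per phase; the hourly
`NA` rule is a bin-level rule and phase aggregates re-apply it at phase
scale rather than inheriting hourly `NA`s.

## Daily proportions and the beta ANOVA

For every complete diel day, each phase's mean rate is divided by the sum
of the phase mean rates (**proportional migration intensity**) and each
phase's total traffic by the day's total (**proportional migration
traffic**). Both sum to 1 per day; they differ by duration weighting — a
short evening twilight can have the most *intense* migration while the long
day still carries the most *traffic*. Days with any missing phase, or with
zero traffic everywhere (a 0/0 share), are excluded.

Cross-site comparison treats each phase separately. Proportions are moved
off the boundary with the shrinkage transform

$$y' = \frac{y\,(N-1) + 0.5}{N},$$

where $N$ is the number of site-days with values for that phase in the
data being tested (sites excluded from the comparison are dropped *before*
$N$ is counted). The "ANOVA with beta distributions" is realised as beta
regression with a group (site) factor: each site has mean $\mu_g$ on a
logit link and all sites share a precision $\phi$, with shapes
$(\mu_g\phi, (1-\mu_g)\phi)$. The omnibus test is the likelihood-ratio
statistic $2(\ell_\text{full} - \ell_\text{null})$ on $g-1$ df against
$\chi^2$; post-hoc tests are two-group LRTs for every unordered site pair,
with the difference of fitted means as effect size and Holm correction
applied within each phase's family of $\binom{g}{2}$ pairs (pooling the
four phases into one family is available via configuration, but the
per-phase family matches how the post-hoc unit is defined). With 14
retained sites that is 91 tests per phase and 364 per measure.

Numerics: the beta likelihood depends on data only through per-group
$(n_g, \sum\log y, \sum\log(1-y))$, so fits cost $O(g)$ per iteration
regardless of sample size. Optimisation is BFGS with analytic gradients on
$(\operatorname{logit}\mu_1,\dots,\log\phi)$, multi-started from
method-of-moments values and $\phi_0 \in \{1, 10, 100\}$; the best of the
converged starts is kept. The suite verifies the fit against an independent
beta-regression implementation (glmmTMB), checks type-I error calibration
of the omnibus test (nominal 5%, accepted 3–7% over 1000 null networks of
14 sites × 30 days), the Holm familywise error (≤ 7%), and mean recovery
(±0.05 at n = 500 across $\mu \in \{0.1,\dots,0.9\}$). Holm adjustment
itself delegates to `stats::p.adjust` and is tested against an exhaustive
step-down computation over all permutations of up to six p-values.

## Monthly summaries

`monthly_phase_summary()` reports, per site × month × phase: the arithmetic
means of the daily proportions; the *relative* mean RCSmax (phase mean
divided by the sum of phase means, so shares sum to 1 per site-month —
months with a phase entirely absent get `NA` shares rather than silently
renormalising); and the monthly mean of the *daily median* flight altitude
of phase-assigned insect echoes. Daily-median-then-monthly-mean was chosen
(over a single monthly median) because the daily median is robust to
within-day bursts while the monthly mean preserves day-to-day variation.
`hourly_proportion_matrix()` produces the dates × 24 UTC-hour heatmap of
daily proportional hourly rates, keeping true zeros distinct from missing
hours. UTC hour columns keep sites comparable; sunrise/sunset overlays can
be derived from the emitted phase tables when plotting.

## The synthetic generator

`simulate_site()` emulates the statistical structure the analysis assumes,
not meteorological reality. The true flux density (insects·km⁻¹·h⁻¹) is

$$\lambda(t) = S(\mathrm{doy}) \left[ a_\mathrm{day}\max(0,\sin e)^k
 + a_\mathrm{dusk}\, g(e)\,\mathbf{1}_\mathrm{setting}
 + a_\mathrm{dawn}\, g(e)\,\mathbf{1}_\mathrm{rising}
 + a_\mathrm{night}\,\mathbf{1}_{e<-12^\circ} \right]$$

with $e$ the solar elevation, $g$ a Gaussian bump centred at −6° (width
3°), and $S$ a Gaussian seasonal envelope (default peak 300 insects·km⁻¹·h⁻¹
around mid July, SD 60 days, floor 5). The defaults produce the canonical
summer shape: low activity after sunrise rising to a noon peak, a stronger
evening-twilight peak, a weak dawn peak, and a low nocturnal plateau.

Event times are sampled exactly from an inhomogeneous Poisson process with
the rate held piecewise-constant over 1 min steps; candidates are drawn at
rate $\lambda(t)\,w(h_{\max})$ and kept with probability
$w(h)/w(h_{\max})$, which makes the $1/w$ estimator unbiased by
construction. Altitudes are gamma (shape 6, day mean 160 m, night +40 m)
truncated to the 50–500 m band; RCS is lognormal (day median 0.1 cm²,
σ = 1 on the log scale) with the night median multiplied by 3, matching
the qualitative observation that nocturnal migrants are larger and fly
higher. The day/night regime switch for RCS and altitude follows the
night-phase boundary (−12°). Insect class probabilities are drawn noisy
but above the 0.4 filter threshold (so filtering does not bias recovery
tests); bird and non-biological contaminants (5% each by default) are
added below it to exercise the filter. Rain (0.15 intervals/day, mean
90 min) and outages (0.05/day, mean 3 h) are emitted as interval tables;
outages remove echoes and protocol coverage, rain removes neither.

Ground truth per phase is the exact integral of the piecewise-constant
rate over each phase interval (for the 1 min step rate this integral is
computed in closed form; it agrees with a 1 s Riemann sum of the smooth
rate to well under 1%). What the generator does *not* emulate — weather
dependence, wind drift, taxonomic mixtures, size-dependent detection
volume, inter-annual variation — bounds what green tests mean: they
validate the estimators and statistics under the stated model, not the
biology of any particular dataset.

## Determinism and problem sizes

Every simulation takes a mandatory seed; per-site streams are derived from
the master seed by a stable hash of the site id, so site sets can be
extended without perturbing existing sites. The test suite exercises:
solar crossings against 1 s scans over a 50-site × 20-date grid spanning
43–61° N; 10⁴ random timestamps against an elevation-based phase oracle;
estimator recovery over 22 fully monitored synthetic days (>500 hourly
bins); beta calibration over 1000 null networks; and a three-month
synthetic summer for the qualitative intensity/traffic contrast. The
acceptance script runs a 17-site, four-month network end to end. These
sizes were chosen to make Monte-Carlo tolerances (3 SE bands, 3–7%
rejection windows) meaningful while keeping a full run comfortable on one
CPU.

## Known limitations

* The MTR normalisation is the pure −3 dB beam geometry; absolute rates
  from real radars depend on device-specific detectability corrections, so
  cross-device absolute comparisons need care even though proportional
  measures are robust to a site-constant factor.
* The beta ANOVA assumes independent daily proportions; temporal
  autocorrelation within a season is not modelled.
* Proportional measures are compositional; the per-phase tests do not model
  the sum-to-one coupling across phases.
* The twilight-split rule uses the clock midpoint (see above); a
  solar-midnight split would differ by seconds to tens of seconds.

## A worked example

```{r example, eval = FALSE}
library(dielflux)

sites <- tibble::tibble(site_id = "demo", name = "Demo", lat_deg = 47,
                        lon_deg = 8, elev_m = 400)
cfg <- dielflux_config(period = as.Date(c("2021-07-01", "2021-07-14")))
net <- simulate_network(sites, seq(cfg$period[1], cfg$period[2], "day"),
                        sim_params(), seed = 1, config = cfg)
res <- run_pipeline(sites, net$echoes, net$intervals, cfg)
head(res$daily_props)
plot_diel_heatmap(res$heatmap, "prop", site = "demo")
```
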