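---
title: "Wavelet analysis of spatial synchrony and its drivers"
author: "wavesync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet analysis of spatial synchrony and its drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavesync)
```

# The problem

Spatial synchrony is the tendency for fluctuations of an ecological variable
to be correlated across locations. It matters because synchronous
fluctuations reinforce one another when summed over a region, destabilizing
regional totals, and because the *mechanism* of synchrony — a spatially
correlated environmental driver acting on separate local systems, the Moran
effect — can often be identified statistically from monitoring data.

`wavesync` implements a timescale-resolved workflow for this inference on
site-by-month panels: how strong is synchrony, at which timescales, at which
times; which candidate drivers are coherent with the response across space;
and how much of the observed synchrony a linear model built from those
drivers can account for, driver by driver. The motivating application is a
cross-ecosystem resource-subsidy cascade: giant kelp biomass on nearshore
reefs, fragmented by waves and delivered onto sandy beaches as wrack
(detrital kelp), where — mediated by the width of dry beach available for
deposition — it feeds invertebrates and, one trophic level up, the
shorebirds that forage on them. Five beaches monitored monthly for eleven
years (N = 5, T = 132) is the canonical data shape.

# The methods

## Morlet transform with timescale = period

Every series is first cleaned per site — optional Box–Cox transform, then
least-squares linear detrend, then scaling to zero mean and unit variance
(`clean_series()`; the order is fixed, and missing values are a hard error
with `sts_interpolate()` as the explicit repair tool). Cleaned series are
convolved with the analytic Morlet kernel

$$\psi_\sigma(v) \;=\; \frac{1}{Z(\sigma)}\,
  e^{\,2\pi i v/\sigma}\, e^{-v^2/(2\sigma^2)},$$

truncated at $|v| \le 4\sigma$ and L1-normalized ($Z$ is the discrete
envelope sum), on a log-uniform grid of timescales $\sigma$ (default 2 to
$\min(72, T)$ months, ratio 1.05). With this parameterization (dimensionless
central frequency 1) the timescale *is* the period: a unit cosine of period
$P$ yields $|W| \approx 1/2$, maximized over $\sigma$ exactly at $P$, and
$\arg W$ advances by $2\pi$ per $P$ months. The grid spans the three
reporting bands used throughout: 2–8 (intra-annual), 8–16 (annual) and 16–60
months (interannual).

Convolution is direct (non-circular); nothing is zero-padded behind the
user's back. Instead, coefficients closer than `coi_factor`·$\sigma$ to
either end of the record are flagged invalid (the cone of influence), and
every downstream statistic averages over valid cells only. The default
`coi_factor = 1` is deliberately lenient — a 60-month timescale on an
11-year record retains one valid year — because the alternative (a stricter
cone) would simply delete the interannual band; the parameter is exposed
for users who prefer a harsher rule. For the default grid the longest
timescales (above $T/2$) can have an empty cone; their normalization then
falls back to all-times power and band statistics skip them. All three
reporting bands have valid cells at $T = 132$.

## Normalization, mean fields, and the random-phasor null

Per-site transforms are normalized at each timescale. `across_locations`
divides all sites by the square root of the across-site mean of per-site
mean valid-time powers: relative amplitudes between sites are preserved and
the across-site mean power is exactly 1 at every timescale. This is the
normalization under which the **wavelet mean field**
$\mathrm{WMF}(t,\sigma) = \tfrac1N \sum_n \tilde W_n(t,\sigma)$ is
interpretable: $|\mathrm{WMF}|^2$ is near 1 when sites oscillate together
and near $1/N$ for independent sites. The **wavelet phasor mean field**
replaces each coefficient by its unit phasor, measuring phase synchrony
irrespective of amplitude (it is invariant to per-site positive rescaling).

Significance of phasor synchrony uses the random-phasor null: under no
synchrony the WPMF magnitude at any cell is the modulus of the mean of $N$
independent uniform phasors. A single global threshold per significance
level (the $(1-\alpha)$ quantile over `n_rand = 1000` seeded draws) applies
to all cells, since the null is identical across cells; contours are
pointwise, with no field-wise multiplicity correction (stated in the report
rather than corrected, matching standard practice for these displays).

## Spatial wavelet coherence and surrogate testing

For a driver $x$ and response $y$, the per-timescale spatial coherence is
the mean over sites and valid times of
$\overline{\tilde W^x}\,\tilde W^y$; band values average the per-timescale
coherences (unweighted over the log-spaced grid — an average over
log-timescale, the natural scale for octave-like bands). The magnitude lies
in $[0,1]$ by Cauchy–Schwarz. The phase $\phi$, reported in fractions of
$\pi$ on $(-1,1]$, uses the convention that $\phi$ near 0 is in-phase, near
$\pm 1$ anti-phase, and otherwise **negative $\phi$ means the response lags
the driver** (e.g. a 3-month lag of a 12-month oscillation gives
$\phi = -0.5$). `classify_phase()` applies the interval convention
$-0.25 < \phi < 0.25$ (in-phase), $|\phi| > 0.75$ (anti-phase), boundary
values falling to the lag/lead classes.

Significance testing surrogates the *driver*, holding the response fixed:
Fourier surrogates randomize each site's discrete-Fourier phases with one
shared random sequence, preserving each site's periodogram exactly and the
driver's own cross-site synchrony — the null is "no cross-variable
relationship", not "no structure". An amplitude-adjusted variant (AAFT)
additionally preserves marginal distributions for skewed variables.
P-values use the add-one rule $(1 + \#\{S_{\mathrm{surr}} \ge
S_{\mathrm{obs}}\})/(n_{\mathrm{surr}}+1)$.

Two evaluation schemes are provided. The **slow** scheme rebuilds every
surrogate series and re-transforms it through the full wavelet machinery —
the reference implementation. The **fast** scheme exploits the linearity of
the transform: the band cross-statistic of a phase-randomized surrogate is
$\sum_f e^{i\theta_f} c_k(f)$ with $c_k(f)$ precomputed once from the
driver's FFT, the kernel, the cone mask and the fixed response fields, so
all 10,000 surrogates cost one small matrix product. In both schemes the
per-timescale normalizers of the surrogate statistic are the *observed*
driver's across-site mean powers — fixed constants of the observed data.
Because constants reweight timescales identically for the observed and every
surrogate statistic, the test remains exchangeable (a valid surrogate
test), and the fast scheme is an exact algebraic equivalent of the slow
one: with shared seeds their p-values are identical to machine precision,
which the test suite asserts. The measured type-I error of the default test
at $\alpha = 0.05$ (independent AR(1) panels, N = 5, T = 132) is 0.06 over
200 replicates, inside the binomial band.

## Wavelet linear models and synchrony attribution

For each grid timescale in a band, the response's normalized coefficients
are regressed on the predictors' by complex least squares, pooling sites and
valid times (no intercept: the fields are zero-mean; collinearity beyond
condition number $10^8$ is an error naming the timescale). Coefficients are
fitted per timescale rather than per band so gain and phase may vary across
a multi-octave span; band quantities then aggregate.

Writing $M_j(t,\sigma) = \beta_j(\sigma)\,\mathrm{WMF}^{x_j}(t,\sigma)$ for
predictor $j$'s fitted component mean field, the model-predicted synchrony
is $S_{\mathrm{mod}} = \langle |\sum_j M_j|^2 \rangle$ over valid band
cells, the observed synchrony $S_{\mathrm{obs}} = \langle
|\mathrm{WMF}^y|^2 \rangle$, and

$$S_{\mathrm{mod}} \;=\; \sum_j \big\langle |M_j|^2 \big\rangle
  \;+\; \sum_{j<k} \big\langle 2\,\mathrm{Re}(M_j \overline{M_k})
  \big\rangle$$

holds exactly (asserted to $10^{-10}$ on arbitrary seeded inputs): the
first terms are nonnegative per-driver contributions, the signed cross
terms are pairwise interactions — positive synergistic, negative
antagonistic. The fraction explained $S_{\mathrm{mod}}/S_{\mathrm{obs}}$
can exceed 1 in overfit corners; it is reported raw with a warning, never
clipped.

**Model phases.** The phase reported for predictor $j$ is the argument of
the $|\beta_j|$-weighted band average of the cross-products
$\langle \overline{\tilde W^{x_j}}\,(\tilde W^y - \sum_{k\ne j}\beta_k
\tilde W^{x_k})\rangle$: the *other* predictors' fitted components are
partialled out of the response first. This was a genuinely open design
point. The naive bivariate cross-phase is contaminated whenever two
predictors share a spectral line — exactly the situation of the shorebird
model, where air temperature is included to absorb the migratory seasonal
cycle; partialling removes that contamination while reducing to the
bivariate phase for single-predictor models, and it reproduces the expected
conventions exactly (lag-1 of a 12-month signal $\to -1/6$; identical
response $\to 0$; negated response $\to +1$). Raw $\arg\beta_j(\sigma)$ per
timescale is also kept in the fit object.

**Diagnostics.** `wlm_diagnostics()` reports a per-timescale $R^2$
analogue, the residual phasor mean field against its random-phasor
threshold (a sound model leaves no significant residual synchrony), and —
given the predictor series — surrogate coherence tests between residual
fields and each predictor, which should not reject. Omitting a strong
driver makes both residual probes fire, which the test suite checks.

## The cascade pipeline

`run_cascade()` chains the full analysis: aggregate raw tables
(transect means for wrack, species totals over a configurable shorebird
list, monthly means of daily maximum wave heights); first-difference wave
intensity — the mechanistically relevant quantity, since waves dislodge
progressively less kelp as less remains, making *increases* in wave action
the productive episodes — indexing $\Delta x(t) = x(t) - x(t-1)$ at the
later month and trimming all variables to the common months $2..T$; clean;
transform; then (1) wrack mean fields with significance contours, (2)
screening of the four candidate drivers (local kelp, regional kelp,
$\Delta$waves, beach width) against wrack in each band at $P < 0.1$, with
the rule that when both kelp scales pass, only the lower-P one enters the
model (ties at the attainable floor $1/(n_{\mathrm{surr}}+1)$ break toward
the larger coherence magnitude), (3) per-band wrack models with
attribution, phases and diagnostics, (4) bird mean fields, (5) bird–wrack
coherence per band, (6) bird models with wrack and air temperature as
predictors in *all* bands, caution-flagged wherever bird–wrack coherence is
not significant, and (7) a multiple-testing summary (tests run vs
rejections at 0.05) in lieu of formal correction. Every random stage
derives its seed from the single configured seed; two runs of the same
configuration produce byte-identical JSON reports, and `write_report()`
emits the report, the mean-field matrices as CSV, and an MD5 manifest.

# The synthetic cascade generator

Because the motivating field data are external survey products, the package
carries a first-class generator (`cascade_scenario()` /
`generate_cascade_scenario()`) whose defaults encode the study conditions:
5 sites, 132 monthly steps, and a mechanistic chain

$$\mathrm{wrack}_n(t) = a\,\mathrm{kelp}^{\mathrm{reg}}_n(t-\ell_k)
 + b\,\Delta\mathrm{waves}_n(t) + c\,\mathrm{width}_n(t) + \varepsilon,$$
$$\mathrm{birds}_n(t) = e\,\mathrm{temp}_n(t)
 + d\,\mathrm{wrack}_n(t-\ell_b) + \varepsilon,$$

with every driver built as seasonal-plus-AR(1) Moran forcing: a 12-month
cosine with site-invariant phase, plus $\sqrt\rho$ times a spatially common
AR(1) and $\sqrt{1-\rho}$ times site-independent AR(1) (unit-variance
innovations), so the expected between-site correlation of the nonseasonal
part is exactly $\rho$. Three generator choices deserve explanation, since
they decide what the null and recovery tests mean:

* **Calendar-locked seasonal phases.** Each variable's seasonal phase is a
  fixed offset from one shared random base phase (kelp and temperature peak
  in summer, waves in winter, width in late summer). Annual cycles in
  nature are mutually locked; drawing independent random phases per
  variable makes the annual band behave unrealistically (drivers compete
  incoherently at 12 months).
* **Lognormal interannual modulation of seasonal amplitude**
  (`seasonal_mod`, default 0.8, AR(0.9) envelope), partly shared across
  drivers (`env_shared`, default 0.7) as one common climate mode — strong
  storm seasons coincide with anomalous kelp years. This matters
  statistically: a fixed-amplitude seasonal line is a single Fourier
  component, and phase surrogates rotate all within-band coherences built
  on it by one common angle, so a pure line carries *no* discriminating
  information under surrogate testing. Year-to-year amplitude variation —
  the realistic regime — spreads that energy into randomizable sidebands
  and restores test power at the annual band.
* **The local kelp analog does not drive wrack**; it is correlated with the
  regional field (`local_regional_cor = 0.4`), mirroring a 1.5-km-radius
  measurement of a resource transported at regional scale. Screening should
  therefore prefer the regional analog — the structural pattern the
  acceptance suite checks by majority vote across replicate worlds, since
  at T = 132 any single world can fall on the wrong side of the $P < 0.1$
  line.

Naturally nonnegative variables (kelp, width, wrack, birds) are shifted by
3 within-site standard deviations and truncated at zero, with the
truncation rate recorded in the truth object (near zero at default noise).
The generator records the implied band phases (e.g. $\ell_b = 1$ at the
12-month timescale implies $\phi = -1/6$); defaults for gains and noise are
one choice of a plausible regime, made once, with couplings strong enough
that the cascade is detectable at the study's record length — as it was in
the motivating system.

What the generator does *not* emulate: non-Gaussian marginals beyond the
truncation, observation error distinct from process noise, distance-decay
in synchrony (sites are exchangeable), nonstationary trends, and the
monitoring gap present in the real program. Tests passing on this generator
show the estimators recover known structure under the stated stochastic
model, not that the ecological conclusions of any particular field dataset
are correct.

# Numerical and design notes

* Timescale grid: log-uniform, ratio 1.05; band membership is inclusive
  ($lo \le \sigma \le hi$).
* The kernel is truncated at $\pm 4\sigma$ (envelope $< 3.4\times10^{-4}$
  of peak); the transform agrees with a naive direct-convolution oracle to
  $10^{-8}$ and better.
* Complex least squares is solved through the SVD pseudo-inverse;
  degeneracy is an error, never a silent drop.
* The zero-variance guard in cleaning is relative ($10^{-10}$ of the raw
  scale), so an exactly linear series errors rather than amplifying
  rounding noise.
* p-values can never be 0 (add-one rule) and `n_surr < 19` is rejected
  as unable to resolve $\alpha = 0.05$.
* Simulation sizes in the test suite (100 replicates for null levels, 200
  for type-I error at `n_surr = 500`, 50 paired datasets for fast-vs-slow,
  20 seeds for phase recovery, 3 for coefficient recovery at T = 528) were
  chosen to keep the default suite fast while leaving Monte-Carlo error
  well inside the asserted tolerances.

# Known limitations

* Statistical power at a band dominated by a common deterministic seasonal
  line is inherently limited under phase surrogates (see above); with
  eleven years of data, annual-band driver tests near the screening
  threshold are genuinely variable between realizations.
* Pointwise significance contours carry no field-wise multiplicity
  control; the report's tests-vs-rejections summary is the intended
  reading aid.
* Coefficient standard errors and confidence intervals for the wavelet
  regression are out of scope, as is any spatially explicit (distance-decay)
  analysis: sites enter exchangeably.
* `sync_explained` compares model and observed synchrony through mean
  fields; it is not an $R^2$ and can exceed 1 when a model overfits a weakly
  synchronous response.
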