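# wavesync

Wavelet tools for quantifying **spatial synchrony** — correlated temporal
fluctuations of an ecological variable across locations — and for
attributing it to environmental drivers, on site-by-month monitoring
panels. The motivating system is a cross-ecosystem resource-subsidy
cascade: giant kelp produced on nearshore reefs is fragmented by waves and
deposited on sandy beaches as wrack (detrital kelp), where — mediated by
dry beach width — it fuels an invertebrate food web and, one level up, the
shorebirds foraging on it. Synchronous kelp supply can therefore
synchronize beach ecosystems across a region, and the package's job is to
detect, localize (in time and timescale) and explain that synchrony.

## What it computes

For cleaned site × month series \(x_n(t)\) (N sites, T months), the package
builds continuous Morlet wavelet transforms \(W_n(t,\sigma)\) on a
log-uniform timescale grid, with the convention that timescale σ equals
period, explicit cone-of-influence masking, and across-site power
normalization \(\tilde W_n\). On top of these:

* **Wavelet mean field** \(\mathrm{WMF}(t,\sigma)=\frac1N\sum_n \tilde
  W_n(t,\sigma)\): its squared magnitude measures synchrony at each time
  and timescale. The **wavelet phasor mean field** does the same with unit
  phasors (phase synchrony only), and its significance comes from a
  random-phasor null (`1,000` seeded draws by default).
* **Spatial wavelet coherence** between a driver x and response y:
  per-timescale \(\langle \overline{\tilde W^x}\tilde W^y\rangle\) over
  sites and valid times, aggregated over timescale bands (2–8, 8–16, 16–60
  months by default), with magnitude in [0, 1] and phase φ in fractions of
  π (negative = response lags driver). Significance by Fourier-surrogate
  testing of the driver (shared phases across sites preserve its own
  synchrony), with an exact fast frequency-domain scheme equivalent to the
  slow re-transform scheme.
* **Multivariate wavelet linear models**: per-timescale complex least
  squares of \(\tilde W^y\) on driver fields, the model-predicted mean
  field, the fraction of band synchrony explained, and its *exact*
  decomposition into nonnegative per-driver contributions plus signed
  pairwise interaction terms, with model-based band phases and residual
  diagnostics.
* **The cascade pipeline** (`run_cascade()`): preprocessing (transect
  means, species totals, monthly wave aggregation and first-differencing),
  per-band driver screening at P < 0.1 with the local/regional kelp
  exclusivity rule, wrack models, bird mean fields, bird–wrack coherence
  and bird models (wrack + air temperature), a multiple-testing summary,
  and deterministic JSON/CSV reports.
* **A ground-truth synthetic generator** (`cascade_scenario()`,
  `generate_cascade_scenario()`) emulating the kelp→wrack→shorebird chain
  with Moran-forced drivers (calendar-locked seasonality with lognormal
  interannual amplitude modulation plus shared/independent AR(1)), known
  gains, lags and implied phases — the test bed for every stage.

## Worked example

Generate an 11-year, 5-beach synthetic world with known structure and run
the full analysis:

```r
library(wavesync)

scenario <- cascade_scenario(seed = 42)      # study-shaped defaults
world <- generate_cascade_scenario(scenario)
report <- run_cascade(world$data, run_config(seed = 7, n_surr = 1000))
print(report)
```

```
cascade synchrony report
  months analyzed: 2009-02 .. 2019-12 (131)
  wrack screening: 12 tests, 9 significant at 0.05
  wrack 2-8 mo: predictors kelp_regional+dwaves+width; synchrony explained 0.98
  wrack 8-16 mo: predictors kelp_regional+dwaves+width; synchrony explained 1.01
  wrack 16-60 mo: predictors kelp_regional+width; synchrony explained 0.94
  birds 2-8 mo: P(bird-wrack)=0.000999, synchrony explained 0.94
  birds 8-16 mo: P(bird-wrack)=0.000999, synchrony explained 1.00
  birds 16-60 mo: P(bird-wrack)=0.002, synchrony explained 0.98
```

The screening table for the annual band shows the driver logic at work —
the regional kelp analog beats the merely-correlated local one (which is
excluded by the lower-P rule), and wave-height first differences and beach
width are coherent with wrack:

```r
tab <- report$wrack_screening$table
tab[tab$band == "8-16", c("driver", "p_value", "phi", "selected")]
#>         driver p_value   phi selected
#>     kelp_local   0.022 -0.27    FALSE
#>  kelp_regional   0.002 -0.22     TRUE
#>         dwaves   0.001  0.20     TRUE
#>          width   0.002 -0.39     TRUE
```

(Note waves are *absent* from the 16–60 mo model above: first-differencing
strips interannual wave power, so the generator reproduces the expected
band structure.) Synchrony explained decomposes exactly into per-driver and
interaction terms (here kelp dominates, the kelp×waves interaction is
synergistic):

```r
report$wrack_models[["8-16"]]$contributions
#> kelp_regional=0.543, dwaves=0.217, width=0.049
report$wrack_models[["8-16"]]$crossterms
#> kelp_regional:dwaves=0.187, kelp_regional:width=-0.008, dwaves:width=-0.056
```

and the bird model's phase for wrack is −0.189 (fractions of π) at 8–16
months — the shorebird analog tracks wrack with a slight lag, consistent
with the generator's built-in one-month consumer lag (−1/6 ≈ −0.167 at the
12-month timescale).

`write_report(report, "out/")` serializes everything (JSON + CSV mean
fields + MD5 manifest); two runs with one seed are byte-identical. A thin
command-line front end with `simulate` / `transform` / `meanfield` /
`coherence` / `wlm` / `cascade` subcommands lives at
`inst/scripts/wavesync-cli.R`.

See the methods vignette (`vignettes/wavelet-synchrony.Rmd`) for the model,
conventions (phase signs, cone of influence, surrogate schemes) and the
generator's design.

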