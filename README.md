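# rhythmsync

Simulation and quantification of chemically driven synchronization of
gene expression across isolated microbial communities.

Spatially separated yeast colonies carrying a two-receptor synthetic
circuit — an auxin (IAA)-responsive activator and a salicylic-acid
(SA)-responsive repressor in front of a short-lived dEGFP reporter — can
pulse in near-perfect synchrony when driven by antiphase chemical
rhythms, without any cell-to-cell coupling. The coordination rests on
**rate-dependent hysteresis**: the promoter behaves as a noisy
Schmitt trigger whose switching band

\[ h(T) = h_0\,(1 + \kappa\,T_\mathrm{ref}/T), \qquad
   \theta_\mathrm{on/off} = m \pm h(T)/2 \]

widens with the input rate \(1/T\), so fast rhythms gate out noise while
slow rhythms chatter. `rhythmsync` implements this model end to end:

* **Generator** — antiphase pulse programs (`input_program()`), a
  Hill-based effective drive with first-order sensing relaxation
  (`chemical_to_drive()`), the hysteretic stochastic switch
  (`simulate_switch()`), single communities, uncoupled ensembles and a
  killer/sensitive two-strain consortium with toxin-induced period
  doubling (`simulate_community()`, `simulate_ensemble()`,
  `simulate_consortium()`).
* **Trace pipeline** — growth normalization `dEGFP/(dEGFP + mCherry)`,
  linear detrending, Savitzky-Golay smoothing (window 15), 0-1
  rescaling, burst detection with the nups/ndowns = 6 rule and full
  width at half prominence (`trace_peaks()`).
* **Metrics** — response precision, per-community periods and
  amplitudes, inter-community phase drift (% of the period),
  synchronized fraction, cumulative ACF, power spectra with dominant
  period, and period-doubling ratios (`phase_drift()`,
  `sync_fraction()`, `cumulative_acf()`, `power_spectrum()`,
  `doubling_ratios()`).
* **Dose-response** — four-parameter Hill fitting with log-scale EC50
  (`fit_hill()`, with `tidy()`/`glance()`/`autoplot()` methods).

Everything is tidy-first: functions take and return tibbles, so stages
chain with the pipe; `run_pipeline()` ties generation, conditioning and
metrics together and can write all artifacts (traces CSV, heatmap
matrix, JSON report, reproducibility log) to disk.

## Worked example

Simulate 46 communities under a 4-h antiphase rhythm for 48 h and
quantify them:

```r
library(rhythmsync)

prog   <- input_program(period_h = 4, pulse_width_h = 2, duration_h = 48)
cfg    <- pipeline_config(program = prog, n_communities = 46, seed = 11)
report <- run_pipeline(cfg)
report
#> <sync_report> 46 communities, 4 h cycles
#>   phase drift: 9.82%   sync fraction: 0.02
#>   dominant period: 4.09 h   median precision: 0.956
```

The ensemble locks to the 4-h rhythm (dominant spectral period 4.09 h)
with bursts whose width closely matches the 2-h pulse (median precision
0.956) and a community-to-community phase drift of ~10% of the period.
The same run at a 10-h rhythm gives 15.5% drift — slower rhythms see a
narrower hysteresis band relative to the noise and synchronize worse,
the signature of rate-dependent switching. (The strict sync-fraction
score counts only communities with one clean burst in ≥ 90% of cycles,
which noise-chattered simulated ensembles rarely achieve.) Per-community
detail is available via `tidy(report)`, ensemble summaries via
`glance(report)`, and `autoplot(report)`, `plot_traces()`,
`plot_trace_heatmap()` draw the standard figures.

Receptor calibration from a simulated dose-response table:

```r
d   <- simulate_dose_response(ec50 = 0.13, hill_n = 2, seed = 1)
fit <- fit_hill(d)
fit
#> <hill_fit> EC50 = 0.133 uM (SE 0.00362), n = 1.95,
#>            range [0.0497, 1.01], RSS = 0.0129
```

The fit recovers the generating EC50 (0.13 uM) within its standard
error.

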