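---
title: "Methods: simulating and quantifying chemically synchronized gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying chemically synchronized gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmsync)
```

## The system

`rhythmsync` models a minimal synthetic circuit that converts an external
chemical rhythm into synchronized pulses of gene expression across
spatially isolated yeast communities. Two bacterial Mar-family receptors
sense the inputs: an IAA (auxin)-responsive activator and an SA
(salicylic acid)-responsive repressor, driving a short-lived fluorescent
reporter (dEGFP) next to a constitutive mCherry growth marker. Antiphase
rectangular pulses of IAA and SA (e.g. 2 h IAA / 2 h SA in a 4-h cycle)
entrain every community independently: there is no cell-to-cell coupling,
and the coordination arises entirely from rate-dependent hysteretic
switching of the promoter.

The package contains (i) a stochastic simulator that emulates
microfluidics time-lapse recordings of such communities, (ii) the trace
quantification pipeline used on those recordings, and (iii) Hill
dose-response fitting for the receptor calibration curves.

## Effective drive

The chemical state is collapsed into a single dimensionless drive. With
Hill occupancies $H(c; K, n) = c^n / (c^n + K^n)$,

$$u_\text{raw}(t) = H(c_\text{IAA}; K_\text{IAA}, n_\text{IAA})
                  - H(c_\text{SA}; K_\text{SA}, n_\text{SA}) \in [-1, 1],$$

and receptor turnover and sensing delays are lumped into a first-order
relaxation $\dot u = (u_\text{raw} - u) / \tau_u$ with $u(0) =
u_\text{raw}(0)$, integrated exactly on each step. The defaults use the
fitted receptor midpoints $K_\text{IAA} = 0.13\ \mu M$, $K_\text{SA} =
407.3\ \mu M$, Hill coefficients of 2, and $\tau_u = 1.5$ h, chosen so
that reporter deactivation lags the chemical offset by hours, as the
pulse-response recordings show. This mapping is deliberately minimal: the
underlying receptor ODEs are not published, and every qualitative claim
the package tests depends only on "fast activation, slow decay, bounded
drive".

## Rate-dependent hysteretic switch

The promoter is a two-state Schmitt trigger. For a drive of period $T$
the switching band is

$$h(T) = h_0 \left(1 + \kappa \frac{T_\text{ref}}{T}\right), \qquad
  \theta_\text{on/off} = m \pm h(T)/2,$$

i.e. the hysteresis region widens linearly with the input *rate* $1/T$,
the defining feature of rate-dependent (as opposed to permanent-memory)
hysteresis. Ornstein-Uhlenbeck noise $\eta$ with standard deviation
$\sigma$ and correlation time $\tau_\eta$ rides on the drive; the state
flips ON when $u + \eta > \theta_\text{on}$ and OFF when $u + \eta <
\theta_\text{off}$, with strict inequalities (a sample landing exactly on
a threshold does not flip). A discrete switch keeps every downstream
metric exactly computable and makes the noiseless case verifiable against
a pen-and-paper crossing scan, which the test suite does exhaustively.

Defaults: $m = 0.325$, $h_0 = 0.2$, $\kappa = 1.25$, $T_\text{ref} = 10$
h, $\tau_\eta = 0.5$ h, $\sigma = 0.3$, integration step $1/120$ h (0.5
min). The noise scale is set against the *slow-rhythm* band $h(10\,h) =
0.45$: at $\sigma = 0.3$ a 10-h rhythm chatters visibly (~20% phase
drift across communities) while the enlarged band at 4 h,
$h(4\,h) = 0.825$, absorbs the same noise, reproducing the
slow-worse/fast-better ordering that motivates the design. A much
smaller $\sigma$ would make slow rhythms the most precise ones, the
opposite of what is observed.

Two consequences of this parameterization are worth stating plainly.
First, at 4-h cycles the relaxed drive peaks at $u \approx 0.65$, just
below $\theta_\text{on}(4\,h) = 0.74$: fast-rhythm switching is
noise-assisted, which is exactly the stochastic-resonance regime the
switch model is built on; the noiseless simulator oscillates
deterministically at 10-h (and slower) rhythms, and those are what the
deterministic oracle tests use. Second, at 2-h cycles the bounded
chemical drive cannot reach the enlarged threshold at all, so the
chemically driven simulator does not reproduce the 2-h recordings; the
rate-dependence claims at such periods are exercised in the switch module
directly (`sweep_noise_rate()`), where the square-wave drive amplitude
(default 1.2) is free to clear the widened band.

## Reporter and ensemble

While the promoter state is $P(t) \in \{0, 1\}$ the reporter follows

$$\dot G = \alpha_\text{eff}(G)\,\big(b + (1 - b) P(t)\big)
         - \big(\ln 2 / t_{1/2} + \mu\big) G,$$

with basal fraction $b = 0.02$, half-life $t_{1/2} = 2.5$ h, growth
dilution $\mu = 0.1\,h^{-1}$ and maximal production $\alpha = 1$ a.u./h
(Euler integration at the 0.5-min switch step, sampled every 10 min to
mimic the imaging cadence). Feedback variants rescale production
phenomenologically around $G_\text{ref} = \alpha t_{1/2} / \ln 2$:
negative feedback $\alpha / (1 + g G / G_\text{ref})$, positive feedback
$\alpha (1 + g G/G_\text{ref}) / (1 + G/G_\text{ref})$. These are
deliberately not calibrated to the closed-loop amplitude data and are
excluded from all quantitative checks.

Ensembles draw per-community lognormal perturbations (CV 0.1) of
$\alpha$, $t_{1/2}$, $\tau_u$ and the mCherry level, and both sampled
channels carry multiplicative lognormal measurement noise (CV 0.05).
Each community owns an RNG stream keyed by its index, so ensembles are
bit-reproducible and adding communities never perturbs existing ones.

## Killer/sensitive consortium

The killer strain runs the same switch but produces K1 toxin instead of
the reporter: $\dot X = k_X P_\text{killer} - d_X X$. Sensitive
communities integrate stress $\dot s = X - s$ (1-h relaxation). The
toxin acts through a cycle-skipping refractory rule: a community that is
stressed ($s$ above threshold) at a cycle onset skips that cycle and the
next $r - 1$ cycles with its switch held OFF, responds once, and only
then re-evaluates stress. Under sustained toxin this forces a
skip/respond alternation and therefore a reporter period of $(r + 1) T$
— period doubling for $r = 1$, consistent with the successive doublings
seen in toxin-exposed co-cultures. No equations for K1 action are
published; this is the simplest mechanism that produces clean doublings,
and it reduces *exactly* (bit-for-bit, same seeds) to the plain ensemble
when the toxin rate is zero. The re-evaluation-after-response clause is
what prevents a persistently stressed community from halting outright
instead of doubling.

## Trace conditioning

The canonical order, applied per community by `run_pipeline()`:

1. growth normalization `dEGFP / (dEGFP + mCherry)`, with `0/0` defined
   as 0 (a dead or empty region of interest reads as no signal);
2. least-squares linear detrending (the classic `detrend` default; the
   constant-only variant is a documented alternative we did not take);
3. Savitzky-Golay smoothing, window 15 samples (150 min at 10-min
   sampling), polynomial order 3. Edges are handled by evaluating the
   leading/trailing window's polynomial fit at the edge positions — no
   wrap-around, so bursts near the record boundaries are not aliased;
4. 0-1 rescaling, used only for heatmap export (it is affine, so widths
   and peak times are unaffected; constant traces are rejected rather
   than silently mapped).

## Metrics

* **Peaks**: a sample is a burst peak if preceded by ≥ `nups` and
  followed by ≥ `ndowns` monotone steps (default 6 and 6, i.e. one hour
  each at 10-min sampling) with topographic prominence above a floor
  (pipeline default 0.05 on the normalized scale). Burst width is the
  full width at half prominence (FWHP), interpolated between samples;
  FWHP was chosen over half-maximum because it is insensitive to
  baseline drift.
* **Periods**: first differences of successive peak times, in hours.
* **Response precision**: $1 - |w_\text{out} - w_\text{in}| /
  (w_\text{out} + w_\text{in})$ comparing the burst FWHP with the pulse
  ON duration. The absolute value keeps the score in $(0, 1]$ whichever
  width is larger (the printed formula would exceed 1 for narrow
  bursts). The pulse-response precision reported for the open-loop
  single-receptor experiment is measured on the burst evoked from the
  resting state by a 5-h pulse; later bursts in a running rhythm start
  from an elevated trough, are narrower, and score higher.
* **Phase drift**: per cycle, each community is assigned its peak
  nearest the cycle onset (within ± half a period); the drift is the
  standard deviation of assigned peak times across communities, as a
  percentage of the period, averaged over cycles with at least two
  assignments. SD across communities was chosen over range- or
  pairwise-based dispersion and is documented as such.
* **Sync fraction**: share of communities with exactly one in-window
  peak in ≥ 90% of cycles and mean absolute lag below a quarter period.
  `run_pipeline()` references lags to the ensemble-median burst lag so a
  common response delay is not scored as desynchronization.
* **ACF / PSD**: per-community autocorrelation with biased normalization
  (guaranteeing a positive-semidefinite sequence), averaged across
  communities; periodogram of the ensemble-mean trace, unwindowed,
  zero-padded to 4x length, one-sided and normalized so total power
  equals the input variance (Parseval is a test). The dominant period is
  the inverse of the maximal-power frequency, excluding the zero bin.
* **Doubling ratios**: median reporter period over the input period,
  snapped to {1, 2, 4, 8} when within 25% relative distance; raw values
  are retained and unsnappable ratios are flagged rather than forced.

## Dose-response fitting

`fit_hill()` fits the four-parameter Hill model by Levenberg-Marquardt
least squares with EC50 and slope parameterized on the log scale, started
from the data quartiles (extreme mean responses, geometric mid-range,
slope 1). Zero doses enter through the untransformed model, so no
logarithm of zero is ever taken. The EC50 standard error comes from the
Jacobian via the delta method. Data whose fitted dynamic range is below
three residual standard deviations raise a classed fit-failure error
instead of returning a silent estimate. Pooled fitting across replicates
is used (whether the printed EC50s came from pooled or per-replicate
fits is not recoverable; pooled is the documented choice).

## Numerical choices

* Promoter/noise: Euler-Maruyama at 1/120 h. Threshold crossing under
  discrete noise carries an $O(\sqrt{dt})$ bias; the refinement test
  compares switching rates at a step and a 10x finer step and documents
  a ~10% residual at 1/960 h. Metrics are dominated by drive-led
  crossings, which converge much faster.
* Reporter: explicit Euler at the same step (decay rate 0.38/h, so the
  step is ~1/300 of the fastest time constant).
* Ties: exact threshold hits never flip the switch; plateau peaks
  collapse to their first sample; ratios farther than 25% from any
  doubling target stay unsnapped.
* Degenerate inputs are rejected with classed errors (constant traces in
  `rescale01()`, non-commensurate sampling steps, ragged grids, missing
  channels, flat dose-response data), never silently repaired.

## What the generator does and does not emulate

It reproduces: 10-min sampling over up-to-72-h records, antiphase
rectangular chemistry with the published amplitudes, bursts with fast
activation and multi-hour decay lag, trap-to-trap parameter scatter,
noise-gated synchronization that deteriorates at slow rhythms and under
10-fold weaker driving, and toxin-induced period doubling.

It does not reproduce: absolute fluorescence scales, growth-stage trends
beyond a constant dilution, spatial structure inside a trap, the
closed-loop amplitude changes, the 2-h-cycle regime of the chemically
driven system (see above), or the *magnitude* of the fast-rhythm phase
drift (simulated ~10% at 4 h versus ~2% in the recordings — the discrete
switch has only one noise entry point, so timing jitter cannot be made
arbitrarily small without also removing the slow-rhythm chatter).
Passing tests therefore certify the metrics and the model's qualitative
structure, not quantitative agreement with any particular recording.

Metric-recovery checks consequently use *constructed* peak ensembles
whose dispersion is engineered to the printed drift and synchrony values
(46 communities × 10 cycles for drift, 100 × 12 for the locked
fraction), rather than simulator output: they validate the estimators at
exactly the published operating points. Test problem sizes (ensembles of
~14-46 communities, 40-100 h records, 200-fit calibration loops) were
chosen to keep the full suite in the minutes range on one CPU while
leaving Monte-Carlo standard errors well inside the asserted tolerances.

## Known limitations

* The $h(T)$ law is linear in rate and the OU noise is additive on the
  drive; both are stated modeling decisions, not reconstructions of an
  unpublished model.
* The toxin mechanism is one of several consistent with the observed
  doublings; its dose-response is not calibrated.
* `sync_fraction` is strict (90% cycle coverage): ensembles whose
  switching chatters lose coverage quickly, so the default simulated
  ensembles score low even when their surviving bursts are well aligned.
* Euler-Maruyama switching rates at the default step are biased high
  relative to a refined reference for purely noise-driven switching (see
  above); comparisons across parameter settings use a common step.
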