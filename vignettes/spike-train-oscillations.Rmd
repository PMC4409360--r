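---
title: "Quantifying oscillations in spike trains: model, estimator and corrections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying oscillations in spike trains: model, estimator and corrections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeosc)
```

## The problem

Single-unit spike trains reflect their underlying firing-rate rhythm only
stochastically: even a strongly oscillatory neuron skips most oscillation
cycles. When an oscillation is quantified by the height of a power-spectrum
peak in signal-to-noise-ratio (SNR) units, the result grows *linearly with
the firing rate* and with the *square root of the recording duration* — two
quantities that have nothing to do with how deeply the rate is modulated.
Comparisons across neurons, brain regions (e.g. pallidal segments with 45
vs 75 sp/s mean rates), behavioural states, or recordings of unequal length
are then confounded, and slow-firing oscillators can be undetectable
outright.

`spikeosc` implements an estimation pipeline whose target is the
*modulation index* `m` of the rate function itself — a quantity in `[0, 1]`
that does not depend on rate or duration — together with the simulation
machinery needed to calibrate it and a planner for how long one must record
to detect a given oscillation.

## Model

Spiking is modelled as an inhomogeneous Poisson process with rate

$$\lambda(t) = r_0\,\bigl(1 + m \cos(2\pi f_0 t)\bigr),$$

with baseline rate $r_0$ (sp/s), modulation index $0 \le m \le 1$ and
oscillation frequency $f_0$ (Hz). The power spectrum of a realisation of
duration $T$ has a closed form (`analytic_psd()`), which for large $T$
reduces to a flat baseline $S(f \ne f_0) = r_0$ and a peak

$$S(f_0) = r_0\Bigl(1 + \frac{r_0 T m^2}{4}\Bigr).$$

Both limits are exact whenever $f_0 T$ is an integer; the package evaluates
the full eight-term finite-$T$ expression, so no large-$T$ assumption is
hidden in the analytic route.

Inverting the peak relation gives the estimator at the package's core:

$$\hat m = 2\sqrt{\frac{\hat S(f_0) - \hat r_0}{\hat r_0^2\, T}},$$

with $\hat r_0 = N_{spikes}/T$. Negative excess power (no peak above
baseline) clamps $\hat m$ to 0; values above 1 clamp to 1 with a warning.

## Spectral estimation and the Welch correction

Spectra are estimated from 1-ms binned counts by Welch's method with
**non-overlapping 1000-bin Hamming windows** (1 Hz resolution, 500 Hz
Nyquist; `welch_psd()`). A trailing partial window is dropped. The SNR at
each frequency is the power minus the mean power of the **100–500 Hz noise
band**, divided by that band's standard deviation (`snr_spectrum()`); the
conventional detection rule declares a train oscillatory when the band peak
reaches 5 SD.

Welch peak values are not on the analytic scale: windows are short, and the
taper attenuates coherent line power. `welch_to_analytic()` applies, in
order, (i) the sampling-frequency scale factor $F_s/2$, (ii) the resolution
correction $P \cdot N_{wins} - (N_{wins}-1)\hat r_0$, and (iii) the taper
coherence factor $\overline{w}\,wl/(w'w)$. The package's internal PSD
convention (the one-sided density of the binned counts multiplied by $F_s$)
is chosen so this correction lands exactly on the analytic scale: the
corrected baseline of a homogeneous train estimates $r_0$ in sp/s. Broadband
power needs only step (i) (`baseline_power()`): the taper factor corrects
coherent lines, not incoherent power, which the $w'w$ normalisation already
handles.

Numerical points worth knowing:

* **DC leakage.** Counts are not mean-subtracted, so the rate's DC line is
  present and, under the Hamming taper, leaks into the 1–2 Hz bins. The DC
  bin is excluded from every peak search and noise statistic; searches
  should in addition start at 3 Hz or above. Beta-band searches are
  unaffected.
* **Taper attenuation of the raw SNR.** The Hamming window transmits only
  $(\sum w)^2 / (wl \cdot w'w) \approx 0.73$ of a spectral line's excess
  power relative to its noise normalisation. The Welch *correction* removes
  this for $\hat m$ (which is why $\hat m$ is unbiased), but the raw
  detection SNR — and therefore the analytic planner, which ignores the
  taper — runs about 25% above what a Hamming-windowed measurement
  delivers. `simulated_detection()` exists to check a plan empirically.
* **Bernoulli discretisation.** The 1-ms Bernoulli generator (below) has
  per-bin variance $p(1-p)$ rather than Poisson $p$, so measured noise
  floors sit a few percent below $r_0$ at high rates (3.5% at 30 sp/s).
  The same deficit afflicts any 1-ms-resolution simulation of this model;
  closed-form comparisons in the tests carry 5–10% tolerances for this
  reason, and $\hat m$ recovery stays within ±0.05 across 10–80 sp/s.
* **Ties** in a peak search resolve to the lower frequency, for
  determinism.

## The simulator

`generate_train()` draws each 1-ms bin as an independent Bernoulli event
with probability $\lambda(t)\,dt$ (rates up to 1000 sp/s are representable;
the model range of interest is ≤ 180 sp/s). Spike times sit at bin centres.
This per-bin scheme, rather than exact time-rescaling, is deliberate: it is
the standard discrete-time generator for this model, and the estimator is
calibrated against the spectra it produces.

An **absolute refractory period** sets the instantaneous rate to zero for
$\tau_{ref}$ after each accepted spike (dead time, not ISI rejection).
A **jittered oscillation** (`generate_jittered_train()`) lets the
instantaneous frequency perform a bounded random walk inside a band — one
uniform step of at most a quarter band width per cycle, reflected at the
edges — integrated into a continuous phase. The mechanism of real frequency
jitter is not observable from the data this package targets; this choice
produces an approximately 1 Hz-wide spectral peak like those seen in
pallidal recordings without phase discontinuities, and degenerates exactly
to the fixed-frequency generator when the band has zero width.

What the simulator does *not* emulate: bursting, relative refractoriness,
rate non-stationarity, spike-sorting contamination. Passing tests therefore
demonstrate correctness of the estimator under the stated point-process
model, not robustness to every property of real recordings.

## Significance and the refractory correction

The null distribution of $\hat m$ at a given rate and duration is obtained
by simulation: `significance_threshold()` runs the full pipeline on
homogeneous trains and returns the null mean plus two standard deviations.
Thresholds are computed at the train's own (rate, duration) — rounded to a
1-sp/s bin for caching — rather than interpolated from a table.

Refractoriness preferentially deletes spikes near the oscillation crest, so
the raw $\hat m$ *underestimates* the true modulation, increasingly so at
high rates. `correct_for_refractoriness()` inverts this numerically:
compute the Poisson-equivalent rate
$\hat r_p = N_{spikes}/(T - \tau_{ref} N_{spikes})$, then search for the
rate-function modulation $m_p$ whose forward simulation (100 refractory
trains per iteration by default) reproduces the observed $\hat m$. The
search is a bisection on $[\hat m, 1]$ with tolerance 0.01 and at most 20
iterations — the forward map is monotone in $m_p$, so bisection implements
the increase/decrease-and-repeat rule with guaranteed convergence. The peak
frequency is held at the uncorrected estimate for stability. If even
$m_p = 1$ cannot reproduce the observation the correction saturates and
says so. $\tau_{ref}$ can be supplied (recommended) or estimated from the
leading empty bins of the 1-ms ISI histogram (first bin exceeding 5% of the
modal count, minus one bin).

## Recording-duration planning

From the large-$T$ SNR $r_0 T m^2/4$ and the $\sqrt{N_{wins}}$ gain of
Welch averaging, the duration at which the predicted peak reaches a target
SNR is

$$\hat T = \frac{16\,SNR^2}{wl\, \hat r_0^2\, \hat m^4}.$$

E.g. `required_duration(plan_inputs(75, 0.25, 5))` gives 18.2 s — under
half a minute for a typical high-rate pallidal neuron — while the same
neuron needs 35.7 s for a 7-SD peak. (The prose rule of thumb "about a
minute" for the latter is a rounding-up; the formula and the curves it
generates are the normative output.) Because threshold crossing is
stochastic and the analytic form ignores the taper attenuation discussed
above, a recording of length $\hat T$ yields a *mean* peak SNR somewhat
below the target and roughly even odds of crossing it;
`simulated_detection()` reports both quantities for a candidate plan.

## Calibration choices in the test suite

Calibration simulations (parameter recovery, detection curves, null
calibration) read the spectral statistics **at the known oscillation
frequency** — the single 12-Hz bin — as one does when the generating
frequency is known; experimental-style assessment defaults to searching the
10–15 Hz beta band, the band of interest for Parkinsonian pallidal data.
Searching a band instead of the known bin inflates the null (a maximum over
exchangeable bins) and is the right null model for data whose frequency is
unknown; both routes use the identical `find_peak()` machinery. Note that
the null of $\hat m$ is not Gaussian — it is zero-inflated with a
right-skewed square-root tail — so the mean-plus-2-SD rule is only a
nominal significance level: over a band search it is conservative, while at
a single known bin it can fire at somewhat above 5% under the null.

Monte-Carlo problem sizes were chosen to resolve each effect comfortably on
a single CPU: 500 replicates for detection probabilities (binomial SE
≈ 2%), 200 per cell for functional-form fits, 100 per cell for the 16-cell
recovery grid at $T = 300$ s, 12 outer replicates × 40 trains per bisection
iteration for the refractory correction (the corrected index's SD is ≈
0.02, so the mean is determined to well under the ±0.07 check).

## Known limitations

* The estimator assumes a single cosine component; multi-peaked or
  broadband rhythms are outside the model.
* When refractoriness suppresses the peak entirely ($\hat m = 0$), the
  correction has nothing to invert; ISI-shuffling approaches are the
  remedy, and are out of scope here.
* The planner inherits the large-$T$ simplification and the taper optimism
  noted above; treat $\hat T$ as a lower bound and verify by simulation.
* Bernoulli binning caps representable rates at $1/dt$ and slightly
  depresses noise floors at rates approaching ~100 sp/s.
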