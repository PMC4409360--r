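# spikeosc

Detection and quantification of oscillations in single-unit spike trains.

## The problem

Oscillatory neuronal activity — beta-band rhythms in the Parkinsonian basal
ganglia being the canonical example — is usually quantified from a spike
train's power spectrum: the height of the spectral peak in
signal-to-noise-ratio (SNR) units, measured against the 100–500 Hz noise
band. That statistic is severely biased. For a neuron whose firing rate
r₀ is modulated as

    λ(t) = r₀ · (1 + m · cos(2π f₀ t)),      0 ≤ m ≤ 1,

the expected spectral peak of a recording of duration T is

    S(f₀) = r₀ · (1 + r₀ T m² / 4),    S(f ≠ f₀) = r₀,

so the peak SNR grows **linearly with the firing rate** and with **√T** —
two quantities unrelated to how strongly the rate is actually modulated.
Slow-firing oscillators go undetected, and comparisons across neurons,
regions or recording lengths are confounded.

`spikeosc` implements the remedy: invert the peak-power relation to
estimate the **modulation index**

    m̂ = 2 · √( (Ŝ(f₀) − r̂₀) / (r̂₀² T) ),

a rate- and duration-free measure of oscillation strength, together with

* an inhomogeneous-Poisson spike-train simulator (1-ms Bernoulli thinning,
  optional absolute refractory period and frequency jitter),
* Welch spectra of binned trains (non-overlapping 1000-bin Hamming
  windows) with the correction that maps Welch peaks onto the analytic
  scale,
* Monte-Carlo significance thresholds (null mean + 2 SD at matched rate
  and duration),
* an iterative correction for the downward bias that an absolute
  refractory period inflicts on m̂,
* an analytic planner for the recording duration needed to detect an
  oscillation at a target SNR: T̂ = 16·SNR² / (wl · r̂₀² · m̂⁴).

## Worked example

```r
library(spikeosc)

# a 5-minute recording of a 60 sp/s neuron, 12-Hz oscillation, m = 0.5
train <- generate_train(osc_params(r0 = 60, m = 0.5, f0 = 12), T = 300,
                        seed = 82)

res <- assess(train, f_band = c(10, 15),
              config = run_config(n_null = 300, seed = 83))
res
#> Modulation-index assessment (T = 300 s):
#>   baseline rate r0_hat: 60.03 sp/s
#>   peak frequency:       12 Hz (SNR 48.42)
#>   modulation index:     0.484  (null threshold 0.091 -> significant)
```

`r0_hat` is the mean firing rate; the 12-Hz peak is 48 noise-band
standard deviations high; and the estimated modulation index 0.484
recovers the generator's `m = 0.5` to within Monte-Carlo noise. The null
threshold (0.091) is the mean + 2 SD of the index obtained from 300
unmodulated trains at the same rate and duration. For the same neuron, a plain SNR rule would have failed at
low rates: at 16 sp/s and one minute the spectral peak clears 5 SD in only
a minority of recordings, while the modulation index remains detectable.

How long must one record to detect a typical high-rate pallidal neuron
(75 sp/s, m ≈ 0.25) at 5 SD with 1-s Welch windows?

```r
required_duration(plan_inputs(r0_hat = 75, m_hat = 0.25, target_snr = 5))
#> [1] 18.20444     # seconds — under half a minute
```

Spike trains with a refractory period underestimate m̂; the correction
recovers the rate function's true modulation:

```r
tr <- generate_train(osc_params(60, 0.5, 12, tau_ref = 0.002), 300, seed = 101)
r  <- assess(tr, f_band = c(12, 12), config = run_config(n_null = 0))
r$m_hat
#> [1] 0.4077822    # biased low by the 2-ms refractory period
correct_for_refractoriness(tr, r, refractory_model(0.002), seed = 1,
                           config = run_config(n_null = 0))
#> [1] 0.4818094    # corrected
```

A thin command-line interface with subcommands
`simulate | psd | snr | modindex | plan | batch` is installed at
`system.file("cli", "spikeosc", package = "spikeosc")`.

## References

The estimator, corrections and planner implemented here follow the
spike-train oscillation-quantification methodology developed for
Parkinsonian basal-ganglia recordings; see the package vignette
(`vignettes/spike-train-oscillations.Rmd`) for the model, its assumptions
and the package's design choices.
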