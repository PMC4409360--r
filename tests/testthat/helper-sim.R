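# Shared simulation helpers for the test suite.
#
# Calibration simulations extract the spectral peak at the known oscillation
# frequency (single 12-Hz bin) unless a wider band is asked for; experimental
# style searches use the beta band c(10, 15).

pipe_stats <- function(tr, band = c(12, 12), wl = 1000, dt = 0.001,
                       window = "hamming", noise_band = c(100, 500)) {
  spikeosc:::pipeline_once(tr, band, wl, dt, window, noise_band)
}

# Per-rep peak SNR and modulation index for `reps` simulated trains.
rep_stats <- function(r0, m, T, reps, seed, band = c(12, 12), f0 = 12,
                      tau_ref = 0, wl = 1000) {
  set.seed(seed)
  pars <- osc_params(r0, m, f0, tau_ref = tau_ref)
  vals <- replicate(reps, {
    out <- pipe_stats(generate_train(pars, T), band, wl = wl)
    c(out$peak_snr, out$m_hat, out$peak_power)
  })
  list(snr = vals[1, ], m_hat = vals[2, ], peak = vals[3, ])
}

r_squared <- function(fit) summary(fit)$r.squared
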