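#' Welch power spectrum of a binned spike train
#'
#' Estimates the power spectral density of a binned spike train by Welch's
#' method with non-overlapping segments: the count vector is split into
#' `floor(n_bins/wl)` segments of `wl` bins (a trailing partial segment is
#' discarded), each segment is tapered and its one-sided periodogram
#' computed, and the per-segment periodograms are averaged. Defaults follow
#' standard practice for 1-ms binned spike trains: 1000-bin Hamming segments,
#' giving 1 Hz resolution up to a 500 Hz Nyquist frequency.
#'
#' The PSD is scaled so that, after the peak correction of
#' [welch_to_analytic()] (or the broadband scaling of [baseline_power()]), the
#' values land on the analytic spectrum of the underlying point process, whose
#' flat baseline equals the rate `r0` in spikes/s. Counts are not
#' mean-subtracted: the rate's DC structure belongs to the model, and mean
#' subtraction would only alter the excluded f = 0 bin (and leak under
#' tapering). The DC bin is excluded from all downstream peak searches and
#' noise statistics.
#'
#' @param binned A [bin_train()] result.
#' @param wl Segment (window) length in bins (default 1000).
#' @param window Taper name: `"hamming"` (default), `"hann"` or
#'   `"rectangular"`.
#' @return An object of class `power_spectrum`: `freqs` (Hz), `power`, `Fs`,
#'   `wl`, `n_wins`, `window` (the taper vector) and `window_name`.
#' @seealso [snr_spectrum()], [welch_to_analytic()], [analytic_psd()]
#' @export
welch_psd <- function(binned, wl = 1000, window = "hamming") {
  stopifnot(inherits(binned, "binned_train"))
  stopifnot_scalar(wl, "wl", positive = TRUE)
  wl <- as.integer(wl)
  x <- binned$counts
  n_wins <- length(x) %/% wl
  if (n_wins < 1L)
    stop(sprintf("insufficient data: %d bins < one %d-bin window",
                 length(x), wl), call. = FALSE)
  w <- make_window(window, wl)
  seg <- matrix(x[seq_len(n_wins * wl)], nrow = wl, ncol = n_wins)
  ft <- stats::mvfft(seg * w)
  nfreq <- wl %/% 2L + 1L
  pw <- Mod(ft[seq_len(nfreq), , drop = FALSE])^2
  power <- 2 * rowMeans(pw) / sum(w * w)
  power[1L] <- power[1L] / 2            # DC not doubled
  if (wl %% 2L == 0L) power[nfreq] <- power[nfreq] / 2  # Nyquist not doubled
  structure(
    list(freqs = (seq_len(nfreq) - 1) * binned$Fs / wl, power = power,
         Fs = binned$Fs, wl = wl, n_wins = n_wins, window = w,
         window_name = window),
    class = "power_spectrum"
  )
}

make_window <- function(name, wl) {
  switch(name,
    hamming = as.numeric(signal::hamming(wl)),
    hann = ,
    hanning = as.numeric(signal::hanning(wl)),
    rectangular = ,
    boxcar = rep(1, wl),
    stop(sprintf("unknown window '%s'", name), call. = FALSE)
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf(
    "Welch power spectrum: %d freqs (0-%g Hz, %g Hz resolution), %d x %d-bin %s windows\n",
    length(x$freqs), max(x$freqs), x$Fs / x$wl, x$n_wins, x$wl, x$window_name))
  invisible(x)
}

#' Closed-form spectrum of a finite oscillatory Poisson process
#'
#' Evaluates the exact power spectrum of an inhomogeneous Poisson process
#' with cosine-modulated rate observed for a finite duration `T`:
#' \deqn{S(f) = r_0 + r_0 m\,\mathrm{sinc}(2 f_0 T)
#'   + r_0^2 T\,\mathrm{sinc}^2(f T)
#'   + r_0^2 T m\,\mathrm{sinc}(f T)\,\mathrm{sinc}((f - f_0) T)
#'   + r_0^2 T m\,\mathrm{sinc}(f T)\,\mathrm{sinc}((f + f_0) T)}
#' \deqn{\quad + \tfrac{r_0^2 T m^2}{4}\,\mathrm{sinc}^2((f - f_0) T)
#'   + \tfrac{r_0^2 T m^2}{4}\,\mathrm{sinc}^2((f + f_0) T)
#'   + \tfrac{r_0^2 T m^2}{2}\,\mathrm{sinc}((f - f_0) T)\,
#'     \mathrm{sinc}((f + f_0) T)}
#' with \eqn{\mathrm{sinc}(x) = \sin(\pi x)/(\pi x)}. For large `T` this
#' simplifies to the peak value \eqn{r_0 (1 + r_0 T m^2 / 4)} at \eqn{f = f_0}
#' and the flat baseline \eqn{r_0} everywhere else. No large-`T`
#' simplification is applied here; all eight terms are evaluated.
#'
#' The formula assumes a pure Poisson process; `tau_ref > 0` is rejected.
#'
#' @param params An [osc_params()] object with `tau_ref = 0`.
#' @param T Observation duration in seconds.
#' @param freqs Frequencies (Hz) at which to evaluate.
#' @return Numeric vector of power values (same units as the rate, sp/s).
#' @examples
#' p <- osc_params(r0 = 5, m = 0.5, f0 = 12)
#' analytic_psd(p, T = 300, freqs = 12)  # 5 * (1 + 5*300*0.25/4) = 473.75
#' @export
analytic_psd <- function(params, T, freqs) {
  stopifnot(inherits(params, "osc_params"))
  if (params$tau_ref > 0)
    stop("analytic spectrum is unsupported for tau_ref > 0 (non-Poisson model)",
         call. = FALSE)
  stopifnot_scalar(T, "T", positive = TRUE)
  r0 <- params$r0; m <- params$m; f0 <- params$f0; f <- freqs
  sm <- sinc((f - f0) * T)
  sp <- sinc((f + f0) * T)
  s0 <- sinc(f * T)
  r0 + r0 * m * sinc(2 * f0 * T) +
    r0^2 * T * (s0^2 + m * s0 * sm + m * s0 * sp +
                  (m^2 / 4) * sm^2 + (m^2 / 4) * sp^2 + (m^2 / 2) * sm * sp)
}

#' SNR spectrum relative to a high-frequency noise band
#'
#' Normalises a power spectrum to signal-to-noise-ratio units: for each
#' frequency, the power minus the mean power of the noise band, in units of
#' the noise band's standard deviation. The 100-500 Hz band of a 1-ms binned
#' spike train contains no oscillatory structure of interest and serves as
#' the noise baseline; both endpoints are inclusive.
#'
#' @param ps A [welch_psd()] result.
#' @param noise_band Length-2 numeric, Hz (default `c(100, 500)`).
#' @return An object of class `snr_spectrum`: `freqs`, `snr`, `noise_band`,
#'   `noise_mean`, `noise_sd`.
#' @export
snr_spectrum <- function(ps, noise_band = c(100, 500)) {
  stopifnot(inherits(ps, "power_spectrum"), length(noise_band) == 2L)
  idx <- ps$freqs >= noise_band[1] & ps$freqs <= noise_band[2] & ps$freqs > 0
  if (sum(idx) < 10L)
    stop("noise band covers fewer than 10 frequency bins", call. = FALSE)
  noise_mean <- mean(ps$power[idx])
  noise_sd <- stats::sd(ps$power[idx])
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop(sprintf(
      "degenerate noise band: zero variance over %g-%g Hz (mean power %g); SNR undefined",
      noise_band[1], noise_band[2], noise_mean), call. = FALSE)
  structure(
    list(freqs = ps$freqs, snr = (ps$power - noise_mean) / noise_sd,
         noise_band = noise_band, noise_mean = noise_mean,
         noise_sd = noise_sd),
    class = "snr_spectrum"
  )
}

#' Locate the strongest spectral peak within a band
#'
#' Finds the frequency of maximal SNR within `band` (DC excluded; ties broken
#' toward the lower frequency) and reports its power on the analytic scale
#' via [welch_to_analytic()].
#'
#' @param snr A [snr_spectrum()] result.
#' @param ps The matching [welch_psd()] result.
#' @param band Length-2 numeric search band in Hz (must exclude 0).
#' @param r0_hat Estimated baseline rate in sp/s (see [estimate_rate()]),
#'   used by the Welch-to-analytic correction.
#' @return An object of class `spectral_peak`: `f_peak` (Hz), `peak_power`
#'   (analytic scale), `peak_snr` (SD units), `band`.
#' @export
find_peak <- function(snr, ps, band, r0_hat) {
  stopifnot(inherits(snr, "snr_spectrum"), inherits(ps, "power_spectrum"),
            length(band) == 2L)
  idx <- which(snr$freqs >= band[1] & snr$freqs <= band[2] & snr$freqs > 0)
  if (!length(idx))
    stop(sprintf("empty search band %g-%g Hz", band[1], band[2]),
         call. = FALSE)
  k <- idx[which.max(snr$snr[idx])]  # which.max -> first max = lowest freq
  structure(
    list(f_peak = snr$freqs[k],
         peak_power = welch_to_analytic(ps$power[k], ps, r0_hat),
         peak_snr = snr$snr[k], band = band),
    class = "spectral_peak"
  )
}

#' Map a Welch-estimated peak onto the analytic spectrum scale
#'
#' Welch's method estimates the spectrum from short, tapered segments; its
#' peak values are not directly comparable to the closed-form spectrum of
#' the whole recording ([analytic_psd()]). Three corrections, applied in
#' order, make them comparable: (1) scale the Welch power by the sampling
#' frequency and divide by 2; (2) undo the coarser spectral resolution by
#' multiplying by the number of windows and subtracting the baseline power
#' times (number of windows minus 1); (3) undo the taper's attenuation of
#' coherent line power by the factor `mean(w) * wl / (w'w)`, where `w'w` is
#' the sum of squared taper values:
#' \deqn{P_{analytic} = [(P_{Welch} \cdot F_s / 2) N_{wins}
#'   - (N_{wins} - 1)\, \hat r_0] \cdot
#'   \frac{\overline{w}\, wl}{w'w}}
#'
#' A non-positive result (no excess peak power) is passed through unclamped;
#' clamping is the modulation-index estimator's responsibility.
#'
#' @param peak_welch Welch power value at the peak frequency.
#' @param ps The [welch_psd()] result carrying `Fs`, `n_wins` and the taper.
#' @param r0_hat Estimated baseline rate, sp/s.
#' @return Peak power on the analytic scale (comparable to [analytic_psd()]).
#' @export
welch_to_analytic <- function(peak_welch, ps, r0_hat) {
  stopifnot(inherits(ps, "power_spectrum"))
  if (ps$n_wins < 1L) stop("n_wins must be >= 1", call. = FALSE)
  w <- ps$window
  ((peak_welch * ps$Fs / 2) * ps$n_wins - (ps$n_wins - 1) * r0_hat) *
    (mean(w) * ps$wl / sum(w * w))
}

#' Broadband Welch power on the analytic scale
#'
#' Maps the mean Welch power over a band onto the analytic spectrum scale.
#' Incoherent (broadband) power needs only the `Fs/2` scale factor: the
#' taper-coherence correction of [welch_to_analytic()] applies to spectral
#' lines, and the resolution correction leaves a flat baseline unchanged.
#' For a homogeneous Poisson train the result estimates the rate `r0`.
#'
#' @param ps A [welch_psd()] result.
#' @param band Length-2 numeric band in Hz (default the 100-500 Hz noise
#'   band).
#' @return Mean band power on the analytic scale (sp/s).
#' @export
baseline_power <- function(ps, band = c(100, 500)) {
  stopifnot(inherits(ps, "power_spectrum"), length(band) == 2L)
  idx <- ps$freqs >= band[1] & ps$freqs <= band[2] & ps$freqs > 0
  if (!any(idx)) stop("band contains no frequency bins", call. = FALSE)
  mean(ps$power[idx]) * ps$Fs / 2
}

#' Estimate the baseline firing rate of a spike train
#'
#' @param train A [spike_train()].
#' @return `n_spikes / T` in sp/s (0 for an empty train).
#' @export
estimate_rate <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  if (train$T <= 0) stop("train duration must be > 0", call. = FALSE)
  train$n_spikes / train$T
}
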