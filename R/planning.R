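#' Analytic SNR of a finite oscillatory Poisson spike train
#'
#' The analytic counterpart of the empirical spectral SNR: the power of the
#' rate function's Fourier transform at `f0`, relative to the expected spike
#' count. The full finite-duration expression is
#' \deqn{SNR(f_0) = \frac{r_0^2 T^2 [\mathrm{sinc}^2(f_0 T)
#'   + m\,\mathrm{sinc}(f_0 T) + m\,\mathrm{sinc}(f_0 T)\mathrm{sinc}(2 f_0 T)
#'   + m^2/4 + (m^2/4)\mathrm{sinc}^2(2 f_0 T)
#'   + (m^2/2)\mathrm{sinc}(2 f_0 T)]}
#'   {r_0 T [1 + m\,\mathrm{sinc}(2 f_0 T)]}}
#' which converges, for large `T`, to the simple form
#' \deqn{SNR(f_0) = r_0 T m^2 / 4.}
#'
#' @param params An [osc_params()] object.
#' @param T Duration in seconds.
#' @param simplified If `TRUE`, return the large-`T` form `r0*T*m^2/4`.
#' @return The analytic SNR (dimensionless).
#' @examples
#' p <- osc_params(40, 0.25, 12)
#' analytic_snr(p, 60, simplified = TRUE)  # 40*60*0.0625/4 = 37.5
#' @export
analytic_snr <- function(params, T, simplified = FALSE) {
  stopifnot(inherits(params, "osc_params"))
  stopifnot_scalar(T, "T", positive = TRUE)
  r0 <- params$r0; m <- params$m; f0 <- params$f0
  if (simplified) return(r0 * T * m^2 / 4)
  s1 <- sinc(f0 * T)
  s2 <- sinc(2 * f0 * T)
  num <- r0^2 * T^2 *
    (s1^2 + m * s1 + m * s1 * s2 + m^2 / 4 + (m^2 / 4) * s2^2 +
       (m^2 / 2) * s2)
  den <- r0 * T * (1 + m * s2)
  num / den
}

#' Recording-plan inputs
#'
#' Bundles the quantities a planner needs: the (grossly estimated) baseline
#' rate and modulation index — obtainable from a few short preliminary
#' recordings — the target SNR for peak detection, the Welch window length in
#' seconds, and the oscillation frequency.
#'
#' @param r0_hat Baseline rate, sp/s (> 0).
#' @param m_hat Modulation index in \[0, 1\].
#' @param target_snr Required SNR in SD units (default 5).
#' @param wl_s Welch window length in seconds (default 1, i.e. 1 Hz
#'   resolution at 1-ms binning).
#' @param f0 Oscillation frequency in Hz (default 12), used for exact
#'   finite-duration evaluations.
#' @return An object of class `plan_inputs`.
#' @export
plan_inputs <- function(r0_hat, m_hat, target_snr = 5, wl_s = 1, f0 = 12) {
  stopifnot_scalar(r0_hat, "r0_hat", positive = TRUE)
  stopifnot_scalar(m_hat, "m_hat", nonneg = TRUE)
  if (m_hat > 1) stop("`m_hat` must be <= 1", call. = FALSE)
  stopifnot_scalar(target_snr, "target_snr", positive = TRUE)
  stopifnot_scalar(wl_s, "wl_s", positive = TRUE)
  stopifnot_scalar(f0, "f0", positive = TRUE)
  structure(list(r0_hat = r0_hat, m_hat = m_hat, target_snr = target_snr,
                 wl_s = wl_s, f0 = f0),
            class = "plan_inputs")
}

#' Predicted Welch-spectrum peak SNR
#'
#' With Welch's method the spectrum is averaged over `N_wins = T / wl`
#' non-overlapping windows, which shrinks the noise floor's standard
#' deviation by `sqrt(N_wins)`: the peak SNR is the single-window SNR
#' (`r0 * wl * m^2 / 4`, the large-`T` analytic form evaluated at the window
#' length) multiplied by `sqrt(T / wl)`.
#'
#' @param plan A [plan_inputs()] object.
#' @param T Total recording duration, seconds (must be >= `plan$wl_s`).
#' @return Predicted peak SNR in SD units.
#' @export
predicted_welch_snr <- function(plan, T) {
  stopifnot(inherits(plan, "plan_inputs"))
  stopifnot_scalar(T, "T", positive = TRUE)
  if (T < plan$wl_s)
    stop("recording duration shorter than one Welch window", call. = FALSE)
  (plan$r0_hat * plan$wl_s * plan$m_hat^2 / 4) * sqrt(T / plan$wl_s)
}

#' Recording duration required to detect an oscillation
#'
#' Inverts the predicted Welch SNR for the total duration at which the peak
#' reaches `target_snr`:
#' \deqn{\hat T = \frac{16\, SNR^2}{wl\, \hat r_0^2\, \hat m^4}}
#' The required duration falls with the square of the firing rate and the
#' fourth power of the modulation index, and grows with the square of the
#' target SNR. For example, a pallidal neuron firing at 75 sp/s with a
#' modulation index of 0.25 needs about 18 s — under half a minute — for a
#' 5-SD peak (1-s windows).
#'
#' With `m_hat = 0` there is no oscillation to detect; `Inf` is returned
#' (an "undetectable" verdict, not an error).
#'
#' @param plan A [plan_inputs()] object.
#' @return Required duration `T_hat` in seconds (`Inf` when `m_hat = 0`).
#' @examples
#' required_duration(plan_inputs(75, 0.25, target_snr = 5))  # ~18.2 s
#' @export
required_duration <- function(plan) {
  stopifnot(inherits(plan, "plan_inputs"))
  if (plan$m_hat == 0) return(Inf)
  16 * plan$target_snr^2 / (plan$wl_s * plan$r0_hat^2 * plan$m_hat^4)
}

#' Simulated detection probability at a planned duration
#'
#' The SNR-threshold crossing is stochastic, so the analytic duration of
#' [required_duration()] yields roughly 50% detection at the target SNR.
#' This helper verifies a plan by simulation: it generates `reps` oscillatory
#' trains of duration `T`, runs the Welch/SNR pipeline, and reports the mean
#' peak SNR and the fraction crossing the target.
#'
#' @param plan A [plan_inputs()] object.
#' @param T Recording duration in seconds (default:
#'   [required_duration()] of the plan, rounded up to a whole window).
#' @param reps Number of simulated trains (default 200).
#' @param seed Optional integer seed.
#' @param f_band Peak search band in Hz (default `c(10, 15)`).
#' @param wl,dt,window,noise_band Spectral settings as in [welch_psd()] /
#'   [snr_spectrum()].
#' @return A list: `T`, `mean_peak_snr`, `detection` (fraction with peak SNR
#'   >= target), `peak_snr` (per-rep values).
#' @export
simulated_detection <- function(plan, T = NULL, reps = 200, seed = NULL,
                                f_band = c(10, 15), wl = 1000, dt = 0.001,
                                window = "hamming",
                                noise_band = c(100, 500)) {
  stopifnot(inherits(plan, "plan_inputs"))
  if (is.null(T)) {
    T <- required_duration(plan)
    if (!is.finite(T)) stop("plan is undetectable (m_hat = 0)", call. = FALSE)
    T <- ceiling(T / plan$wl_s) * plan$wl_s
  }
  pars <- osc_params(plan$r0_hat, plan$m_hat, plan$f0)
  snrs <- with_seed(seed, vapply(seq_len(reps), function(i) {
    tr <- generate_train(pars, T, dt = dt)
    pipeline_once(tr, f_band, wl, dt, window, noise_band)$peak_snr
  }, numeric(1)))
  list(T = T, mean_peak_snr = mean(snrs),
       detection = mean(snrs >= plan$target_snr), peak_snr = snrs)
}
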