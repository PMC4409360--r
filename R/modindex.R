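#' Modulation index from peak power, rate and duration
#'
#' Inverts the large-`T` peak-power relation
#' \eqn{S(f_0) = r_0 (1 + r_0 T m^2 / 4)} to estimate the modulation index of
#' the underlying rate function:
#' \deqn{\hat m = 2 \sqrt{\frac{\hat S(f_0) - \hat r_0}{\hat r_0^2\, T}}}
#' Unlike the spectral SNR, this estimate does not grow with the firing rate
#' or the recording duration, so it can be compared across neurons, brain
#' regions and recordings of different lengths.
#'
#' When the peak power does not exceed the baseline (`peak_analytic <=
#' r0_hat`) there is no evidence of modulation and the index is clamped to 0;
#' values above 1 (not attainable by a nonnegative rate function) are clamped
#' to 1 with a warning.
#'
#' @param peak_analytic Peak power on the analytic scale (see
#'   [welch_to_analytic()]).
#' @param r0_hat Estimated baseline rate, sp/s (> 0).
#' @param T Recording duration, seconds (> 0).
#' @return The modulation index estimate in \[0, 1\].
#' @examples
#' modulation_index(560, r0_hat = 20, T = 60)  # 0.3
#' @export
modulation_index <- function(peak_analytic, r0_hat, T) {
  stopifnot_scalar(peak_analytic, "peak_analytic")
  stopifnot_scalar(r0_hat, "r0_hat", positive = TRUE)
  stopifnot_scalar(T, "T", positive = TRUE)
  excess <- peak_analytic - r0_hat
  if (excess <= 0) return(0)
  m_hat <- 2 * sqrt(excess / (r0_hat^2 * T))
  if (m_hat > 1) {
    warning(sprintf("modulation index %.3g exceeds 1; clamping", m_hat),
            call. = FALSE)
    m_hat <- 1
  }
  m_hat
}

# Shared cache for Monte-Carlo null thresholds (keyed on all inputs).
.threshold_cache <- new.env(parent = emptyenv())

# One pass of the estimation pipeline on a train: Welch -> SNR -> band peak ->
# analytic-scale correction -> modulation index. Returns peak info + m_hat.
pipeline_once <- function(train, f_band, wl, dt, window, noise_band) {
  r0_hat <- estimate_rate(train)
  ps <- welch_psd(bin_train(train, dt), wl = wl, window = window)
  sn <- snr_spectrum(ps, noise_band)
  pk <- find_peak(sn, ps, f_band, r0_hat)
  m_hat <- if (r0_hat > 0)
    suppressWarnings(modulation_index(pk$peak_power, r0_hat, train$T)) else 0
  list(r0_hat = r0_hat, f_peak = pk$f_peak, peak_power = pk$peak_power,
       peak_snr = pk$peak_snr, m_hat = m_hat)
}

#' Monte-Carlo significance threshold for the modulation index
#'
#' The null distribution of the modulation index at a given firing rate and
#' duration is obtained by simulating `n_sim` homogeneous (unmodulated)
#' Poisson trains at rate `r0_hat` for duration `T` and running the full
#' estimation pipeline (Welch spectrum, peak search in `f_band`,
#' Welch-to-analytic correction, index inversion) on each. The significance
#' threshold is the null mean plus two standard deviations. Results are
#' cached, keyed on all arguments, so batch analyses sharing a rate bin and
#' duration compute each threshold once.
#'
#' @param r0_hat Baseline rate for the null simulations, sp/s.
#' @param T Duration in seconds.
#' @param f_band Peak search band, Hz.
#' @param n_sim Number of null trains (>= 100 recommended; default 1000).
#' @param seed Optional integer seed for reproducible thresholds.
#' @param wl,dt,window,noise_band Spectral settings (defaults: 1000-bin
#'   Hamming windows on 1-ms bins, 100-500 Hz noise band).
#' @return The threshold (numeric scalar) with attributes `null_mean`,
#'   `null_sd` and `n_sim`.
#' @export
significance_threshold <- function(r0_hat, T, f_band = c(10, 15),
                                   n_sim = 1000, seed = NULL, wl = 1000,
                                   dt = 0.001, window = "hamming",
                                   noise_band = c(100, 500)) {
  stopifnot_scalar(r0_hat, "r0_hat", positive = TRUE)
  stopifnot_scalar(T, "T", positive = TRUE)
  key <- paste(r0_hat, T, paste(f_band, collapse = "-"), n_sim,
               if (is.null(seed)) "NULL" else seed, wl, dt, window,
               paste(noise_band, collapse = "-"), sep = "|")
  if (!is.null(seed) && !is.null(.threshold_cache[[key]]))
    return(.threshold_cache[[key]])
  pars <- osc_params(r0 = r0_hat, m = 0)
  m_null <- with_seed(seed, vapply(seq_len(n_sim), function(i) {
    tr <- generate_train(pars, T)
    pipeline_once(tr, f_band, wl, dt, window, noise_band)$m_hat
  }, numeric(1)))
  thr <- mean(m_null) + 2 * stats::sd(m_null)
  attr(thr, "null_mean") <- mean(m_null)
  attr(thr, "null_sd") <- stats::sd(m_null)
  attr(thr, "n_sim") <- n_sim
  if (!is.null(seed)) .threshold_cache[[key]] <- thr
  thr
}

#' Assess the oscillatory modulation of a spike train
#'
#' Runs the full modulation-index pipeline on one spike train: estimate the
#' baseline rate, compute the Welch spectrum and its SNR, locate the
#' strongest peak in `f_band`, map the peak onto the analytic scale, invert
#' for the modulation index, and (unless `config$n_null == 0`) compare it to
#' the Monte-Carlo null threshold at the train's own rate and duration. For
#' threshold caching across units, the null simulations use the rate rounded
#' to the nearest 1 sp/s.
#'
#' @param train A [spike_train()].
#' @param f_band Search band in Hz (default `config$search_band`).
#' @param config A [run_config()] (spectral settings, null-simulation size,
#'   seed, SNR detection threshold).
#' @return An object of class `mod_index_result`: `r0_hat`, `f_peak`,
#'   `m_hat`, `threshold`, `significant` (`m_hat > threshold`), `peak_snr`,
#'   `snr_significant` (`peak_snr >= config$snr_threshold`), `m_p_hat` and
#'   `tau_ref` (NA until [correct_for_refractoriness()] is applied), `T`.
#' @examples
#' tr <- generate_train(osc_params(60, 0.5, 12), T = 60, seed = 1)
#' res <- assess(tr, config = run_config(n_null = 100, seed = 2))
#' res$m_hat
#' @export
assess <- function(train, f_band = NULL, config = run_config()) {
  stopifnot(inherits(train, "spike_train"))
  if (is.null(f_band)) f_band <- config$search_band
  out <- pipeline_once(train, f_band, config$wl, config$bin_dt,
                       config$window_name, config$noise_band)
  threshold <- NA_real_
  significant <- NA
  if (config$n_null > 0 && out$r0_hat > 0) {
    r0_bin <- max(1, round(out$r0_hat))
    threshold <- as.numeric(
      significance_threshold(r0_bin, train$T, f_band, n_sim = config$n_null,
                             seed = config$seed, wl = config$wl,
                             dt = config$bin_dt, window = config$window_name,
                             noise_band = config$noise_band))
    significant <- out$m_hat > threshold
  }
  structure(
    list(r0_hat = out$r0_hat, f_peak = out$f_peak, m_hat = out$m_hat,
         threshold = threshold, significant = significant,
         peak_snr = out$peak_snr,
         snr_significant = out$peak_snr >= config$snr_threshold,
         m_p_hat = NA_real_, tau_ref = NA_real_, T = train$T),
    class = "mod_index_result"
  )
}

#' @export
print.mod_index_result <- function(x, ...) {
  cat(sprintf("Modulation-index assessment (T = %g s):\n", x$T))
  cat(sprintf("  baseline rate r0_hat: %.2f sp/s\n", x$r0_hat))
  cat(sprintf("  peak frequency:       %g Hz (SNR %.2f)\n",
              x$f_peak, x$peak_snr))
  cat(sprintf("  modulation index:     %.3f", x$m_hat))
  if (!is.na(x$threshold))
    cat(sprintf("  (null threshold %.3f -> %s)", x$threshold,
                if (isTRUE(x$significant)) "significant" else "not significant"))
  cat("\n")
  if (!is.na(x$m_p_hat))
    cat(sprintf("  refractory-corrected: %.3f (tau_ref = %g ms)\n",
                x$m_p_hat, 1000 * x$tau_ref))
  invisible(x)
}

#' Poisson-equivalent firing rate of a refractory spike train
#'
#' An absolute refractory period removes `tau_ref` seconds of firing
#' opportunity after every spike, so the observed rate underestimates the
#' rate of the driving Poisson process. The rate a refractory-free Poisson
#' process would need to produce the observed count is
#' \deqn{\hat r_p = N_{spikes} / (T - \tau_{ref} N_{spikes})}
#'
#' @param train A [spike_train()].
#' @param tau_ref Absolute refractory period in seconds.
#' @return `r_p_hat` in sp/s (always >= the observed rate `n_spikes/T`).
#' @examples
#' tr <- spike_train(seq(0.01, 59.99, length.out = 3000), T = 60)
#' poisson_equivalent_rate(tr, 0.002)  # 3000/54 = 55.56 sp/s
#' @export
poisson_equivalent_rate <- function(train, tau_ref) {
  stopifnot(inherits(train, "spike_train"))
  stopifnot_scalar(tau_ref, "tau_ref", nonneg = TRUE)
  denom <- train$T - tau_ref * train$n_spikes
  if (denom <= 0)
    stop("degenerate input: refractory dead time >= recording duration",
         call. = FALSE)
  train$n_spikes / denom
}

#' Estimate the absolute refractory period from the ISI histogram
#'
#' The dead time appears as empty leading bins of the inter-spike-interval
#' histogram. Using 1-ms right-closed bins, the estimate is one bin less than
#' the first bin whose count exceeds 5% of the modal bin count. An explicit
#' `override` (seconds) always wins and is recommended when the refractory
#' period is known from the recording setup.
#'
#' @param train A [spike_train()] with at least 100 ISIs.
#' @param dt Histogram bin width in seconds (default 0.001).
#' @param override Optional known refractory period in seconds.
#' @return Estimated `tau_ref` in seconds.
#' @export
estimate_tau_ref <- function(train, dt = 0.001, override = NULL) {
  if (!is.null(override)) {
    stopifnot_scalar(override, "override", nonneg = TRUE)
    return(override)
  }
  stopifnot(inherits(train, "spike_train"))
  isi <- diff(train$times)
  if (length(isi) < 100L)
    stop("insufficient data: need >= 100 inter-spike intervals", call. = FALSE)
  bins <- as.integer(ceiling(isi / dt - 1e-9))  # ISI in ((k-1)dt, k*dt] -> k
  counts <- tabulate(bins)
  first <- which(counts > 0.05 * max(counts))[1]
  (first - 1L) * dt
}

#' Refractory-correction search settings
#'
#' @param tau_ref Absolute refractory period, seconds.
#' @param n_sim Simulated trains per search iteration (default 100).
#' @param tol Convergence tolerance on the modulation index (default 0.01).
#' @param max_iter Bisection iteration cap (default 20).
#' @return An object of class `refractory_model`.
#' @export
refractory_model <- function(tau_ref, n_sim = 100, tol = 0.01, max_iter = 20) {
  stopifnot_scalar(tau_ref, "tau_ref", nonneg = TRUE)
  stopifnot_scalar(n_sim, "n_sim", positive = TRUE)
  stopifnot_scalar(tol, "tol", positive = TRUE)
  stopifnot_scalar(max_iter, "max_iter", positive = TRUE)
  structure(list(tau_ref = tau_ref, n_sim = as.integer(n_sim), tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "refractory_model")
}

#' Correct the modulation index for refractory-period distortion
#'
#' Refractoriness thins spikes preferentially near the oscillation crest
#' (where more spikes are due), flattening the apparent modulation; the raw
#' index therefore underestimates the true modulation of the driving rate
#' function, and more so at high firing rates. The correction searches for
#' the rate-function modulation `m_p` that, when simulated forward with the
#' train's Poisson-equivalent rate and refractory period, reproduces the
#' observed index:
#' (1) compute `r_p_hat` from the spike count, duration and `tau_ref`;
#' (2) propose a rate function at (`r_p_hat`, `m_p`, `f_peak`), starting from
#' `m_p = m_hat`;
#' (3) simulate `n_sim` refractory Poisson trains from it and average their
#' estimated indices;
#' (4) if the simulated mean is below the observed index, increase `m_p` and
#' repeat; stop when it matches within `tol`.
#' The search is a bisection on `[m_hat, 1]` (the forward map is monotone in
#' `m_p`). The peak frequency is held fixed at the uncorrected assessment's
#' `f_peak` rather than re-searched each iteration.
#'
#' If even `m_p = 1` cannot reproduce the observed index, the correction
#' saturates: 1 is returned with a warning.
#'
#' @param train The original [spike_train()].
#' @param result The uncorrected [assess()] result for `train` (must have
#'   `m_hat > 0`).
#' @param model A [refractory_model()].
#' @param seed Optional integer seed for the simulation stream.
#' @param config A [run_config()] with the spectral settings used for
#'   `result`.
#' @return The corrected index `m_p_hat` in `[m_hat, 1]`, with attribute
#'   `saturated` if the search hit the upper bound.
#' @export
correct_for_refractoriness <- function(train, result,
                                       model = refractory_model(0.002),
                                       seed = NULL, config = run_config()) {
  stopifnot(inherits(train, "spike_train"),
            inherits(result, "mod_index_result"),
            inherits(model, "refractory_model"))
  if (model$tau_ref == 0) return(result$m_hat)
  if (result$m_hat <= 0)
    stop("refractory correction requires m_hat > 0", call. = FALSE)
  r_p_hat <- poisson_equivalent_rate(train, model$tau_ref)
  f_peak <- result$f_peak
  forward <- function(m_p) {
    pars <- osc_params(r0 = r_p_hat, m = m_p, f0 = f_peak,
                       tau_ref = model$tau_ref)
    mean(vapply(seq_len(model$n_sim), function(i) {
      tr <- generate_train(pars, train$T, dt = config$bin_dt)
      r0_s <- estimate_rate(tr)
      ps <- welch_psd(bin_train(tr, config$bin_dt), wl = config$wl,
                      window = config$window_name)
      k <- which.min(abs(ps$freqs - f_peak))
      pk <- welch_to_analytic(ps$power[k], ps, r0_s)
      suppressWarnings(modulation_index(pk, r0_s, tr$T))
    }, numeric(1)))
  }
  with_seed(seed, {
    lo <- result$m_hat
    hi <- 1
    if (forward(lo) >= result$m_hat) return(lo)
    f_hi <- forward(hi)
    if (f_hi < result$m_hat - model$tol) {
      warning("refractory correction saturated: even m_p = 1 cannot reproduce the observed index",
              call. = FALSE)
      return(structure(1, saturated = TRUE))
    }
    mid <- hi
    for (iter in seq_len(model$max_iter)) {
      mid <- (lo + hi) / 2
      fm <- forward(mid)
      if (abs(fm - result$m_hat) <= model$tol) return(mid)
      if (fm < result$m_hat) lo <- mid else hi <- mid
    }
    mid
  })
}

#' Reconstruct the estimated oscillatory rate function
#'
#' Once the baseline rate, peak frequency and modulation index are
#' estimated, the underlying rate function is fully described:
#' \eqn{\hat\lambda(t) = \hat r_0 (1 + \hat m \cos(2\pi \hat f_{peak} t))}.
#' The refractory-corrected index is used when available.
#'
#' @param result A [assess()] result.
#' @param t Times (s) at which to sample the rate function.
#' @return Numeric vector `lambda_hat(t)` in sp/s.
#' @export
reconstruct_rate <- function(result, t) {
  stopifnot(inherits(result, "mod_index_result"))
  m <- if (!is.na(result$m_p_hat)) result$m_p_hat else result$m_hat
  result$r0_hat * (1 + m * cos(2 * pi * result$f_peak * t))
}

#' SNR of the first autocorrelation peak (biased alternative measure)
#'
#' Oscillations also surface as peaks in the spike-train autocorrelation
#' histogram, the first near lag `1/f0`. This measure is provided for
#' comparison only: like the spectral SNR (the autocorrelation and the
#' spectrum are a Fourier pair), it grows with the firing rate and is
#' therefore a biased oscillation measure.
#'
#' The autocorrelation histogram is computed at 1-ms lags with the zero-lag
#' bin excluded. The first peak is located on a lightly smoothed copy (the
#' first local maximum after the initial descent); the SNR is the raw
#' histogram's value there minus its mean, in units of its standard
#' deviation.
#'
#' @param train A non-empty [spike_train()].
#' @param max_lag Maximum lag in seconds (default 0.2).
#' @param dt Lag bin width in seconds (default 0.001).
#' @return A list: `snr` (SD units), `peak_lag` (s), `acf` (the histogram),
#'   `lags` (s).
#' @export
autocorr_snr <- function(train, max_lag = 0.2, dt = 0.001) {
  stopifnot(inherits(train, "spike_train"))
  if (train$n_spikes == 0) stop("empty spike train", call. = FALSE)
  x <- bin_train(train, dt)$counts
  L <- min(as.integer(round(max_lag / dt)), length(x) - 1L)
  n <- length(x)
  ac <- vapply(seq_len(L), function(l) sum(x[seq_len(n - l)] * x[(l + 1):n]),
               numeric(1))
  sm <- as.numeric(stats::filter(ac, rep(1 / 11, 11), sides = 2))
  sm[is.na(sm)] <- ac[is.na(sm)]
  # first local maximum after the initial descent, among maxima that rise
  # above the histogram's mean level (suppresses small-lag noise bumps)
  is_ext <- function(i, cmp) {
    lo <- max(1L, i - 10L); hi <- min(L, i + 10L)
    cmp(sm[i], sm[lo:hi])
  }
  i_min <- NA_integer_
  for (i in 2:(L - 1L)) {
    if (is_ext(i, function(v, w) v <= min(w))) { i_min <- i; break }
  }
  i_peak <- NA_integer_
  if (!is.na(i_min) && i_min < L - 1L) {
    lvl <- mean(sm)
    for (i in (i_min + 1L):(L - 1L)) {
      if (sm[i] >= lvl && is_ext(i, function(v, w) v >= max(w))) {
        i_peak <- i
        break
      }
    }
  }
  if (is.na(i_peak)) i_peak <- which.max(sm)
  list(snr = (ac[i_peak] - mean(ac)) / stats::sd(ac),
       peak_lag = i_peak * dt, acf = ac, lags = seq_len(L) * dt)
}
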