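#' Parameters of a cosine-modulated oscillatory rate function
#'
#' Defines the instantaneous firing rate
#' \deqn{\lambda(t) = r_0 (1 + m \cos(2\pi f_0 t + \phi))}
#' of an inhomogeneous Poisson neuron: baseline rate `r0` (spikes/s),
#' modulation index `m` (0 = no modulation, 1 = rate reaches zero at the
#' trough), oscillation frequency `f0` (Hz), optional absolute refractory
#' period `tau_ref` (s) during which the rate is forced to zero after each
#' spike, and an optional frequency `jitter_band` within which the
#' instantaneous frequency is allowed to wander (see
#' [generate_jittered_train()]).
#'
#' @param r0 Baseline firing rate, spikes/s (> 0).
#' @param m Modulation index, dimensionless in \[0, 1\].
#' @param f0 Oscillation frequency, Hz (> 0). Defaults to 12 Hz, a beta-band
#'   frequency typical of pallidal recordings in Parkinsonism.
#' @param jitter_band Optional length-2 numeric `c(f_lo, f_hi)` in Hz with
#'   `f_lo <= f0 <= f_hi`.
#' @param tau_ref Absolute refractory period in seconds (0 = pure Poisson).
#' @param phase Phase offset in radians at `t = 0`; the cosine as written has
#'   phase 0 at the time origin, so the default is 0.
#' @return An object of class `osc_params`.
#' @examples
#' p <- osc_params(r0 = 5, m = 0.5, f0 = 12)
#' rate_at(p, c(0, 1 / 24))  # 7.5 sp/s at the crest, 2.5 sp/s at the trough
#' @seealso [generate_train()], [analytic_psd()]
#' @export
osc_params <- function(r0, m = 0, f0 = 12, jitter_band = NULL, tau_ref = 0,
                       phase = 0) {
  stopifnot_scalar(r0, "r0", positive = TRUE)
  stopifnot_scalar(m, "m", nonneg = TRUE)
  if (m > 1) stop("`m` must lie in [0, 1]", call. = FALSE)
  stopifnot_scalar(f0, "f0", positive = TRUE)
  stopifnot_scalar(tau_ref, "tau_ref", nonneg = TRUE)
  stopifnot_scalar(phase, "phase")
  if (!is.null(jitter_band)) {
    if (length(jitter_band) != 2L || !is.numeric(jitter_band))
      stop("`jitter_band` must be c(f_lo, f_hi)", call. = FALSE)
    if (jitter_band[1] > jitter_band[2])
      stop("jitter band has f_lo > f_hi", call. = FALSE)
    if (f0 < jitter_band[1] || f0 > jitter_band[2])
      stop("`f0` must lie within `jitter_band`", call. = FALSE)
  }
  structure(
    list(r0 = r0, m = m, f0 = f0, jitter_band = jitter_band,
         tau_ref = tau_ref, phase = phase),
    class = "osc_params"
  )
}

#' @export
print.osc_params <- function(x, ...) {
  cat(sprintf("Oscillatory rate function: r0 = %g sp/s, m = %g, f0 = %g Hz\n",
              x$r0, x$m, x$f0))
  if (x$tau_ref > 0)
    cat(sprintf("  absolute refractory period: %g ms\n", 1000 * x$tau_ref))
  if (!is.null(x$jitter_band))
    cat(sprintf("  frequency jitter band: %g-%g Hz\n",
                x$jitter_band[1], x$jitter_band[2]))
  invisible(x)
}

#' Evaluate the oscillatory rate function
#'
#' @param params An [osc_params()] object.
#' @param t Times in seconds.
#' @return `lambda(t)` in spikes/s.
#' @export
rate_at <- function(params, t) {
  stopifnot(inherits(params, "osc_params"))
  params$r0 * (1 + params$m * cos(2 * pi * params$f0 * t + params$phase))
}

#' Construct a spike train object
#'
#' A spike train is a sorted vector of event times (seconds) on `[0, T)`.
#'
#' @param times Numeric vector of spike times, seconds.
#' @param T Recording duration, seconds.
#' @return An object of class `spike_train` with fields `times`, `T` and
#'   `n_spikes`.
#' @export
spike_train <- function(times, T) {
  stopifnot_scalar(T, "T", nonneg = TRUE)
  times <- as.numeric(times)
  if (anyNA(times)) stop("spike times contain NA", call. = FALSE)
  if (is.unsorted(times, strictly = FALSE)) times <- sort(times)
  if (length(times) && (times[1] < 0 || times[length(times)] >= T))
    stop("spike times must lie in [0, T)", call. = FALSE)
  structure(list(times = times, T = T, n_spikes = length(times)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes over %g s (mean rate %.2f sp/s)\n",
              x$n_spikes, x$T, if (x$T > 0) x$n_spikes / x$T else NA_real_))
  invisible(x)
}

# Bernoulli thinning of a per-bin spike probability vector, with optional
# absolute dead time. Candidate spikes in dead bins are rejected and do not
# retrigger the dead time (the rate, not the spikes, is set to zero).
thin_bernoulli <- function(p, dt, tau_ref) {
  u <- stats::runif(length(p))
  cand <- which(u < p)
  if (tau_ref > 0 && length(cand) > 1L) {
    keep <- logical(length(cand))
    last <- -Inf
    for (i in seq_along(cand)) {
      if ((cand[i] - last) * dt > tau_ref) {
        keep[i] <- TRUE
        last <- cand[i]
      }
    }
    cand <- cand[keep]
  }
  cand
}

check_bin_probs <- function(p, r0, dt) {
  if (r0 * dt >= 1)
    stop(sprintf(
      "rate saturation: r0*dt = %.3g >= 1; the Bernoulli-per-bin generator cannot represent rates above 1/dt",
      r0 * dt), call. = FALSE)
  if (any(p >= 1)) {
    warning("per-bin spike probability lambda(t)*dt reaches 1; clipping",
            call. = FALSE)
    p <- pmin(p, 1)
  }
  p
}

#' Simulate an inhomogeneous Poisson spike train
#'
#' Generates a spike train from the cosine-modulated rate function of
#' `params` by per-bin Bernoulli thinning at resolution `dt` (default 1 ms):
#' each bin fires with probability `lambda(t)*dt`, independently, matching the
#' discrete-time generator commonly used for this model. An absolute
#' refractory period (`params$tau_ref > 0`) is implemented by forcing the
#' instantaneous rate to zero for `tau_ref` seconds after every spike. Spike
#' times are placed at bin centres.
#'
#' The expected spike count of the refractory-free process is
#' `r0*T*(1 + m*sinc(2*f0*T))`, which reduces to `r0*T` whenever `2*f0*T` is
#' an integer.
#'
#' @param params An [osc_params()] object.
#' @param T Recording duration in seconds (> 0).
#' @param seed Optional integer seed (reproducible trains); `NULL` uses the
#'   current RNG stream.
#' @param dt Simulation resolution in seconds (default 0.001).
#' @return A [spike_train()].
#' @examples
#' tr <- generate_train(osc_params(r0 = 30, m = 0.5), T = 10, seed = 1)
#' tr$n_spikes / tr$T
#' @export
generate_train <- function(params, T, seed = NULL, dt = 0.001) {
  stopifnot(inherits(params, "osc_params"))
  stopifnot_scalar(T, "T", positive = TRUE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  n_bins <- round(T / dt)
  tt <- (seq_len(n_bins) - 0.5) * dt
  p <- check_bin_probs(rate_at(params, tt) * dt, params$r0, dt)
  idx <- with_seed(seed, thin_bernoulli(p, dt, params$tau_ref))
  spike_train((idx - 0.5) * dt, T)
}

# Piecewise-constant instantaneous frequency: a bounded random walk updated
# once per oscillation cycle, uniform steps of at most a quarter band width,
# reflected at the band edges. Returns the per-bin frequency vector.
# Draws no random numbers when the band is degenerate (f_lo == f_hi).
jitter_frequency_bins <- function(params, T, dt) {
  band <- params$jitter_band
  n_bins <- round(T / dt)
  f <- params$f0
  width <- band[2] - band[1]
  f_bins <- numeric(n_bins)
  pos <- 1L
  while (pos <= n_bins) {
    cyc_bins <- max(1L, round(1 / (f * dt)))
    end <- min(n_bins, pos + cyc_bins - 1L)
    f_bins[pos:end] <- f
    pos <- end + 1L
    if (width > 0) {
      f <- f + stats::runif(1, -width / 4, width / 4)
      if (f > band[2]) f <- 2 * band[2] - f
      if (f < band[1]) f <- 2 * band[1] - f
    }
  }
  f_bins
}

#' Simulate a spike train with a jittered oscillation frequency
#'
#' Real neurons are not perfect oscillators: their oscillation frequency
#' wanders within a narrow band (about 1 Hz wide in Parkinsonian pallidal
#' recordings). This generator lets the instantaneous frequency follow a
#' bounded random walk inside `params$jitter_band` — one uniform step per
#' oscillation cycle, reflected at the band edges — and integrates the
#' instantaneous frequency into a continuous phase, so there are no phase
#' jumps at frequency updates. With a degenerate band (`f_lo == f_hi`) the
#' output is identical to [generate_train()] under the same seed.
#'
#' @inheritParams generate_train
#' @return A [spike_train()].
#' @export
generate_jittered_train <- function(params, T, seed = NULL, dt = 0.001) {
  stopifnot(inherits(params, "osc_params"))
  if (is.null(params$jitter_band))
    stop("`params` has no jitter_band; use generate_train()", call. = FALSE)
  stopifnot_scalar(T, "T", positive = TRUE)
  with_seed(seed, {
    f_bins <- jitter_frequency_bins(params, T, dt)
    # phase at bin centres: integrate 2*pi*f(t), half-step offset so a
    # constant f reproduces cos(2*pi*f*(k - 0.5)*dt) exactly
    phase <- 2 * pi * (cumsum(f_bins) - f_bins / 2) * dt + params$phase
    p <- check_bin_probs(params$r0 * (1 + params$m * cos(phase)) * dt,
                         params$r0, dt)
    idx <- thin_bernoulli(p, dt, params$tau_ref)
    spike_train((idx - 0.5) * dt, T)
  })
}

#' Bin a spike train into counts
#'
#' Half-open bins `[k*dt, (k+1)*dt)`; the total count is conserved.
#'
#' @param train A [spike_train()].
#' @param dt Bin width in seconds (default 0.001, i.e. 1 ms).
#' @return An object of class `binned_train` with fields `counts` (integer
#'   per-bin counts), `dt` and `Fs = 1/dt`.
#' @export
bin_train <- function(train, dt = 0.001) {
  stopifnot(inherits(train, "spike_train"))
  stopifnot_scalar(dt, "dt", positive = TRUE)
  n_bins <- max(1L, as.integer(ceiling(train$T / dt - 1e-9)))
  idx <- pmin(floor(train$times / dt) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(counts = counts, dt = dt, Fs = 1 / dt),
            class = "binned_train")
}

#' Generate a deterministic grid of simulated spike trains
#'
#' Expands a grid of simulation cells (all combinations of `r0`, `m`, `T`,
#' with `reps` trains per cell and consecutive seeds derived from
#' `base_seed`), simulates every train, optionally writes each train and a
#' JSON manifest to `dir`, and returns the manifest. Re-running with the same
#' configuration and base seed reproduces the identical set.
#'
#' @param config A list with fields `r0`, `m`, `T` (numeric vectors), `reps`
#'   (trains per cell), `base_seed` (integer), and optionally `f0` (default
#'   12) and `tau_ref` (default 0).
#' @param dir Optional directory; when given, trains are written as plain-text
#'   timestamp files and a `manifest.json` is written alongside.
#' @return Invisibly, a data frame manifest with one row per train (`r0`,
#'   `m`, `f0`, `tau_ref`, `T`, `rep`, `seed`, `path`) and the simulated
#'   trains attached as the `"trains"` attribute.
#' @export
make_fixture_grid <- function(config, dir = NULL) {
  stopifnot(is.list(config),
            all(c("r0", "m", "T", "reps", "base_seed") %in% names(config)))
  f0 <- if (is.null(config$f0)) 12 else config$f0
  tau_ref <- if (is.null(config$tau_ref)) 0 else config$tau_ref
  cells <- expand.grid(rep = seq_len(config$reps), T = config$T, m = config$m,
                       r0 = config$r0, KEEP.OUT.ATTRS = FALSE)
  cells <- cells[, c("r0", "m", "T", "rep")]
  cells$f0 <- f0
  cells$tau_ref <- tau_ref
  cells$seed <- config$base_seed + seq_len(nrow(cells)) - 1L
  cells$path <- NA_character_
  trains <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    pars <- osc_params(cells$r0[i], cells$m[i], f0, tau_ref = tau_ref)
    trains[[i]] <- generate_train(pars, cells$T[i], seed = cells$seed[i])
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      fn <- sprintf("train_r0%g_m%g_T%g_rep%d.txt",
                    cells$r0[i], cells$m[i], cells$T[i], cells$rep[i])
      cells$path[i] <- file.path(dir, fn)
      write_spike_times(trains[[i]], cells$path[i])
    }
  }
  manifest <- cells[, c("r0", "m", "f0", "tau_ref", "T", "rep", "seed", "path")]
  if (!is.null(dir)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         dataframe = "rows", digits = NA, pretty = TRUE)
  }
  attr(manifest, "trains") <- trains
  invisible(manifest)
}
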