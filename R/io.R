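#' Analysis configuration
#'
#' Collects every tunable of the estimation pipeline in one object. The
#' defaults reproduce the standard analysis settings for 1-ms binned spike
#' trains: 1000-bin non-overlapping Hamming windows (1 Hz resolution, 500 Hz
#' Nyquist), a 100-500 Hz noise band, a 5-SD spectral detection threshold,
#' a 10-15 Hz (beta band) peak search, and 1000 null simulations for the
#' modulation-index significance threshold.
#'
#' @param bin_dt Bin width in seconds (default 0.001).
#' @param wl Welch window length in bins (default 1000).
#' @param window_name Taper name (default `"hamming"`).
#' @param search_band Peak search band in Hz (default `c(10, 15)`).
#' @param noise_band Noise band in Hz (default `c(100, 500)`).
#' @param snr_threshold Spectral detection threshold in SD units (default 5).
#' @param n_null Null simulations for the modulation-index threshold
#'   (default 1000; 0 disables significance testing).
#' @param seed Optional integer seed used for null simulations.
#' @param tau_ref_mode `"zero"` (no refractory correction, default),
#'   `"auto"` (estimate from the ISI histogram) or `"fixed"` (use
#'   `tau_ref`).
#' @param tau_ref Refractory period in seconds for `tau_ref_mode = "fixed"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(bin_dt = 0.001, wl = 1000, window_name = "hamming",
                       search_band = c(10, 15), noise_band = c(100, 500),
                       snr_threshold = 5, n_null = 1000, seed = NULL,
                       tau_ref_mode = c("zero", "auto", "fixed"),
                       tau_ref = 0.002) {
  tau_ref_mode <- match.arg(tau_ref_mode)
  stopifnot_scalar(bin_dt, "bin_dt", positive = TRUE)
  stopifnot_scalar(wl, "wl", positive = TRUE)
  stopifnot_scalar(snr_threshold, "snr_threshold", positive = TRUE)
  stopifnot_scalar(n_null, "n_null", nonneg = TRUE)
  nyquist <- 1 / (2 * bin_dt)
  for (b in list(search_band = search_band, noise_band = noise_band)) {
    if (length(b) != 2L || b[1] > b[2] || b[2] > nyquist)
      stop("frequency bands must be c(lo, hi) within the Nyquist frequency",
           call. = FALSE)
  }
  structure(
    list(bin_dt = bin_dt, wl = as.integer(wl), window_name = window_name,
         search_band = search_band, noise_band = noise_band,
         snr_threshold = snr_threshold, n_null = as.integer(n_null),
         seed = seed, tau_ref_mode = tau_ref_mode, tau_ref = tau_ref),
    class = "run_config"
  )
}

#' Read and write analysis configurations as YAML
#'
#' @param path File path.
#' @param config A [run_config()].
#' @return `read_run_config()` returns a [run_config()];
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals <- vals[names(vals) %in% names(formals(run_config))]
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read spike trains from plain-text or CSV files
#'
#' Two formats are accepted: plain text with one timestamp (seconds) per
#' line, and CSV with columns `unit_id` and `time_s` (one train per unit).
#' Unsorted input is sorted with a warning; duplicate timestamps are kept
#' with a warning; negative times are an error. The duration is taken from
#' `T` when given, otherwise from the last spike rounded up to a whole
#' second.
#'
#' @param path File path.
#' @param format `"auto"` (by extension, default), `"times"` or `"csv"`.
#' @param T Optional recording duration in seconds.
#' @return A [spike_train()], or a named list of them for multi-unit CSV.
#' @export
read_spike_times <- function(path, format = c("auto", "times", "csv"),
                             T = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "times"
  as_train <- function(times) {
    if (anyNA(times)) stop("non-numeric spike times in input", call. = FALSE)
    if (any(times < 0)) stop("negative spike times in input", call. = FALSE)
    if (is.unsorted(times)) {
      warning("unsorted spike times; sorting", call. = FALSE)
      times <- sort(times)
    }
    if (anyDuplicated(times))
      warning("duplicate spike times in input", call. = FALSE)
    dur <- if (!is.null(T)) T
      else if (length(times)) max(1, ceiling(max(times) + 1e-9)) else 0
    spike_train(times, dur)
  }
  if (format == "times") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    return(as_train(suppressWarnings(as.numeric(lines))))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("unit_id", "time_s") %in% names(df)))
    stop("CSV must have columns unit_id,time_s", call. = FALSE)
  trains <- lapply(split(df$time_s, df$unit_id), as_train)
  if (length(trains) == 1L) trains[[1]] else trains
}

#' Write spike trains to plain-text or CSV files
#'
#' Plain text writes one timestamp per line, seconds, six decimal places
#' (microsecond precision). CSV writes `unit_id,time_s`; pass a named list
#' of trains for multiple units.
#'
#' @param train A [spike_train()] or a named list of them (CSV only).
#' @param path Output path.
#' @param format `"auto"` (by extension, default), `"times"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_spike_times <- function(train, path, format = c("auto", "times", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "times"
  if (format == "times") {
    stopifnot(inherits(train, "spike_train"))
    writeLines(sprintf("%.6f", train$times), path)
  } else {
    trains <- if (inherits(train, "spike_train")) list(unit1 = train) else train
    stopifnot(all(vapply(trains, inherits, logical(1), "spike_train")))
    ids <- names(trains)
    if (is.null(ids)) ids <- paste0("unit", seq_along(trains))
    df <- do.call(rbind, lapply(seq_along(trains), function(i)
      data.frame(unit_id = ids[i], time_s = sprintf("%.6f", trains[[i]]$times))))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write and read a power spectrum with its SNR
#'
#' The spectrum is written as CSV (`freq_hz,power,snr`) with a JSON sidecar
#' (`<path>.json`) carrying the Welch metadata (`Fs`, `wl`, `window_name`,
#' `n_wins`) needed to reconstruct the taper and apply the analytic-scale
#' correction.
#'
#' @param ps A [welch_psd()] result.
#' @param snr Optional matching [snr_spectrum()].
#' @param path CSV output path.
#' @return `write_spectrum()` returns `path` invisibly; `read_spectrum()`
#'   returns a list with elements `ps` (a `power_spectrum`) and `snr` (a
#'   numeric vector or `NULL`).
#' @export
write_spectrum <- function(ps, path, snr = NULL) {
  stopifnot(inherits(ps, "power_spectrum"))
  df <- data.frame(freq_hz = ps$freqs, power = ps$power,
                   snr = if (is.null(snr)) NA_real_ else snr$snr)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(Fs = ps$Fs, wl = ps$wl, window_name = ps$window_name,
               n_wins = ps$n_wins)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ps <- structure(
    list(freqs = df$freq_hz, power = df$power, Fs = meta$Fs, wl = meta$wl,
         n_wins = meta$n_wins, window = make_window(meta$window_name, meta$wl),
         window_name = meta$window_name),
    class = "power_spectrum"
  )
  list(ps = ps, snr = if (all(is.na(df$snr))) NULL else df$snr)
}

#' Batch modulation-index analysis
#'
#' Runs [assess()] (and, when configured, the refractory correction) on each
#' input file and collects one row per unit. Null-threshold simulations are
#' cached across units sharing a 1-sp/s rate bin and duration. A failing
#' unit is logged in its row's `error` column and the batch continues. The
#' configuration is embedded in the result (attribute `config`) so every
#' report is reproducible.
#'
#' @param paths Character vector of spike-time files (see
#'   [read_spike_times()]).
#' @param config A [run_config()].
#' @param T Optional recording duration passed to the reader.
#' @return A data frame with columns `unit_id`, `path`, `r0_hat`, `f_peak`,
#'   `m_hat`, `threshold`, `significant`, `peak_snr`, `tau_ref`, `m_p_hat`,
#'   `error`; the configuration as attribute `"config"`.
#' @export
run_batch <- function(paths, config = run_config(), T = NULL) {
  stopifnot(inherits(config, "run_config"))
  rows <- list()
  for (path in paths) {
    trains <- tryCatch(read_spike_times(path, T = T), error = identity)
    if (inherits(trains, "error")) {
      rows[[length(rows) + 1L]] <- batch_row(basename(path), path,
                                             error = conditionMessage(trains))
      next
    }
    if (inherits(trains, "spike_train"))
      trains <- stats::setNames(list(trains), tools::file_path_sans_ext(basename(path)))
    for (uid in names(trains)) {
      row <- tryCatch({
        res <- assess(trains[[uid]], config = config)
        tau <- switch(config$tau_ref_mode,
                      zero = 0,
                      fixed = config$tau_ref,
                      auto = estimate_tau_ref(trains[[uid]], dt = config$bin_dt))
        m_p <- NA_real_
        if (tau > 0 && res$m_hat > 0) {
          m_p <- as.numeric(correct_for_refractoriness(
            trains[[uid]], res, refractory_model(tau), seed = config$seed,
            config = config))
        }
        batch_row(uid, path, r0_hat = res$r0_hat, f_peak = res$f_peak,
                  m_hat = res$m_hat, threshold = res$threshold,
                  significant = res$significant, peak_snr = res$peak_snr,
                  tau_ref = tau, m_p_hat = m_p)
      }, error = function(e) batch_row(uid, path,
                                       error = conditionMessage(e)))
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- config
  out
}

batch_row <- function(unit_id, path, r0_hat = NA_real_, f_peak = NA_real_,
                      m_hat = NA_real_, threshold = NA_real_,
                      significant = NA, peak_snr = NA_real_,
                      tau_ref = NA_real_, m_p_hat = NA_real_,
                      error = NA_character_) {
  data.frame(unit_id = unit_id, path = path, r0_hat = r0_hat,
             f_peak = f_peak, m_hat = m_hat, threshold = threshold,
             significant = significant, peak_snr = peak_snr,
             tau_ref = tau_ref, m_p_hat = m_p_hat, error = error,
             stringsAsFactors = FALSE)
}

#' Write a batch report with its provenance
#'
#' Writes the [run_batch()] table as CSV and its embedded configuration as a
#' JSON sidecar (`<path>.config.json`).
#'
#' @param report A [run_batch()] result.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_batch_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  cfg <- attr(report, "config")
  if (!is.null(cfg))
    jsonlite::write_json(unclass(cfg), paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
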