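test_that("rate function follows the cosine model and parameters are validated", {
  p <- osc_params(r0 = 5, m = 0.5, f0 = 12)
  expect_equal(rate_at(p, 0), 7.5)            # crest
  expect_equal(rate_at(p, 1 / 24), 2.5)       # trough at half a period
  expect_equal(mean(rate_at(p, seq(0, 1 / 12, length.out = 1201)[-1201])), 5,
               tolerance = 1e-10)
  expect_error(osc_params(r0 = -1), "r0")
  expect_error(osc_params(r0 = 5, m = 1.2), "0, 1")
  expect_error(osc_params(r0 = 5, tau_ref = -0.001), "tau_ref")
  expect_error(osc_params(r0 = 5, f0 = 12, jitter_band = c(13, 14)), "f0")
  expect_error(osc_params(r0 = 5, f0 = 12, jitter_band = c(13, 11)), "f_lo")
})

test_that("homogeneous trains are Poisson-consistent (count and ISI law)", {
  r0 <- 5; T <- 200
  tr <- generate_train(osc_params(r0, m = 0), T, seed = 421)
  # count within 3 standard errors of Poisson
  expect_lt(abs(tr$n_spikes - r0 * T), 3 * sqrt(r0 * T))
  # ISIs consistent with Exponential(r0) at alpha = 0.01
  ks <- suppressWarnings(stats::ks.test(diff(tr$times), "pexp", r0))
  expect_gt(ks$p.value, 0.01)
})

test_that("expected spike count follows the finite-duration formula", {
  # k_bar(T) = r0*T*(1 + m*sinc(2*f0*T)); T chosen so the sinc term is nonzero
  r0 <- 20; m <- 0.5; f0 <- 12; T <- 1.02; reps <- 300
  pars <- osc_params(r0, m, f0)
  set.seed(7)
  counts <- replicate(reps, generate_train(pars, T)$n_spikes)
  k_bar <- r0 * T * (1 + m * sinc(2 * f0 * T))
  expect_lt(abs(mean(counts) - k_bar), 3 * sd(counts) / sqrt(reps))
})

test_that("absolute refractoriness enforces the dead time and removes spikes", {
  pars_free <- osc_params(60, 0.5, 12)
  pars_ref <- osc_params(60, 0.5, 12, tau_ref = 0.002)
  free <- generate_train(pars_free, 120, seed = 9)
  ref <- generate_train(pars_ref, 120, seed = 9)   # same uniform stream
  expect_gte(min(diff(ref$times)), 0.002)
  expect_lt(ref$n_spikes, free$n_spikes)
  expect_true(all(ref$times %in% free$times))      # thinning only removes
  # saturation guard
  expect_error(generate_train(osc_params(1200), 1), "saturation")
})

test_that("generation is seed-deterministic and binning conserves counts", {
  pars <- osc_params(30, 0.5, 12)
  a <- generate_train(pars, 30, seed = 11)
  b <- generate_train(pars, 30, seed = 11)
  expect_identical(a$times, b$times)
  bt <- bin_train(a)
  expect_identical(sum(bt$counts), a$n_spikes)
  # explicit binning example
  expect_identical(bin_train(spike_train(c(0.0005, 0.0015), 0.01))$counts[1:3],
                   c(1L, 1L, 0L))
  expect_true(all(bin_train(spike_train(numeric(0), 1))$counts == 0L))
})

test_that("degenerate jitter band reproduces the fixed-frequency train exactly", {
  p_fix <- osc_params(40, 0.5, 12)
  p_jit <- osc_params(40, 0.5, 12, jitter_band = c(12, 12))
  expect_identical(generate_jittered_train(p_jit, 60, seed = 3)$times,
                   generate_train(p_fix, 60, seed = 3)$times)
  expect_error(generate_jittered_train(p_fix, 60, seed = 3), "jitter_band")
})

test_that("jittered frequency stays within the band and conserves band power", {
  p <- osc_params(40, 0.5, 12, jitter_band = c(11.5, 12.5))
  for (s in 1:5) {
    f <- spikeosc:::jitter_frequency_bins(p, 60, 0.001)
    expect_true(all(f >= 11.5 & f <= 12.5))
  }
  # oscillation energy is spread, not lost: total 11-13 Hz excess power of
  # jittered trains matches the unjittered peak excess (Monte-Carlo means)
  band_excess <- function(gen, seed) {
    set.seed(seed)
    mean(replicate(12, {
      ps <- welch_psd(bin_train(gen()), 1000, "hamming")
      idx <- ps$freqs >= 11 & ps$freqs <= 13
      noise <- mean(ps$power[ps$freqs >= 100 & ps$freqs <= 500])
      sum(ps$power[idx] - noise)
    }))
  }
  e_jit <- band_excess(function() generate_jittered_train(p, 100), 31)
  e_fix <- band_excess(function() generate_train(osc_params(40, 0.5, 12), 100), 32)
  expect_lt(abs(e_jit / e_fix - 1), 0.25)
})

test_that("fine spectral resolution dilutes a jittered peak", {
  p <- osc_params(40, 0.5, 12, jitter_band = c(11.5, 12.5))
  tr <- generate_jittered_train(p, 300, seed = 17)
  bt <- bin_train(tr)
  snr_1hz <- snr_spectrum(welch_psd(bt, 1000, "hamming"))
  snr_01hz <- snr_spectrum(welch_psd(bt, 10000, "hamming"))
  peak <- function(s) max(s$snr[s$freqs >= 10 & s$freqs <= 15])
  expect_lt(peak(snr_01hz), peak(snr_1hz))
})

test_that("fixture grids are deterministic and enumerate every cell", {
  cfg <- list(r0 = c(10, 30), m = c(0, 0.5), T = 2, reps = 2, base_seed = 5)
  d1 <- file.path(tempdir(), "grid1"); d2 <- file.path(tempdir(), "grid2")
  m1 <- make_fixture_grid(cfg, d1)
  m2 <- make_fixture_grid(cfg, d2)
  expect_equal(nrow(m1), 8)                      # 2 r0 x 2 m x 2 reps
  expect_equal(anyDuplicated(m1$seed), 0)
  trains1 <- attr(m1, "trains"); trains2 <- attr(m2, "trains")
  for (i in seq_along(trains1))
    expect_identical(trains1[[i]]$times, trains2[[i]]$times)
  j1 <- readLines(file.path(d1, "manifest.json"))
  j2 <- readLines(file.path(d2, "manifest.json"))
  expect_identical(gsub("grid1", "grid2", j1), j2)
  # files round-trip through the reader
  back <- read_spike_times(m1$path[1], T = m1$T[1])
  expect_equal(back$times, trains1[[1]]$times, tolerance = 1e-6)
})
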