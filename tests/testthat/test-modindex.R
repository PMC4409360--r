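test_that("modulation index inverts the peak-power relation", {
  # forward: 20*(1 + 20*60*0.3^2/4) = 560; invert back to 0.3
  expect_equal(modulation_index(560, r0_hat = 20, T = 60), 0.3)
  expect_equal(modulation_index(20, r0_hat = 20, T = 60), 0)
  expect_equal(modulation_index(10, r0_hat = 20, T = 60), 0)  # clamp at 0
  expect_warning(m1 <- modulation_index(1e6, r0_hat = 5, T = 10), "clamping")
  expect_equal(m1, 1)
  expect_error(modulation_index(560, r0_hat = 0, T = 60), "r0_hat")
  expect_error(modulation_index(560, r0_hat = 20, T = 0), "T")
})

test_that("significance threshold is positive, cached and tightens with rate", {
  thr <- vapply(seq_along(c(10, 30, 60, 100)), function(i)
    as.numeric(significance_threshold(c(10, 30, 60, 100)[i], T = 60,
                                      f_band = c(12, 12), n_sim = 150,
                                      seed = 60 + i)), numeric(1))
  expect_true(all(thr > 0))
  expect_true(all(diff(thr) < 0))   # more spikes -> tighter null
  # determinism + caching
  t1 <- significance_threshold(40, 60, c(12, 12), n_sim = 100, seed = 77)
  t2 <- significance_threshold(40, 60, c(12, 12), n_sim = 100, seed = 77)
  expect_identical(as.numeric(t1), as.numeric(t2))
  expect_equal(as.numeric(t1),
               attr(t1, "null_mean") + 2 * attr(t1, "null_sd"))
})

test_that("assess recovers the true modulation and calibrates the null", {
  st <- rep_stats(60, 0.5, 300, reps = 20, seed = 81)
  expect_lt(abs(mean(st$m_hat) - 0.5), 0.05)
  # full assess object on one train
  tr <- generate_train(osc_params(60, 0.5, 12), 300, seed = 82)
  res <- assess(tr, f_band = c(12, 12),
                config = run_config(n_null = 100, seed = 83))
  expect_s3_class(res, "mod_index_result")
  expect_equal(res$f_peak, 12)
  expect_true(res$significant)
  expect_identical(res$significant, res$m_hat > res$threshold)
  # unmodulated trains are rarely declared significant
  cfg <- run_config(n_null = 300, seed = 84)
  set.seed(85)
  sig <- replicate(60, {
    assess(generate_train(osc_params(40, m = 0), 60), f_band = c(12, 12),
           config = cfg)$significant
  })
  expect_lte(mean(sig), 0.10)
})

test_that("assessment is invariant to circular shifts by whole windows", {
  tr <- generate_train(osc_params(40, 0.5, 12), 60, seed = 90)
  shifted <- spike_train(sort((tr$times + 7) %% 60), 60)
  cfg <- run_config(n_null = 0)
  a <- assess(tr, f_band = c(10, 15), config = cfg)
  b <- assess(shifted, f_band = c(10, 15), config = cfg)
  expect_equal(a$m_hat, b$m_hat, tolerance = 1e-12)
  expect_equal(a$peak_snr, b$peak_snr, tolerance = 1e-12)
})

test_that("Poisson-equivalent rate follows the dead-time formula", {
  tr <- spike_train(seq(0.005, 59.995, length.out = 3000), 60)
  expect_equal(poisson_equivalent_rate(tr, 0.002), 3000 / 54)
  expect_equal(poisson_equivalent_rate(tr, 0), 50)
  expect_error(poisson_equivalent_rate(tr, 0.02), "degenerate")
  # inverting the formula on simulated refractory trains recovers the
  # driving Poisson rate within 2% (homogeneous trains, for which the
  # dead-time relation is exact; modest modulation changes little)
  for (r0 in c(40, 100)) {
    trr <- generate_train(osc_params(r0, m = 0, tau_ref = 0.002), 600,
                          seed = r0)
    expect_lt(abs(poisson_equivalent_rate(trr, 0.002) / r0 - 1), 0.02)
  }
  trm <- generate_train(osc_params(40, 0.5, 12, tau_ref = 0.002), 600,
                        seed = 41)
  expect_lt(abs(poisson_equivalent_rate(trm, 0.002) / 40 - 1), 0.02)
})

test_that("refractory period is recovered from the ISI histogram", {
  trr <- generate_train(osc_params(60, 0.5, 12, tau_ref = 0.002), 600,
                        seed = 95)
  expect_true(estimate_tau_ref(trr) %in% c(0.001, 0.002, 0.003))
  trp <- generate_train(osc_params(60, 0.5, 12), 600, seed = 96)
  expect_equal(estimate_tau_ref(trp), 0)
  expect_equal(estimate_tau_ref(trr, override = 0.002), 0.002)
  expect_error(estimate_tau_ref(spike_train(c(0.1, 0.2), 1)), "insufficient")
})

test_that("refractory correction is identity at tau 0 and recovers the truth", {
  cfg <- run_config(n_null = 0)
  tr <- generate_train(osc_params(60, 0.5, 12), 120, seed = 97)
  res <- assess(tr, f_band = c(12, 12), config = cfg)
  expect_identical(correct_for_refractoriness(tr, res, refractory_model(0),
                                              config = cfg), res$m_hat)
  # distorted trains: m_p >= m_hat and the mean recovers the true modulation
  m_p <- vapply(1:3, function(i) {
    trr <- generate_train(osc_params(60, 0.5, 12, tau_ref = 0.002), 300,
                          seed = 200 + i)
    r <- assess(trr, f_band = c(12, 12), config = cfg)
    expect_lt(r$m_hat, 0.5)       # refractoriness flattens the modulation
    mp <- correct_for_refractoriness(trr, r, refractory_model(0.002, n_sim = 30),
                                     seed = 300 + i, config = cfg)
    expect_gte(as.numeric(mp), r$m_hat)
    as.numeric(mp)
  }, numeric(1))
  expect_lt(abs(mean(m_p) - 0.5), 0.07)
})

test_that("reconstructed rate function matches the estimated parameters", {
  res <- structure(list(r0_hat = 5, f_peak = 12, m_hat = 0.5,
                        m_p_hat = NA_real_, T = 60),
                   class = "mod_index_result")
  expect_equal(reconstruct_rate(res, 0), 7.5)
  expect_equal(reconstruct_rate(res, 1 / 24), 2.5)
  tt <- seq(0, 1 / 12, length.out = 1201)[-1201]
  expect_equal(mean(reconstruct_rate(res, tt)), 5, tolerance = 1e-10)
  res$m_hat <- 0
  expect_true(all(reconstruct_rate(res, tt) == 5))
  res$m_p_hat <- 0.8              # corrected index takes precedence
  expect_equal(max(reconstruct_rate(res, tt)), 9, tolerance = 1e-6)
})

test_that("autocorrelation SNR peaks near 1/f0 and shares the rate bias", {
  tr <- generate_train(osc_params(30, 0.5, 12), 200, seed = 50)
  ac <- autocorr_snr(tr)
  expect_gt(ac$peak_lag, 0.075)   # 1/f0 = 83 ms
  expect_lt(ac$peak_lag, 0.092)
  # SNR of the autocorrelation peak increases with the firing rate
  mean_ac <- vapply(c(5, 15, 30), function(r0) {
    set.seed(500 + r0)
    mean(replicate(8,
      autocorr_snr(generate_train(osc_params(r0, 0.5, 12), 150))$snr))
  }, numeric(1))
  expect_true(all(diff(mean_ac) > 0))
  expect_error(autocorr_snr(spike_train(numeric(0), 1)), "empty")
})
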