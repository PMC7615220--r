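# Intracellular feature extraction against planted and analytic oracles.

test_that("spike detection: flat traces, refractory rule, DC invariance", {
  fs <- 20000
  flat <- patch_record(voltage = rep(-60, fs), sampling_rate = fs)
  expect_length(detect_spikes(flat), 0L)

  # two crossings 1 ms apart with a 2 ms refractory count once
  v <- rep(-60, fs)
  v[1000 + 0:3] <- 0          # crossing 1
  v[1000 + 20 + 0:3] <- 0     # 1 ms later at 20 kHz
  r2 <- patch_record(voltage = v, sampling_rate = fs)
  expect_length(detect_spikes(r2, refractory_ms = 2), 1L)
  expect_length(detect_spikes(r2, refractory_ms = 0.5), 2L)

  # relative threshold makes detection invariant to a DC offset
  r <- generate_patch_record(patch_config(duration_s = 20,
                                          spike_rate_true = 4, seed = 2L))
  st <- detect_spikes(r)
  r_off <- patch_record(voltage = r$voltage + 17.3, current = r$current,
                        sampling_rate = fs, baseline_window = c(0, 20))
  st_off <- detect_spikes(r_off)
  # same spikes; times may shift by one sample when the offset moves the
  # estimated baseline mode within its bin
  expect_length(st_off, length(st))
  expect_true(all(abs(st_off - st) <= 1 / fs + 1e-12))
})

test_that("baseline features recover planted rate and resting potential", {
  r0 <- generate_patch_record(patch_config(duration_s = 60, silent = TRUE,
                                           seed = 1L))
  bf0 <- baseline_features(r0)
  expect_equal(bf0$baseline_firing_hz, 0)
  expect_true(bf0$is_silent)

  err_v <- err_f <- numeric(10)
  for (sd_ in 1:10) {
    r <- generate_patch_record(patch_config(
      duration_s = 60, spike_rate_true = 5, resting_potential_true = -70,
      noise_sd_mv = 1, seed = sd_))
    bf <- baseline_features(r)
    err_v[sd_] <- bf$resting_potential_mv - (-70)
    err_f[sd_] <- bf$baseline_firing_hz -
      length(r$ground_truth$spike_times) / 60
  }
  expect_true(all(abs(err_v) < 0.5))
  expect_true(all(abs(err_f) <= 0.1))
  expect_warning(baseline_features(r0, baseline_window = c(0, 0.5)),
                 "window")
})

test_that("depolarization block detection follows the planted block current", {
  steps <- c(50, 100, 150, 200, 250)
  r_blk <- generate_patch_record(patch_config(
    duration_s = 20, spike_rate_true = 1, current_steps = steps,
    depol_block_current = 200, seed = 3L))
  db <- detect_depolarization_block(r_blk)
  expect_true(db$depol_block)
  expect_equal(db$block_current_pa, 200)

  r_mono <- generate_patch_record(patch_config(
    duration_s = 20, spike_rate_true = 1, current_steps = steps, seed = 4L))
  db2 <- detect_depolarization_block(r_mono)
  expect_false(db2$depol_block)
  expect_true(all(diff(db2$step_counts) >= 0))

  r_sil <- generate_patch_record(patch_config(
    duration_s = 20, silent = TRUE, current_steps = c(2, 4, 6),
    step_gain_hz_per_pa = 0.05, seed = 5L))
  db3 <- detect_depolarization_block(r_sil)
  expect_false(db3$depol_block)
  expect_equal(db3$status, "insufficient spiking")
})

test_that("AP half-width matches the analytic triangle value", {
  # triangle of base width 2 ms at the threshold level -> 1.0 ms half-width
  r <- planted_spike_record(times = c(2, 4, 6), base_width_ms = 2)
  st <- detect_spikes(r)
  expect_length(st, 3L)
  expect_equal(ap_half_width(r, st), 1.0, tolerance = 0.06)

  # analytic half-width 0.8 ms, within one sample period at 20 kHz
  r2 <- planted_spike_record(times = c(2, 5), base_width_ms = 1.6)
  hw <- ap_half_width(r2, detect_spikes(r2))
  expect_lt(abs(hw - 0.8), 1 / 20000 * 1000 + 1e-9)

  expect_error(ap_half_width(r, numeric()), "at least one spike")
})

test_that("half-width estimate converges with sampling rate", {
  hw <- sapply(c(10000, 50000), function(fs) {
    r <- planted_spike_record(times = c(2, 4), fs = fs, base_width_ms = 2)
    ap_half_width(r, detect_spikes(r))
  })
  expect_lt(abs(hw[2] - 1.0), abs(hw[1] - 1.0) + 1e-9)
  expect_lt(abs(hw[2] - 1.0), 1 / 50000 * 1000 + 1e-9)
})

test_that("PSC detection recovers planted Poisson trains unbiasedly", {
  flat <- patch_record(current = rep(0, 20000 * 5), sampling_rate = 20000)
  p0 <- detect_pscs(flat)
  expect_length(p0$event_times, 0L)
  expect_equal(p0$frequency_hz, 0)

  bias <- numeric(20)
  for (sd_ in 1:20) {
    r <- generate_patch_record(patch_config(
      duration_s = 30, psc_rate_true = 2, psc_amplitude_mean = 20,
      seed = 100L + sd_))
    p <- detect_pscs(r, amplitude_threshold_pa = 5)
    bias[sd_] <- p$frequency_hz - length(r$ground_truth$psc_times) / 30
  }
  expect_lt(abs(mean(bias)), 2 * stats::sd(bias) / sqrt(20) + 1e-9)
  expect_true(all(abs(bias) <= 0.1))

  r1 <- generate_patch_record(patch_config(duration_s = 30, psc_rate_true = 2,
                                           epsc_fraction = 1, seed = 8L))
  expect_equal(detect_pscs(r1)$ipsc_frequency_hz, 0)
})

test_that("silent-cell fraction over a cohort matches the planted fraction", {
  planted <- 0.4; n <- 40
  silent_flags <- logical(n)
  for (i in seq_len(n)) {
    is_sil <- (i / n) <= planted  # deterministic assignment of 16/40
    r <- generate_patch_record(patch_config(
      duration_s = 20, silent = is_sil, spike_rate_true = 2,
      psc_rate_true = 0, seed = 200L + i))
    silent_flags[i] <- baseline_features(r)$is_silent
  }
  se <- sqrt(planted * (1 - planted) / n)
  expect_lt(abs(mean(silent_flags) - planted), 3 * se)
})
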