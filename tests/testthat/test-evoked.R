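# Event-aligned population analysis: Z-scoring, detection, alignment,
# activation classification, latency and clustering.

test_that("Z-scoring: closed form, constant traces, idempotence", {
  x <- rbind(c(rep(2, 50) + rep(c(-0.5, 0.5), 25), 3),
             rep(7, 51))
  tm <- trace_matrix(x, sampling_rate = 10)
  mask <- c(rep(TRUE, 50), FALSE)
  z <- zscore_traces(tm, mask)
  # baseline mu = 2, sd ~ 0.5025; value 3 -> Z ~ 2
  expect_equal(z$traces[1, 51], (3 - 2) / stats::sd(x[1, 1:50]))
  expect_true(z$constant[2])
  expect_true(all(z$traces[2, ] == 0))
  # idempotence on already-Z-scored data
  z2 <- zscore_traces(z, mask)
  expect_lt(max(abs(z2$traces[1, ] - z$traces[1, ])), 1e-9)
  # all-constant matrix: flagged, no error
  zc <- zscore_traces(trace_matrix(matrix(1, 3, 20), 10))
  expect_true(all(zc$constant))
})

test_that("planted transient amplitude appears at the planted Z height", {
  s <- generate_population_session(population_config(
    n_neurons = 1, duration_s = 120, silent_fraction = 0,
    spontaneous_rate = 0, noise_sd = 0.2, amplitude_cv = 0,
    tuning_matrix = matrix(c(5 * 0.2, 0), 1), response_latency_mean = 0,
    seed = 21L))
  z <- zscore_traces(s$traces, baseline_mask(s$traces, s$events))
  ev <- s$events[s$events$label == "pup_sniff", ]
  peaks <- sapply(ev$onset_s, function(t0)
    max(z$traces[1, trace_times(z) >= t0 & trace_times(z) <= t0 + 0.5]))
  expect_true(all(abs(peaks - 5) < 4 * 1))  # 5 sigma transient +/- noise
  expect_gt(mean(peaks), 3)
})

test_that("detected-neuron count follows the planted silent fraction", {
  s0 <- generate_population_session(population_config(
    n_neurons = 10, duration_s = 120, silent_fraction = 1, seed = 3L))
  expect_equal(count_detected(s0$traces, s0$events)$count, 0L)

  s <- generate_population_session(population_config(
    n_neurons = 100, duration_s = 240, silent_fraction = 0.4, seed = 4L))
  det <- count_detected(s$traces, s$events)
  expect_lt(abs(det$count - 60), 3 * sqrt(100 * 0.4 * 0.6))
  # limiting case: infinite criterion detects nothing
  expect_equal(count_detected(s$traces, s$events, k = Inf)$count, 0L)
})

test_that("alignment recovers planted amplitudes and drops edge events", {
  s <- deterministic_session(amp_a = 2, amp_b = 0, n_neurons = 3)
  al <- aligned_pair(s)
  # deterministic frame-locked transients: per-bout responses identical up
  # to the vanishing decay tails of neighboring bouts
  expect_true(all(apply(al[[1]]$event_diffs, 1, stats::sd) < 1e-9))
  expect_true(all(al[[1]]$evoked_amplitude > 0.3))
  # the untuned stimulus never yields a positive evoked amplitude
  expect_true(all(al[[2]]$evoked_amplitude <= 1e-6))

  # event at the recording edge is dropped and counted
  ev_edge <- event_table(c(1, 50), c(4, 53), c("pup_sniff", "pup_sniff"))
  al_e <- align_events(s$traces, ev_edge, "pup_sniff", pre_s = 2, post_s = 5)
  expect_equal(al_e$n_events, 1L)
  expect_equal(al_e$n_dropped, 1L)
  # zero usable events: empty result with reason
  al_0 <- align_events(s$traces, ev_edge[1, ], "pup_sniff", pre_s = 3)
  expect_equal(al_0$n_events, 0L)
  expect_match(al_0$reason, "no usable events")
})

test_that("alignment is translation-equivariant", {
  s <- generate_population_session(population_config(
    n_neurons = 4, duration_s = 120, noise_sd = 0.1, seed = 31L))
  z <- zscore_traces(s$traces, baseline_mask(s$traces, s$events))
  al <- align_events(z, s$events, "pup_sniff")
  # shift both traces and events by exactly 2 s
  shift_n <- 2 * z$sampling_rate
  z_shift <- trace_matrix(cbind(matrix(0, 4, shift_n), z$traces),
                          z$sampling_rate, zscored = TRUE)
  ev_shift <- event_table(s$events$onset_s + 2, s$events$offset_s + 2,
                          s$events$label)
  al_s <- align_events(z_shift, ev_shift, "pup_sniff")
  expect_equal(al_s$evoked_amplitude, al$evoked_amplitude, tolerance = 1e-12)
  expect_equal(al_s$mean_traces, al$mean_traces, tolerance = 1e-12)
})

test_that("activation classification is one-sided, powered, and gated", {
  # planted 3 Z amplitude, 10 events -> activated
  s <- generate_population_session(population_config(
    n_neurons = 2, duration_s = 300, silent_fraction = 0,
    spontaneous_rate = 0, noise_sd = 0.2,
    tuning_matrix = matrix(c(3 * 0.2, 0, 0, 0), 2, byrow = TRUE),
    n_bouts_per_stimulus = 10, response_latency_mean = 0.2, seed = 41L))
  z <- zscore_traces(s$traces, baseline_mask(s$traces, s$events))
  al <- align_events(z, s$events, "pup_sniff")
  act <- classify_activated(al)
  expect_true(act$activated[1])
  expect_false(act$activated[2])

  # suppressed responses are never classified activated (one-sidedness)
  al_neg <- al
  al_neg$event_diffs <- -al$event_diffs
  expect_false(any(classify_activated(al_neg)$activated[1]))

  # fewer than 3 events: indeterminate
  al_few <- al
  al_few$n_events <- 2L
  expect_true(all(is.na(classify_activated(al_few)$activated)))
})

test_that("onset latency: step response, planted latency, never-crossing", {
  fake <- structure(list(
    window_t = seq(-1, 3, by = 0.05), sampling_rate = 20,
    mean_traces = rbind(
      c(rep(0, 20), rep(2, 61)),            # step at t = 0
      c(rep(0, 20), rep(0, 10), rep(2, 51)),# step at t = 0.5
      rep(0, 81))),                          # never crosses
    class = "aligned_set")
  lat <- onset_latency(fake, threshold_z = 1, sustain_s = 0.25)
  expect_equal(lat[1], 0)
  expect_equal(lat[2], 0.5)
  expect_true(is.na(lat[3]))
})

test_that("planted response latency is recovered within one bin", {
  s <- generate_population_session(population_config(
    n_neurons = 1, duration_s = 200, silent_fraction = 0,
    spontaneous_rate = 0, noise_sd = 0.05, amplitude_cv = 0,
    tuning_matrix = matrix(c(3 * 0.05 * 20, 0), 1),
    response_latency_mean = 0.5, n_bouts_per_stimulus = 8, seed = 42L))
  # latency draws have SD 0.1 s around 0.5 s, and the 1 Z threshold is
  # crossed on the rising flank of the latency distribution, so allow 2 SD
  z <- zscore_traces(s$traces, baseline_mask(s$traces, s$events))
  al <- align_events(z, s$events, "pup_sniff")
  lat <- onset_latency(al, threshold_z = 1)
  expect_lte(abs(lat[1] - 0.5), 0.2)
})

test_that("clustering recovers planted onset groups in onset order", {
  # two groups with onsets 0 s vs 1 s, 20 neurons each
  set.seed(51)
  wt <- seq(-2, 5, by = 0.05)
  early <- t(sapply(1:20, function(i)
    ifelse(wt >= 0, 2 * exp(-(wt) / 1.5), 0) +
      stats::rnorm(length(wt), 0, 0.02)))
  late <- t(sapply(1:20, function(i)
    ifelse(wt >= 1, 2 * exp(-(wt - 1) / 1.5), 0) +
      stats::rnorm(length(wt), 0, 0.02)))
  fake <- structure(list(window_t = wt, sampling_rate = 20,
                         mean_traces = rbind(early, late),
                         neuron_ids = 1:40), class = "aligned_set")
  co <- cluster_and_order(fake)
  expect_equal(co$n_clusters, 2L)
  expect_true(all(co$labels[1:20] == 1L))
  expect_true(all(co$labels[21:40] == 2L))
  expect_lt(co$cluster_onsets[1], co$cluster_onsets[2])
  # permuting the input neurons does not change the partition
  perm <- c(seq(2, 40, 2), seq(1, 39, 2))
  fake_p <- fake
  fake_p$mean_traces <- fake$mean_traces[perm, ]
  fake_p$neuron_ids <- fake$neuron_ids[perm]
  co_p <- cluster_and_order(fake_p)
  expect_equal(co_p$labels[match(1:40, perm)], co$labels)

  # two distinct neurons: two singleton clusters ordered by onset
  fake2 <- structure(list(window_t = wt, sampling_rate = 20,
                          mean_traces = rbind(late[1, ], early[1, ]),
                          neuron_ids = 1:2), class = "aligned_set")
  co2 <- cluster_and_order(fake2)
  expect_equal(co2$n_clusters, 2L)
  expect_equal(co2$labels, c(2L, 1L))  # late neuron listed first -> cluster 2
  # identical traces: one cluster
  fake1 <- structure(list(window_t = wt, sampling_rate = 20,
                          mean_traces = rbind(early[1, ], early[1, ]),
                          neuron_ids = 1:2), class = "aligned_set")
  expect_equal(cluster_and_order(fake1)$n_clusters, 1L)
})

test_that("activated fraction uses the detected denominator", {
  expect_equal(activated_fraction(c(TRUE, TRUE), c(TRUE, TRUE))$fraction, 1)
  expect_equal(activated_fraction(30L, 100L)$fraction, 0.30)
  expect_true(is.na(activated_fraction(0L, 0L)$fraction))
})

test_that("planted responsive fraction is recovered end to end", {
  set.seed(61)
  resp <- rep(c(TRUE, FALSE), c(30, 70))[sample.int(100)]
  s <- generate_population_session(population_config(
    n_neurons = 100, duration_s = 300, silent_fraction = 0,
    spontaneous_rate = 1, noise_sd = 0.1,
    tuning_matrix = cbind(ifelse(resp, 0.6, 0), 0),
    n_bouts_per_stimulus = 10, response_latency_mean = 0.3, seed = 62L))
  out <- evoked_summary(s$traces, s$events, "pup_sniff")
  expect_lt(abs(out$fraction$fraction - 0.30), 0.12)
})
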