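# Shared fixture builders. Everything is generated in code under fixed seeds.

# A noise-free two-stimulus session with fully deterministic evoked
# amplitudes (no amplitude CV, no latency jitter, no spontaneous activity),
# used wherever exact anchor values are asserted.
deterministic_session <- function(amp_a, amp_b, n_neurons = 1,
                                  stimuli = c("pup_sniff", "object_sniff"),
                                  n_bouts = 5, seed = 1L) {
  tun <- cbind(rep(amp_a, length.out = n_neurons),
               rep(amp_b, length.out = n_neurons))
  cfg <- population_config(
    n_neurons = n_neurons, duration_s = 180, sampling_rate = 20,
    silent_fraction = 0, spontaneous_rate = 0, noise_sd = 0,
    calcium_decay_tau = 0.5,  # short tail: bouts decouple numerically
    stimulus_set = stimuli, tuning_matrix = tun,
    response_latency_mean = 0, amplitude_cv = 0, snap_bouts = TRUE,
    n_bouts_per_stimulus = n_bouts, seed = seed)
  generate_population_session(cfg)
}

# aligned sets for both stimuli of a deterministic session (raw traces:
# noise-free baselines make Z-scoring degenerate by construction)
aligned_pair <- function(session, stimuli = c("pup_sniff", "object_sniff")) {
  lapply(stimuli, function(s)
    align_events(session$traces, session$events, s))
}

# brute-force Rand Index by explicit enumeration of all sample pairs
rand_index_bruteforce <- function(a, b) {
  n <- length(a)
  agree <- 0L; total <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    total <- total + 1L
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    if (same_a == same_b) agree <- agree + 1L
  }
  agree / total
}

# all set partitions of n items as label vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, mx) {
    k <- length(prefix)
    if (k == n) { out[[length(out) + 1L]] <<- prefix; return(invisible()) }
    for (v in seq_len(mx + 1L)) grow(c(prefix, v), max(mx, v))
  }
  grow(1L, 1L)
  out
}

# exact two-sided Mann-Whitney p-value by exhaustive enumeration of all
# rank arrangements (no ties assumed)
u_test_bruteforce <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2L, function(ix) sum(seq_len(n + m)[ix]) - n * (n + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# patch record with spikes at fixed times on a flat baseline (no noise)
planted_spike_record <- function(times, duration_s = 10, fs = 20000,
                                 rest = -60, base_width_ms = 2,
                                 peak_mv = 20) {
  cfg <- patch_config(duration_s = duration_s, sampling_rate = fs,
                      resting_potential_true = rest, spike_rate_true = 0,
                      silent = TRUE, psc_rate_true = 0, noise_sd_mv = 0,
                      noise_sd_pa = 0, ap_base_width_ms = base_width_ms,
                      ap_peak_mv = peak_mv, seed = 1L)
  r <- generate_patch_record(cfg)
  v <- r$voltage
  v <- galpop:::add_spikes(v, times, cfg, fs, rest)
  patch_record(voltage = v, current = r$current, sampling_rate = fs,
               baseline_window = c(0, duration_s))
}
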