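# Synthetic session generators with recorded ground truth. Every stochastic
# quantity a downstream stage estimates (silent flags, evoked amplitudes,
# event times, transition counts) is returned in metadata so recovery can be
# tested without external data.

#' Configuration for a synthetic population imaging session
#'
#' Describes one miniscope-style session: a population of neurons (a seeded
#' fraction of which is silent), spontaneous calcium transients in active
#' neurons, and stimulus/behavior bouts that evoke transients according to a
#' neuron-by-stimulus tuning matrix.
#'
#' Calcium transients are modeled as an instantaneous rise followed by a
#' single-exponential decay. Evoked amplitudes are lognormal around the
#' tuning-matrix mean (coefficient of variation `amplitude_cv`); onset
#' latencies are truncated-normal (>= 0) around `response_latency_mean` with
#' SD equal to 20% of the mean.
#'
#' @param n_neurons number of neurons.
#' @param duration_s session length, seconds.
#' @param sampling_rate frame rate, Hz.
#' @param silent_fraction fraction of neurons with no spontaneous or evoked
#'   transients (noise only), in `[0, 1]`. Silent neurons are chosen by a
#'   seeded shuffle, not by raw index order.
#' @param spontaneous_rate spontaneous transient rate per active neuron,
#'   events/min; scalar, or one value per neuron (heterogeneous baseline
#'   activity).
#' @param calcium_decay_tau transient decay time constant, seconds.
#' @param noise_sd additive Gaussian noise SD, fluorescence units.
#' @param stimulus_set character vector of stimulus/behavior labels.
#' @param tuning_matrix `n_neurons x length(stimulus_set)` matrix of mean
#'   evoked amplitudes (fluorescence units, >= 0; 0 = unresponsive). Default:
#'   amplitude 1 for every neuron and stimulus.
#' @param response_latency_mean mean evoked-onset latency after bout onset,
#'   seconds.
#' @param amplitude_cv coefficient of variation of evoked/spontaneous
#'   amplitudes (lognormal; 0 gives deterministic amplitudes).
#' @param n_bouts_per_stimulus bouts generated per stimulus.
#' @param bout_duration_s bout length, seconds.
#' @param snap_bouts snap bout onsets to the frame grid (frame-locked
#'   stimulus presentation); removes frame-phase variability of evoked
#'   responses across bouts, useful for exact fixtures.
#' @param state_label one of `"Vir"`, `"D10"`, `"D18"`, `"D22"`, `"D50"`.
#' @param seed integer seed; identical configs (including seed) generate
#'   bit-identical sessions.
#'
#' @return list of class `population_config`.
#' @export
population_config <- function(n_neurons, duration_s = 600, sampling_rate = 20,
                              silent_fraction = 0.2, spontaneous_rate = 2,
                              calcium_decay_tau = 1.5, noise_sd = 0.1,
                              stimulus_set = c("pup_sniff", "object_sniff"),
                              tuning_matrix = NULL,
                              response_latency_mean = 0.5,
                              amplitude_cv = 0.3,
                              n_bouts_per_stimulus = 8, bout_duration_s = 3,
                              snap_bouts = FALSE,
                              state_label = "Vir", seed = 1L) {
  stopifnot(n_neurons >= 0, duration_s > 0, sampling_rate > 0,
            silent_fraction >= 0, silent_fraction <= 1,
            all(spontaneous_rate >= 0),
            length(spontaneous_rate) %in% c(1L, as.integer(n_neurons)),
            calcium_decay_tau > 0, noise_sd >= 0,
            response_latency_mean >= 0, amplitude_cv >= 0,
            n_bouts_per_stimulus >= 0, bout_duration_s > 0)
  if (is.null(tuning_matrix))
    tuning_matrix <- matrix(1, n_neurons, length(stimulus_set))
  tuning_matrix <- as.matrix(tuning_matrix)
  if (!identical(dim(tuning_matrix),
                 c(as.integer(n_neurons), length(stimulus_set))) &&
      !(n_neurons == 0 && ncol(tuning_matrix) == length(stimulus_set)))
    stop("tuning_matrix must be n_neurons x length(stimulus_set)")
  if (any(tuning_matrix < 0)) stop("tuning amplitudes must be >= 0")
  structure(as.list(environment()), class = "population_config")
}

# lognormal draws with a given arithmetic mean and CV; cv = 0 is deterministic
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# truncated normal at zero; sd = 0 collapses to the mean
rtnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic population imaging session
#'
#' Produces a trace matrix, the event table of the stimulus bouts actually
#' placed, and a ground-truth list containing everything downstream stages
#' estimate: silent flags, spontaneous transient times, and per-bout evoked
#' amplitudes and latencies.
#'
#' Bouts are laid out in seeded-shuffled stimulus order over equal time slots
#' (with a 10 s lead-in and enough tail for post-onset analysis windows);
#' a session too short to hold the requested bouts is an error.
#'
#' @param config a [population_config()].
#' @return list with elements `traces` ([trace_matrix()]), `events`
#'   ([event_table()]) and `ground_truth`.
#' @export
generate_population_session <- function(config) {
  stopifnot(inherits(config, "population_config"))
  c_ <- config
  set.seed(c_$seed)
  n_t <- round(c_$duration_s * c_$sampling_rate)
  tt <- (seq_len(n_t) - 1L) / c_$sampling_rate

  if (c_$n_neurons == 0) {
    tm <- trace_matrix(matrix(numeric(), 0, n_t), c_$sampling_rate,
                       neuron_ids = integer(), state_label = c_$state_label)
    return(list(traces = tm, events = event_table(),
                ground_truth = list(silent = logical(),
                                    evoked_amplitude = NULL)))
  }

  # bout layout: lead-in, equal slots, jittered onsets, shuffled labels
  labels <- rep(c_$stimulus_set, each = c_$n_bouts_per_stimulus)
  n_bouts <- length(labels)
  lead_in <- 10; tail_s <- 6
  if (n_bouts > 0) {
    slot <- (c_$duration_s - lead_in - tail_s) / n_bouts
    if (slot < c_$bout_duration_s + 1)
      stop("capacity error: duration too short for requested bouts")
    labels <- labels[sample.int(n_bouts)]
    # onset jitter capped at 2 s so successive bouts keep a comfortable gap
    # for pre-onset baseline windows
    jitter <- stats::runif(n_bouts, 0, min(2, slot - c_$bout_duration_s - 1))
    onsets <- lead_in + (seq_len(n_bouts) - 1L) * slot + jitter
    if (isTRUE(c_$snap_bouts))
      onsets <- round(onsets * c_$sampling_rate) / c_$sampling_rate
    events <- event_table(onsets, onsets + c_$bout_duration_s, labels,
                          timepoint = c_$state_label)
  } else {
    events <- event_table()
  }

  shuffle <- sample.int(c_$n_neurons)
  silent <- rep(FALSE, c_$n_neurons)
  silent[shuffle[seq_len(floor(c_$silent_fraction * c_$n_neurons))]] <- TRUE

  traces <- matrix(stats::rnorm(c_$n_neurons * n_t, 0, c_$noise_sd),
                   c_$n_neurons, n_t)
  stim_idx <- match(events$label, c_$stimulus_set)
  evoked_amp <- matrix(0, c_$n_neurons, nrow(events))
  evoked_lat <- matrix(NA_real_, c_$n_neurons, nrow(events))
  spont_times <- vector("list", c_$n_neurons)

  add_transient <- function(row, t0, amp) {
    i0 <- ceiling(t0 * c_$sampling_rate - 1e-9) + 1L  # first frame at/after onset
    if (i0 > n_t) return(row)
    idx <- i0:n_t
    row[idx] <- row[idx] + amp * exp(-(tt[idx] - t0) / c_$calcium_decay_tau)
    row
  }

  spont_rate <- rep_len(c_$spontaneous_rate, c_$n_neurons)
  for (i in seq_len(c_$n_neurons)) {
    if (silent[i]) { spont_times[[i]] <- numeric(); next }
    n_sp <- stats::rpois(1L, spont_rate[i] / 60 * c_$duration_s)
    st <- sort(stats::runif(n_sp, 0, c_$duration_s))
    spont_times[[i]] <- st
    row <- traces[i, ]
    if (n_sp > 0) {
      amps <- rlnorm_mean_cv(n_sp, 1, c_$amplitude_cv)
      for (k in seq_len(n_sp)) row <- add_transient(row, st[k], amps[k])
    }
    if (nrow(events) > 0) {
      for (b in seq_len(nrow(events))) {
        mu <- c_$tuning_matrix[i, stim_idx[b]]
        if (mu <= 0) next
        amp <- rlnorm_mean_cv(1L, mu, c_$amplitude_cv)
        lat <- rtnorm_pos(1L, c_$response_latency_mean,
                          0.2 * c_$response_latency_mean)
        evoked_amp[i, b] <- amp
        evoked_lat[i, b] <- lat
        row <- add_transient(row, events$onset_s[b] + lat, amp)
      }
    }
    traces[i, ] <- row
  }

  tm <- trace_matrix(traces, c_$sampling_rate, state_label = c_$state_label)
  list(traces = tm, events = events,
       ground_truth = list(
         silent = silent, spontaneous_times = spont_times,
         evoked_amplitude = evoked_amp, evoked_latency = evoked_lat,
         tuning_matrix = c_$tuning_matrix, stimulus_set = c_$stimulus_set))
}

#' Preset session configurations for virgin-like and late-pregnancy-like states
#'
#' Encodes the qualitative contrast between the virgin and late-pregnancy
#' (D18) population regimes as planted ground truth: at D18, more silent
#' neurons, a smaller fraction of retrieval-responsive neurons, stronger and
#' shorter-latency pup-evoked responses, weaker responses to non-pup
#' stimuli, and a negative coupling between a neuron's spontaneous baseline
#' rate and its pup-evoked amplitude (quieter neurons are more pup-tuned).
#'
#' @param state `"Vir"` or `"D18"`.
#' @param n_neurons,duration_s,seed passed through to [population_config()].
#' @return a [population_config()] with `stimulus_set =
#'   c("retrieval", "pup_sniff", "object_sniff")`.
#' @export
state_preset_config <- function(state = c("Vir", "D18"), n_neurons = 60,
                                duration_s = 400, seed = 1L) {
  state <- match.arg(state)
  set.seed(seed + 7777L)  # responsiveness assignment, separate from session RNG
  stim <- c("retrieval", "pup_sniff", "object_sniff")
  p <- switch(state,
    Vir = list(silent = 0.15, latency = 1.0,
               resp = c(0.70, 0.60, 0.55), amp = c(2.0, 1.5, 1.2)),
    D18 = list(silent = 0.45, latency = 0.4,
               resp = c(0.35, 0.60, 0.30), amp = c(3.0, 3.0, 0.5)))
  tun <- sapply(seq_along(stim), function(j)
    ifelse(stats::runif(n_neurons) < p$resp[j], p$amp[j], 0))
  spont_rate <- 2
  if (state == "D18") {
    # plant the sparsening-tuning link: pup amplitude falls with the
    # neuron's spontaneous baseline rate
    spont_rate <- stats::runif(n_neurons, 0.3, 4)
    pup <- tun[, 2] > 0
    tun[pup, 2] <- 0.5 + 4.5 * (4 - spont_rate[pup]) / 3.7
  }
  population_config(
    n_neurons = n_neurons, duration_s = duration_s,
    silent_fraction = p$silent, spontaneous_rate = spont_rate,
    stimulus_set = stim, tuning_matrix = tun,
    response_latency_mean = p$latency,
    n_bouts_per_stimulus = 8, bout_duration_s = 3,
    state_label = state, seed = seed)
}

#' Configuration for a synthetic bout-level ethogram
#'
#' @param behavior_labels character vector of behaviors.
#' @param transition_matrix_true row-stochastic matrix (rows sum to 1 within
#'   1e-9) giving the probability of the next behavior given the current one.
#' @param dwell_mean mean bout duration(s), seconds; scalar or one value per
#'   behavior.
#' @param n_bouts number of bouts to draw (before merging of consecutive
#'   identical labels).
#' @param seed integer seed.
#' @return list of class `ethogram_config`.
#' @export
ethogram_config <- function(behavior_labels, transition_matrix_true,
                            dwell_mean = 5, n_bouts = 100, seed = 1L) {
  P <- as.matrix(transition_matrix_true)
  k <- length(behavior_labels)
  stopifnot(nrow(P) == k, ncol(P) == k, all(P >= 0), n_bouts >= 1,
            all(dwell_mean > 0))
  rs <- rowSums(P)
  if (any(rs == 0)) stop("config error: absorbing row with zero mass")
  if (any(abs(rs - 1) > 1e-9)) stop("transition matrix rows must sum to 1")
  dwell_mean <- rep_len(dwell_mean, k)
  structure(list(behavior_labels = behavior_labels, P = P,
                 dwell_mean = dwell_mean, n_bouts = n_bouts, seed = seed),
            class = "ethogram_config")
}

#' Generate a synthetic behavioral bout sequence
#'
#' Draws a Markov chain of behavior labels from the configured transition
#' matrix with exponentially distributed dwell times, then merges consecutive
#' identical labels into single bouts (bout-level ethograms leave A->A
#' undefined).
#'
#' @param config an [ethogram_config()].
#' @param timepoint,animal_id metadata stored on the returned table.
#' @return an [event_table()]; attribute `state_sequence` holds the unmerged
#'   chain (ground truth for transition-recovery tests).
#' @export
generate_ethogram <- function(config, timepoint = NA_character_,
                              animal_id = NA_character_) {
  stopifnot(inherits(config, "ethogram_config"))
  set.seed(config$seed)
  k <- length(config$behavior_labels)
  states <- integer(config$n_bouts)
  states[1L] <- sample.int(k, 1L)
  for (i in seq_len(config$n_bouts - 1L))
    states[i + 1L] <- sample.int(k, 1L, prob = config$P[states[i], ])
  dwell <- stats::rexp(config$n_bouts, 1 / config$dwell_mean[states])
  # merge consecutive identical states, summing their dwell times
  keep <- c(TRUE, states[-1L] != states[-config$n_bouts])
  grp <- cumsum(keep)
  m_states <- states[keep]
  m_dwell <- as.numeric(tapply(dwell, grp, sum))
  offs <- cumsum(m_dwell)
  ons <- c(0, offs[-length(offs)])
  ev <- event_table(ons, offs, config$behavior_labels[m_states],
                    animal_id = animal_id, timepoint = timepoint,
                    assay_duration_s = offs[length(offs)])
  attr(ev, "state_sequence") <- config$behavior_labels[states]
  ev
}

#' Configuration for a synthetic intracellular recording
#'
#' @param duration_s baseline (pre-stimulation) recording length, seconds.
#' @param sampling_rate Hz; >= 10 kHz recommended for half-width fidelity.
#' @param resting_potential_true mV.
#' @param spike_rate_true baseline firing rate, Hz (ignored when `silent`).
#' @param silent logical; a silent cell fires no baseline spikes.
#' @param depol_block_current current (pA) at and above which the cell stops
#'   spiking and plateaus depolarized; `NULL` for no block.
#' @param current_steps injected current steps, pA (1 s each, 0.5 s apart,
#'   appended after the baseline).
#' @param step_gain_hz_per_pa firing-rate gain during sub-block steps.
#' @param psc_rate_true spontaneous postsynaptic current rate, Hz.
#' @param psc_amplitude_mean mean PSC amplitude, pA.
#' @param psc_decay_tau_ms PSC decay time constant, ms.
#' @param epsc_fraction probability a PSC is excitatory (negative deflection
#'   at the modeled holding potential).
#' @param noise_sd_mv,noise_sd_pa Gaussian noise SD of the voltage / current
#'   traces.
#' @param ap_peak_mv spike peak voltage, mV.
#' @param ap_base_width_ms spike width at the detection-threshold level
#'   (baseline + 20 mV); the triangular waveform makes the analytic
#'   half-width `ap_base_width_ms / 2`.
#' @param seed integer seed.
#' @return list of class `patch_config`.
#' @export
patch_config <- function(duration_s = 60, sampling_rate = 20000,
                         resting_potential_true = -60,
                         spike_rate_true = 2, silent = FALSE,
                         depol_block_current = NULL,
                         current_steps = numeric(),
                         step_gain_hz_per_pa = 0.05,
                         psc_rate_true = 2, psc_amplitude_mean = 20,
                         psc_decay_tau_ms = 5, epsc_fraction = 0.6,
                         noise_sd_mv = 0.5, noise_sd_pa = 1.5,
                         ap_peak_mv = 20, ap_base_width_ms = 2,
                         seed = 1L) {
  stopifnot(duration_s > 0, sampling_rate > 0,
            epsc_fraction >= 0, epsc_fraction <= 1,
            psc_rate_true >= 0, spike_rate_true >= 0, ap_base_width_ms > 0)
  if (!is.null(depol_block_current) && length(current_steps) &&
      depol_block_current <= min(current_steps))
    warning("depol_block_current at or below the smallest step; no spiking step will precede the block")
  structure(as.list(environment()), class = "patch_config")
}

# Triangular spike waveform, returned as the excursion above the baseline
# level `base`. The triangle peaks at ap_peak_mv and its width at the
# detection-threshold level (base + 20 mV) is exactly ap_base_width_ms, so
# the analytic half-width (at the midpoint between threshold and peak) is
# ap_base_width_ms / 2.
spike_waveform <- function(config, fs, base) {
  thr <- base + 20
  peak <- config$ap_peak_mv
  stopifnot(peak > thr)
  half_thr_s <- config$ap_base_width_ms / 2 / 1000   # half of width at thr, s
  slope <- (peak - thr) / half_thr_s                  # mV per s
  half_full_s <- (peak - base) / slope                # half of width at base
  n_half <- ceiling(half_full_s * fs)
  t_rel <- (-n_half:n_half) / fs
  pmax(peak - slope * abs(t_rel) - base, 0)
}

# adds spike excursions (above baseline `base`) at given times
add_spikes <- function(v, times, config, fs, base) {
  if (!length(times)) return(v)
  w <- spike_waveform(config, fs, base)
  half <- (length(w) - 1L) %/% 2L
  n <- length(v)
  for (t0 in times) {
    c0 <- round(t0 * fs) + 1L
    idx <- (c0 - half):(c0 + half)
    ok <- idx >= 1L & idx <= n
    v[idx[ok]] <- v[idx[ok]] + w[ok]
  }
  v
}

#' Generate a synthetic intracellular recording
#'
#' Voltage trace: Gaussian noise around the true resting potential, with
#' stereotyped triangular spikes at Poisson times (none when `silent`);
#' current steps appended after the baseline elicit regular spiking at
#' `step_gain_hz_per_pa * step_pa` Hz, except at/above `depol_block_current`
#' where spiking ceases and the membrane plateaus ~30 mV depolarized.
#' Current trace (same duration as the baseline): PSCs with instantaneous
#' rise and exponential decay; sign is excitatory (negative) with probability
#' `epsc_fraction`.
#'
#' @param config a [patch_config()].
#' @param cell_id,group_label metadata.
#' @return a [patch_record()]; `$ground_truth` holds planted spike times,
#'   PSC times/signs and all true parameters.
#' @export
generate_patch_record <- function(config, cell_id = NA_character_,
                                  group_label = NA_character_) {
  stopifnot(inherits(config, "patch_config"))
  c_ <- config
  set.seed(c_$seed)
  fs <- c_$sampling_rate
  rest <- c_$resting_potential_true

  step_dur <- 1; step_gap <- 0.5
  n_steps <- length(c_$current_steps)
  total_dur <- c_$duration_s + n_steps * (step_dur + step_gap)
  n <- round(total_dur * fs)
  v <- rest + stats::rnorm(n, 0, c_$noise_sd_mv)
  t_all <- (seq_len(n) - 1L) / fs

  # waveform margin so spikes sit fully inside their window
  margin <- (c_$ap_peak_mv - rest) /
    ((c_$ap_peak_mv - (rest + 20)) / (c_$ap_base_width_ms / 2 / 1000))

  spike_times <- numeric()
  if (!c_$silent && c_$spike_rate_true > 0) {
    n_sp <- stats::rpois(1L, c_$spike_rate_true * c_$duration_s)
    spike_times <- sort(stats::runif(n_sp, margin, c_$duration_s - margin))
    # enforce a 10 ms minimum separation so planted count is recoverable
    if (length(spike_times) > 1L) {
      keep <- c(TRUE, diff(spike_times) > 0.010)
      while (!all(keep)) {
        spike_times <- spike_times[keep]
        keep <- c(TRUE, diff(spike_times) > 0.010)
      }
    }
  }
  v <- add_spikes(v, spike_times, c_, fs, rest)

  # current-step segments
  sp_rows <- NULL
  step_spike_times <- list()
  if (n_steps) {
    starts <- c_$duration_s + step_gap + (seq_len(n_steps) - 1L) * (step_dur + step_gap)
    sp_rows <- data.frame(step_pa = c_$current_steps, start_s = starts,
                          end_s = starts + step_dur)
    for (s in seq_len(n_steps)) {
      i0 <- round(starts[s] * fs) + 1L
      i1 <- round((starts[s] + step_dur) * fs)
      blocked <- !is.null(c_$depol_block_current) &&
        c_$current_steps[s] >= c_$depol_block_current
      if (blocked) {
        v[i0:i1] <- rest + 30 + stats::rnorm(i1 - i0 + 1L, 0, c_$noise_sd_mv)
        step_spike_times[[s]] <- numeric()
      } else {
        rate <- c_$step_gain_hz_per_pa * max(c_$current_steps[s], 0)
        n_sp <- floor(rate * step_dur)
        st <- if (n_sp > 0)
          starts[s] + margin + (seq_len(n_sp) - 0.5) / n_sp * (step_dur - 2 * margin)
        else numeric()
        v <- add_spikes(v, st, c_, fs, rest)
        step_spike_times[[s]] <- st
      }
    }
  }

  # voltage-clamp current trace over the baseline duration
  n_c <- round(c_$duration_s * fs)
  cur <- stats::rnorm(n_c, 0, c_$noise_sd_pa)
  psc_times <- numeric(); psc_kind <- character(); psc_amp <- numeric()
  if (c_$psc_rate_true > 0) {
    n_psc <- stats::rpois(1L, c_$psc_rate_true * c_$duration_s)
    psc_times <- sort(stats::runif(n_psc, 0.05, c_$duration_s - 0.05))
    if (length(psc_times) > 1L) {  # separable by construction
      keep <- c(TRUE, diff(psc_times) > 0.05)
      while (!all(keep)) {
        psc_times <- psc_times[keep]
        keep <- c(TRUE, diff(psc_times) > 0.05)
      }
    }
    n_psc <- length(psc_times)
    psc_kind <- ifelse(stats::runif(n_psc) < c_$epsc_fraction, "EPSC", "IPSC")
    psc_amp <- rlnorm_mean_cv(n_psc, c_$psc_amplitude_mean, 0.3)
    tau_s <- c_$psc_decay_tau_ms / 1000
    tt <- (seq_len(n_c) - 1L) / fs
    for (k in seq_len(n_psc)) {
      i0 <- round(psc_times[k] * fs) + 1L
      i1 <- min(i0 + round(10 * tau_s * fs), n_c)
      sgn <- if (psc_kind[k] == "EPSC") -1 else 1
      cur[i0:i1] <- cur[i0:i1] +
        sgn * psc_amp[k] * exp(-(tt[i0:i1] - tt[i0]) / tau_s)
    }
  }

  patch_record(
    voltage = v, current = cur, sampling_rate = fs,
    step_protocol = sp_rows, baseline_window = c(0, c_$duration_s),
    cell_id = cell_id, group_label = group_label,
    ground_truth = list(
      spike_times = spike_times, step_spike_times = step_spike_times,
      psc_times = psc_times, psc_kind = psc_kind, psc_amplitude = psc_amp,
      resting_potential_true = rest, spike_rate_true = c_$spike_rate_true,
      psc_rate_true = c_$psc_rate_true, silent = c_$silent,
      depol_block_current = c_$depol_block_current,
      analytic_half_width_ms = c_$ap_base_width_ms / 2))
}
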