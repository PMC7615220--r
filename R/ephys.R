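# Feature extraction from intracellular records: spikes, baseline firing,
# resting potential, silent classification, depolarization block, AP
# half-width, and spontaneous postsynaptic currents.

# mode of the voltage distribution (0.5 mV bins); robust baseline level even
# in the presence of spikes or plateau segments
voltage_mode <- function(v, bin_mv = 0.5) {
  b <- round(v / bin_mv)
  as.numeric(names(which.max(table(b)))) * bin_mv
}

#' Detect action potentials by threshold crossing
#'
#' Spikes are upward crossings of a voltage threshold separated by at least
#' the refractory interval. By default the threshold is relative: the mode of
#' the baseline-window voltage plus 20 mV, which makes detection invariant to
#' DC offsets and to resting-potential differences between groups.
#'
#' @param record a [patch_record()] with a voltage trace.
#' @param threshold_mv absolute threshold in mV; `NULL` (default) uses
#'   baseline mode + `relative_offset_mv`.
#' @param relative_offset_mv offset above the baseline mode, mV.
#' @param refractory_ms minimum inter-spike interval, ms.
#' @param window optional `c(start, end)` seconds restricting detection.
#' @return numeric vector of spike times (seconds, crossing sample).
#' @export
detect_spikes <- function(record, threshold_mv = NULL,
                          relative_offset_mv = 20, refractory_ms = 2,
                          window = NULL) {
  stopifnot(inherits(record, "patch_record"), !is.null(record$voltage))
  fs <- record$sampling_rate
  if (fs < 2000 / refractory_ms)
    warning("sampling rate too low to resolve the refractory interval")
  v <- record$voltage
  if (!length(v)) return(numeric())
  if (is.null(threshold_mv)) {
    bw <- record$baseline_window
    bi <- pmax(1L, round(bw[1] * fs) + 1L):min(length(v), round(bw[2] * fs))
    threshold_mv <- voltage_mode(v[bi]) + relative_offset_mv
  }
  i0 <- 1L; i1 <- length(v)
  if (!is.null(window)) {
    i0 <- max(1L, round(window[1] * fs) + 1L)
    i1 <- min(length(v), round(window[2] * fs))
    if (i0 >= i1) return(numeric())
  }
  seg <- v[i0:i1]
  up <- which(seg[-1L] >= threshold_mv & seg[-length(seg)] < threshold_mv) + 1L
  if (!length(up)) return(numeric())
  refr <- refractory_ms / 1000 * fs
  keep <- logical(length(up)); last <- -Inf
  for (k in seq_along(up)) {
    if (up[k] - last >= refr) { keep[k] <- TRUE; last <- up[k] }
  }
  (up[keep] + i0 - 2L) / fs
}

#' Baseline firing, resting potential and silent classification
#'
#' Firing frequency is the spike count over the baseline window divided by
#' its length; resting potential is the median voltage after masking +/- 5 ms
#' around each spike; a cell is silent when its baseline firing falls below
#' `silent_threshold_hz` (default 0.05 Hz, i.e. no spike in a 20 s window).
#'
#' @param record a [patch_record()].
#' @param baseline_window `c(start, end)` seconds; default the record's
#'   baseline window (which precedes any current step).
#' @param silent_threshold_hz firing rate below which a cell is silent.
#' @param ... passed to [detect_spikes()].
#' @return list with `baseline_firing_hz`, `resting_potential_mv`,
#'   `is_silent`, `spike_times`.
#' @export
baseline_features <- function(record, baseline_window = NULL,
                              silent_threshold_hz = 0.05, ...) {
  stopifnot(inherits(record, "patch_record"))
  bw <- if (is.null(baseline_window)) record$baseline_window else baseline_window
  len <- bw[2] - bw[1]
  if (len < 1) warning("baseline window under 1 s; firing estimate imprecise")
  st <- detect_spikes(record, window = bw, ...)
  fs <- record$sampling_rate
  idx <- pmax(1L, round(bw[1] * fs) + 1L):min(length(record$voltage),
                                              round(bw[2] * fs))
  tt <- (idx - 1L) / fs
  mask <- rep(TRUE, length(idx))
  for (s in st) mask[abs(tt - s) <= 0.005] <- FALSE
  list(baseline_firing_hz = length(st) / len,
       resting_potential_mv = stats::median(record$voltage[idx][mask]),
       is_silent = (length(st) / len) < silent_threshold_hz,
       spike_times = st)
}

#' Detect depolarization block across a current-step protocol
#'
#' Computes per-step spike counts, then declares block at the first step
#' whose count drops below 50% of the maximum across lower steps while the
#' mean step voltage exceeds the mean voltage of the spiking (lower) steps by
#' at least 5 mV. Cells in which no step elicits at least 2 spikes are
#' indeterminate.
#'
#' @param record a [patch_record()] with `step_protocol` of >= 3 steps.
#' @param drop_fraction count-drop criterion (default 0.5).
#' @param plateau_mv required depolarization of the blocked step relative to
#'   spiking steps, mV.
#' @param ... passed to [detect_spikes()].
#' @return list with `depol_block` (flag), `block_current_pa` (`NA` when no
#'   block), `step_counts`, and `status` (`"ok"` or `"insufficient spiking"`).
#' @export
detect_depolarization_block <- function(record, drop_fraction = 0.5,
                                        plateau_mv = 5, ...) {
  stopifnot(inherits(record, "patch_record"))
  sp <- record$step_protocol
  if (is.null(sp) || nrow(sp) < 3)
    stop("step protocol with >= 3 increasing steps required")
  sp <- sp[order(sp$step_pa), , drop = FALSE]
  fs <- record$sampling_rate
  counts <- integer(nrow(sp)); vmean <- numeric(nrow(sp))
  for (s in seq_len(nrow(sp))) {
    st <- detect_spikes(record, window = c(sp$start_s[s], sp$end_s[s]), ...)
    counts[s] <- length(st)
    idx <- (round(sp$start_s[s] * fs) + 1L):round(sp$end_s[s] * fs)
    vmean[s] <- mean(record$voltage[idx])
  }
  if (max(counts) < 2)
    return(list(depol_block = FALSE, block_current_pa = NA_real_,
                step_counts = counts, status = "insufficient spiking"))
  for (s in 2:nrow(sp)) {
    lower <- seq_len(s - 1L)
    mx <- max(counts[lower])
    if (mx < 2) next
    spiking <- lower[counts[lower] > 0]
    if (counts[s] < drop_fraction * mx &&
        vmean[s] >= mean(vmean[spiking]) + plateau_mv)
      return(list(depol_block = TRUE, block_current_pa = sp$step_pa[s],
                  step_counts = counts, status = "ok"))
  }
  list(depol_block = FALSE, block_current_pa = NA_real_,
       step_counts = counts, status = "ok")
}

#' Action-potential half-width
#'
#' For each spike, the width of the waveform at the level halfway between
#' the threshold voltage and the spike peak, found by linear interpolation on
#' both flanks; the median across spikes is returned. Clipped spikes (peak
#' pinned at the trace maximum for more than 2 samples) are excluded with a
#' warning.
#'
#' @param record a [patch_record()].
#' @param spike_times spike times from [detect_spikes()]; >= 1 required.
#' @param threshold_mv threshold voltage defining the spike base; default the
#'   baseline mode + 20 mV (the detection default).
#' @param search_ms half-window around each spike time searched for the
#'   peak, ms.
#' @return median half-width in ms.
#' @export
ap_half_width <- function(record, spike_times, threshold_mv = NULL,
                          search_ms = 4) {
  stopifnot(inherits(record, "patch_record"))
  if (!length(spike_times)) stop("at least one spike required")
  v <- record$voltage; fs <- record$sampling_rate
  if (is.null(threshold_mv)) {
    bw <- record$baseline_window
    bi <- pmax(1L, round(bw[1] * fs) + 1L):min(length(v), round(bw[2] * fs))
    threshold_mv <- voltage_mode(v[bi]) + 20
  }
  vmax <- max(v)
  hw <- numeric(0); clipped <- 0L
  for (s in spike_times) {
    c0 <- round(s * fs) + 1L
    idx <- max(1L, c0 - round(search_ms / 1000 * fs)):
      min(length(v), c0 + round(search_ms / 1000 * fs))
    seg <- v[idx]
    pk <- which.max(seg)
    if (sum(seg >= vmax - 1e-9) > 2) { clipped <- clipped + 1L; next }
    half <- (threshold_mv + seg[pk]) / 2
    # left flank crossing
    li <- pk; while (li > 1L && seg[li - 1L] >= half) li <- li - 1L
    if (li == 1L || seg[li - 1L] > half) next
    fl <- (li - 1L) + (half - seg[li - 1L]) / (seg[li] - seg[li - 1L])
    # right flank crossing
    ri <- pk; while (ri < length(seg) && seg[ri + 1L] >= half) ri <- ri + 1L
    if (ri == length(seg)) next
    fr <- ri + (seg[ri] - half) / (seg[ri] - seg[ri + 1L])
    hw <- c(hw, (fr - fl) / fs * 1000)
  }
  if (clipped > 0)
    warning(sprintf("%d clipped spike(s) excluded from half-width", clipped))
  if (!length(hw)) return(NA_real_)
  stats::median(hw)
}

#' Detect spontaneous postsynaptic currents
#'
#' Events are deflections of the current trace exceeding
#' `amplitude_threshold_pa` relative to the trace median, separated by at
#' least `min_separation_ms`, whose post-peak decay fits a single exponential
#' with a time constant inside `tau_bounds_ms`. Negative deflections are
#' classified EPSC (inward current at the modeled holding potential),
#' positive IPSC; the convention is recorded in the result.
#'
#' @param record a [patch_record()] with a current trace.
#' @param amplitude_threshold_pa detection threshold over local baseline, pA.
#' @param decay_fit_window_ms window after the peak used for the
#'   exponential-decay fit, ms.
#' @param tau_bounds_ms admissible decay time constants, ms.
#' @param min_separation_ms events closer than this are split at the local
#'   minimum between peaks and flagged.
#' @return list of class `psc_events`: `event_times`, `amplitudes` (signed
#'   pA), `kinds`, `frequency_hz`, `epsc_frequency_hz`, `ipsc_frequency_hz`,
#'   `sign_convention`, `n_split`.
#' @export
detect_pscs <- function(record, amplitude_threshold_pa = 5,
                        decay_fit_window_ms = 15, tau_bounds_ms = c(0.5, 50),
                        min_separation_ms = 5, smooth_ms = 0.5) {
  stopifnot(inherits(record, "patch_record"), !is.null(record$current))
  x <- record$current - stats::median(record$current)
  fs <- record$sampling_rate
  # light boxcar smoothing suppresses single-sample noise excursions without
  # attenuating PSC peaks (decay constants are an order of magnitude longer)
  klen <- max(1L, round(smooth_ms / 1000 * fs))
  if (klen > 1L) {
    sm <- stats::filter(x, rep(1 / klen, klen), sides = 2L)
    x <- as.numeric(ifelse(is.na(sm), x, sm))
  }
  dur <- length(x) / fs
  sep <- round(min_separation_ms / 1000 * fs)
  over <- which(abs(x) > amplitude_threshold_pa)
  times <- numeric(); amps <- numeric(); n_split <- 0L
  if (length(over)) {
    # group supra-threshold samples separated by < sep into candidate events
    brk <- c(0L, which(diff(over) >= sep), length(over))
    for (g in seq_len(length(brk) - 1L)) {
      idx <- over[(brk[g] + 1L):brk[g + 1L]]
      seg <- x[idx]
      pk_rel <- which.max(abs(seg))
      pk <- idx[pk_rel]
      # overlapping events: additional local extremum beyond the decay window
      # of the first peak -> split at the intervening local minimum
      sub_peaks <- pk
      if (length(idx) > 1L) {
        runs <- split(idx, cumsum(c(1L, diff(idx) > 1L)))
        cand <- vapply(runs, function(r) r[which.max(abs(x[r]))], integer(1))
        cand <- cand[abs(x[cand]) > amplitude_threshold_pa]
        cand <- sort(unique(cand))
        if (length(cand) > 1L) {
          keep <- cand[c(TRUE, diff(cand) >= sep)]
          if (length(keep) > 1L) { sub_peaks <- keep; n_split <- n_split + length(keep) - 1L }
        }
      }
      for (p in sub_peaks) {
        # fast-rise requirement: PSC onsets rise near-instantaneously, so
        # slow re-crossings on a decay tail are not separate events
        i_pre <- max(1L, p - round(0.001 * fs))
        if (abs(x[p]) - abs(x[i_pre]) < amplitude_threshold_pa / 2) next
        # exponential-decay check on the rectified post-peak segment
        wlen <- round(decay_fit_window_ms / 1000 * fs)
        di <- p:min(length(x), p + wlen)
        y <- abs(x[di])
        usable <- y > max(amplitude_threshold_pa / 4, 1e-9)
        run <- cumprod(usable) > 0  # leading usable run only
        if (sum(run) < 4) next  # too brief to be a PSC at this sampling rate
        tfit <- (di[run] - p) / fs
        fit <- stats::lm.fit(cbind(1, tfit), log(y[run]))
        tau_ms <- -1000 / fit$coefficients[2]
        if (!is.finite(tau_ms) || tau_ms < tau_bounds_ms[1] ||
            tau_ms > tau_bounds_ms[2]) next
        times <- c(times, (p - 1L) / fs)
        amps <- c(amps, x[p])
      }
    }
  }
  kinds <- ifelse(amps < 0, "EPSC", "IPSC")
  structure(list(
    event_times = times, amplitudes = amps, kinds = kinds,
    frequency_hz = length(times) / dur,
    epsc_frequency_hz = sum(kinds == "EPSC") / dur,
    ipsc_frequency_hz = sum(kinds == "IPSC") / dur,
    sign_convention = "negative deflection = EPSC",
    n_split = n_split), class = "psc_events")
}

#' Full per-cell feature extraction
#'
#' Convenience wrapper combining [baseline_features()],
#' [detect_depolarization_block()] (when a step protocol exists),
#' [ap_half_width()] and [detect_pscs()] into one row of features.
#'
#' @param record a [patch_record()].
#' @param ... passed to [baseline_features()].
#' @return one-row tibble of EphysFeatures.
#' @export
extract_ephys_features <- function(record, ...) {
  bf <- baseline_features(record, ...)
  db <- if (!is.null(record$step_protocol) && nrow(record$step_protocol) >= 3)
    detect_depolarization_block(record)
  else list(depol_block = NA, block_current_pa = NA_real_)
  hw <- if (length(bf$spike_times))
    ap_half_width(record, bf$spike_times) else NA_real_
  psc <- if (!is.null(record$current)) detect_pscs(record) else NULL
  tibble::tibble(
    cell_id = record$cell_id, group_label = record$group_label,
    baseline_firing_hz = bf$baseline_firing_hz,
    resting_potential_mv = bf$resting_potential_mv,
    is_silent = bf$is_silent,
    depol_block = db$depol_block, block_current_pa = db$block_current_pa,
    ap_half_width_ms = hw,
    psc_frequency_hz = if (is.null(psc)) NA_real_ else psc$frequency_hz,
    epsc_frequency_hz = if (is.null(psc)) NA_real_ else psc$epsc_frequency_hz,
    ipsc_frequency_hz = if (is.null(psc)) NA_real_ else psc$ipsc_frequency_hz)
}
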