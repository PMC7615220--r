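# Event-aligned population analysis: Z-scoring, transient detection,
# activated-neuron classification, onset latency, and onset-ordered
# hierarchical clustering.

#' Baseline mask from an event table
#'
#' Samples outside every event window padded by `pad_s` on both sides.
#'
#' @param tm a [trace_matrix()].
#' @param events an [event_table()] (or `NULL` for an all-`TRUE` mask).
#' @param pad_s padding around each event, seconds.
#' @return logical vector over samples.
#' @export
baseline_mask <- function(tm, events = NULL, pad_s = 2) {
  tt <- trace_times(tm)
  mask <- rep(TRUE, length(tt))
  if (!is.null(events) && nrow(events)) {
    for (b in seq_len(nrow(events)))
      mask[tt >= events$onset_s[b] - pad_s & tt <= events$offset_s[b] + pad_s] <- FALSE
  }
  mask
}

#' Z-score traces against a baseline period
#'
#' Per neuron, `(x - mu_base) / sd_base` over the masked baseline samples.
#' Neurons with zero baseline SD are flagged constant and their Z trace set
#' to 0; an all-constant matrix is handled without error.
#'
#' @param tm a [trace_matrix()].
#' @param mask logical baseline mask over samples (default: all samples; use
#'   [baseline_mask()] to exclude event windows).
#' @return a Z-scored [trace_matrix()] with per-neuron `constant` flags.
#' @export
zscore_traces <- function(tm, mask = NULL) {
  stopifnot(inherits(tm, "trace_matrix"))
  if (is.null(mask)) mask <- rep(TRUE, ncol(tm$traces))
  if (!any(mask)) stop("baseline mask is empty")
  base <- tm$traces[, mask, drop = FALSE]
  mu <- rowMeans(base)
  sd <- apply(base, 1L, stats::sd)
  constant <- !is.finite(sd) | sd < 1e-12
  z <- (tm$traces - mu) / ifelse(constant, 1, sd)
  z[constant, ] <- 0
  trace_matrix(z, tm$sampling_rate, tm$neuron_ids, tm$state_label,
               tm$animal_id, zscored = TRUE, constant = constant)
}

#' Detect calcium transients per neuron
#'
#' A transient is a run of samples at or above `k` baseline SDs (i.e. Z >= k
#' on Z-scored data) lasting at least `min_duration_s`.
#'
#' @param tm a [trace_matrix()]; Z-scored internally (against `mask`) when
#'   not already.
#' @param k threshold in baseline-SD units.
#' @param min_duration_s minimum supra-threshold duration, seconds.
#' @param mask optional baseline mask for internal Z-scoring; also restricts
#'   which onsets are counted when `restrict = TRUE`.
#' @param restrict count only transients whose onset falls in `mask`.
#' @param k_end hysteresis floor: an event lasts until the trace falls below
#'   `k_end` SDs, and a new event cannot start before that, so noise
#'   re-crossings on a decay tail are not counted as fresh transients.
#' @return list per neuron of transient onset times (seconds).
#' @export
detect_transients <- function(tm, k = 3, min_duration_s = 0.2, mask = NULL,
                              restrict = FALSE, k_end = 0.5) {
  stopifnot(inherits(tm, "trace_matrix"))
  z <- if (isTRUE(tm$zscored)) tm else zscore_traces(tm, mask)
  min_len <- max(1L, round(min_duration_s * tm$sampling_rate))
  tt <- trace_times(tm)
  lapply(seq_len(nrow(z$traces)), function(i) {
    if (!is.finite(k)) return(numeric())
    zi <- z$traces[i, ]
    hot <- zi >= k
    if (!any(hot)) return(numeric())
    cold <- zi < k_end
    onsets <- integer(); run <- 0L; armed <- TRUE; start <- NA_integer_
    in_event <- FALSE
    for (j in seq_along(zi)) {
      if (in_event) {
        if (cold[j]) { in_event <- FALSE; armed <- TRUE; run <- 0L }
        next
      }
      if (!armed) { if (cold[j]) armed <- TRUE; run <- 0L; next }
      if (hot[j]) {
        run <- run + 1L
        if (run == 1L) start <- j
        if (run >= min_len) { onsets <- c(onsets, start); in_event <- TRUE }
      } else run <- 0L
    }
    out <- tt[onsets]
    if (restrict && !is.null(mask)) out <- out[mask[onsets]]
    out
  })
}

#' Count transient onsets by their fast rise
#'
#' Rate-oriented transient counter: an onset is a local maximum of the
#' boxcar rise signal (forward-window mean minus backward-window mean)
#' exceeding `k_onset` robust SDs of that signal. Because calcium transients
#' rise near-instantaneously and decay slowly, a fresh onset is visible even
#' on the decay tail of a previous transient, so overlapping events are
#' counted separately — unlike threshold-crossing detection, which merges
#' them. Used for baseline transient-rate estimates.
#'
#' @param tm a [trace_matrix()] (raw or Z-scored).
#' @param mask optional logical baseline mask; the robust SD of the rise
#'   signal is estimated on masked samples, and with `restrict = TRUE` only
#'   onsets inside the mask are returned.
#' @param k_onset threshold in robust (MAD-based) SDs of the rise signal.
#' @param smooth_s rise-window length, seconds.
#' @param min_sep_s minimum separation between counted onsets, seconds.
#' @param restrict return only onsets inside `mask`.
#' @return list per neuron of onset times (seconds).
#' @export
detect_transient_onsets <- function(tm, mask = NULL, k_onset = 5,
                                    smooth_s = 0.25, min_sep_s = 0.5,
                                    restrict = FALSE) {
  stopifnot(inherits(tm, "trace_matrix"))
  fs <- tm$sampling_rate
  L <- max(1L, round(smooth_s * fs))
  W <- max(1L, round(min_sep_s * fs))
  tt <- trace_times(tm)
  n_t <- ncol(tm$traces)
  lapply(seq_len(nrow(tm$traces)), function(i) {
    x <- tm$traces[i, ]
    if (n_t < 2L * L + 2L) return(numeric())
    cs <- cumsum(x)
    # rise[t] = mean(x[t .. t+L-1]) - mean(x[t-L .. t-1])
    t_idx <- (L + 1L):(n_t - L + 1L)
    fwd <- (cs[t_idx + L - 1L] - c(0, cs)[t_idx]) / L
    bwd <- (cs[t_idx - 1L] - c(0, cs)[t_idx - L]) / L
    rise <- fwd - bwd
    msk <- if (is.null(mask)) rep(TRUE, length(rise)) else mask[t_idx]
    sig <- stats::mad(rise[msk])
    if (!is.finite(sig) || sig < 1e-12) sig <- stats::mad(rise)
    if (!is.finite(sig) || sig < 1e-12) return(numeric())
    cand <- which(rise >= k_onset * sig)
    if (!length(cand)) return(numeric())
    # local maxima of the rise signal within +/- min_sep
    is_peak <- vapply(cand, function(c0) {
      lo <- max(1L, c0 - W); hi <- min(length(rise), c0 + W)
      rise[c0] >= max(rise[lo:hi])
    }, logical(1))
    on <- cand[is_peak]
    if (length(on) > 1L) {       # enforce separation among tied plateaus
      keep <- c(TRUE, diff(on) >= W)
      on <- on[keep]
    }
    out_idx <- t_idx[on]
    out <- tt[out_idx]
    if (restrict && !is.null(mask)) out <- out[mask[out_idx]]
    out
  })
}

#' Count detected (non-silent) neurons
#'
#' A neuron is detected when it exhibits at least one calcium transient
#' (>= `k` baseline SDs sustained for `min_duration_s`). `k = Inf` detects
#' nothing, by construction.
#'
#' @inheritParams detect_transients
#' @param events events used to build the Z-scoring baseline mask (optional).
#' @param pad_s baseline-mask padding, seconds.
#' @return list with `count` and logical `detected` per neuron.
#' @export
count_detected <- function(tm, events = NULL, k = 3, min_duration_s = 0.2,
                           pad_s = 2) {
  mask <- baseline_mask(tm, events, pad_s)
  tr <- detect_transients(tm, k = k, min_duration_s = min_duration_s,
                          mask = mask)
  detected <- lengths(tr) > 0
  list(count = sum(detected), detected = detected)
}

#' Align traces to event onsets
#'
#' Builds, for every neuron, an events-by-window matrix aligned to the onset
#' of each bout with the requested label; events whose window extends beyond
#' the recording are dropped and counted. The evoked amplitude is the mean
#' over the response window minus the mean over the pre-onset baseline
#' window, averaged across events.
#'
#' @param tm a [trace_matrix()] (normally Z-scored).
#' @param events an [event_table()].
#' @param label bout label to align to.
#' @param pre_s,post_s window before/after onset, seconds.
#' @param response_window `c(start, end)` seconds relative to onset used for
#'   the evoked amplitude.
#' @return list of class `aligned_set`: `window_t`, `aligned` (list of
#'   events x window matrices per neuron), `mean_traces` (neurons x window),
#'   `evoked_amplitude`, `event_diffs` (neurons x events matrix of per-event
#'   response-minus-baseline means), `n_events`, `n_dropped`, `label`,
#'   `sampling_rate`, `neuron_ids`.
#' @export
align_events <- function(tm, events, label, pre_s = 2, post_s = 5,
                         response_window = c(0, 3)) {
  stopifnot(inherits(tm, "trace_matrix"))
  ev <- events_with_label(events, label)
  fs <- tm$sampling_rate
  tt <- trace_times(tm)
  n_pre <- round(pre_s * fs); n_post <- round(post_s * fs)
  window_t <- (-n_pre:n_post) / fs
  onset_idx <- round(ev$onset_s * fs) + 1L
  ok <- onset_idx - n_pre >= 1L & onset_idx + n_post <= length(tt)
  n_dropped <- sum(!ok)
  onset_idx <- onset_idx[ok]
  n_ev <- length(onset_idx)
  if (n_ev == 0) {
    return(structure(list(window_t = window_t, aligned = NULL,
                          mean_traces = NULL, evoked_amplitude = NULL,
                          event_diffs = NULL, n_events = 0L,
                          n_dropped = n_dropped, label = label,
                          sampling_rate = fs, neuron_ids = tm$neuron_ids,
                          reason = "no usable events"),
                     class = "aligned_set"))
  }
  resp_cols <- which(window_t >= response_window[1] & window_t <= response_window[2])
  base_cols <- which(window_t >= -pre_s & window_t < 0)
  n <- nrow(tm$traces)
  aligned <- vector("list", n)
  mean_traces <- matrix(0, n, length(window_t))
  event_diffs <- matrix(0, n, n_ev)
  for (i in seq_len(n)) {
    m <- t(vapply(onset_idx, function(o)
      tm$traces[i, (o - n_pre):(o + n_post)], numeric(length(window_t))))
    aligned[[i]] <- m
    mean_traces[i, ] <- colMeans(m)
    event_diffs[i, ] <- rowMeans(m[, resp_cols, drop = FALSE]) -
      rowMeans(m[, base_cols, drop = FALSE])
  }
  structure(list(window_t = window_t, aligned = aligned,
                 mean_traces = mean_traces,
                 evoked_amplitude = rowMeans(event_diffs),
                 event_diffs = event_diffs, n_events = n_ev,
                 n_dropped = n_dropped, label = label, sampling_rate = fs,
                 neuron_ids = tm$neuron_ids),
            class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("<aligned_set> label '%s': %d neurons x %d events (%d dropped), window [%g, %g] s\n",
              x$label, length(x$neuron_ids), x$n_events, x$n_dropped,
              min(x$window_t), max(x$window_t)))
  invisible(x)
}

#' Classify neurons as activated by an event
#'
#' One-sided paired sign-permutation test of the per-event response-window
#' means against the baseline-window means: a neuron is activated when the
#' permutation p-value is below `alpha` AND the mean effect is at least
#' `min_effect` (Z units). All `2^n_events` sign patterns are enumerated when
#' feasible; otherwise `n_perm` random sign flips under a fixed seed, so the
#' classification is deterministic given the seed. Neurons with fewer than 3
#' events are indeterminate (`NA`).
#'
#' @param aligned an [align_events()] result.
#' @param alpha significance level.
#' @param min_effect minimum mean response-minus-baseline effect, Z units.
#' @param n_perm number of random sign permutations when exhaustive
#'   enumeration exceeds `n_perm`.
#' @param seed seed for the random permutations.
#' @return list with logical `activated` per neuron, `p_value`, `effect`.
#' @export
classify_activated <- function(aligned, alpha = 0.05, min_effect = 0.5,
                               n_perm = 10000, seed = 1L) {
  stopifnot(inherits(aligned, "aligned_set"))
  d <- aligned$event_diffs
  n <- length(aligned$neuron_ids)
  if (is.null(d) || aligned$n_events < 3) {
    return(list(activated = rep(NA, n), p_value = rep(NA_real_, n),
                effect = rep(NA_real_, n)))
  }
  m <- ncol(d)
  if (2^m <= n_perm) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), m)))
  } else {
    rng <- local({ set.seed(seed); matrix(sample(c(-1, 1), n_perm * m,
                                                 replace = TRUE), n_perm, m) })
    signs <- rbind(rep(1, m), rng)  # include identity
  }
  perm_means <- signs %*% t(d) / m          # permutations x neurons
  obs <- colMeans(t(d))
  p <- colMeans(sweep(perm_means, 2L, obs, ">=") | abs(
    sweep(perm_means, 2L, obs, "-")) < 1e-12)
  effect <- rowMeans(d)
  list(activated = (p < alpha) & (effect >= min_effect),
       p_value = p, effect = effect)
}

#' Response-onset latency
#'
#' First post-onset time at which the mean aligned trace reaches
#' `threshold_z` and stays there for at least `sustain_s`; `NA` when the
#' threshold is never sustained.
#'
#' @param aligned an [align_events()] result.
#' @param threshold_z threshold on the mean trace, Z units.
#' @param sustain_s required supra-threshold duration, seconds.
#' @param which neuron indices to evaluate (default all).
#' @return numeric vector of latencies (seconds; `NA` if never).
#' @export
onset_latency <- function(aligned, threshold_z = 1, sustain_s = 0.25,
                          which = NULL) {
  stopifnot(inherits(aligned, "aligned_set"))
  if (is.null(aligned$mean_traces)) return(numeric())
  idx <- if (is.null(which)) seq_len(nrow(aligned$mean_traces)) else which
  post <- aligned$window_t >= 0
  tpost <- aligned$window_t[post]
  need <- max(1L, round(sustain_s * aligned$sampling_rate))
  vapply(idx, function(i) {
    x <- aligned$mean_traces[i, post] >= threshold_z
    r <- rle(x)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= need)
    if (!length(hit)) return(NA_real_)
    tpost[starts[hit[1L]]]
  }, numeric(1))
}

#' Cluster mean responses and order by cluster onset
#'
#' Agglomerative clustering (correlation distance, average linkage) of
#' unit-normalized mean aligned traces. The cluster count is chosen by the
#' largest mean silhouette over 2..min(8, n-1) when `n_clusters = "auto"`.
#' Clusters are renumbered by ascending mean onset latency and the returned
#' permutation orders neurons by cluster, then by onset within cluster, then
#' by neuron id (ties) — so the partition does not depend on input order.
#'
#' @param aligned an [align_events()] result.
#' @param which neuron indices to cluster (e.g. the activated set); >= 2.
#' @param n_clusters integer, or `"auto"` for silhouette selection.
#' @param threshold_z,sustain_s onset-latency parameters (see
#'   [onset_latency()]).
#' @return list of class `cluster_ordering`: `labels` (cluster per neuron,
#'   onset-ordered ids), `order` (permutation of `which`), `cluster_onsets`,
#'   `n_clusters`, `neuron_ids`.
#' @export
cluster_and_order <- function(aligned, which = NULL, n_clusters = "auto",
                              threshold_z = 1, sustain_s = 0.25) {
  stopifnot(inherits(aligned, "aligned_set"))
  idx <- if (is.null(which)) seq_len(nrow(aligned$mean_traces)) else which
  if (length(idx) < 2) stop("need >= 2 neurons to cluster")
  m <- aligned$mean_traces[idx, , drop = FALSE]
  nrm <- sqrt(rowSums(m^2)); nrm[nrm < 1e-12] <- 1
  mu <- m / nrm
  cc <- suppressWarnings(stats::cor(t(mu)))
  cc[!is.finite(cc)] <- 1  # flat traces: treat as identical
  d <- stats::as.dist(1 - cc)
  if (max(d) < 1e-10) {
    labels <- rep(1L, length(idx))
    onsets <- onset_latency(aligned, threshold_z, sustain_s, which = idx)
    ord <- order(onsets, idx, na.last = TRUE)
    return(structure(list(labels = labels, order = idx[ord],
                          cluster_onsets = mean(onsets, na.rm = TRUE),
                          n_clusters = 1L, neuron_ids = aligned$neuron_ids[idx]),
                     class = "cluster_ordering"))
  }
  hc <- stats::hclust(d, method = "average")
  if (identical(n_clusters, "auto")) {
    if (length(idx) == 2L) {
      n_clusters <- 2L   # two distinct traces: singletons
    } else {
      ks <- 2:min(8L, length(idx) - 1L)
      sil <- vapply(ks, function(k) {
        ct <- stats::cutree(hc, k)
        if (length(unique(ct)) < 2) return(-Inf)
        mean(cluster::silhouette(ct, d)[, "sil_width"])
      }, numeric(1))
      n_clusters <- ks[which.max(sil)]
    }
  }
  labels <- stats::cutree(hc, n_clusters)
  onsets <- onset_latency(aligned, threshold_z, sustain_s, which = idx)
  cl_on <- vapply(seq_len(max(labels)), function(k) {
    o <- onsets[labels == k]
    if (all(is.na(o))) Inf else mean(o, na.rm = TRUE)
  }, numeric(1))
  rank_map <- order(cl_on)                 # old id in ascending-onset order
  new_labels <- match(labels, rank_map)
  ord <- order(new_labels, onsets, idx, na.last = TRUE)
  structure(list(labels = new_labels, order = idx[ord],
                 cluster_onsets = sort(cl_on),
                 n_clusters = as.integer(max(new_labels)),
                 neuron_ids = aligned$neuron_ids[idx]),
            class = "cluster_ordering")
}

#' Activated fraction
#'
#' Fraction of detected (non-silent) neurons classified as activated; the
#' denominator is the session's detected count, so the fraction is
#' well-defined per session. A zero denominator is flagged undefined.
#'
#' @param activated logical vector (or count) of activated neurons.
#' @param detected logical vector (or count) of detected neurons.
#' @return list with `fraction`, `n_activated`, `n_detected`.
#' @export
activated_fraction <- function(activated, detected) {
  n_act <- if (is.logical(activated)) sum(activated, na.rm = TRUE) else activated
  n_det <- if (is.logical(detected)) sum(detected) else detected
  list(fraction = if (n_det > 0) n_act / n_det else NA_real_,
       n_activated = n_act, n_detected = n_det)
}

#' One-call session summary for one event label
#'
#' Z-scores the session, counts detected neurons, aligns to the label,
#' classifies activated neurons (among detected), and computes onset
#' latencies and the activated fraction.
#'
#' @param tm raw [trace_matrix()].
#' @param events [event_table()].
#' @param label event label to analyze.
#' @param pre_s,post_s,response_window see [align_events()].
#' @param k,min_duration_s detection criterion (see [count_detected()]).
#' @param alpha,min_effect,seed activation criterion (see
#'   [classify_activated()]).
#' @return list with `detected`, `aligned`, `activated`, `latency`,
#'   `fraction` components.
#' @export
evoked_summary <- function(tm, events, label, pre_s = 2, post_s = 5,
                           response_window = c(0, 3), k = 3,
                           min_duration_s = 0.2, alpha = 0.05,
                           min_effect = 0.5, seed = 1L) {
  mask <- baseline_mask(tm, events)
  z <- if (isTRUE(tm$zscored)) tm else zscore_traces(tm, mask)
  det <- count_detected(tm, events, k = k, min_duration_s = min_duration_s)
  al <- align_events(z, events, label, pre_s, post_s, response_window)
  act <- classify_activated(al, alpha, min_effect, seed = seed)
  is_act <- act$activated & det$detected
  lat <- onset_latency(al)
  lat[!(is_act %in% TRUE)] <- NA_real_
  fr <- activated_fraction(sum(is_act, na.rm = TRUE), det$count)
  list(detected = det, aligned = al, activated = is_act,
       p_value = act$p_value, effect = act$effect, latency = lat,
       fraction = fr)
}
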