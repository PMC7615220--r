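# Per-neuron tuning and selectivity statistics and the baseline-activity
# relationship.

#' Event-free baseline transient rate
#'
#' Detected calcium transients per minute of event-free time (outside every
#' bout padded by `pad_s`). Undefined (NA, with a flag) when less than
#' `min_free_s` of event-free time is available.
#'
#' @param tm raw or Z-scored [trace_matrix()].
#' @param events [event_table()] defining occupied time.
#' @param pad_s padding around events, seconds.
#' @param min_free_s minimum event-free time required, seconds.
#' @param k_onset rise-detection threshold (see [detect_transient_onsets()],
#'   which counts overlapping transients separately and is therefore the
#'   rate estimator of choice).
#' @return list with `rate_per_min` (per neuron), `event_free_s`, `defined`.
#' @export
baseline_activity <- function(tm, events, pad_s = 2, min_free_s = 60,
                              k_onset = 5) {
  stopifnot(inherits(tm, "trace_matrix"))
  mask <- baseline_mask(tm, events, pad_s)
  free_s <- sum(mask) / tm$sampling_rate
  if (free_s < min_free_s) {
    return(list(rate_per_min = rep(NA_real_, nrow(tm$traces)),
                event_free_s = free_s, defined = FALSE))
  }
  tr <- detect_transient_onsets(tm, mask = mask, k_onset = k_onset,
                                restrict = TRUE)
  list(rate_per_min = lengths(tr) / (free_s / 60),
       event_free_s = free_s, defined = TRUE)
}

# mean rectified (negative -> 0) window mean across bouts, per neuron
rectified_window_mean <- function(aligned, cols) {
  vapply(aligned$aligned, function(m)
    mean(pmax(rowMeans(m[, cols, drop = FALSE]), 0)), numeric(1))
}

#' Tuning index
#'
#' `TI = (mu_resp - mu_base) / (|mu_resp| + |mu_base| + eps)`, where
#' `mu_resp` is the mean rectified response-window Z across bouts and
#' `mu_base` the mean rectified pre-onset baseline-window Z. Bounded in
#' `[-1, 1]`, symmetric, and monotone in the evoked amplitude; `eps = 1e-9`
#' guards the 0/0 case. Undefined with fewer than 3 bouts.
#'
#' @param aligned an [align_events()] result for the stimulus.
#' @param response_window `c(start, end)` seconds relative to onset.
#' @param eps stabilizer.
#' @return numeric vector of tuning indices per neuron (all `NA` when fewer
#'   than 3 bouts are available).
#' @export
tuning_index <- function(aligned, response_window = c(0, 3), eps = 1e-9) {
  stopifnot(inherits(aligned, "aligned_set"))
  n <- length(aligned$neuron_ids)
  if (is.null(aligned$aligned) || aligned$n_events < 3)
    return(rep(NA_real_, n))
  wt <- aligned$window_t
  resp_cols <- which(wt >= response_window[1] & wt <= response_window[2])
  base_cols <- which(wt < 0)
  mu_r <- rectified_window_mean(aligned, resp_cols)
  mu_b <- rectified_window_mean(aligned, base_cols)
  (mu_r - mu_b) / (abs(mu_r) + abs(mu_b) + eps)
}

#' Min-max normalization across a session's neurons
#'
#' Maps values onto `[0, 1]` by `(x - min) / (max - min)`; rank order is
#' preserved exactly. Degenerate (zero-range) input maps to 0.5.
#'
#' @param x numeric vector.
#' @return normalized vector.
#' @export
normalize_minmax <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1]) || r[2] - r[1] < 1e-12) return(rep(0.5, length(x)) + x * 0)
  (x - r[1]) / (r[2] - r[1])
}

#' Pairwise stimulus selectivity score
#'
#' `S = A_a / (A_a + A_b)` with `A_x = max(0, evoked amplitude for stimulus
#' x)`; when both rectified amplitudes are 0 the neuron is non-selective by
#' convention, `S = 0.5`. A score of 1 means activation only by stimulus
#' `a` (pup, by convention the reference), 0 activation only by stimulus
#' `b`, 0.5 a non-selective response. Antisymmetric:
#' `S(a, b) = 1 - S(b, a)`.
#'
#' @param amp_a,amp_b evoked amplitudes for the reference and comparison
#'   stimulus (vectors, matched per neuron), or [align_events()] results.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
selectivity_score <- function(amp_a, amp_b) {
  if (inherits(amp_a, "aligned_set")) amp_a <- amp_a$evoked_amplitude
  if (inherits(amp_b, "aligned_set")) amp_b <- amp_b$evoked_amplitude
  stopifnot(length(amp_a) == length(amp_b))
  a <- pmax(amp_a, 0); b <- pmax(amp_b, 0)
  ifelse(a + b == 0, 0.5, a / (a + b))
}

#' Regression of normalized tuning on normalized baseline activity
#'
#' Ordinary least squares of the min-max-normalized tuning index on the
#' min-max-normalized baseline activity across a session's neurons, the
#' statistic relating neuronal silencing to pup-evoked tuning. Group-aware
#' (per-animal) inference is out of scope here and, when needed, should be
#' delegated to a mixed-model fit; this is noted in the result metadata.
#'
#' @param tuning_norm,baseline_norm numeric vectors on `[0, 1]`.
#' @return list with `slope`, `r_squared`, `p_value`, `n`, `inference`.
#' @export
baseline_tuning_regression <- function(tuning_norm, baseline_norm) {
  ok <- is.finite(tuning_norm) & is.finite(baseline_norm)
  if (sum(ok) < 3) stop("need >= 3 neurons with defined values")
  if (stats::sd(baseline_norm[ok]) < 1e-12)
    return(list(slope = NA_real_, r_squared = NA_real_, p_value = NA_real_,
                n = sum(ok), inference = "undefined: zero predictor variance"))
  fit <- stats::lm(tuning_norm[ok] ~ baseline_norm[ok])
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2L, 4L],
       n = sum(ok),
       inference = "OLS, neurons pooled; per-animal grouping not modeled")
}
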