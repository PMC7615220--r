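#' Fluorescence trace matrix
#'
#' Container for a neuron-by-time fluorescence (or Z-scored) recording with
#' its sampling rate and session metadata. This is the substrate of all
#' event-aligned population analyses.
#'
#' @param traces numeric matrix, neurons in rows, samples in columns.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param neuron_ids optional character/integer vector of neuron identifiers;
#'   defaults to `1:nrow(traces)`.
#' @param state_label reproductive-state label for the session (e.g. `"Vir"`,
#'   `"D10"`, `"D18"`, `"D22"`, `"D50"`).
#' @param animal_id optional animal identifier.
#' @param zscored logical; `TRUE` when the traces are baseline Z-scores.
#' @param constant logical vector flagging neurons whose baseline standard
#'   deviation was zero at Z-scoring time (their Z trace is identically 0).
#'
#' @return An object of class `trace_matrix`.
#' @export
trace_matrix <- function(traces, sampling_rate, neuron_ids = NULL,
                         state_label = NA_character_, animal_id = NA_character_,
                         zscored = FALSE, constant = NULL) {
  traces <- as.matrix(traces)
  stopifnot(is.numeric(sampling_rate), length(sampling_rate) == 1L,
            sampling_rate > 0)
  if (any(!is.finite(traces))) stop("trace matrix contains non-finite values")
  if (is.null(neuron_ids)) neuron_ids <- seq_len(nrow(traces))
  if (length(neuron_ids) != nrow(traces))
    stop("neuron_ids length must equal number of rows")
  if (is.null(constant)) constant <- rep(FALSE, nrow(traces))
  structure(
    list(traces = traces, sampling_rate = sampling_rate,
         neuron_ids = neuron_ids, state_label = state_label,
         animal_id = animal_id, zscored = zscored, constant = constant),
    class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix> %d neurons x %d samples @ %g Hz (%.1f s)%s\n",
              nrow(x$traces), ncol(x$traces), x$sampling_rate,
              ncol(x$traces) / x$sampling_rate,
              if (isTRUE(x$zscored)) ", Z-scored" else ""))
  if (!is.na(x$state_label)) cat("  state:", x$state_label, "\n")
  invisible(x)
}

#' @export
dim.trace_matrix <- function(x) dim(x$traces)

#' Time vector of a trace matrix
#' @param tm a [trace_matrix()].
#' @return numeric vector of sample times in seconds (first sample at 0).
#' @export
trace_times <- function(tm) {
  (seq_len(ncol(tm$traces)) - 1L) / tm$sampling_rate
}

#' Behavioral / stimulus event table
#'
#' Builds a tibble of timestamped labeled bouts. Bouts of a single actor must
#' not overlap and every onset must precede its offset.
#'
#' @param onset_s,offset_s bout boundaries in seconds.
#' @param label character label per bout (behavior or stimulus identity).
#' @param actor actor performing/receiving the bout (default `"focal"`).
#' @param animal_id,timepoint,assay_duration_s optional assay metadata stored
#'   as attributes.
#'
#' @return tibble with columns `onset_s`, `offset_s`, `label`, `actor`,
#'   ordered by onset.
#' @export
event_table <- function(onset_s = numeric(), offset_s = numeric(),
                        label = character(), actor = "focal",
                        animal_id = NA_character_, timepoint = NA_character_,
                        assay_duration_s = NA_real_) {
  n <- length(onset_s)
  stopifnot(length(offset_s) == n, length(label) == n)
  actor <- rep_len(actor, n)
  if (n && any(onset_s >= offset_s)) stop("every onset must precede its offset")
  ev <- tibble::tibble(onset_s = as.numeric(onset_s),
                       offset_s = as.numeric(offset_s),
                       label = as.character(label), actor = actor)
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  for (a in unique(ev$actor)) {
    sub <- ev[ev$actor == a, ]
    if (nrow(sub) > 1L && any(sub$onset_s[-1L] < sub$offset_s[-nrow(sub)] - 1e-9))
      stop("bouts of one actor must not overlap")
  }
  attr(ev, "animal_id") <- animal_id
  attr(ev, "timepoint") <- timepoint
  attr(ev, "assay_duration_s") <- assay_duration_s
  ev
}

#' Intracellular patch-clamp record
#'
#' Voltage (current-clamp) and optionally current (voltage-clamp) time series
#' from one cell, with the current-step stimulation protocol.
#'
#' @param voltage membrane voltage in mV (may be `NULL` when only a
#'   voltage-clamp trace exists).
#' @param current clamp current trace in pA, or `NULL`.
#' @param sampling_rate Hz.
#' @param step_protocol data.frame with columns `step_pa`, `start_s`, `end_s`
#'   describing injected current steps; windows must be disjoint and inside
#'   the record.
#' @param baseline_window numeric length-2, seconds, the pre-stimulation
#'   window used for baseline features.
#' @param cell_id,group_label metadata (e.g. group `"Vir"`, `"D18"`,
#'   `"D18+TQ"`, `"Esr1-KO"`, `"PR-KO"`).
#' @param ground_truth optional list of planted parameters (synthetic records).
#'
#' @return object of class `patch_record`.
#' @export
patch_record <- function(voltage = NULL, current = NULL, sampling_rate,
                         step_protocol = NULL, baseline_window = NULL,
                         cell_id = NA_character_, group_label = NA_character_,
                         ground_truth = NULL) {
  stopifnot(sampling_rate > 0)
  if (is.null(voltage) && is.null(current))
    stop("at least one of voltage or current must be present")
  n <- if (!is.null(voltage)) length(voltage) else length(current)
  dur <- n / sampling_rate
  if (!is.null(step_protocol)) {
    sp <- step_protocol[order(step_protocol$start_s), , drop = FALSE]
    if (any(sp$end_s <= sp$start_s) || any(sp$end_s > dur + 1e-9))
      stop("step windows must be within the record")
    if (nrow(sp) > 1L && any(sp$start_s[-1L] < sp$end_s[-nrow(sp)] - 1e-9))
      stop("step windows must be non-overlapping")
    step_protocol <- sp
  }
  if (is.null(baseline_window)) {
    baseline_window <- c(0, if (is.null(step_protocol) || !nrow(step_protocol))
      dur else min(step_protocol$start_s))
  }
  structure(
    list(voltage = voltage, current = current, sampling_rate = sampling_rate,
         step_protocol = step_protocol, baseline_window = baseline_window,
         cell_id = cell_id, group_label = group_label,
         ground_truth = ground_truth),
    class = "patch_record")
}

#' @export
print.patch_record <- function(x, ...) {
  n <- if (!is.null(x$voltage)) length(x$voltage) else length(x$current)
  cat(sprintf("<patch_record> %.1f s @ %g kHz; voltage: %s, current: %s, steps: %d\n",
              n / x$sampling_rate, x$sampling_rate / 1000,
              if (is.null(x$voltage)) "no" else "yes",
              if (is.null(x$current)) "no" else "yes",
              if (is.null(x$step_protocol)) 0L else nrow(x$step_protocol)))
  invisible(x)
}

# internal: rows of `events` with the requested label (all rows when NULL)
events_with_label <- function(events, label = NULL) {
  if (is.null(label)) events else events[events$label %in% label, , drop = FALSE]
}

#' Write / read a synthetic session as plain text
#'
#' Traces go to a CSV (one row per neuron, first column `neuron_id`), events
#' to a CSV, and ground truth plus session metadata to a JSON sidecar.
#'
#' @param session list as returned by [generate_population_session()].
#' @param dir output directory (created if missing).
#' @return `write_session`: the directory, invisibly. `read_session`: a list
#'   with elements `traces` (a [trace_matrix()]) and `events`.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tm <- session$traces
  df <- data.frame(neuron_id = tm$neuron_ids, tm$traces, check.names = FALSE)
  utils::write.csv(df, file.path(dir, "traces.csv"), row.names = FALSE)
  utils::write.csv(session$events, file.path(dir, "events.csv"), row.names = FALSE)
  meta <- list(sampling_rate = tm$sampling_rate, state_label = tm$state_label,
               animal_id = tm$animal_id, zscored = tm$zscored,
               ground_truth = session$ground_truth)
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  df <- utils::read.csv(file.path(dir, "traces.csv"), check.names = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "session.json"), simplifyVector = TRUE)
  tm <- trace_matrix(as.matrix(df[, -1L, drop = FALSE]),
                     sampling_rate = meta$sampling_rate,
                     neuron_ids = df$neuron_id,
                     state_label = meta$state_label,
                     animal_id = meta$animal_id, zscored = isTRUE(meta$zscored))
  ev <- utils::read.csv(file.path(dir, "events.csv"))
  events <- event_table(ev$onset_s, ev$offset_s, ev$label, ev$actor)
  list(traces = tm, events = events, ground_truth = meta$ground_truth)
}
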