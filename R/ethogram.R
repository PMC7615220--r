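# Behavioral-sequence analytics: assay summaries, bout-level transition
# matrices with rank-sum edge tests, and Kaplan-Meier latency analysis.

#' Merge consecutive identical bouts
#'
#' Bout-level ethograms leave self-transitions undefined, so consecutive
#' bouts with the same label (per actor) are merged into one bout spanning
#' from the first onset to the last offset.
#'
#' @param events an [event_table()].
#' @return an [event_table()] with the same attributes.
#' @export
merge_bouts <- function(events) {
  if (nrow(events) < 2) return(events)
  out <- NULL
  for (a in unique(events$actor)) {
    sub <- events[events$actor == a, , drop = FALSE]
    grp <- cumsum(c(TRUE, sub$label[-1L] != sub$label[-nrow(sub)]))
    m <- tibble::tibble(
      onset_s = as.numeric(tapply(sub$onset_s, grp, min)),
      offset_s = as.numeric(tapply(sub$offset_s, grp, max)),
      label = as.character(tapply(sub$label, grp, `[`, 1L)),
      actor = a)
    out <- rbind(out, m)
  }
  ev <- event_table(out$onset_s, out$offset_s, out$label, out$actor,
                    animal_id = attr(events, "animal_id"),
                    timepoint = attr(events, "timepoint"),
                    assay_duration_s = attr(events, "assay_duration_s"))
  ev
}

#' Summarize one pup-exposure assay
#'
#' Retrieval latency is the onset of the first retrieval bout,
#' right-censored at the assay end when no retrieval occurs; crouch and
#' nest-time fractions are total bout time over assay duration; contact
#' latency is the onset of the first pup-directed contact.
#'
#' @param events an [event_table()].
#' @param assay_duration_s assay length, seconds (default: the table's
#'   attribute, else 600).
#' @param retrieval_label,crouch_label,nest_labels,contact_labels label
#'   vocabulary.
#' @return list with `retrieval_latency_s`, `retrieval_censored`,
#'   `crouch_fraction`, `nest_time_fraction`, `contact_latency_s`,
#'   `contact_censored`, `assay_duration_s`.
#' @export
summarize_assay <- function(events, assay_duration_s = NULL,
                            retrieval_label = "retrieve",
                            crouch_label = "crouch",
                            nest_labels = c("in_nest", "nest_enter"),
                            contact_labels = c("sniff", "retrieve", "groom",
                                               "crouch")) {
  if (is.null(assay_duration_s))
    assay_duration_s <- attr(events, "assay_duration_s")
  if (is.null(assay_duration_s) || is.na(assay_duration_s))
    assay_duration_s <- 600
  if (assay_duration_s <= 0) stop("zero-duration assay")
  first_onset <- function(labels) {
    hit <- events$onset_s[events$label %in% labels]
    if (length(hit)) c(min(hit), FALSE) else c(assay_duration_s, TRUE)
  }
  ret <- first_onset(retrieval_label)
  con <- first_onset(contact_labels)
  tot <- function(labels)
    sum(pmin(events$offset_s[events$label %in% labels], assay_duration_s) -
          pmin(events$onset_s[events$label %in% labels], assay_duration_s))
  list(retrieval_latency_s = ret[1], retrieval_censored = as.logical(ret[2]),
       crouch_fraction = tot(crouch_label) / assay_duration_s,
       nest_time_fraction = tot(nest_labels) / assay_duration_s,
       contact_latency_s = con[1], contact_censored = as.logical(con[2]),
       assay_duration_s = assay_duration_s)
}

#' Bout-level behavior transition matrix
#'
#' Consecutive identical labels are merged, then `counts[i, j]` is the
#' number of bouts labeled `i` immediately followed by a bout labeled `j`;
#' `P_T` is the row-normalized count matrix. Rows with no outgoing
#' transitions are left at zero and flagged. Behaviors below `min_count`
#' total occurrences can be excluded.
#'
#' @param events an [event_table()] with >= 2 bouts (after merging a single
#'   bout yields empty flagged counts).
#' @param behaviors label universe (default: labels observed in the table).
#' @param min_count minimum total occurrences for a behavior to enter the
#'   matrix (default 0 = keep all).
#' @return list of class `transition_matrix`: `behaviors`, `counts`, `P_T`,
#'   `zero_rows`, `n_bouts`, `animal_id`, `timepoint`.
#' @export
transition_matrix <- function(events, behaviors = NULL, min_count = 0) {
  ev <- merge_bouts(events)
  labs <- ev$label
  if (is.null(behaviors)) behaviors <- sort(unique(labs))
  if (min_count > 0) {
    keep <- names(which(table(labs) >= min_count))
    behaviors <- intersect(behaviors, keep)
    labs <- labs[labs %in% behaviors]
  }
  k <- length(behaviors)
  counts <- matrix(0L, k, k, dimnames = list(behaviors, behaviors))
  if (length(labs) >= 2) {
    from <- labs[-length(labs)]; to <- labs[-1L]
    ok <- from != to   # merging guarantees this within an actor stream
    for (i in which(ok))
      counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
  }
  rs <- rowSums(counts)
  p <- counts / ifelse(rs == 0, 1, rs)
  structure(list(behaviors = behaviors, counts = counts, P_T = p,
                 zero_rows = behaviors[rs == 0],
                 n_bouts = length(labs),
                 single_bout = length(labs) < 2,
                 animal_id = attr(events, "animal_id"),
                 timepoint = attr(events, "timepoint")),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d behaviors, %d bouts%s\n",
              length(x$behaviors), x$n_bouts,
              if (length(x$zero_rows))
                paste0("; zero rows: ", paste(x$zero_rows, collapse = ", "))
              else ""))
  print(round(x$P_T, 3))
  invisible(x)
}

#' Per-edge group comparison of transition probabilities
#'
#' For every behavior-to-behavior edge, compares the per-animal transition
#' probabilities between two groups with a two-sided Mann-Whitney U test
#' (exact null for small samples, normal approximation with tie correction
#' otherwise); edges with `p < alpha` are flagged. Edges absent (no outgoing
#' transition from the source behavior) in every animal of both groups are
#' skipped and listed. No multiple-testing correction is applied by default
#' (edges are flagged at the raw level); a Benjamini-Hochberg switch is
#' available.
#'
#' @param group_a,group_b lists of [transition_matrix()] objects (>= 3
#'   animals each).
#' @param alpha flagging level.
#' @param exact_max_n use the exact U null when both group sizes are at or
#'   below this (default 8).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return list with `edges` (tibble: from, to, n_a, n_b, mean_a, mean_b,
#'   statistic, p_value, flagged) and `skipped` (tibble of untestable
#'   edges).
#' @export
compare_transition_groups <- function(group_a, group_b, alpha = 0.05,
                                      exact_max_n = 8, p_adjust = "none") {
  stopifnot(length(group_a) >= 3, length(group_b) >= 3)
  behaviors <- sort(unique(unlist(lapply(c(group_a, group_b),
                                         function(t) t$behaviors))))
  edge_vals <- function(group, i, j) {
    vapply(group, function(t) {
      if (!(i %in% t$behaviors) || !(j %in% t$behaviors))
        return(NA_real_)
      if (i %in% t$zero_rows) return(NA_real_)  # no outgoing mass observed
      t$P_T[i, j]
    }, numeric(1))
  }
  rows <- list(); skipped <- list()
  for (i in behaviors) for (j in setdiff(behaviors, i)) {
    va <- edge_vals(group_a, i, j); vb <- edge_vals(group_b, i, j)
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (!length(va) || !length(vb) || (all(va == 0) && all(vb == 0))) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(from = i, to = j)
      next
    }
    exact <- length(va) <= exact_max_n && length(vb) <= exact_max_n
    wt <- suppressWarnings(stats::wilcox.test(va, vb, exact = exact,
                                              correct = TRUE))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      from = i, to = j, n_a = length(va), n_b = length(vb),
      mean_a = mean(va), mean_b = mean(vb),
      statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  edges <- do.call(rbind, rows)
  if (!is.null(edges)) {
    p <- if (identical(p_adjust, "BH"))
      stats::p.adjust(edges$p_value, "BH") else edges$p_value
    edges$p_adjusted <- p
    edges$flagged <- p < alpha
  }
  list(edges = edges,
       skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
       alpha = alpha, p_adjust = p_adjust)
}

#' Kaplan-Meier latency analysis with log-rank test
#'
#' Product-limit survival curves of (right-censored) latencies per group and
#' the log-rank chi-square across groups (df = groups - 1). With every
#' observation censored in every group the statistic is undefined but the
#' curves are still returned.
#'
#' @param latency_s latencies in seconds.
#' @param observed logical; `FALSE` marks right-censored observations
#'   (latency = censoring time, e.g. assay end).
#' @param group group label per observation.
#' @return list with `curves` (tibble: group, time, survival, n_risk),
#'   `chisq`, `df`, `p_value`, `fit` (the `survival::survfit` object).
#' @export
km_survival <- function(latency_s, observed, group) {
  stopifnot(length(latency_s) == length(observed),
            length(latency_s) == length(group))
  surv <- survival::Surv(latency_s, as.integer(observed))
  gf <- factor(group)
  fit <- survival::survfit(surv ~ gf)
  strata <- if (is.null(fit$strata)) rep(levels(gf)[1L], length(fit$time))
  else rep(sub("^gf=", "", names(fit$strata)), fit$strata)
  curves <- tibble::tibble(group = strata, time = fit$time,
                           survival = fit$surv, n_risk = fit$n.risk)
  chisq <- NA_real_; p <- NA_real_; df <- length(levels(gf)) - 1L
  if (any(observed) && length(levels(gf)) > 1) {
    sd_ <- tryCatch(survival::survdiff(surv ~ gf), error = function(e) NULL)
    if (!is.null(sd_)) {
      chisq <- sd_$chisq
      p <- stats::pchisq(chisq, df = df, lower.tail = FALSE)
    }
  }
  list(curves = curves, chisq = chisq, df = df, p_value = p, fit = fit)
}
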