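# Stimulus separability: temporal-bin features, shrinkage Fisher LDA,
# confidence ellipsoids, Rand Index, and the separability-sparseness
# relationship.

#' Build a bout feature matrix with temporal bins as features
#'
#' One sample per (neuron, bout): the features are the mean Z value in each
#' temporal bin of the bout-aligned window, and the sample label is the
#' bout's stimulus. An alternative reading — population-vector bins as
#' samples (`sample_mode = "population_bins"`: one sample per bout and bin
#' index, features = neurons) — is provided as a switch.
#'
#' @param tm Z-scored [trace_matrix()].
#' @param events [event_table()].
#' @param stimuli >= 2 stimulus labels, each with >= 3 usable bouts.
#' @param window `c(start, end)` seconds relative to bout onset.
#' @param bin_width_s temporal bin width, seconds.
#' @param sample_mode `"neuron_bouts"` (default) or `"population_bins"`.
#' @return list of class `bout_features`: `x` (samples x features),
#'   `labels`, `neuron_id`, `bout_id`, `bin_width_s`, `window`, `n_dropped`.
#' @export
build_features <- function(tm, events, stimuli, window = c(0, 4),
                           bin_width_s = 0.5,
                           sample_mode = c("neuron_bouts", "population_bins")) {
  stopifnot(inherits(tm, "trace_matrix"), length(stimuli) >= 2)
  sample_mode <- match.arg(sample_mode)
  fs <- tm$sampling_rate
  n_bins <- floor((window[2] - window[1]) / bin_width_s + 1e-9)
  if (n_bins < 1) stop("window shorter than one bin")
  ev <- events_with_label(events, stimuli)
  onset_idx <- round(ev$onset_s * fs) + 1L
  i_lo <- onset_idx + round(window[1] * fs)
  i_hi <- i_lo + round(n_bins * bin_width_s * fs) - 1L
  ok <- i_lo >= 1L & i_hi <= ncol(tm$traces)
  n_dropped <- sum(!ok)
  ev <- ev[ok, , drop = FALSE]; i_lo <- i_lo[ok]
  for (s in stimuli)
    if (sum(ev$label == s) < 3)
      stop(sprintf("stimulus '%s' has fewer than 3 usable bouts", s))
  bin_len <- round(bin_width_s * fs)
  n_neur <- nrow(tm$traces)
  bout_bins <- function(b) {  # neurons x bins matrix of bin means for bout b
    cols <- i_lo[b] + seq_len(n_bins * bin_len) - 1L
    m <- tm$traces[, cols, drop = FALSE]
    dim(m) <- c(n_neur, bin_len, n_bins)
    apply(m, c(1L, 3L), mean)
  }
  if (sample_mode == "neuron_bouts") {
    xs <- lapply(seq_len(nrow(ev)), bout_bins)
    x <- do.call(rbind, xs)
    labels <- rep(ev$label, each = n_neur)
    neuron_id <- rep(tm$neuron_ids, times = nrow(ev))
    bout_id <- rep(seq_len(nrow(ev)), each = n_neur)
  } else {
    xs <- lapply(seq_len(nrow(ev)), function(b) t(bout_bins(b)))
    x <- do.call(rbind, xs)
    labels <- rep(ev$label, each = n_bins)
    neuron_id <- rep(NA_integer_, nrow(x))
    bout_id <- rep(seq_len(nrow(ev)), each = n_bins)
  }
  structure(list(x = x, labels = labels, neuron_id = neuron_id,
                 bout_id = bout_id, bin_width_s = bin_width_s,
                 window = window, n_dropped = n_dropped,
                 sample_mode = sample_mode),
            class = "bout_features")
}

# pooled within-class and between-class scatter (covariance form)
scatter_matrices <- function(x, labels) {
  classes <- sort(unique(labels))
  mu <- colMeans(x)
  p <- ncol(x)
  sw <- matrix(0, p, p); sb <- matrix(0, p, p)
  for (cl in classes) {
    xc <- x[labels == cl, , drop = FALSE]
    mc <- colMeans(xc)
    d <- sweep(xc, 2L, mc)
    sw <- sw + crossprod(d)
    sb <- sb + nrow(xc) * tcrossprod(mc - mu)
  }
  list(sw = sw / (nrow(x) - length(classes)), sb = sb / nrow(x),
       classes = classes)
}

# leave-one-out Gaussian log-likelihood of the shared-covariance class model
# at shrinkage lambda; exact refits (small feature dimension)
loo_loglik <- function(x, labels, lambda) {
  n <- nrow(x)
  ll <- 0
  for (i in seq_len(n)) {
    sc <- scatter_matrices(x[-i, , drop = FALSE], labels[-i])
    s <- (1 - lambda) * sc$sw + lambda * diag(diag(sc$sw), ncol(x))
    mu_i <- colMeans(x[-i, , drop = FALSE][labels[-i] == labels[i], ,
                                           drop = FALSE])
    d <- x[i, ] - mu_i
    ch <- tryCatch(chol(s), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    ll <- ll - sum(log(diag(ch))) -
      0.5 * sum(backsolve(ch, d, transpose = TRUE)^2)
  }
  ll
}

#' Fisher discriminant projection with diagonal shrinkage
#'
#' Projects samples to `C - 1` dimensions maximizing between- over
#' within-class scatter. The within-class scatter is regularized toward its
#' diagonal, `S_w(lambda) = (1 - lambda) S_w + lambda diag(S_w)`; `lambda`
#' is chosen by exact leave-one-out Gaussian log-likelihood over a small
#' grid when `"auto"`, and automatically increased when the scatter is
#' singular. The projection is deterministic; each axis's sign is fixed by
#' making its largest-magnitude loading positive.
#'
#' @param features a [build_features()] result, or a numeric matrix (then
#'   `labels` is required).
#' @param labels class labels (ignored when `features` is a
#'   `bout_features`).
#' @param lambda shrinkage in `[0, 1]`, or `"auto"`.
#' @param lambda_grid grid searched when `lambda = "auto"`.
#' @return list of class `lda_fit`: `scaling` (features x C-1), `embedding`
#'   (samples x C-1), `labels`, `lambda`, `class_means` (in embedding),
#'   `degenerate` (near-zero between-class scatter flag).
#' @export
fit_lda <- function(features, labels = NULL, lambda = "auto",
                    lambda_grid = c(0.001, 0.01, 0.05, 0.1, 0.25, 0.5)) {
  if (inherits(features, "bout_features")) {
    x <- features$x; labels <- features$labels
  } else x <- as.matrix(features)
  stopifnot(!is.null(labels), nrow(x) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need >= 2 classes")
  if (min(table(labels)) < 2) stop("every class needs >= 2 samples")
  if (identical(lambda, "auto")) {
    # cap LOO cost on large sample sets: evaluate on a deterministic subset
    idx <- if (nrow(x) > 200) round(seq(1, nrow(x), length.out = 200)) else
      seq_len(nrow(x))
    ll <- vapply(lambda_grid, function(l)
      loo_loglik(x[idx, , drop = FALSE], labels[idx], l), numeric(1))
    lambda <- lambda_grid[which.max(ll)]
  }
  sc <- scatter_matrices(x, labels)
  sw <- (1 - lambda) * sc$sw + lambda * diag(diag(sc$sw), ncol(x))
  ch <- tryCatch(chol(sw), error = function(e) NULL)
  while (is.null(ch) && lambda < 1) {   # singular: increase shrinkage
    lambda <- min(1, lambda * 4 + 0.01)
    sw <- (1 - lambda) * sc$sw +
      lambda * (diag(diag(sc$sw), ncol(x)) + 1e-8 * diag(ncol(x)))
    ch <- tryCatch(chol(sw), error = function(e) NULL)
  }
  if (is.null(ch)) stop("within-class scatter irreparably singular")
  # symmetric eigenproblem: W^{-1/2} Sb W^{-1/2}
  wi <- backsolve(ch, diag(ncol(x)), transpose = TRUE)  # ch^-T
  m <- wi %*% sc$sb %*% t(wi)
  eg <- eigen((m + t(m)) / 2, symmetric = TRUE)
  k <- length(classes) - 1L
  v <- t(wi) %*% eg$vectors[, seq_len(k), drop = FALSE]
  v <- sweep(v, 2L, sqrt(colSums(v^2)), "/")
  for (j in seq_len(k)) {                # sign convention
    i_mx <- which.max(abs(v[, j]))
    if (v[i_mx, j] < 0) v[, j] <- -v[, j]
  }
  emb <- sweep(x, 2L, colMeans(x)) %*% v
  degenerate <- sum(diag(sc$sb)) < 1e-10 * max(sum(diag(sc$sw)), 1e-300)
  cm <- do.call(rbind, lapply(classes, function(cl)
    colMeans(emb[labels == cl, , drop = FALSE])))
  rownames(cm) <- classes
  structure(list(scaling = v, embedding = emb, labels = labels,
                 lambda = lambda, class_means = cm, degenerate = degenerate,
                 eigenvalues = eg$values[seq_len(k)]),
            class = "lda_fit")
}

#' Confidence ellipsoid of a point cloud
#'
#' Center = sample mean; the ellipsoid is `{x : (x - mu)' Sigma^-1 (x - mu)
#' <= q}` with `q` the chi-square quantile at `level` with `dim` degrees of
#' freedom. A singular covariance gets a small ridge (logged in the result).
#'
#' @param points samples x dims matrix (needs `>= dims + 1` rows).
#' @param level coverage level in `[0, 1)`.
#' @return list with `center`, `covariance`, `q` (squared Mahalanobis
#'   radius), `radius` (`sqrt(q)`), `level`, `ridged`.
#' @export
confidence_ellipsoid <- function(points, level = 0.95) {
  points <- as.matrix(points)
  d <- ncol(points)
  if (nrow(points) < d + 1) stop("need >= dim + 1 points")
  ctr <- colMeans(points)
  sig <- stats::cov(points)
  ridged <- FALSE
  if (!all(is.finite(sig)) || rcond_psd(sig) < 1e-12) {
    sig <- sig + diag(1e-8 * max(diag(sig), 1e-12), d)
    ridged <- TRUE
  }
  q <- stats::qchisq(level, df = d)
  list(center = ctr, covariance = sig, q = q, radius = sqrt(q),
       level = level, ridged = ridged)
}

rcond_psd <- function(s) {
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) 0 else min(ev) / max(ev)
}

#' Points inside a confidence ellipsoid
#'
#' @param points samples x dims matrix.
#' @param ellipsoid a [confidence_ellipsoid()] result.
#' @return logical vector.
#' @export
in_ellipsoid <- function(points, ellipsoid) {
  md <- stats::mahalanobis(as.matrix(points), ellipsoid$center,
                           ellipsoid$covariance)
  md <= ellipsoid$q
}

#' Rand Index between two partitions
#'
#' `RI = (a + b) / C(n, 2)` where `a` counts sample pairs placed together in
#' both partitions and `b` pairs placed apart in both. Invariant to label
#' renaming; in `[0, 1]`.
#'
#' @param labels_true,labels_pred equal-length label vectors, `n >= 2`.
#' @return Rand Index.
#' @export
rand_index <- function(labels_true, labels_pred) {
  n <- length(labels_true)
  stopifnot(length(labels_pred) == n)
  if (n < 2) stop("Rand Index undefined for n < 2")
  tab <- table(labels_true, labels_pred)
  ch2 <- function(x) x * (x - 1) / 2
  a <- sum(ch2(tab))
  total <- ch2(n)
  rows <- sum(ch2(rowSums(tab))); cols <- sum(ch2(colSums(tab)))
  b <- total + a - rows - cols
  (a + b) / total
}

#' Population separability of a stimulus set
#'
#' Full pipeline: temporal-bin features ([build_features()]) -> shrinkage
#' LDA ([fit_lda()]) -> k-means in the embedding with `k` = number of
#' stimuli (fixed seed, `nstart` restarts, best inertia) -> Rand Index
#' between bout stimulus labels and cluster labels. Per-stimulus 95%
#' confidence ellipsoids of the embedding are attached.
#'
#' @param tm Z-scored [trace_matrix()] (raw input is Z-scored internally
#'   against the non-event baseline).
#' @param events [event_table()].
#' @param stimuli stimulus labels to separate.
#' @param window,bin_width_s,sample_mode see [build_features()].
#' @param neurons `"detected"` (default) restricts samples to detected
#'   (non-silent) neurons — the recorded population of the in-vivo analyses;
#'   alternatively an index vector, or `NULL` for all neurons.
#' @param level ellipsoid coverage level.
#' @param nstart k-means restarts.
#' @param seed k-means seed.
#' @return list of class `separability_result`: `rand_index`, `embedding`,
#'   `labels`, `cluster`, `ellipsoids`, `n_samples`, `lambda`, `config`.
#' @export
separability <- function(tm, events, stimuli, window = c(0, 4),
                         bin_width_s = 0.5, sample_mode = "neuron_bouts",
                         neurons = "detected", level = 0.95, nstart = 50,
                         seed = 1L) {
  raw <- tm
  if (!isTRUE(tm$zscored)) tm <- zscore_traces(tm, baseline_mask(tm, events))
  if (identical(neurons, "detected"))
    neurons <- which(count_detected(raw, events)$detected)
  if (!is.null(neurons)) {
    if (length(neurons) < 1) stop("no neurons selected")
    tm <- trace_matrix(tm$traces[neurons, , drop = FALSE], tm$sampling_rate,
                       tm$neuron_ids[neurons], tm$state_label, tm$animal_id,
                       zscored = TRUE)
  }
  feats <- build_features(tm, events, stimuli, window, bin_width_s,
                          sample_mode)
  fit <- fit_lda(feats)
  emb <- fit$embedding
  k <- length(unique(feats$labels))
  km <- local({
    set.seed(seed)
    stats::kmeans(emb, centers = k, nstart = nstart, iter.max = 100)
  })
  ri <- rand_index(feats$labels, km$cluster)
  ells <- lapply(split(seq_len(nrow(emb)), feats$labels), function(ix) {
    if (length(ix) >= ncol(emb) + 1)
      confidence_ellipsoid(emb[ix, , drop = FALSE], level) else NULL
  })
  structure(list(rand_index = ri, embedding = emb, labels = feats$labels,
                 cluster = km$cluster, ellipsoids = ells,
                 n_samples = nrow(emb), lambda = fit$lambda,
                 config = list(stimuli = stimuli, window = window,
                               bin_width_s = bin_width_s,
                               sample_mode = sample_mode, level = level,
                               nstart = nstart, seed = seed)),
            class = "separability_result")
}

#' @export
print.separability_result <- function(x, ...) {
  cat(sprintf("<separability_result> stimuli {%s}: RI = %.3f (%d samples, lambda = %g)\n",
              paste(unique(x$labels), collapse = ", "), x$rand_index,
              x$n_samples, x$lambda))
  invisible(x)
}

#' Regression of separability on the activated fraction
#'
#' Least-squares regression of Rand-Index separability on the activated
#' fraction across sessions, the statistic linking improved pup
#' representations to population sparsening.
#'
#' @param ri Rand-Index values per session.
#' @param activated_fraction activated fractions per session.
#' @return list with `slope`, `r_squared`, `p_value`, `n`.
#' @export
separability_vs_sparseness <- function(ri, activated_fraction) {
  ok <- is.finite(ri) & is.finite(activated_fraction)
  if (sum(ok) < 3) stop("need >= 3 sessions with both quantities")
  if (stats::sd(activated_fraction[ok]) < 1e-12 || stats::sd(ri[ok]) < 1e-12)
    return(list(slope = NA_real_, r_squared = NA_real_, p_value = NA_real_,
                n = sum(ok)))
  fit <- stats::lm(ri[ok] ~ activated_fraction[ok])
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]), r_squared = sm$r.squared,
       p_value = sm$coefficients[2L, 4L], n = sum(ok))
}
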