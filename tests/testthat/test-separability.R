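# Temporal-bin features, shrinkage LDA, confidence ellipsoids, Rand Index
# and the separability pipeline.

test_that("feature matrix has the expected shape and planted structure", {
  s <- deterministic_session(amp_a = 3, amp_b = 0, n_neurons = 10,
                             n_bouts = 3)
  z <- s$traces  # noise-free; use raw traces directly
  f <- build_features(z, s$events, c("pup_sniff", "object_sniff"),
                      window = c(0, 4), bin_width_s = 0.5)
  expect_equal(ncol(f$x), 8L)            # 4 s window, 0.5 s bins
  expect_equal(nrow(f$x), 10 * 6)        # 10 neurons x (3 + 3) bouts
  # planted stimulus-specific amplitude separates class means in every bin
  mu_p <- colMeans(f$x[f$labels == "pup_sniff", ])
  mu_o <- colMeans(f$x[f$labels == "object_sniff", ])
  expect_true(all(mu_p > mu_o))
  expect_true(all(abs(mu_o) < 1e-3))   # only residual decay tails
  expect_gt(mu_p[1], 1)               # evoked response concentrated early
})

test_that("LDA separates Gaussian classes and matches the classical fit", {
  set.seed(11)
  n <- 100
  x <- rbind(matrix(stats::rnorm(n * 2, -3), n),
             matrix(stats::rnorm(n * 2, 3), n))
  labels <- rep(c("a", "b"), each = n)
  fit <- fit_lda(x, labels)
  # training accuracy by nearest class mean in the embedding
  pred <- rownames(fit$class_means)[apply(fit$embedding, 1L, function(e)
    which.min((e - fit$class_means)^2))]
  expect_gt(mean(pred == labels), 0.95)
  # cross-check the projection direction against MASS::lda
  skip_if_not_installed("MASS")
  m <- MASS::lda(x, grouping = labels)
  expect_gt(abs(stats::cor(x %*% m$scaling, fit$embedding[, 1])), 0.99)
})

test_that("LDA is deterministic, sign-fixed and flags degenerate input", {
  set.seed(12)
  x <- matrix(stats::rnorm(60 * 4), 60)
  labels <- rep(c("a", "b", "c"), each = 20)
  f1 <- fit_lda(x, labels); f2 <- fit_lda(x, labels)
  expect_identical(f1$embedding, f2$embedding)
  expect_equal(ncol(f1$embedding), 2L)   # C - 1 dimensions
  # sign convention: largest-magnitude loading positive on each axis
  for (j in 1:2) expect_gt(f1$scaling[which.max(abs(f1$scaling[, j])), j], 0)
  # feature permutation: same embedding after permuting columns
  perm <- c(3, 1, 4, 2)
  fp <- fit_lda(x[, perm], labels, lambda = f1$lambda)
  f_ref <- fit_lda(x, labels, lambda = f1$lambda)
  expect_equal(abs(fp$embedding), abs(f_ref$embedding), tolerance = 1e-6)
  # identical class distributions: near-zero between-class scatter flagged
  xx <- matrix(stats::rnorm(40 * 3), 40)
  fd <- fit_lda(rbind(xx, xx), rep(c("a", "b"), each = 40))
  expect_true(fd$degenerate)
})

test_that("confidence ellipsoids have closed-form and limiting behavior", {
  set.seed(13)
  # 1-D case: interval mu +/- sqrt(q) * sigma
  x1 <- matrix(stats::rnorm(500, 2, 3), ncol = 1)
  e1 <- confidence_ellipsoid(x1, 0.95)
  expect_equal(e1$q, stats::qchisq(0.95, 1))
  half <- sqrt(e1$q) * stats::sd(x1)
  inside <- abs(x1 - mean(x1)) <= half
  expect_equal(as.vector(inside), as.vector(in_ellipsoid(x1, e1)))
  # level -> 0 degenerates to the center
  e0 <- confidence_ellipsoid(x1, 0)
  expect_equal(e0$radius, 0)
  # singular covariance gets ridged, not an error
  xs <- cbind(1:10, (1:10) * 2)
  es <- confidence_ellipsoid(xs)
  expect_true(es$ridged)
})

test_that("Rand Index equals brute-force enumeration on all partitions", {
  # frozen brute-force values
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), 1 / 3)
  expect_equal(rand_index(c(1, 1, 1), c(1, 2, 3)), 0)
  expect_equal(rand_index(1:5, 1:5), 1)
  # exhaustive: all partition pairs for n <= 5
  for (n in 2:5) {
    parts <- all_partitions(n)
    for (p in parts) for (q in parts)
      expect_identical(rand_index(p, q), rand_index_bruteforce(p, q))
  }
  # larger n: every partition against seeded random partners
  set.seed(14)
  for (n in 6:8) {
    parts <- all_partitions(n)
    for (p in parts) {
      q <- sample.int(3, n, replace = TRUE)
      expect_identical(rand_index(p, q), rand_index_bruteforce(p, q))
    }
  }
  expect_error(rand_index(1, 1), "n < 2")
})

test_that("Rand Index is invariant to label bijections", {
  set.seed(15)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    a <- sample.int(3, n, replace = TRUE)
    b <- sample.int(4, n, replace = TRUE)
    ri <- rand_index(a, b)
    sig <- sample.int(3); tau <- sample.int(4)
    expect_equal(rand_index(sig[a], tau[b]), ri)
    expect_true(ri >= 0 && ri <= 1)
  }
})

test_that("separability pipeline recovers planted structure and nulls", {
  # strongly stimulus-separated population
  ri_strong <- sapply(1:5, function(sd_) {
    s <- generate_population_session(population_config(
      n_neurons = 25, duration_s = 300, silent_fraction = 0,
      spontaneous_rate = 0.5, noise_sd = 0.1,
      stimulus_set = c("pup", "obj"),
      tuning_matrix = cbind(rep(4, 25), 0), response_latency_mean = 0.3,
      seed = 600L + sd_))
    separability(s$traces, s$events, c("pup", "obj"), seed = sd_)$rand_index
  })
  expect_true(all(ri_strong > 0.9))
  # untuned (null) population: RI within the permutation-null band
  s0 <- generate_population_session(population_config(
    n_neurons = 25, duration_s = 300, silent_fraction = 0,
    spontaneous_rate = 0.5, noise_sd = 0.1, stimulus_set = c("pup", "obj"),
    tuning_matrix = cbind(rep(0, 25), 0), seed = 610L))
  res0 <- separability(s0$traces, s0$events, c("pup", "obj"), seed = 1L)
  set.seed(16)
  null_ri <- replicate(200, rand_index(sample(res0$labels), res0$cluster))
  expect_gte(res0$rand_index, stats::quantile(null_ri, 0.025) - 0.02)
  expect_lte(res0$rand_index, stats::quantile(null_ri, 0.975) + 0.02)
})

test_that("monotonicity: stronger planted contrast never lowers median RI", {
  contrasts <- c(0, 0.5, 1, 2, 4)
  med_ri <- sapply(contrasts, function(a) {
    ri <- sapply(1:5, function(sd_) {
      s <- generate_population_session(population_config(
        n_neurons = 20, duration_s = 250, silent_fraction = 0,
        spontaneous_rate = 0.5, noise_sd = 0.1,
        stimulus_set = c("pup", "obj"), tuning_matrix = cbind(rep(a, 20), 0),
        n_bouts_per_stimulus = 6, seed = 700L + sd_))
      separability(s$traces, s$events, c("pup", "obj"),
                   seed = sd_)$rand_index
    })
    stats::median(ri)
  })
  expect_true(all(diff(med_ri) >= -0.03))
  expect_gt(med_ri[5], med_ri[1])
})

test_that("separability-sparseness regression recovers planted coupling", {
  # planted monotone coupling across 12 synthetic sessions
  set.seed(17)
  frac <- seq(0.2, 0.8, length.out = 12)
  ri <- 0.95 - 0.5 * frac + stats::rnorm(12, 0, 0.03)
  f <- separability_vs_sparseness(ri, frac)
  expect_lt(f$slope, 0)
  expect_lt(f$p_value, 0.05)
  # identical sessions: undefined
  f0 <- separability_vs_sparseness(rep(0.7, 5), rep(0.4, 5))
  expect_true(is.na(f0$slope))
})
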