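# Behavioral-sequence analytics: assay summaries, transition matrices,
# rank-sum edge comparisons, Kaplan-Meier latency analysis.

test_that("assay summary: censoring rule and time fractions", {
  # no retrieval in a 600 s assay: latency censored at 600
  ev <- event_table(c(10, 50), c(20, 60), c("sniff", "groom"))
  s <- summarize_assay(ev, assay_duration_s = 600)
  expect_equal(s$retrieval_latency_s, 600)
  expect_true(s$retrieval_censored)
  expect_false(s$contact_censored)

  # crouch bouts totaling 103.8 s of a 600 s assay -> 0.173
  ev2 <- event_table(c(5, 200, 400), c(45, 240, 223.8 + 200),
                     c("crouch", "crouch", "crouch"))
  s2 <- summarize_assay(ev2, assay_duration_s = 600)
  expect_equal(s2$crouch_fraction, 103.8 / 600)

  # planted crouch fraction recovered exactly from a generated table
  ev3 <- event_table(c(0, 150), c(150, 600), c("crouch", "sniff"))
  expect_equal(summarize_assay(ev3, assay_duration_s = 600)$crouch_fraction,
               0.25)
  expect_error(summarize_assay(ev, assay_duration_s = 0), "zero-duration")
})

test_that("transition matrix: merge rule, row stochasticity, flags", {
  ev <- event_table(c(0, 1, 2, 3), c(1, 2, 3, 4), c("A", "B", "A", "B"))
  tmx <- transition_matrix(ev)
  expect_equal(tmx$P_T["A", "B"], 1)
  expect_equal(tmx$P_T["B", "A"], 1)  # one B->A transition, last B ends the assay
  # A,A,B merges to A,B: one transition
  ev2 <- event_table(c(0, 1, 2), c(1, 2, 3), c("A", "A", "B"))
  tmx2 <- transition_matrix(ev2)
  expect_equal(sum(tmx2$counts), 1)
  expect_equal(tmx2$counts["A", "B"], 1L)
  # merge idempotence
  expect_identical(transition_matrix(merge_bouts(ev2))$counts, tmx2$counts)
  # single bout: empty counts, flagged
  tmx1 <- transition_matrix(event_table(0, 1, "A"))
  expect_true(tmx1$single_bout)
  expect_equal(sum(tmx1$counts), 0)
  # rows with outgoing transitions are stochastic; others zero and flagged
  set.seed(21)
  labs <- sample(c("A", "B", "C"), 40, replace = TRUE)
  ev3 <- event_table(seq_along(labs) - 1, seq_along(labs), labs)
  tmx3 <- transition_matrix(ev3)
  rs <- rowSums(tmx3$P_T)
  has_out <- rowSums(tmx3$counts) > 0
  expect_true(all(abs(rs[has_out] - 1) < 1e-9))
  expect_true(all(rs[!has_out] == 0))
})

test_that("U test on edges matches exhaustive rank enumeration", {
  # frozen example: U = 0, exact two-sided p = 0.1
  a <- c(0.1, 0.2, 0.3); b <- c(0.4, 0.5, 0.6)
  wt <- stats::wilcox.test(a, b, exact = TRUE)
  expect_equal(unname(wt$statistic), 0)
  expect_equal(wt$p.value, 0.1)
  expect_equal(u_test_bruteforce(a, b), 0.1)
  # enumeration oracle for assorted group sizes <= 5 (no ties)
  set.seed(22)
  for (i in 1:12) {
    n <- sample(3:5, 1); m <- sample(3:5, 1)
    x <- sample(seq(0.01, 0.99, 0.01), n)
    y <- sample(setdiff(seq(0.01, 0.99, 0.01), x), m)
    expect_equal(stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 u_test_bruteforce(x, y), tolerance = 1e-12)
  }
})

test_that("group edge comparison flags planted differences, not nulls", {
  make_group <- function(p_edge, n, seed0) {
    lapply(seq_len(n), function(i) {
      P <- matrix(c(0, p_edge, 1 - p_edge,
                    0.5, 0, 0.5,
                    0.5, 0.5, 0), 3, byrow = TRUE)
      ev <- generate_ethogram(ethogram_config(c("sniff", "retrieve", "groom"),
                                              P, n_bouts = 150,
                                              seed = seed0 + i))
      transition_matrix(ev)
    })
  }
  # identical groups: all ties, nothing flagged
  ga <- make_group(0.5, 5, 100)
  res0 <- compare_transition_groups(ga, ga)
  expect_true(all(!res0$edges$flagged))
  expect_true(all(res0$edges$p_value >= 0.05))
  # planted difference on sniff->retrieve (0.2 vs 0.6, n = 10/10)
  hits <- sapply(1:10, function(r) {
    ga <- make_group(0.2, 10, 1000 * r)
    gb <- make_group(0.6, 10, 1000 * r + 500)
    res <- compare_transition_groups(ga, gb)
    e <- res$edges[res$edges$from == "sniff" & res$edges$to == "retrieve", ]
    e$flagged
  })
  expect_gte(mean(hits), 0.9)
})

test_that("Kaplan-Meier reduces to empirical survival without censoring", {
  set.seed(23)
  x <- stats::rexp(40, 1 / 50)
  km <- km_survival(x, rep(TRUE, 40), rep("g", 40))
  emp <- sapply(km$curves$time, function(t) mean(x > t))
  expect_equal(km$curves$survival, emp, tolerance = 1e-12)
  expect_true(all(diff(km$curves$survival) <= 1e-12))

  # identical groups: log-rank statistic near 0, p near 1
  km2 <- km_survival(c(x, x), rep(TRUE, 80), rep(c("a", "b"), each = 40))
  expect_lt(km2$chisq, 1e-9)
  expect_gt(km2$p_value, 0.99)

  # all-censored groups: undefined statistic, curves still returned
  km3 <- km_survival(c(600, 600, 600, 600), rep(FALSE, 4),
                     rep(c("a", "b"), each = 2))
  expect_true(is.na(km3$chisq))
  expect_equal(nrow(km3$curves), 2L)
})

test_that("directional ethogram contrast flags the planted edges", {
  labels <- c("sniff", "groom", "nest_enter", "retrieve", "crouch",
              "nest_build")
  # virgin-like: mass on sniff -> groom -> nest_enter cycles
  P_vir <- rbind(c(0, .6, .3, .04, .03, .03),
                 c(.5, 0, .4, .04, .03, .03),
                 c(.55, .35, 0, .04, .03, .03),
                 c(.3, .3, .2, 0, .1, .1),
                 c(.3, .3, .2, .1, 0, .1),
                 c(.3, .3, .2, .1, .1, 0))
  # D18-like: mass on retrieve -> crouch -> nest_build chains
  P_d18 <- rbind(c(0, .1, .1, .6, .1, .1),
                 c(.1, 0, .1, .5, .2, .1),
                 c(.1, .1, 0, .5, .2, .1),
                 c(.05, .05, .05, 0, .65, .2),
                 c(.05, .05, .05, .15, 0, .7),
                 c(.1, .1, .1, .3, .4, 0))
  grp <- function(P, seed0) lapply(1:10, function(i)
    transition_matrix(generate_ethogram(
      ethogram_config(labels, P, n_bouts = 120, seed = seed0 + i))))
  hits <- sapply(1:5, function(r) {
    res <- compare_transition_groups(grp(P_vir, 3000 * r),
                                     grp(P_d18, 3000 * r + 77))
    e <- res$edges
    all(e$flagged[(e$from == "sniff" & e$to == "retrieve") |
                    (e$from == "retrieve" & e$to == "crouch") |
                    (e$from == "crouch" & e$to == "nest_build")])
  })
  expect_gte(mean(hits), 0.95)
})
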