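test_that("profiles aggregate mean, sem and n per position", {
  m <- data.frame(cell_id = c("a", "b", "c"), condition = "x",
                  distance_um = c(2, 2, 2), time_min = 120,
                  conc_nM = c(10, 12, 14))
  p <- build_profile(m, "x", axis = "distance")
  expect_equal(p$mean_conc, 12)
  expect_equal(p$sem_conc, sd(c(10, 12, 14)) / sqrt(3))
  expect_equal(p$n, 3)
  # single measurement: sem 0 with n = 1
  p1 <- build_profile(m[1, ], "x", axis = "distance")
  expect_equal(p1$sem_conc, 0)
  expect_equal(p1$n, 1)
})

test_that("profile means are invariant to cell ordering", {
  d <- generate_gradient_dataset(gradient_config(seed = 14))
  p1 <- build_profile(d, "receptor_none", axis = "distance", at = 120)
  d_shuffled <- d[rev(seq_len(nrow(d))), ]
  p2 <- build_profile(d_shuffled, "receptor_none", axis = "distance", at = 120)
  expect_equal(p1$mean_conc, p2$mean_conc)
  expect_equal(p1$sem_conc, p2$sem_conc)
})

test_that("one-sample t-test reproduces printed summary comparisons", {
  # near-coverslip concentrations vs the 1.8 nM added concentration
  r <- one_sample_ttest(mean = 5.1, sem = 0.8, n = 8, mu0 = 1.8)
  expect_equal(r$statistic, 4.125)
  expect_equal(r$df, 7)
  expect_equal(r$p_value, 0.0044317, tolerance = 1e-4)
  r2 <- one_sample_ttest(mean = 3.2, sem = 0.4, n = 8, mu0 = 1.8)
  expect_equal(r2$statistic, 3.5)
  expect_equal(r2$p_value, 0.0099930, tolerance = 1e-4)
})

test_that("t-test degenerate and null cases behave as documented", {
  expect_equal(one_sample_ttest(mean = 1.8, sem = 0.4, n = 8, mu0 = 1.8)$p_value, 1)
  r <- one_sample_ttest(mean = 2, sem = 0, n = 5, mu0 = 1.8)
  expect_equal(r$p_value, 0)
  expect_match(r$flag, "degenerate")
  expect_error(one_sample_ttest(mean = 2, sem = 1, n = 1, mu0 = 0), "at least 2")
})

test_that("raw-values route equals the summary route and stats::t.test", {
  set.seed(33)
  x <- rnorm(12, 3, 1)
  raw <- one_sample_ttest(x, mu0 = 1.8)
  summ <- one_sample_ttest(mean = mean(x), sem = sd(x) / sqrt(12), n = 12,
                           mu0 = 1.8)
  expect_equal(raw$statistic, summ$statistic)
  expect_equal(raw$p_value, summ$p_value)
  ref <- stats::t.test(x, mu = 1.8)
  expect_equal(raw$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(raw$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("two-way ANOVA flags zero-variance input instead of failing", {
  d <- expand.grid(condition = c("a", "b"), distance_um = c(2, 200),
                   cell = 1:3)
  d$conc_nM <- 5
  res <- two_way_anova(d)
  expect_true(all(res$tests$flag == "zero variance"))
  expect_error(posthoc(res), "degenerate")
})

test_that("two-way ANOVA detects a condition effect and feeds post-hoc tests", {
  set.seed(8)
  d <- expand.grid(condition = c("high", "none"), distance_um = c(2, 10, 200),
                   cell = 1:8)
  d$conc_nM <- 5 + 4 * (d$condition == "high") + rnorm(nrow(d), 0, 1)
  res <- two_way_anova(d)
  p_cond <- res$tests$p_value[res$tests$comparison == "condition"]
  expect_lt(p_cond, 0.01)
  cmp <- posthoc(res, "tukey")
  expect_equal(nrow(cmp), 3)        # one contrast per distance stratum
  expect_true(all(cmp$p_value < 0.05))
  expect_true(all(cmp$adjusted))
})

test_that("unbalanced designs warn and report Type-II tests", {
  set.seed(9)
  d <- expand.grid(condition = c("a", "b"), distance_um = c(2, 200), cell = 1:6)
  d$conc_nM <- rnorm(nrow(d), 5)
  d <- d[-(1:3), ]
  expect_warning(res <- two_way_anova(d), "unbalanced")
  expect_equal(nrow(res$tests), 3)
})

test_that("post-hoc comparisons of identical groups are non-significant", {
  set.seed(10)
  d <- expand.grid(condition = c("a", "b", "c"), distance_um = c(2, 200),
                   cell = 1:10)
  d$conc_nM <- rnorm(nrow(d), 5, 1)
  res <- suppressWarnings(two_way_anova(d))
  cmp <- posthoc(res, "tukey")
  expect_true(all(cmp$p_value > 0.05))
  dn <- posthoc(res, "dunnett", reference = "a")
  expect_true(all(dn$p_value > 0.05))
  expect_error(posthoc(res, "dunnett"), "reference")
})

test_that("tukey-adjusted p values are never below unadjusted pairwise p", {
  set.seed(12)
  for (i in 1:5) {
    d <- expand.grid(condition = c("a", "b", "c", "d"), distance_um = c(2, 20),
                     cell = 1:6)
    d$conc_nM <- rnorm(nrow(d), 5, 1) + 0.5 * (d$condition == "b")
    res <- two_way_anova(d)
    adj <- posthoc(res, "tukey")
    emm <- emmeans::emmeans(res$fit, ~ A | B)
    unadj <- summary(emmeans::contrast(emm, "pairwise", adjust = "none"))
    expect_true(all(adj$p_value >= unadj$p.value - 1e-12))
  }
})

test_that("true-affinity correction holds its algebraic identities", {
  res <- true_affinity(1.8, l_bulk = 1.8, l_micro = 45.7)
  expect_equal(res$fold, 45.7 / 1.8)
  expect_equal(res$kd_true_nM, 45.7)
  expect_equal(res$kd_true_nM / res$kd_apparent_nM, res$l_micro_nM / res$l_bulk_nM)
  same <- true_affinity(1.8, 1.8, 1.8)
  expect_equal(same$fold, 1)
  expect_equal(same$kd_true_nM, 1.8)
  expect_equal(true_affinity(1.8, 1.8, 91.4)$kd_true_nM, 2 * 45.7)
  expect_error(true_affinity(-1, 1, 1), "positive")
})
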