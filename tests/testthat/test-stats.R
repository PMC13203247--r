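# from-scratch textbook formulas, kept independent of the implementation
oracle_paired_t <- function(pre, post) {
  d <- post - pre
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), n - 1))
}

oracle_indep_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

test_that("paired t and Cohen's d match the formula oracle", {
  expect_equal(paired_t_and_d(c(1, 2, 3), c(1, 2, 3))[c("t", "p", "d")],
               list(t = 0, p = 1, d = NA_real_))
  # diffs {1,2,3}: mean 2, sample SD 1 -> d = 2
  r <- paired_t_and_d(c(0, 0, 0), c(1, 2, 3))
  expect_equal(r$d, 2)
  set.seed(31)
  pre <- rnorm(12, 4, 2)
  post <- rnorm(12, 3, 2)
  got <- paired_t_and_d(pre, post)
  ora <- oracle_paired_t(pre, post)
  expect_equal(got$t, ora$t, tolerance = 1e-10)
  expect_equal(got$p, ora$p, tolerance = 1e-10)
  expect_equal(got$df, 11)
  expect_equal(got$d, mean(post - pre) / sd(post - pre), tolerance = 1e-12)
})

test_that("change-score interaction is the squared pooled t with df2 = n_a + n_b - 2", {
  x <- c(1, 2, 3, 4)
  expect_error(interaction_from_change_scores(c(1, 1), c(1, 1)), "pooled")
  same <- interaction_from_change_scores(x, x)
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  set.seed(13)
  a <- rnorm(12, 0.5)
  b <- rnorm(12)
  got <- interaction_from_change_scores(a, b)
  expect_equal(got$df2, 22L)
  expect_equal(got$df1, 1L)
  expect_equal(got$F, oracle_indep_t(a, b)^2, tolerance = 1e-10)
  expect_equal(got$F, got$t^2, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(oracle_indep_t(a, b)), 22),
               tolerance = 1e-10)
})

test_that("Holm adjustment steps down, preserves order and caps at one", {
  expect_equal(holm_adjust(0.03), 0.03)
  # hand-stepped: sorted {0.01,0.03,0.04} x {3,2,1} -> {0.03,0.06,0.06}
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  set.seed(2)
  p <- runif(10)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
  expect_true(all(adj <= 1))
})

test_that("ICC(2,1) matches the mean-squares oracle and its fixed points", {
  x <- c(9, 6, 8, 7, 10, 6)
  expect_equal(icc_test_retest(x, x)$icc, 1)
  # independent draws decorrelate
  set.seed(17)
  r0 <- icc_test_retest(rnorm(10000), rnorm(10000))
  expect_lt(abs(r0$icc), 0.05)
  # independent route: two-way ANOVA mean squares on a small table
  s1 <- c(9, 6, 8, 7, 10)
  s2 <- c(8, 5, 9, 6, 9)
  n <- 5; k <- 2
  fit <- aov(c(s1, s2) ~ factor(rep(1:n, 2)) + factor(rep(1:2, each = n)))
  ms <- anova(fit)[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc_test_retest(s1, s2)$icc, oracle, tolerance = 1e-10)
  got <- icc_test_retest(s1, s2)
  expect_equal(c(got$msr, got$msc, got$mse), c(msr, msc, mse),
               tolerance = 1e-10)
})

test_that("baseline-adjusted ANCOVA recovers a planted group effect", {
  # post tracking baseline with no group effect: beta ~ 0, p large
  set.seed(3)
  base <- c(1, 2, 3, 4, 5, 6, 7, 8)
  g <- rep(c("a", "b"), 4)
  r0 <- ancova_baseline(base + rnorm(8, 0, 1e-6), base, g)
  expect_equal(r0$beta, 0, tolerance = 1e-5)
  expect_gt(r0$p, 0.1)
  set.seed(23)
  n <- 10000
  grp <- rep(c("sham", "tdcs"), each = n / 2)
  baseline <- rnorm(n, 5, 2)
  post <- 0.6 * baseline + 2.0 * (grp == "tdcs") + rnorm(n)
  r <- ancova_baseline(post, baseline, grp)
  expect_equal(r$beta, 2.0, tolerance = 0.1)
  expect_lt(r$p, 1e-6)
})

test_that("ANCOVA coefficients equal the normal-equations solution on a toy table", {
  post <- c(2.1, 2.9, 3.4, 4.2, 5.1, 5.8)
  base <- c(1.0, 2.0, 3.0, 1.5, 2.5, 3.5)
  grp <- c("a", "a", "a", "b", "b", "b")
  X <- cbind(1, grp == "b", base)
  beta_hat <- solve(t(X) %*% X, t(X) %*% post)
  r <- ancova_baseline(post, base, grp)
  expect_equal(r$beta, beta_hat[2], tolerance = 1e-10)
})

test_that("change-score correlation matches the covariance formula", {
  dx <- c(1, -2, 0.5, 3)
  expect_equal(change_score_correlation(dx, -dx)$r, -1, tolerance = 1e-12)
  set.seed(29)
  n <- 10000
  x <- rnorm(n)
  y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
  expect_equal(change_score_correlation(x, y)$r, 0.5, tolerance = 0.03 / 0.5)
  a <- c(0.3, 1.2, -0.7, 2.2, 0.9)
  b <- c(1.0, 0.4, -0.2, 1.8, 0.1)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(change_score_correlation(a, b)$r, oracle, tolerance = 1e-12)
  expect_error(change_score_correlation(rep(1, 4), 1:4), "variance")
})

test_that("the full report wires every component together on one table", {
  set.seed(41)
  make_rows <- function(metric) {
    data.frame(id = sprintf("P%02d", 1:24),
               group = rep(c("sham", "tdcs"), each = 12),
               metric = metric,
               pre = rnorm(24, 4, 1),
               post = rnorm(24, 4, 1))
  }
  tab <- rbind(make_rows("undershoot"), make_rows("rmse"),
               make_rows("band_power_1_3"))
  rep <- build_report(tab)
  m <- rep$metrics
  expect_equal(nrow(m), 3L)
  expect_true(all(m$interaction_df2 == 22))
  expect_true(all(m$sham_p_holm >= m$sham_p))
  expect_true(all(m$tdcs_p_holm >= m$tdcs_p))
  expect_true(all(m$interaction_p >= 0 & m$interaction_p <= 1))
  # interaction equals the squared change-score t recomputed by hand
  und <- tab[tab$metric == "undershoot", ]
  tch <- oracle_indep_t(with(und[und$group == "tdcs", ], post - pre),
                        with(und[und$group == "sham", ], post - pre))
  expect_equal(m$interaction_F[m$metric == "undershoot"], tch^2,
               tolerance = 1e-10)
  # cells reproduce plain group means
  expect_equal(m$sham_pre_mean[m$metric == "rmse"],
               mean(tab$pre[tab$metric == "rmse" & tab$group == "sham"]))
  expect_equal(nrow(rep$change_correlations), 3L)

  single <- build_report(make_rows("undershoot"))
  expect_equal(nrow(single$metrics), 1L)
  expect_null(single$change_correlations)
  expect_output(print(rep), "Sham PRE")
})

test_that("malformed study tables are rejected with clear messages", {
  ok <- data.frame(id = c("a", "b", "a", "b"),
                   group = c("sham", "tdcs", "sham", "tdcs"),
                   metric = "undershoot", pre = 1:4, post = 2:5)
  expect_error(build_report(ok[, -1]), "columns")
  bad_group <- ok
  bad_group$group <- c("x", "y", "x", "y")
  expect_error(build_report(bad_group), "sham")
  dup <- rbind(ok, ok[1, ])
  expect_error(build_report(dup), "duplicate")
})
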