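test_that("speed percentiles follow the midpoint quantile convention", {
  expect_equal(unname(speed_percentiles(1:5, 0.5)), 3)
  expect_equal(unname(speed_percentiles(rep(2.5, 7))), rep(2.5, 5))
  set.seed(3)
  x <- rgamma(37, 2, 30)
  taus <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  q <- speed_percentiles(x, taus)
  expect_true(all(diff(q) >= 0))
  for (i in seq_along(taus))
    expect_equal(check_loss(x, q[i], taus[i]), min_check_loss(x, taus[i]),
                 tolerance = 1e-10)
})

test_that("quantile contrast equals the difference of group quantiles", {
  r <- quantile_group_contrast(c(1, 2, 3), c(2, 3, 4), taus = 0.5,
                               n_boot = 200, seed = 1)
  expect_equal(r$estimate, 1)
  same <- quantile_group_contrast(1:20, 1:20, n_boot = 200, seed = 1)
  expect_equal(same$estimate, rep(0, 5))
  # a pure location shift is recovered at every tau, within the bootstrap CI
  set.seed(4)
  ctrl <- rgamma(300, 2, 30)
  delta <- 0.02
  r2 <- quantile_group_contrast(ctrl, ctrl - delta, n_boot = 400,
                                seed = 2)
  expect_equal(r2$estimate, rep(-delta, 5), tolerance = 1e-9)
  expect_true(all(r2$ci_lo <= -delta & -delta <= r2$ci_hi))
  # identity with independently computed per-group quantiles
  pat <- rgamma(200, 1.5, 40)
  r3 <- quantile_group_contrast(ctrl, pat, n_boot = 200, seed = 3)
  expect_equal(r3$estimate,
               check_quantile(pat, c(0.1, 0.25, 0.5, 0.75, 0.9)) -
                 check_quantile(ctrl, c(0.1, 0.25, 0.5, 0.75, 0.9)))
  expect_warning(
    quantile_group_contrast(rep(1, 5), 1:5, n_boot = 200, seed = 1),
    "degenerate")
})

test_that("summary t-tests reproduce printed figure-legend statistics", {
  mts <- t_from_summary(98.71, 11.09, 5, 68.57, 5.85, 5)
  expect_equal(mts$statistic, 2.404, tolerance = 5e-4)
  expect_equal(mts$df, 8)
  counts <- t_from_summary(80.4, 4.46, 5, 58.06, 3.83, 5)
  expect_equal(counts$statistic, 3.808, tolerance = 0.005 * 3.808)
  atp <- t_from_summary(54.35, 6.38, 5, 35.41, 3.79, 5)
  expect_equal(atp$statistic, 2.562, tolerance = 0.005 * 2.562)
  expect_equal(t_from_summary(5, 1, 5, 5, 1, 5)$statistic, 0)
  expect_error(t_from_summary(1, 0, 5, 2, 1, 5), "positive")
})

test_that("raw-value t-test matches the pooled formula and the summary form", {
  set.seed(6)
  g1 <- rnorm(5, 10); g2 <- rnorm(5, 8)
  ours <- t_from_values(g1, g2)
  ref <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  # equal group sizes: summary-based and pooled t agree exactly
  via_summary <- t_from_summary(mean(g1), sd(g1) / sqrt(5), 5,
                                mean(g2), sd(g2) / sqrt(5), 5)
  expect_equal(ours$statistic, via_summary$statistic, tolerance = 1e-10)
  expect_equal(t_from_values(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_warning(t_from_values(rep(0, 4), rep(1, 4)), "zero variance")
})

test_that("chi-square matches direct computation and chisq.test", {
  even <- chi_square_table(matrix(10, 2, 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$df, 1)
  diag <- chi_square_table(matrix(c(20, 0, 0, 20), 2, 2))
  expect_equal(diag$statistic, 40)
  set.seed(9)
  tab <- matrix(rpois(9, 20) + 1, 3, 3)
  ours <- chi_square_table(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(ours$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter))
  # invariance under simultaneous row and column permutation
  perm <- tab[c(2, 3, 1), c(3, 1, 2)]
  expect_equal(chi_square_table(perm)$statistic, ours$statistic)
  expect_error(chi_square_table(matrix(c(0, 0, 1, 2), 2, 2)), "zero")
})

test_that("mixed RM-ANOVA matches a hand-worked 2x2 design", {
  # 2 groups x 2 lines x 2 conditions, worked by hand from first principles
  vals <- matrix(c(10, 12, 20, 22,    # condition 1: g1 lines, g2 lines
                   14, 18, 21, 25),   # condition 2
                 nrow = 4)
  groups <- c("a", "a", "b", "b")
  # hand sums of squares:
  #  grand mean 17.75; group means 13.5, 22; condition means 16, 19.5
  #  SS_group = 2*2*((13.5-17.75)^2+(22-17.75)^2) = 144.5
  #  subject means 12,15,20.5,23.5 -> SS_subj = 2*((12-13.5)^2+(15-13.5)^2
  #    +(20.5-22)^2+(23.5-22)^2) = 18
  #  SS_cond = 4*((16-17.75)^2+(19.5-17.75)^2) = 24.5
  #  cell means 11,21,16,23 -> SS_int = 2*sum((cell-grp-cond+grand)^2) = 4.5
  #  SS_err = total SS - rest; total = sum((x-17.75)^2) = 193.5 -> 2
  r <- mixed_rm_anova(vals, groups)
  expect_equal(r$ss$ss, c(144.5, 18, 24.5, 4.5, 2), tolerance = 1e-10)
  expect_equal(r$group$F, (144.5 / 1) / (18 / 2), tolerance = 1e-10)
  expect_equal(r$condition$F, (24.5 / 1) / (2 / 2), tolerance = 1e-10)
  expect_equal(r$interaction$F, (4.5 / 1) / (2 / 2), tolerance = 1e-10)
  expect_equal(r$group$df, c(1, 2))
  expect_equal(r$condition$df, c(1, 2))
})

test_that("mixed RM-ANOVA agrees with aov's multistratum decomposition", {
  set.seed(11)
  n_per <- 5; C <- 3
  vals <- matrix(rnorm(2 * n_per * C, 50, 5), nrow = 2 * n_per)
  vals[6:10, ] <- vals[6:10, ] + 4
  vals[, 2] <- vals[, 2] + 3
  groups <- rep(c("ctrl", "pat"), each = n_per)
  r <- mixed_rm_anova(vals, groups)
  df <- data.frame(y = as.vector(vals),
                   subj = factor(rep(seq_len(2 * n_per), C)),
                   grp = factor(rep(groups, C)),
                   cond = factor(rep(seq_len(C), each = 2 * n_per)))
  a <- summary(aov(y ~ grp * cond + Error(subj), data = df))
  between <- a[["Error: subj"]][[1]]
  within <- a[["Error: Within"]][[1]]
  fv <- function(tab, term) tab[trimws(rownames(tab)) == term, "F value"]
  expect_equal(r$group$F, fv(between, "grp"), tolerance = 1e-8)
  expect_equal(r$condition$F, fv(within, "cond"), tolerance = 1e-8)
  expect_equal(r$interaction$F, fv(within, "grp:cond"), tolerance = 1e-8)
  # collapsibility: group F equals one-way ANOVA on condition-averaged data
  one_way <- summary(aov(rowMeans(vals) ~ factor(groups)))[[1]]
  expect_equal(r$group$F, one_way[1, "F value"], tolerance = 1e-8)
})

test_that("mixed RM-ANOVA guards degenerate and unbalanced designs", {
  flat <- matrix(5, 4, 2)
  expect_warning(r <- mixed_rm_anova(flat, c("a", "a", "b", "b")),
                 "zero variance")
  expect_equal(r$group$F, 0)
  # pure group offset: no condition or interaction effect
  off <- matrix(rep(c(1, 1, 7, 7), 2), 4)
  r2 <- suppressWarnings(mixed_rm_anova(off, c("a", "a", "b", "b")))
  expect_equal(r2$condition$F, 0)
  expect_equal(r2$interaction$F, 0)
  holed <- matrix(c(1, 2, 3, NA), 2)
  expect_error(mixed_rm_anova(holed, c("a", "b")), "unbalanced")
  expect_error(mixed_rm_anova(matrix(1:4, 2), c("a", "b")),
               "2 lines per group")
})

test_that("percent fast aggregates per cell line with SEM", {
  sp <- c(0.2, rep(0.05, 9))
  r <- percent_fast(sp, rep("L1", 10))
  expect_equal(r$overall_pct, 10)
  r0 <- percent_fast(rep(0.05, 8), rep(c("L1", "L2"), 4))
  expect_equal(r0$overall_pct, 0)
  expect_equal(r0$mean_pct, 0)
  sp2 <- c(0.2, 0.05, 0.05, 0.05,   # L1: 25%
           0.2, 0.2, 0.05, 0.05)    # L2: 50%
  r2 <- percent_fast(sp2, rep(c("L1", "L2"), each = 4))
  expect_equal(r2$mean_pct, 37.5)
  expect_equal(r2$sem_pct, sd(c(25, 50)) / sqrt(2))
  expect_error(percent_fast(sp, rep("L1", 9)), "parallel")
})
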