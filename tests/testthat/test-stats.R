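test_that("Kruskal-Wallis H matches a hand rank computation and base R", {
  # groups {1,2,3} vs {4,5,6}: ranks 1..6, rank sums 6 and 15
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b"), each = 3)
  H_hand <- 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7
  r <- kruskal_wallis(v, g)
  expect_equal(r$statistic, H_hand)
  expect_equal(r$df, 1)
  ref <- kruskal.test(v, factor(g))
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value)
})

test_that("Kruskal-Wallis handles ties, degenerate input and errors", {
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "at least 2 groups")
  r0 <- kruskal_wallis(rep(2, 9), rep(c("a", "b", "c"), 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  set.seed(31)
  for (i in 1:40) {
    v <- sample(1:6, 30, replace = TRUE)  # heavy ties
    g <- sample(c("a", "b", "c"), 30, replace = TRUE)
    if (length(unique(g)) < 3 || length(unique(v)) < 2) next
    mine <- kruskal_wallis(v, g)
    ref <- kruskal.test(v, factor(g))
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value)
  }
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(32)
  v <- rnorm(45)
  g <- rep(c("a", "b", "c"), 15)
  h1 <- kruskal_wallis(v, g)$statistic
  h2 <- kruskal_wallis(exp(v), g)$statistic
  h3 <- kruskal_wallis(rank(v) + 100, g)$statistic
  expect_equal(h1, h2)
  expect_equal(h1, h3)
})

test_that("Dunn z matches the first-principles oracle; two-group z^2 equals H", {
  set.seed(33)
  for (i in 1:25) {
    v <- round(rnorm(24), 1)  # rounding induces ties
    g <- sample(c("a", "b", "c"), 24, replace = TRUE)
    if (length(unique(g)) < 3) next
    mine <- dunn_posthoc(v, g, adjust = "none")
    orc <- dunn_oracle(v, g)
    expect_equal(mine$z, orc$z, tolerance = 1e-10)
  }
  v <- c(3, 1, 4, 1, 5, 9, 2, 6)
  g <- rep(c("a", "b"), 4)
  z <- dunn_posthoc(v, g)$z
  H <- kruskal_wallis(v, g)$statistic
  expect_equal(z^2, H, tolerance = 1e-10)
})

test_that("Dunn adjustment behaves as documented", {
  set.seed(34)
  v <- rnorm(30); g <- rep(c("a", "b", "c"), 10)
  raw <- dunn_posthoc(v, g, "none")
  bon <- dunn_posthoc(v, g, "bonferroni")
  hol <- dunn_posthoc(v, g, "holm")
  expect_equal(bon$p_adjusted, pmin(1, 3 * raw$p_raw))
  expect_true(all(bon$p_adjusted >= raw$p_raw))
  expect_true(all(hol$p_adjusted >= raw$p_raw))
  # identical groups: all adjusted p = 1
  same <- dunn_posthoc(rep(1:5, 3), rep(c("a", "b", "c"), each = 5))
  expect_true(all(same$p_adjusted == 1))
})

test_that("Spearman rho matches base R; extremes hit +/-1", {
  x <- 1:8
  expect_equal(spearman_cor(x, 2 * x + 1)$statistic, 1)
  expect_equal(spearman_cor(x, -x^3)$statistic, -1)
  set.seed(35)
  for (i in 1:30) {
    n <- sample(5:20, 1)
    x <- sample(1:8, n, replace = TRUE)
    y <- sample(1:8, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(spearman_cor(x, y)$statistic,
                 cor(x, y, method = "spearman"))
  }
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
})

test_that("Spearman exact permutation p matches exhaustive enumeration", {
  set.seed(36)
  x <- c(2, 2, 5, 1, 4)   # with ties
  y <- c(3, 1, 4, 4, 2)
  res <- spearman_cor(x, y)
  expect_identical(res$p_method, "exact permutation")
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  count <- 0
  for (p in perms_oracle(5)) {
    if (abs(cor(rx[p], ry)) >= abs(rho_obs) - 1e-12) count <- count + 1
  }
  expect_equal(res$p_value, count / factorial(5))
  expect_gt(res$p_value, 0)  # identity permutation always counts
})

test_that("Spearman is monotone-invariant and antisymmetric under reversal", {
  set.seed(37)
  x <- rnorm(12); y <- rnorm(12)
  r1 <- spearman_cor(x, y)$statistic
  expect_equal(spearman_cor(exp(x), y)$statistic, r1)
  expect_equal(spearman_cor(x, -y)$statistic, -r1)
})

test_that("two-way ANOVA recovers the textbook balanced 2x2 decomposition", {
  # balanced, so type II equals the classical sums of squares
  d <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"), rep = 1:3)
  set.seed(38)
  mu <- c(a1b1 = 10, a2b1 = 12, a1b2 = 11, a2b2 = 16)
  d$y <- mu[paste0(d$a, d$b)] + rnorm(nrow(d), sd = 0.5)
  out <- two_way_anova(d$y, d$a, d$b)
  grand <- mean(d$y)
  ssa <- sum(tapply(d$y, d$a, function(v) length(v) * (mean(v) - grand)^2))
  ssb <- sum(tapply(d$y, d$b, function(v) length(v) * (mean(v) - grand)^2))
  cellm <- tapply(d$y, paste(d$a, d$b), mean)
  ssc <- sum(table(paste(d$a, d$b)) * (cellm - grand)^2)
  ssab <- ssc - ssa - ssb
  expect_equal(out$sum_sq[out$term == "factor_a"], ssa)
  expect_equal(out$sum_sq[out$term == "factor_b"], ssb)
  expect_equal(out$sum_sq[out$term == "factor_a:factor_b"], ssab)
  expect_identical(attr(out, "ss_type"), "II")
})

test_that("two-way ANOVA flags empty cells and null data behaves", {
  d <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"), rep = 1:2)
  d <- d[!(d$a == "a2" & d$b == "b2"), ]
  expect_error(two_way_anova(rnorm(nrow(d)), d$a, d$b), "empty design cell")
  # pure-noise null: p-values well away from 0
  set.seed(39)
  d2 <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2", "b3"), rep = 1:10)
  out <- two_way_anova(rnorm(nrow(d2)), d2$a, d2$b)
  expect_true(all(out$p_value >= 0 & out$p_value <= 1))
})

test_that("two-way ANOVA type-I error is near nominal under the null", {
  set.seed(40)
  n_sims <- 400
  rej <- 0
  d <- expand.grid(a = c("hi", "lo"), b = c("s1", "s2", "s3"), rep = 1:8)
  for (i in seq_len(n_sims)) {
    out <- two_way_anova(rnorm(nrow(d)), d$a, d$b)
    if (out$p_value[out$term == "factor_a"] < 0.05) rej <- rej + 1
  }
  expect_gt(rej / n_sims, 0.02)
  expect_lt(rej / n_sims, 0.09)
})

test_that("Tukey HSD q matches the direct mean-difference / SE oracle", {
  set.seed(41)
  g <- rep(c("a", "b", "c"), each = 6)
  v <- rnorm(18) + rep(c(0, 0.5, 2), each = 6)
  out <- tukey_hsd(v, g)
  fit <- aov(v ~ factor(g))
  mse <- sum(fit$residuals^2) / fit$df.residual
  for (i in seq_len(nrow(out))) {
    d <- abs(mean(v[g == out$group_a[i]]) - mean(v[g == out$group_b[i]]))
    q_oracle <- d / sqrt(mse / 6)
    expect_equal(out$q[i], q_oracle, tolerance = 1e-10)
    expect_equal(out$p_adjusted[i],
                 ptukey(q_oracle, 3, fit$df.residual, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
  # two identical groups -> zero difference, p = 1; far-apart groups -> tiny p
  expect_equal(tukey_hsd(rep(c(1, 2, 3), 2),
                         rep(c("a", "b"), each = 3))$p_adjusted, 1)
  far <- tukey_hsd(c(rnorm(10), rnorm(10) + 50), rep(c("a", "b"), each = 10))
  expect_lt(far$p_adjusted, 0.001)
})

test_that("the battery runs end to end on a synthetic study", {
  # 18 observers so both high- and low-experience bands are populated
  ds <- simulate_study(canonical_scenario(master_seed = 3, n_observers = 18,
                                          grid = c(64, 64)))
  mats <- lapply(ds$design$images$image_id,
                 function(i) pairwise_dsc_matrix(image_masks(ds, i)))
  rec <- flatten_records(mats, ds$design)
  res <- stats_battery(rec, ds)
  expect_true(all(res$table$p_raw >= 0 & res$table$p_raw <= 1, na.rm = TRUE))
  expect_s3_class(res$stage$omnibus, "seg_test_result")
  expect_equal(nrow(res$stage$posthoc), 3)
  expect_identical(res$difficulty$p_method, "exact permutation")  # 9 images
  expect_false(is.null(res$experience))
  expect_true("factor_a" %in% res$experience$anova$term)
})
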