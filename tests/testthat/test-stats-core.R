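test_that("summary-statistic t-test agrees with t.test on raw data", {
  set.seed(100)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -3, 3), sd = runif(1, .3, 3))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -3, 3), sd = runif(1, .3, 3))
    pooled <- two_sample_t(x, y, "pooled")
    ref_p <- t.test(x, y, var.equal = TRUE)
    expect_equal(pooled$p, ref_p$p.value, tolerance = 1e-12)
    expect_equal(pooled$statistic, unname(ref_p$statistic),
                 tolerance = 1e-12)
    welch <- two_sample_t(x, y, "welch")
    ref_w <- t.test(x, y)
    expect_equal(welch$p, ref_w$p.value, tolerance = 1e-12)
    expect_equal(welch$df, unname(ref_w$parameter), tolerance = 1e-9)
  }
})

test_that("pooled and Welch coincide for equal sd and n; groups swap sign", {
  a <- summary_stats(1.2, 2.0, 15)
  b <- summary_stats(0.1, 2.0, 15)
  p1 <- two_sample_t(a, b, "pooled")
  w1 <- two_sample_t(a, b, "welch")
  expect_equal(p1$statistic, w1$statistic, tolerance = 1e-12)
  expect_equal(p1$df, w1$df, tolerance = 1e-9)
  # two-sided symmetry under group swap
  p2 <- two_sample_t(b, a, "pooled")
  expect_equal(p1$p, p2$p, tolerance = 1e-12)
  expect_equal(p1$statistic, -p2$statistic)
  # identical summaries: t = 0, p = 1
  same <- two_sample_t(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(summary_stats(0, 1, 1), "n")
})

test_that("paired t equals the direct formula on differences", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 5, 7)
  d <- x - y
  t_oracle <- mean(d) / (sd(d) / sqrt(4))
  p_oracle <- 2 * pt(-abs(t_oracle), 3)
  res <- paired_t(x, y)
  expect_equal(res$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  expect_equal(res$estimate, mean(d))
  # incomplete pairs are deleted pairwise
  res2 <- paired_t(c(x, NA, 9), c(y, 1, NA))
  expect_equal(res2$n, 4)
  expect_equal(res2$p, res$p)
  # zero variance convention
  z <- paired_t(x, x)
  expect_true(z$zero_variance)
  expect_equal(z$p, 1)
})

test_that("chi-squared matches the hand formula on random tables", {
  hand <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  set.seed(7)
  for (i in 1:25) {
    m <- matrix(rpois(4, 40) + 1, 2)
    res <- chisq_2x2(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
    expect_equal(res$statistic, hand(m), tolerance = 1e-10)
    expect_equal(res$p, pchisq(hand(m), 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  # dropout-count example: strong method difference
  res <- chisq_2x2(109, 595, 1, 703)
  expect_equal(res$statistic, 115.0, tolerance = 0.05)
  expect_lt(res$p, 1e-4)
  yates <- chisq_2x2(109, 595, 1, 703, yates = TRUE)
  expect_lt(yates$statistic, res$statistic)
  expect_lt(yates$p, 1e-4)
  expect_equal(chisq_2x2(5, 5, 5, 5)$statistic, 0)
  expect_equal(chisq_2x2(5, 5, 5, 5)$p, 1)
  expect_error(chisq_2x2(0, 0, 3, 4), "margin")
})

test_that("BH step-up matches brute-force threshold enumeration", {
  brute_bh <- function(p, q) {
    n <- length(p)
    o <- order(p)
    k <- which(p[o] <= q * seq_len(n) / n)
    rej <- logical(n)
    if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
    rej
  }
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.3)
    res <- bh_fdr(p, q)
    expect_equal(res$reject, brute_bh(p, q))
    expect_true(all(diff(res$p_adjusted[order(res$p)]) >= -1e-12))
  }
  expect_false(any(bh_fdr(rep(1, 10), 0.1)$reject))
})

test_that("screening alpha follows the FDR relation and its monotonicity", {
  # f = alpha m0 / (alpha m0 + power m1) inverts to the implemented form
  a <- jung_alpha(380, 0.05, 0.05, 0.8)
  m1 <- 0.05 * 380; m0 <- 380 - m1
  expect_equal(a * m0 / (a * m0 + 0.8 * m1), 0.05, tolerance = 1e-12)
  expect_equal(a, 0.002216, tolerance = 1e-3)
  # strictly increasing in f and pi1; vanishing as f -> 0
  expect_gt(jung_alpha(380, 0.05, 0.10, 0.8), a)
  expect_gt(jung_alpha(380, 0.10, 0.05, 0.8), a)
  expect_lt(jung_alpha(380, 0.05, 1e-6, 0.8), 1e-6)
  expect_error(jung_alpha(380, 0, 0.05, 0.8), "pi1")
})

test_that("detectable effect solves the noncentral-t power equation", {
  d <- detectable_effect(10, 10, alpha = 0.0038, power = 0.8)
  # oracle 1: equal-n case agrees with power.t.test
  ref <- power.t.test(n = 10, sig.level = 0.0038, power = 0.8)$delta
  expect_equal(d, ref, tolerance = 1e-6)
  # oracle 2: brute-force scan of the power curve at step 1e-4
  grid <- seq(1.5, 2.5, by = 1e-4)
  pow <- sapply(grid, function(dd) {
    ncp <- dd / sqrt(1 / 10 + 1 / 10)
    crit <- qt(1 - 0.0038 / 2, 18)
    pt(-crit, 18, ncp = ncp) + 1 - pt(crit, 18, ncp = ncp)
  })
  expect_equal(d, grid[which(pow >= 0.8)[1]], tolerance = 2e-4)
  # monotone in n; normal-limit sanity at large n
  expect_lt(detectable_effect(40, 40, 0.0038, 0.8), d)
  big <- detectable_effect(5000, 5000, 0.05, 0.5)
  expect_equal(big, 1.96 * sqrt(2 / 5000), tolerance = 1e-2)
})

test_that("logistic-panel AUC equals the concordant-pair rank statistic", {
  scores <- c(0.1, 0.2, 0.3, 0.25, 0.4, 0.9)
  labels <- c(0, 0, 0, 1, 1, 1)
  pairs <- expand.grid(i = 1:3, j = 4:6)
  conc <- mean(ifelse(scores[pairs$j] > scores[pairs$i], 1,
                      ifelse(scores[pairs$j] == scores[pairs$i], 0.5, 0)))
  res <- logistic_panel_auc(data.frame(x = scores), labels)
  expect_equal(res$auc, conc, tolerance = 1e-12)
  expect_true(res$sensitivity >= 0 && res$sensitivity <= 1)
  # Mann-Whitney identity on random single-feature panels with a clear
  # positive association (the model is then monotone increasing in x)
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(30); y <- rep(0:1, each = 15)
    x[y == 1] <- x[y == 1] + runif(1, 1.2, 2)
    r <- suppressWarnings(logistic_panel_auc(data.frame(x = x), y))
    u <- wilcox.test(x[y == 1], x[y == 0])$statistic
    expect_equal(r$auc, unname(u) / (15 * 15), tolerance = 1e-9)
  }
  # perfect separation: AUC 1 with warning
  expect_warning(
    sep <- logistic_panel_auc(data.frame(x = c(1, 2, 3, 10, 11, 12)),
                              c(0, 0, 0, 1, 1, 1)),
    "separation")
  expect_equal(sep$auc, 1)
  # label-independent features give chance-level AUC
  set.seed(12)
  r0 <- logistic_panel_auc(data.frame(x = rnorm(400)), rep(0:1, 200))
  expect_lt(abs(r0$auc - 0.5), 0.1)
})
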