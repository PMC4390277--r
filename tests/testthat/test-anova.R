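# records fixture: balanced two-group, two-operator delta-Ct records
make_records <- function(n_per = 10, beta = c(a = 2, g = 1.5, o = 0.5,
                                              go = 0.25, cov = 1),
                         noise_sd = 0, seed = 1) {
  set.seed(seed)
  d <- expand.grid(sample = sprintf("s%02d", seq_len(2 * n_per)),
                   operator = c("op1", "op2"), stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(sub("s", "", d$sample)) <= n_per,
                    "case", "control")
  d$target <- "t1"; d$method <- "m"; d$timepoint_h <- 0
  g <- as.integer(d$group == "case")
  o <- as.integer(d$operator == "op2")
  d$covariate <- rnorm(nrow(d), 0, 0.4)
  d$delta_ct <- beta["a"] + beta["g"] * g + beta["o"] * o +
    beta["go"] * g * o + beta["cov"] * d$covariate +
    rnorm(nrow(d), 0, noise_sd)
  d
}

test_that("exactly six variants are admissible and misuse errors", {
  v <- anova_variants()
  expect_length(v, 6)
  expect_error(anova_spec(FALSE, TRUE), "interaction")
  expect_error(anova_spec(TRUE, FALSE, "OP1"), "operator")
})

test_that("zero-noise records recover the generating coefficients", {
  d <- make_records(noise_sd = 0)
  fit <- suppressWarnings(
    fit_variant(d, anova_spec(TRUE, TRUE, "ALL", "COVARIATE")))
  est <- fit$coefficients$estimate
  names(est) <- fit$coefficients$term
  expect_equal(unname(est[c("(Intercept)", "group", "operator",
                            "group:operator", "covariate")]),
               c(2, 1.5, 0.5, 0.25, 1), tolerance = 1e-8)
})

test_that("group coefficient equals the difference of group means", {
  d <- make_records(noise_sd = 1.2, beta = c(a = 1, g = 0.8, o = 0,
                                             go = 0, cov = 0), seed = 3)
  fit <- fit_variant(d, anova_spec(FALSE, FALSE, "ALL", "FIXED"))
  i <- match("group", fit$coefficients$term)
  expect_equal(fit$coefficients$estimate[i],
               mean(d$delta_ct[d$group == "case"]) -
                 mean(d$delta_ct[d$group == "control"]),
               tolerance = 1e-10)
  # balanced orthogonal design: dropping the operator term leaves beta1
  fit2 <- fit_variant(d, anova_spec(TRUE, FALSE, "ALL", "FIXED"))
  i2 <- match("group", fit2$coefficients$term)
  expect_equal(fit$coefficients$estimate[i], fit2$coefficients$estimate[i2],
               tolerance = 1e-10)
})

test_that("normalized response equals the covariate fit with beta4 fixed
          at its ideal-doubling value", {
  d <- make_records(noise_sd = 0.8, seed = 5)
  f_norm <- fit_variant(d, anova_spec(TRUE, TRUE, "ALL", "NORMALIZED"))
  f_con <- fit_variant(d, anova_spec(TRUE, TRUE, "ALL", "COVARIATE"),
                       constrain_beta4 = 1)
  expect_equal(f_norm$coefficients$estimate, f_con$coefficients$estimate,
               tolerance = 1e-12)
  expect_equal(f_norm$coefficients$se, f_con$coefficients$se,
               tolerance = 1e-12)
})

test_that("interaction never increases the residual sum of squares", {
  for (s in 1:5) {
    d <- make_records(noise_sd = 1.5, seed = s)
    rss <- function(spec) sum(residuals(fit_variant(d, spec)$lm)^2)
    expect_lte(rss(anova_spec(TRUE, TRUE, "ALL", "FIXED")),
               rss(anova_spec(TRUE, FALSE, "ALL", "FIXED")) + 1e-10)
  }
})

test_that("operator subsets and averaging reshape the data correctly", {
  d <- make_records(noise_sd = 0, beta = c(a = 0, g = 1, o = 2, go = 0,
                                           cov = 0))
  f1 <- suppressWarnings(fit_variant(d, anova_spec(FALSE, FALSE, "OP1")))
  f2 <- suppressWarnings(fit_variant(d, anova_spec(FALSE, FALSE, "OP2")))
  fa <- suppressWarnings(
    fit_variant(d, anova_spec(FALSE, FALSE, "AVERAGED")))
  ic <- function(f) f$coefficients$estimate[
    match("(Intercept)", f$coefficients$term)]
  expect_equal(ic(f1), 0, tolerance = 1e-10)
  expect_equal(ic(f2), 2, tolerance = 1e-10)
  expect_equal(ic(fa), 1, tolerance = 1e-10)  # per-sample operator mean
  expect_equal(fa$n, length(unique(d$sample)))
  # single-operator subset with an operator term is rank-deficient
  d1 <- d[d$operator == "op1", ]
  expect_error(fit_variant(d1, anova_spec(TRUE, FALSE, "ALL", "FIXED")),
               "collinear|operator")
})

test_that("threshold correction restores the group effect that per-plate
          threshold changes would bias", {
  # ideal doubling wells on two "plates" whose auto thresholds differ by
  # x2; the groups are unevenly split across plates (8:4 vs 4:8), so the
  # raw variable-threshold delta-Ct absorbs a spurious plate shift into
  # the group contrast
  n <- 12
  true_b1 <- -1
  base <- data.frame(
    sample = sprintf("s%02d", 1:(2 * n)),
    group = rep(c("case", "control"), each = n),
    target = "t1", operator = "op1", method = "m", timepoint_h = 0,
    stringsAsFactors = FALSE)
  plate2 <- c(rep(c(TRUE, FALSE), c(8, 4)), rep(c(TRUE, FALSE), c(4, 8)))
  # fixed threshold: everyone called at 0.03 -> unbiased
  dct_true <- 4 + true_b1 * (base$group == "case")
  fixed <- base
  fixed$delta_ct <- dct_true
  fixed$covariate <- 0
  # variable: plate-2 target threshold 0.06, plate 1 at 0.03 (ref at 0.03)
  thr <- ifelse(plate2, 0.06, 0.03)
  variable <- base
  variable$delta_ct <- dct_true + log2(thr / 0.03)  # Ct shift on target only
  variable$covariate <- log2(thr / 0.03)
  rep_ <- suppressWarnings(fixed_vs_variable_consistency(fixed, variable))
  b <- function(mode) rep_$beta1[rep_$mode == mode]
  expect_equal(b("fixed"), true_b1, tolerance = 1e-9)
  expect_equal(b("variable_uncorrected"), true_b1 + 1 / 3, tolerance = 1e-9)
  expect_equal(b("variable_normalized"), true_b1, tolerance = 1e-9)
  expect_equal(b("variable_covariate"), true_b1, tolerance = 1e-6)
  # the estimated threshold coefficient is the ideal-curve slope +1
  expect_equal(attr(rep_, "beta4"), 1, tolerance = 1e-6)
})
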