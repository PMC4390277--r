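#' Summary statistics container
#'
#' Mean, standard deviation and sample size — the form in which published
#' variability tables report their cells, and the input from which their
#' t-tests can be recomputed without raw data.
#'
#' @param mean sample mean.
#' @param sd sample standard deviation, >= 0.
#' @param n sample size, >= 2.
#' @return object of class \code{summary_stats}.
#' @export
summary_stats <- function(mean, sd, n) {
  if (sd < 0) stop("summary_stats: sd must be >= 0")
  if (n < 2) stop("summary_stats: n must be >= 2")
  structure(list(mean = mean, sd = sd, n = n), class = "summary_stats")
}

#' @keywords internal
as_summary <- function(x) {
  if (inherits(x, "summary_stats")) return(x)
  x <- x[!is.na(x)]
  summary_stats(mean(x), stats::sd(x), length(x))
}

#' Two-sample t-test from summaries or raw vectors
#'
#' Student (pooled-variance) or Welch two-sample t-test, computable directly
#' from (mean, sd, n) summaries so that published table cells can be
#' re-tested. Pooled:
#' \eqn{s_p^2 = ((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)},
#' df = n1+n2-2; Welch uses the Satterthwaite df. Two-sided p.
#'
#' @param a,b \code{summary_stats} objects or raw numeric vectors.
#' @param variant "pooled" (default) or "welch".
#' @return list(estimate, statistic, df, p, method) of class
#'   \code{test_result}; estimate is mean(a) - mean(b).
#' @export
two_sample_t <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  a <- as_summary(a); b <- as_summary(b)
  est <- a$mean - b$mean
  if (a$sd == 0 && b$sd == 0 && est == 0) {
    return(structure(list(estimate = 0, statistic = 0,
                          df = a$n + b$n - 2, p = 1,
                          method = paste0("two-sample t (", variant, ")")),
                     class = "test_result"))
  }
  if (variant == "pooled") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    v1 <- a$sd^2 / a$n; v2 <- b$sd^2 / b$n
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (a$n - 1) + v2^2 / (b$n - 1))
  }
  stat <- est / se
  structure(list(estimate = est, statistic = stat, df = df,
                 p = 2 * stats::pt(-abs(stat), df),
                 method = paste0("two-sample t (", variant, ")")),
            class = "test_result")
}

#' Paired t-test
#'
#' t-test on within-pair differences after pairwise deletion of incomplete
#' pairs; df = n - 1. All-zero differences return p = 1 with a
#' zero-variance flag rather than an error.
#'
#' @param x,y paired numeric vectors (equal length).
#' @return \code{test_result} with the mean difference as estimate, n used,
#'   and \code{zero_variance} flag.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired_t: unequal lengths")
  ok <- !is.na(x) & !is.na(y)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 2) stop("paired_t: fewer than 2 complete pairs")
  if (stats::sd(d) == 0) {
    return(structure(list(estimate = mean(d), statistic = NA_real_,
                          df = n - 1, p = 1, n = n, zero_variance = TRUE,
                          method = "paired t"),
                     class = "test_result"))
  }
  tt <- stats::t.test(d)
  structure(list(estimate = mean(d), statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value, n = n,
                 zero_variance = FALSE, method = "paired t"),
            class = "test_result")
}

#' Chi-squared test on a 2x2 table
#'
#' Pearson chi-squared (df = 1), optionally Yates-corrected, on counts
#' ((a, b), (c, d)). Used for comparing not-expressed vs expressed counts
#' between extraction methods.
#'
#' @param a,b,c,d non-negative integer cell counts (row-wise).
#' @param yates apply continuity correction (default FALSE: uncorrected
#'   Pearson).
#' @return \code{test_result}.
#' @export
chisq_2x2 <- function(a, b, c, d, yates = FALSE) {
  cnt <- c(a, b, c, d)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("chisq_2x2: counts must be non-negative integers")
  m <- matrix(cnt, 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("chisq_2x2: zero margin")
  res <- stats::chisq.test(m, correct = yates)
  structure(list(estimate = unname(res$statistic),
                 statistic = unname(res$statistic), df = 1,
                 p = res$p.value,
                 method = if (yates) "chi-squared (Yates)"
                          else "chi-squared (Pearson)"),
            class = "test_result")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values and rejection flags at rate q.
#'
#' @param pvalues p-values in [0, 1].
#' @param q target false discovery rate (default 0.10, the screening
#'   design's multiple-test control level).
#' @return data.frame(p, p_adjusted, reject).
#' @export
bh_fdr <- function(pvalues, q = 0.10) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("bh_fdr: p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, p_adjusted = adj, reject = adj <= q)
}

#' FDR-adjusted per-test alpha for a screening design
#'
#' Converts a target false discovery rate into a per-test significance
#' level for an m-feature screen in which a fraction pi1 of features is
#' truly significant and each true signal is detected with the target
#' power: with m1 = pi1 m true and m0 = m - m1 null features, the FDR of
#' per-test level \eqn{\alpha} is
#' \eqn{f = \alpha m_0 / (\alpha m_0 + \mathrm{power} \cdot m_1)}, giving
#' \deqn{\alpha^* = f \cdot \mathrm{power} \cdot m_1 / ((1 - f) m_0).}
#'
#' @param m feature count (e.g. 380 array miRNAs).
#' @param pi1 fraction of truly significant features, in (0, 1).
#' @param fdr target false discovery rate f, in (0, 1).
#' @param power target per-feature power, in (0, 1).
#' @return the adjusted per-test alpha.
#' @export
jung_alpha <- function(m, pi1, fdr, power) {
  if (pi1 <= 0 || pi1 >= 1) stop("jung_alpha: pi1 must be in (0, 1)")
  if (fdr <= 0 || fdr >= 1 || power <= 0 || power >= 1)
    stop("jung_alpha: rates must be in (0, 1)")
  m1 <- pi1 * m
  m0 <- m - m1
  fdr * power * m1 / ((1 - fdr) * m0)
}

#' @keywords internal
#' Exact power of the two-sided two-sample t-test at standardized effect
#' delta (= difference / common sd), from the noncentral t distribution.
t_test_power <- function(delta, n1, n2, alpha) {
  df <- n1 + n2 - 2
  ncp <- delta / sqrt(1 / n1 + 1 / n2)
  crit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-crit, df, ncp = ncp) + 1 - stats::pt(crit, df, ncp = ncp)
}

#' Smallest detectable standardized effect
#'
#' The smallest standardized mean difference delta/sigma at which a
#' two-sided two-sample t-test with group sizes n1, n2 attains the target
#' power at level alpha, solved from the noncentral t distribution.
#'
#' @param n1,n2 group sizes, >= 2.
#' @param alpha two-sided significance level.
#' @param power target power, > alpha.
#' @return standardized detectable difference.
#' @export
detectable_effect <- function(n1, n2, alpha, power) {
  if (n1 < 2 || n2 < 2) stop("detectable_effect: group sizes must be >= 2")
  if (power <= alpha) stop("detectable_effect: power must exceed alpha")
  stats::uniroot(function(d) t_test_power(d, n1, n2, alpha) - power,
                 interval = c(1e-8, 50), tol = 1e-10)$root
}

#' Logistic biomarker-panel ROC
#'
#' Fits an additive logistic model on a samples x features delta-Ct matrix,
#' computes in-sample predicted probabilities, the ROC curve, trapezoidal
#' AUC, and sensitivity/specificity at the Youden-optimal cutpoint. With
#' perfect separation the AUC is 1 and a separation warning is attached
#' (the coefficients are unstable and should not be interpreted).
#'
#' @param features numeric matrix or data.frame, samples x features.
#' @param labels group indicator (two levels; cases = second level of
#'   \code{factor(labels)}).
#' @return list(auc, roc (data.frame specificity/sensitivity), sensitivity,
#'   specificity, cutpoint, separation, model).
#' @export
logistic_panel_auc <- function(features, labels) {
  features <- as.data.frame(features)
  y <- factor(labels)
  if (nlevels(y) != 2) stop("labels must have exactly two levels")
  if (min(table(y)) < 2) stop("need >= 2 samples per class")
  cc <- stats::complete.cases(features)
  features <- features[cc, , drop = FALSE]; y <- y[cc]
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = features, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  prob <- stats::fitted(fit)
  roc <- pROC::roc(response = y, predictor = prob, quiet = TRUE,
                   direction = "<", levels = levels(y))
  best <- pROC::coords(roc, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  if (is.data.frame(best) && nrow(best) > 1) best <- best[1, ]
  if (separation)
    warning("perfect separation: AUC = 1, coefficients unstable")
  list(auc = as.numeric(pROC::auc(roc)),
       roc = data.frame(specificity = roc$specificities,
                        sensitivity = roc$sensitivities),
       sensitivity = as.numeric(best$sensitivity),
       specificity = as.numeric(best$specificity),
       cutpoint = as.numeric(best$threshold),
       separation = separation, model = fit)
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, ": estimate = ", format(x$estimate, digits = 4),
      ", statistic = ", format(x$statistic, digits = 4),
      ", df = ", format(x$df, digits = 4),
      ", p = ", format(round(x$p, 4), nsmall = 4), "\n", sep = "")
  invisible(x)
}
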