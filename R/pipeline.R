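#' Time-to-plasma-extraction analysis
#'
#' For each target and each later timepoint t, the per-subject paired
#' contrast of delta-Ct at the reference timepoint (0 h) minus delta-Ct at
#' t, with its paired t-test. Subjects missing either member of a pair are
#' excluded pairwise and counted.
#'
#' @param table Ct-export data.frame covering several timepoints.
#' @param reference_timepoint baseline timepoint (default 0).
#' @param reference reference target id.
#' @param alpha significance flag level (default 0.05).
#' @return data.frame: target, timepoint_h, mean_diff (0 h minus t h),
#'   p, n_pairs, n_excluded, significant.
#' @export
time_course_analysis <- function(table, reference_timepoint = 0,
                                 reference = "RNU6", alpha = 0.05) {
  recs <- delta_ct_table(table, reference = reference, mode = "FIXED")
  tps <- setdiff(sort(unique(recs$timepoint_h)), reference_timepoint)
  if (!reference_timepoint %in% recs$timepoint_h)
    stop("reference timepoint ", reference_timepoint, " absent from table")
  out <- list()
  for (tg in unique(recs$target)) {
    base <- recs[recs$target == tg &
                   recs$timepoint_h == reference_timepoint, ]
    for (tp in tps) {
      cur <- recs[recs$target == tg & recs$timepoint_h == tp, ]
      mi <- match(paste(base$sample, base$operator, base$method),
                  paste(cur$sample, cur$operator, cur$method))
      x <- base$delta_ct
      y <- cur$delta_ct[mi]
      ok <- !is.na(x) & !is.na(y)
      tt <- paired_t(x[ok], y[ok])
      out[[length(out) + 1]] <- data.frame(
        target = tg, timepoint_h = tp, mean_diff = tt$estimate, p = tt$p,
        n_pairs = tt$n, n_excluded = sum(!ok),
        significant = tt$p < alpha)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Repeated sample-acquisition analysis
#'
#' Within-subject contrast of delta-Ct between two blood draws of the same
#' day (AM vs PM), per target: mean delta-delta-Ct (first draw minus
#' second) and its paired t-test. The two draws are identified by the two
#' distinct timepoint values present (sorted; e.g. 0 = AM, 12 = PM).
#'
#' @param table Ct-export data.frame with exactly two timepoints.
#' @param reference reference target id.
#' @return data.frame: target, mean_ddct, p, n_pairs, n_excluded.
#' @export
repeated_acquisition_analysis <- function(table, reference = "RNU6") {
  recs <- delta_ct_table(table, reference = reference, mode = "FIXED")
  tps <- sort(unique(recs$timepoint_h))
  if (length(tps) != 2)
    stop("repeated-acquisition analysis needs exactly two draws; found ",
         length(tps))
  out <- lapply(unique(recs$target), function(tg) {
    am <- recs[recs$target == tg & recs$timepoint_h == tps[1], ]
    pm <- recs[recs$target == tg & recs$timepoint_h == tps[2], ]
    y <- pm$delta_ct[match(paste(am$sample, am$operator, am$method),
                           paste(pm$sample, pm$operator, pm$method))]
    ok <- !is.na(am$delta_ct) & !is.na(y)
    tt <- paired_t(am$delta_ct[ok], y[ok])
    data.frame(target = tg, mean_ddct = tt$estimate, p = tt$p,
               n_pairs = tt$n, n_excluded = sum(!ok))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Intra-operator (duplicate-well) variability
#'
#' Per target: mean (±SD) raw Ct of duplicate A and duplicate B across
#' samples, the absolute difference of those means |dCT|, and the paired
#' t-test across samples. Pairs with a missing duplicate reduce n and are
#' reported.
#'
#' @param table Ct-export data.frame with replicate wells (analyzed as
#'   given; filter to one operator/method/timepoint for a table-shaped
#'   report).
#' @param alpha significance flag level.
#' @return data.frame: target, mean_a, sd_a, mean_b, sd_b, abs_dct, p,
#'   n_pairs, n_excluded, zero_variance.
#' @export
intra_operator_analysis <- function(table, alpha = 0.05) {
  check_ct_table(table)
  reps <- sort(unique(table$replicate))
  if (length(reps) < 2) stop("duplicate wells required")
  a <- table[table$replicate == reps[1], ]
  b <- table[table$replicate == reps[2], ]
  key <- function(d) paste(d$sample, d$target, d$operator, d$method,
                           d$timepoint_h)
  mi <- match(key(a), key(b))
  out <- lapply(unique(table$target), function(tg) {
    sel <- a$target == tg
    x <- a$ct[sel]
    y <- b$ct[mi[sel]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2)
      return(data.frame(target = tg, mean_a = NA, sd_a = NA, mean_b = NA,
                        sd_b = NA, abs_dct = NA, p = NA,
                        n_pairs = sum(ok), n_excluded = sum(!ok),
                        zero_variance = NA))
    tt <- paired_t(x[ok], y[ok])
    data.frame(target = tg,
               mean_a = mean(x[ok]), sd_a = stats::sd(x[ok]),
               mean_b = mean(y[ok]), sd_b = stats::sd(y[ok]),
               abs_dct = abs(mean(x[ok]) - mean(y[ok])), p = tt$p,
               n_pairs = tt$n, n_excluded = sum(!ok),
               zero_variance = tt$zero_variance)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Inter-operator variability
#'
#' Per target: mean (±SD) delta-Ct per operator (replicates averaged), the
#' count of not-expressed sample entries per operator, the unpaired
#' (pooled) t-test comparing the operators' delta-Ct, and the per-sample
#' |delta-delta-Ct| summary (operator 1 minus operator 2; pairs with either
#' operator not expressed are dropped from |ddCt| but counted in the
#' missingness columns). A grand total-average |ddCt| row pools every
#' target-sample pair.
#'
#' @param table Ct-export data.frame for one method (both operators).
#' @param reference reference target id.
#' @param variant t-test variant, "pooled" (default) or "welch".
#' @param alpha significance flag level.
#' @return list of class \code{inter_operator_result}: \code{per_target}
#'   data.frame, \code{total} (pooled |ddCt| mean/sd/n),
#'   \code{not_expressed_total}, \code{pairs_total}, \code{abs_ddct}
#'   (raw pooled values), \code{method}.
#' @export
inter_operator_analysis <- function(table, reference = "RNU6",
                                    variant = "pooled", alpha = 0.05) {
  recs <- delta_ct_table(table, reference = reference, mode = "FIXED")
  ops <- sort(unique(recs$operator))
  if (length(ops) != 2) stop("exactly two operators required; found ",
                             length(ops))
  ne_tab <- missingness_summary(table[table$target != reference, ])
  all_abs <- numeric(0)
  pair_key <- function(d) paste(d$sample, d$method, d$timepoint_h)
  out <- lapply(unique(recs$target), function(tg) {
    r1 <- recs[recs$target == tg & recs$operator == ops[1], ]
    r2 <- recs[recs$target == tg & recs$operator == ops[2], ]
    x <- r1$delta_ct
    mi <- match(pair_key(r1), pair_key(r2))
    y <- r2$delta_ct[mi]
    # not-expressed counts refer to the target wells themselves; a missing
    # reference invalidates delta-Ct but is not a missing target
    ne1 <- sum(is.na(r1$ct)); ne2 <- sum(is.na(r2$ct[mi]))
    dd <- abs(x - y)
    dd <- dd[!is.na(dd)]
    test_ok <- sum(!is.na(x)) >= 2 && sum(!is.na(y)) >= 2
    tt <- if (test_ok)
      two_sample_t(x[!is.na(x)], y[!is.na(y)], variant = variant)
    else list(p = NA_real_)
    data.frame(target = tg,
               mean_dct_op1 = mean(x, na.rm = TRUE),
               sd_dct_op1 = stats::sd(x[!is.na(x)]),
               n_not_expressed_op1 = ne1,
               mean_dct_op2 = mean(y, na.rm = TRUE),
               sd_dct_op2 = stats::sd(y[!is.na(y)]),
               n_not_expressed_op2 = ne2,
               p = tt$p, significant = !is.na(tt$p) && tt$p < alpha,
               mean_abs_ddct = if (length(dd)) mean(dd) else NA_real_,
               sd_abs_ddct = if (length(dd) > 1) stats::sd(dd)
                             else NA_real_,
               n_pairs = length(dd))
  })
  per_target <- do.call(rbind, out)
  rownames(per_target) <- NULL
  for (tg in per_target$target) {
    r1 <- recs[recs$target == tg & recs$operator == ops[1], ]
    r2 <- recs[recs$target == tg & recs$operator == ops[2], ]
    dd <- abs(r1$delta_ct -
                r2$delta_ct[match(pair_key(r1), pair_key(r2))])
    all_abs <- c(all_abs, dd[!is.na(dd)])
  }
  structure(list(
    per_target = per_target,
    total = list(mean_abs_ddct = mean(all_abs),
                 sd_abs_ddct = stats::sd(all_abs), n = length(all_abs)),
    not_expressed_total = ne_tab$overall$not_expressed,
    pairs_total = ne_tab$overall$total,
    abs_ddct = all_abs,
    operators = ops,
    method = paste(unique(table$method), collapse = "+")),
    class = "inter_operator_result")
}

#' Extraction-method comparison
#'
#' Compares two inter-operator analyses (one per extraction method): per
#' target a two-sample t-test on the |delta-delta-Ct| summaries, a pooled
#' total-row test, and a chi-squared test on the
#' (not expressed, expressed) x method counts.
#'
#' @param a,b \code{inter_operator_result} objects for the two methods.
#' @param variant t-test variant.
#' @param alpha significance flag level.
#' @return list: per_target data.frame (target, mean/sd |ddCt| per method,
#'   not-expressed counts, p), total_test (\code{test_result}),
#'   chisq (\code{test_result} on dropout counts), counts.
#' @export
method_comparison <- function(a, b, variant = "pooled", alpha = 0.05) {
  stopifnot(inherits(a, "inter_operator_result"),
            inherits(b, "inter_operator_result"))
  if (!identical(sort(a$per_target$target), sort(b$per_target$target)))
    stop("mismatched target panels: ",
         paste(symdiff_chr(a$per_target$target, b$per_target$target),
               collapse = ", "))
  pa <- a$per_target
  pb <- b$per_target[match(pa$target, b$per_target$target), ]
  rows <- lapply(seq_len(nrow(pa)), function(i) {
    ok <- pa$n_pairs[i] >= 2 && pb$n_pairs[i] >= 2
    tt <- if (ok) two_sample_t(
      summary_stats(pa$mean_abs_ddct[i], pa$sd_abs_ddct[i], pa$n_pairs[i]),
      summary_stats(pb$mean_abs_ddct[i], pb$sd_abs_ddct[i], pb$n_pairs[i]),
      variant = variant) else list(p = NA_real_)
    data.frame(target = pa$target[i],
               mean_abs_ddct_a = pa$mean_abs_ddct[i],
               sd_abs_ddct_a = pa$sd_abs_ddct[i],
               not_expressed_a = pa$n_not_expressed_op1[i] +
                 pa$n_not_expressed_op2[i],
               mean_abs_ddct_b = pb$mean_abs_ddct[i],
               sd_abs_ddct_b = pb$sd_abs_ddct[i],
               not_expressed_b = pb$n_not_expressed_op1[i] +
                 pb$n_not_expressed_op2[i],
               p = tt$p, significant = !is.na(tt$p) && tt$p < alpha)
  })
  per_target <- do.call(rbind, rows)
  rownames(per_target) <- NULL
  total_test <- two_sample_t(a$abs_ddct, b$abs_ddct, variant = variant)
  counts <- c(ne_a = a$not_expressed_total,
              expr_a = a$pairs_total - a$not_expressed_total,
              ne_b = b$not_expressed_total,
              expr_b = b$pairs_total - b$not_expressed_total)
  chisq <- if (counts[1] == 0 && counts[3] == 0) {
    # no dropout in either method: the dropout margin is degenerate and
    # the methods are indistinguishable on it
    structure(list(estimate = 0, statistic = 0, df = 1, p = 1,
                   method = "chi-squared (Pearson)"),
              class = "test_result")
  } else chisq_2x2(counts[1], counts[2], counts[3], counts[4])
  list(per_target = per_target, total_test = total_test, chisq = chisq,
       counts = counts,
       total_a = a$total, total_b = b$total)
}

#' @keywords internal
symdiff_chr <- function(x, y) union(setdiff(x, y), setdiff(y, x))

#' Group-effect persistence under operator variability
#'
#' Fits the six-variant ANOVA family per target on delta-Ct and reports the
#' group coefficient (beta1) with its p-value for each variant, plus
#' per-target coefficient-of-variation summaries of the raw Ct values
#' (100 sd/mean), to check that a case-control difference survives
#' operator terms.
#'
#' @param table Ct-export data.frame (two groups, both operators).
#' @param reference reference target id.
#' @param threshold_mode threshold handling for all six variants.
#' @param alpha significance flag level.
#' @return list: \code{beta1} data.frame (target x variant: estimate, p,
#'   significant), \code{cv} data.frame (target, cv of raw Ct including the
#'   reference).
#' @export
group_effect_check <- function(table, reference = "RNU6",
                               threshold_mode = "FIXED", alpha = 0.05) {
  check_ct_table(table)
  if (length(unique(table$group)) < 2) stop("two groups required")
  mode <- if (threshold_mode == "FIXED") "FIXED" else "VARIABLE_COVARIATE"
  recs <- delta_ct_table(table, reference = reference, mode = mode)
  variants <- anova_variants(threshold_mode)
  rows <- list()
  for (tg in unique(recs$target)) {
    sub <- recs[recs$target == tg, ]
    for (v in names(variants)) {
      fit <- tryCatch(fit_variant(sub, variants[[v]]),
                      error = function(e) NULL)
      if (is.null(fit)) next
      i <- match("group", fit$coefficients$term)
      rows[[length(rows) + 1]] <- data.frame(
        target = tg, variant = v,
        beta1 = fit$coefficients$estimate[i], p = fit$coefficients$p[i],
        significant = fit$coefficients$p[i] < alpha)
    }
  }
  coll <- collapse_replicates(table)
  cv <- aggregate(ct ~ target, data = coll,
                  FUN = function(x) 100 * stats::sd(x) / mean(x))
  names(cv)[2] <- "cv"
  beta1 <- do.call(rbind, rows)
  rownames(beta1) <- NULL
  list(beta1 = beta1, cv = cv)
}
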