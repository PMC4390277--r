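#' Delta-Ct against the endogenous reference
#'
#' Relative quantification of one target against the reference (RNU6).
#' Modes:
#' \describe{
#'   \item{FIXED}{\eqn{\nabla Ct = C_t - C_R}; both wells called at one
#'     common fixed threshold, no covariate.}
#'   \item{VARIABLE_NORMALIZED}{\eqn{\nabla Ct = C_t - C_R -
#'     \log_2(T_t/T_R)}; per-target automatic thresholds, absorbed into the
#'     response.}
#'   \item{VARIABLE_COVARIATE}{\eqn{\nabla Ct = C_t - C_R} with
#'     \eqn{\log_2(T_t/T_R)} carried separately as a model covariate.}
#' }
#' A record with either call not expressed is returned with status
#' \code{"NOT_EXPRESSED"} and NA delta-Ct — never a silent zero.
#'
#' @param ct target Ct (NA if not expressed).
#' @param ct_ref reference Ct (NA if not expressed).
#' @param mode one of "FIXED", "VARIABLE_NORMALIZED", "VARIABLE_COVARIATE".
#' @param t_t,t_r threshold intensities of target and reference, > 0.
#' @return list(status, delta_ct, covariate, mode).
#' @export
delta_ct <- function(ct, ct_ref, mode = c("FIXED", "VARIABLE_NORMALIZED",
                                          "VARIABLE_COVARIATE"),
                     t_t = NA_real_, t_r = NA_real_) {
  mode <- match.arg(mode)
  if (mode != "FIXED" && (!is.finite(t_t) || !is.finite(t_r) ||
                          t_t <= 0 || t_r <= 0))
    stop("variable-threshold modes require positive thresholds t_t, t_r")
  if (is.na(ct) || is.na(ct_ref))
    return(list(status = "NOT_EXPRESSED", delta_ct = NA_real_,
                covariate = NA_real_, mode = mode))
  cov <- if (mode == "FIXED") NA_real_ else log2(t_t / t_r)
  dct <- switch(mode,
                FIXED = ct - ct_ref,
                VARIABLE_NORMALIZED = ct - ct_ref - cov,
                VARIABLE_COVARIATE = ct - ct_ref)
  list(status = "EXPRESSED", delta_ct = dct,
       covariate = if (mode == "VARIABLE_COVARIATE") cov else NA_real_,
       mode = mode)
}

#' Delta-delta-Ct contrast
#'
#' Difference of two delta-Ct values (first minus second: operator 1 minus
#' operator 2, or reference timepoint minus later timepoint), with its
#' absolute value |delta-delta-Ct| as reported in variability tables.
#'
#' @param a,b finite delta-Ct values (NA propagates).
#' @return list(ddct, abs_ddct).
#' @export
delta_delta_ct <- function(a, b) {
  d <- a - b
  list(ddct = d, abs_ddct = abs(d))
}

#' Fold change from delta-delta-Ct
#'
#' Standard relative quantification: fold = 2^(-ddct).
#' @param ddct delta-delta-Ct value(s).
#' @return fold change(s).
#' @export
fold_change <- function(ddct) 2^(-ddct)

#' Aggregate replicate wells to one Ct
#'
#' Arithmetic mean on the Ct scale of the expressed replicates (the scale on
#' which duplicate means are tabulated); not-expressed wells are dropped and
#' counted. Zero expressed replicates propagates NOT_EXPRESSED.
#'
#' @param ct numeric replicate Ct values, NA = not expressed.
#' @return list(status, ct, n_expressed, n_total).
#' @export
aggregate_replicates <- function(ct) {
  ok <- !is.na(ct)
  if (!any(ok))
    return(list(status = "NOT_EXPRESSED", ct = NA_real_, n_expressed = 0L,
                n_total = length(ct)))
  list(status = "EXPRESSED", ct = mean(ct[ok]),
       n_expressed = sum(ok), n_total = length(ct))
}

#' @keywords internal
#' Validate the Ct-export schema.
check_ct_table <- function(table) {
  need <- c("sample", "group", "target", "operator", "method",
            "timepoint_h", "replicate", "ct", "threshold")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("ct table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(table) == 0) stop("ct table is empty")
  invisible(table)
}

#' Collapse a Ct table over replicates
#'
#' Averages expressed replicate wells within each
#' sample x target x operator x method x timepoint cell
#' (\code{\link{aggregate_replicates}}) and keeps the expressed-replicate
#' count.
#'
#' @param table Ct-export data.frame.
#' @return data.frame with one row per cell: ct (NA if no replicate
#'   expressed), threshold (mean), n_expressed, n_total.
#' @export
collapse_replicates <- function(table) {
  check_ct_table(table)
  key <- interaction(table$sample, table$target, table$operator,
                     table$method, table$timepoint_h, drop = TRUE)
  idx <- split(seq_len(nrow(table)), key)
  rows <- lapply(idx, function(i) {
    ag <- aggregate_replicates(table$ct[i])
    r <- table[i[1], c("sample", "group", "target", "operator", "method",
                       "timepoint_h")]
    r$ct <- ag$ct
    r$threshold <- mean(table$threshold[i], na.rm = TRUE)
    r$n_expressed <- ag$n_expressed
    r$n_total <- ag$n_total
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Delta-Ct records for a whole Ct table
#'
#' Pairs every non-reference target with the reference of the same
#' sample x operator x method x timepoint cell, after replicate averaging,
#' and computes delta-Ct in the requested mode.
#'
#' @param table Ct-export data.frame.
#' @param reference reference target id (default "RNU6").
#' @param mode delta-Ct mode (see \code{\link{delta_ct}}).
#' @return data.frame of delta-Ct records: sample, group, target, operator,
#'   method, timepoint_h, ct, ct_ref, t_t, t_r, delta_ct, covariate, status.
#' @export
delta_ct_table <- function(table, reference = "RNU6",
                           mode = c("FIXED", "VARIABLE_NORMALIZED",
                                    "VARIABLE_COVARIATE")) {
  mode <- match.arg(mode)
  coll <- collapse_replicates(table)
  if (!reference %in% coll$target)
    stop("reference target '", reference, "' absent from table")
  ref <- coll[coll$target == reference, ]
  tgt <- coll[coll$target != reference, ]
  key <- function(d) paste(d$sample, d$operator, d$method, d$timepoint_h)
  mi <- match(key(tgt), key(ref))
  tgt$ct_ref <- ref$ct[mi]
  tgt$t_r <- ref$threshold[mi]
  out <- tgt[, c("sample", "group", "target", "operator", "method",
                 "timepoint_h")]
  out$ct <- tgt$ct
  out$ct_ref <- tgt$ct_ref
  out$t_t <- tgt$threshold
  out$t_r <- tgt$t_r
  recs <- mapply(function(ct, cr, tt, tr)
    delta_ct(ct, cr, mode, t_t = tt, t_r = tr),
    out$ct, out$ct_ref, out$t_t, out$t_r, SIMPLIFY = FALSE)
  out$delta_ct <- vapply(recs, `[[`, numeric(1), "delta_ct")
  out$covariate <- vapply(recs, `[[`, numeric(1), "covariate")
  out$status <- vapply(recs, `[[`, character(1), "status")
  out$mode <- mode
  rownames(out) <- NULL
  out
}

#' Missingness summary of a Ct table
#'
#' Counts not-expressed entries per target and overall, at the
#' replicate-aggregated sample x target level (an entry is not expressed
#' only if no replicate expressed), within each operator x method slice.
#'
#' @param table Ct-export data.frame.
#' @return list(per_target, per_slice, overall) where overall =
#'   list(not_expressed, total, fraction). Per-target counts sum to the
#'   overall count.
#' @export
missingness_summary <- function(table) {
  coll <- collapse_replicates(table)
  ne <- is.na(coll$ct)
  per_target <- aggregate(ne, by = list(target = coll$target),
                          FUN = function(x) c(sum(x), length(x)))
  per_target <- data.frame(target = per_target$target,
                           not_expressed = per_target$x[, 1],
                           total = per_target$x[, 2])
  per_slice <- aggregate(ne, by = list(operator = coll$operator,
                                       method = coll$method),
                         FUN = function(x) c(sum(x), length(x)))
  per_slice <- data.frame(operator = per_slice$operator,
                          method = per_slice$method,
                          not_expressed = per_slice$x[, 1],
                          total = per_slice$x[, 2])
  list(per_target = per_target, per_slice = per_slice,
       overall = list(not_expressed = sum(ne), total = length(ne),
                      fraction = mean(ne)))
}

#' Delta-Ct matrix (samples x targets)
#'
#' Reshapes delta-Ct records to a samples x targets matrix (the data layer
#' of an expression heat map). Multiple operators/methods/timepoints are
#' averaged per cell.
#'
#' @param records data.frame from \code{\link{delta_ct_table}}.
#' @return numeric matrix, rownames = samples, colnames = targets.
#' @export
delta_ct_matrix <- function(records) {
  samples <- unique(records$sample)
  targets <- unique(records$target)
  m <- matrix(NA_real_, length(samples), length(targets),
              dimnames = list(samples, targets))
  agg <- aggregate(delta_ct ~ sample + target, data = records, FUN = mean,
                   na.action = stats::na.omit)
  m[cbind(match(agg$sample, samples), match(agg$target, targets))] <-
    agg$delta_ct
  m
}
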