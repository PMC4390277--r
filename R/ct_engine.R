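#' Baseline-correct an amplification curve
#'
#' Subtracts the mean fluorescence over a baseline window from every cycle.
#' Returned values may be negative. Fixed-threshold calling operates on
#' baseline-corrected fluorescence.
#'
#' @param curve an \code{amplification_curve}.
#' @param window integer cycle range (two values, inclusive) within the
#'   curve's cycles, length >= 3; default cycles 3 to 15 (before the
#'   earliest typical exponential phase).
#' @return the curve with corrected fluorescence.
#' @export
baseline_correct <- function(curve, window = c(3L, 15L)) {
  stopifnot(inherits(curve, "amplification_curve"))
  w <- seq(window[1], window[2])
  if (window[1] < min(curve$cycle) || window[2] > max(curve$cycle))
    stop("baseline window outside cycle range")
  if (length(w) < 3) stop("baseline window must span >= 3 cycles")
  curve$fluorescence <- curve$fluorescence -
    mean(curve$fluorescence[curve$cycle %in% w])
  curve
}

#' @keywords internal
#' Locate the first sustained upward threshold crossing in a fluorescence
#' vector. Returns the fractional cycle, or NA if none. The crossing must
#' stay above the threshold for at least 2 subsequent cycles (suppresses
#' single-point noise spikes). Interpolation between the flanking cycles is
#' log-linear, because fluorescence is geometric in the exponential phase;
#' falls back to linear if the lower flank is non-positive.
locate_crossing <- function(f, threshold) {
  n <- length(f)
  for (c in seq_len(n - 1)) {
    if (f[c] < threshold && f[c + 1] >= threshold) {
      upto <- min(n, c + 3)
      if (all(f[(c + 1):upto] >= threshold)) {
        if (f[c] > 0) {
          return(c + (log2(threshold) - log2(f[c])) /
                   (log2(f[c + 1]) - log2(f[c])))
        }
        return(c + (threshold - f[c]) / (f[c + 1] - f[c]))
      }
    }
  }
  if (f[1] >= threshold && all(f[seq_len(min(3, n))] >= threshold))
    return(1)  # already above threshold at the first cycle
  NA_real_
}

#' Call Ct at a fixed threshold
#'
#' Ct is the first upward crossing of the threshold that stays above it for
#' at least two subsequent cycles, located by log-linear interpolation
#' between the flanking cycles. A curve that never crosses within the trace
#' is NOT_EXPRESSED.
#'
#' @param curve a baseline-corrected \code{amplification_curve}.
#' @param threshold threshold intensity, > 0 (the study's fixed settings
#'   were 0.01, 0.03, 0.05 and 0.5).
#' @return a \code{ct_call}: list(status, ct, threshold, mode = "FIXED").
#' @export
call_ct_fixed <- function(curve, threshold) {
  stopifnot(inherits(curve, "amplification_curve"))
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0")
  ct <- locate_crossing(curve$fluorescence, threshold)
  structure(list(status = if (is.na(ct)) "NOT_EXPRESSED" else "EXPRESSED",
                 ct = ct, threshold = threshold, mode = "FIXED"),
            class = "ct_call")
}

#' @keywords internal
#' Exponential-phase detection: the maximal cycle run (length >= min_len)
#' over which the log2-fluorescence slope is positive (>= slope_min) and
#' uniform within tol. Returns c(start, end) cycle indices or NULL.
find_exponential_phase <- function(f, tol = 0.5, slope_min = 0.25,
                                   min_len = 4L) {
  lf <- log2(pmax(f, 1e-12))
  d <- diff(lf)
  n <- length(d)
  best <- NULL
  i <- 1L
  while (i <= n) {
    if (d[i] >= slope_min) {
      j <- i
      while (j < n && d[j + 1] >= slope_min &&
             max(d[i:(j + 1)]) - min(d[i:(j + 1)]) <= tol) j <- j + 1L
      if (j - i + 2L >= min_len &&
          (is.null(best) || j - i > best[2] - best[1]))
        best <- c(i, j + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  best
}

#' Call Ct with an automatic (variable) per-target threshold
#'
#' Emulates a plate-reader's "automatic Ct" mode: one threshold per target
#' per plate, chosen from the curves' exponential phases. Each curve's
#' exponential phase is the maximal cycle run where log2 fluorescence is
#' linear within tolerance; the threshold is the geometric midpoint of the
#' intersection of the per-curve exponential-phase fluorescence ranges
#' (pooled range if the intersection is empty), so it lies inside every
#' curve's exponential phase whenever possible. Every curve is then called
#' at that threshold exactly as in \code{\link{call_ct_fixed}}. The chosen
#' threshold accompanies every call, as the downstream normalization
#' covariate log2(Tt/TR) requires it.
#'
#' @param curves list of baseline-corrected \code{amplification_curve}s of
#'   one target on one plate.
#' @param tol log2-slope uniformity tolerance for phase detection.
#' @return list(threshold, calls = list of \code{ct_call} with mode
#'   \code{"AUTO"}, flagged = TRUE if no usable exponential phase was found
#'   (all calls NOT_EXPRESSED, threshold NA)).
#' @export
call_ct_auto <- function(curves, tol = 0.5) {
  stopifnot(length(curves) >= 1)
  phases <- lapply(curves, function(cv)
    find_exponential_phase(cv$fluorescence, tol = tol))
  lo <- hi <- numeric(0)
  for (k in seq_along(curves)) {
    ph <- phases[[k]]
    if (!is.null(ph)) {
      fr <- curves[[k]]$fluorescence[ph]
      lo <- c(lo, max(min(fr), 1e-12))
      hi <- c(hi, max(fr))
    }
  }
  if (length(lo) == 0) {
    calls <- lapply(curves, function(cv)
      structure(list(status = "NOT_EXPRESSED", ct = NA_real_,
                     threshold = NA_real_, mode = "AUTO"),
                class = "ct_call"))
    return(list(threshold = NA_real_, calls = calls, flagged = TRUE))
  }
  l <- max(lo); h <- min(hi)
  if (l >= h) { l <- min(lo); h <- max(hi) }  # intersection empty: pool
  threshold <- sqrt(l * h)
  calls <- lapply(curves, function(cv) {
    ct <- locate_crossing(cv$fluorescence, threshold)
    structure(list(status = if (is.na(ct)) "NOT_EXPRESSED" else "EXPRESSED",
                   ct = ct, threshold = threshold, mode = "AUTO"),
              class = "ct_call")
  })
  list(threshold = threshold, calls = calls, flagged = FALSE)
}

#' Call Ct for a long-format curve collection
#'
#' Applies fixed-threshold or automatic per-target-per-plate calling to a
#' long curve table (the \code{simulate_experiment} schema) and returns a
#' Ct-export table, the pipeline's central exchange format.
#'
#' @param curves long data.frame with columns well_id, sample_id, group,
#'   target, operator, method, timepoint_h, replicate, plate, cycle,
#'   fluorescence.
#' @param threshold fixed threshold intensity; ignored when
#'   \code{auto = TRUE}.
#' @param auto use automatic per-target-per-plate thresholds.
#' @param baseline_window baseline-correction cycle window.
#' @return Ct-export data.frame: sample, group, target, operator, method,
#'   timepoint_h, replicate, ct (NA when not expressed), threshold, mode.
#' @export
call_ct_table <- function(curves, threshold = 0.03, auto = FALSE,
                          baseline_window = c(3L, 15L)) {
  need <- c("well_id", "sample_id", "group", "target", "operator", "method",
            "timepoint_h", "replicate", "plate", "cycle", "fluorescence")
  miss <- setdiff(need, names(curves))
  if (length(miss)) stop("curve table lacks column(s): ",
                         paste(miss, collapse = ", "))
  o <- order(curves$well_id, curves$cycle)
  curves <- curves[o, ]
  wid <- unique(curves$well_id)
  n_cyc <- length(unique(curves$cycle))
  meta <- curves[!duplicated(curves$well_id),
                 c("well_id", "sample_id", "group", "target", "operator",
                   "method", "timepoint_h", "replicate", "plate")]
  fmat <- matrix(curves$fluorescence, ncol = n_cyc, byrow = TRUE)
  bw <- seq(baseline_window[1], baseline_window[2])
  fmat <- fmat - rowMeans(fmat[, bw, drop = FALSE])
  ct <- rep(NA_real_, nrow(meta))
  thr <- rep(NA_real_, nrow(meta))
  if (auto) {
    grp <- paste(meta$target, meta$plate)
    for (g in unique(grp)) {
      idx <- which(grp == g)
      cl <- lapply(idx, function(i)
        structure(list(cycle = seq_len(n_cyc), fluorescence = fmat[i, ]),
                  class = "amplification_curve"))
      res <- call_ct_auto(cl)
      ct[idx] <- vapply(res$calls, function(x)
        if (x$status == "EXPRESSED") x$ct else NA_real_, numeric(1))
      thr[idx] <- res$threshold
    }
  } else {
    if (threshold <= 0) stop("threshold must be > 0")
    for (i in seq_len(nrow(meta)))
      ct[i] <- locate_crossing(fmat[i, ], threshold)
    thr[] <- threshold
  }
  data.frame(sample = meta$sample_id, group = meta$group,
             target = meta$target, operator = meta$operator,
             method = meta$method, timepoint_h = meta$timepoint_h,
             replicate = meta$replicate, ct = ct, threshold = thr,
             mode = if (auto) "AUTO" else "FIXED",
             stringsAsFactors = FALSE)
}
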