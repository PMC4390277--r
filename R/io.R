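#' Read a Ct-export CSV
#'
#' Parses and validates the long-format Ct-export table (the emulated
#' plate-software export). A not-expressed well has an empty \code{ct}
#' field (an instrument-style \code{"Undetermined"} string is mapped to
#' missing); Ct is never encoded as 40. Duplicate
#' (sample, target, operator, method, timepoint, replicate) keys and
#' non-positive thresholds are rejected with the offending row number.
#'
#' @param path CSV file path (UTF-8, header row, "." decimal).
#' @return validated Ct-export data.frame.
#' @export
parse_ct_export <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("sample", "group", "target", "operator", "method",
            "timepoint_h", "replicate", "ct", "threshold", "mode")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         " in ", path)
  raw$ct[raw$ct %in% c("", "Undetermined", "undetermined", "NA")] <- NA
  ct <- suppressWarnings(as.numeric(raw$ct))
  bad <- which(!is.na(raw$ct) & is.na(ct))
  if (length(bad)) stop("non-numeric ct at row ", bad[1], " in ", path)
  thr <- suppressWarnings(as.numeric(raw$threshold))
  badt <- which(!is.na(thr) & thr <= 0)
  if (length(badt)) stop("non-positive threshold at row ", badt[1],
                         " in ", path)
  tp <- suppressWarnings(as.numeric(raw$timepoint_h))
  rep_ <- suppressWarnings(as.integer(raw$replicate))
  out <- data.frame(sample = raw$sample, group = raw$group,
                    target = raw$target, operator = raw$operator,
                    method = raw$method, timepoint_h = tp,
                    replicate = rep_, ct = ct, threshold = thr,
                    mode = raw$mode, stringsAsFactors = FALSE)
  key <- paste(out$sample, out$target, out$operator, out$method,
               out$timepoint_h, out$replicate)
  dup <- which(duplicated(key))
  if (length(dup)) stop("duplicate well key at row ", dup[1], " in ", path)
  out
}

#' Write a Ct-export CSV
#'
#' Inverse of \code{\link{parse_ct_export}}: missing Ct written as an empty
#' field.
#'
#' @param table Ct-export data.frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_ct_export <- function(table, path) {
  check_ct_table(table)
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a long-format curve collection CSV
#' @param curves long curve data.frame (\code{simulate_experiment} schema).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_curves <- function(curves, path) {
  utils::write.csv(curves, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format curve collection CSV
#' @param path CSV path.
#' @return long curve data.frame.
#' @export
read_curves <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "sample_id", "target", "cycle", "fluorescence")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         " in ", path)
  if (any(!is.finite(d$fluorescence)))
    stop("non-finite fluorescence in ", path)
  d
}

#' Write the samples x targets delta-Ct matrix CSV
#' @param records delta-Ct records (\code{\link{delta_ct_table}}).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_delta_ct_matrix <- function(records, path) {
  m <- delta_ct_matrix(records)
  utils::write.csv(data.frame(sample = rownames(m), m, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read summary-statistic rows from CSV
#'
#' Reads (label, mean, sd, n) rows, so printed table cells can be re-tested
#' directly against the stats kernel. An example file of published
#' inter-operator summary cells ships as
#' \code{system.file("extdata", "interop_summary_cells.csv",
#' package = "ctrepro")}.
#'
#' @param path CSV with columns label, mean, sd, n.
#' @return named list of \code{summary_stats}.
#' @export
read_summary_stats <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "mean", "sd", "n")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         " in ", path)
  out <- lapply(seq_len(nrow(d)), function(i)
    summary_stats(d$mean[i], d$sd[i], d$n[i]))
  names(out) <- d$label
  out
}
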