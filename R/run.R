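#' @keywords internal
#' Small stable hash of an R object (FNV-style over its deparsed form),
#' for run logging.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  sprintf("%08x", str_hash(s))
}

#' @keywords internal
#' Rebuild a sim_config from a plain (YAML-derived) list.
config_from_list <- function(cl) {
  if (inherits(cl, "sim_config")) return(cl)
  if (!is.null(cl$preset))
    return(study_preset(cl$preset, seed = cl$seed %||% 1L))
  tg <- as.data.frame(do.call(rbind, lapply(cl$targets, as.data.frame)))
  sim_config(n_cases = cl$n_cases, n_controls = cl$n_controls,
             targets = tg, reference = cl$reference,
             operators = as.data.frame(do.call(rbind, lapply(
               cl$operators, as.data.frame))),
             methods = as.data.frame(do.call(rbind, lapply(
               cl$methods, as.data.frame))),
             duplicates = cl$duplicates %||% 2L,
             timepoints_h = unlist(cl$timepoints_h) %||% 0,
             lag_h = cl$lag_h %||% 12,
             run_sd = cl$run_sd %||% 0, well_sd = cl$well_sd %||% 0,
             seed = cl$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a pipeline stage
#'
#' Programmatic command surface tying the stages into reproducible runs.
#' Commands: \code{"simulate"} (config to curves + truth CSVs),
#' \code{"call-ct"} (curves to Ct export; fixed \code{threshold} or
#' \code{auto = TRUE}), \code{"normalize"} (Ct export to delta-Ct records
#' CSV + delta-Ct matrix; \code{mode}), \code{"analyze"}
#' (\code{analysis} one of time/repeat/intra/inter/method/group),
#' \code{"anova"} (\code{variant} 1..6), and \code{"power"} (screening
#' alpha + detectable effect). Every run writes a log line with the config
#' hash and seed. Outputs are deterministic functions of (inputs, config,
#' seed).
#'
#' @param command subcommand name.
#' @param config named list of options (or a YAML file path): \code{out_dir}
#'   plus command-specific entries (\code{curves}, \code{ct},
#'   \code{threshold}, \code{auto}, \code{mode}, \code{analysis},
#'   \code{variant}, \code{sim} ...).
#' @return list of written artifact paths (and the main result object),
#'   invisibly.
#' @export
qpcr_run <- function(command, config = list()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cmds <- c("simulate", "call-ct", "normalize", "analyze", "anova", "power")
  if (!command %in% cmds)
    stop("unknown subcommand '", command, "'; expected one of: ",
         paste(cmds, collapse = ", "))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- sprintf("[ctrepro %s] command=%s config=%s seed=%s",
                      as.character(utils::packageVersion("ctrepro")),
                      command, config_hash(config),
                      config$seed %||% config$sim$seed %||% "NA")
  writeLines(log_line, file.path(out_dir, "run.log"))
  result <- switch(command,
    "simulate" = {
      cfg <- config_from_list(config$sim %||% config)
      sim <- simulate_experiment(cfg)
      write_curves(sim$curves, file.path(out_dir, "curves.csv"))
      utils::write.csv(sim$truth, file.path(out_dir, "truth.csv"),
                       row.names = FALSE)
      sim
    },
    "call-ct" = {
      curves <- if (is.character(config$curves)) read_curves(config$curves)
                else config$curves
      tab <- call_ct_table(curves,
                           threshold = config$threshold %||% 0.03,
                           auto = isTRUE(config$auto))
      write_ct_export(tab, file.path(out_dir, "ct_export.csv"))
      tab
    },
    "normalize" = {
      tab <- if (is.character(config$ct)) parse_ct_export(config$ct)
             else config$ct
      mode <- toupper(gsub("-", "_", config$mode %||% "fixed"))
      recs <- delta_ct_table(tab, reference = config$reference %||% "RNU6",
                             mode = mode)
      utils::write.csv(recs, file.path(out_dir, "delta_ct.csv"),
                       row.names = FALSE, na = "")
      write_delta_ct_matrix(recs, file.path(out_dir, "delta_ct_matrix.csv"))
      recs
    },
    "analyze" = {
      tab <- if (is.character(config$ct)) parse_ct_export(config$ct)
             else config$ct
      an <- config$analysis %||% stop("analyze: 'analysis' required")
      ref <- config$reference %||% "RNU6"
      res <- switch(an,
        time = time_course_analysis(tab, reference = ref),
        repeat_ = ,
        "repeat" = repeated_acquisition_analysis(tab, reference = ref),
        intra = intra_operator_analysis(tab),
        inter = inter_operator_analysis(tab, reference = ref),
        method = {
          ms <- unique(tab$method)
          if (length(ms) != 2) stop("method analysis needs two methods")
          method_comparison(
            inter_operator_analysis(tab[tab$method == ms[1], ],
                                    reference = ref),
            inter_operator_analysis(tab[tab$method == ms[2], ],
                                    reference = ref))
        },
        group = group_effect_check(tab, reference = ref),
        stop("unknown analysis '", an, "'"))
      out <- if (is.data.frame(res)) res
             else if (!is.null(res$per_target)) res$per_target
             else res$beta1
      utils::write.csv(out, file.path(out_dir,
                                      paste0("analysis_", an, ".csv")),
                       row.names = FALSE, na = "")
      res
    },
    "anova" = {
      tab <- if (is.character(config$ct)) parse_ct_export(config$ct)
             else config$ct
      v <- config$variant %||% 1
      variants <- anova_variants(config$threshold_mode %||% "FIXED")
      if (!v %in% seq_along(variants)) stop("anova variant must be 1..6")
      recs <- delta_ct_table(tab, reference = config$reference %||% "RNU6",
        mode = if ((config$threshold_mode %||% "FIXED") == "FIXED")
          "FIXED" else "VARIABLE_COVARIATE")
      tg <- config$target %||% unique(recs$target)[1]
      fit <- fit_variant(recs[recs$target == tg, ], variants[[v]])
      utils::write.csv(fit$coefficients,
                       file.path(out_dir, "anova_coefficients.csv"),
                       row.names = FALSE)
      fit
    },
    "power" = {
      a <- jung_alpha(config$m %||% 380, config$pi1 %||% 0.05,
                      config$fdr %||% 0.05, config$power %||% 0.8)
      eff <- detectable_effect(config$n1 %||% 10, config$n2 %||% 10,
                               alpha = a, power = config$power %||% 0.8)
      res <- data.frame(alpha_star = a, detectable_effect = eff)
      utils::write.csv(res, file.path(out_dir, "power.csv"),
                       row.names = FALSE)
      res
    })
  invisible(list(out_dir = out_dir, result = result))
}
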