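#' Amplification-curve parameters
#'
#' Parameters of the saturating-growth model used to generate single-well
#' RT-qPCR fluorescence traces. The template amount after c cycles is
#' \deqn{X(c) = xmax \cdot x0 (1+E)^c / (xmax + x0((1+E)^c - 1))}
#' which grows geometrically while \eqn{x0(1+E)^c \ll xmax} (exponential
#' phase), bends (linear phase), and saturates at \code{xmax} (plateau).
#' The recorded fluorescence adds a baseline, an optional per-cycle drift,
#' and noise.
#'
#' @param x0 initial template signal (fluorescence units), > 0.
#' @param efficiency per-cycle amplification fraction E in (0, 1];
#'   amplification factor is 1 + E (E = 1 is perfect doubling).
#' @param xmax plateau signal, > x0.
#' @param baseline additive background fluorescence.
#' @param drift additive per-cycle baseline slope.
#' @param noise_sd noise scale: multiplicative log-normal on the
#'   amplification signal (sd on the natural-log scale) plus a small
#'   additive Gaussian term of sd \code{noise_sd / 100} on the baseline.
#' @param n_cycles number of thermal cycles, >= 10 (default 40).
#' @return an object of class \code{curve_params}.
#' @export
curve_params <- function(x0, efficiency = 1, xmax = 3, baseline = 0.05,
                         drift = 0, noise_sd = 0, n_cycles = 40L) {
  if (!is.numeric(x0) || x0 <= 0) stop("invalid curve_params: x0 must be > 0")
  if (efficiency <= 0 || efficiency > 1)
    stop("invalid curve_params: efficiency must be in (0, 1]")
  if (xmax <= x0) stop("invalid curve_params: xmax must be > x0")
  if (noise_sd < 0) stop("invalid curve_params: noise_sd must be >= 0")
  if (n_cycles < 10) stop("invalid curve_params: n_cycles must be >= 10")
  structure(list(x0 = x0, efficiency = efficiency, xmax = xmax,
                 baseline = baseline, drift = drift, noise_sd = noise_sd,
                 n_cycles = as.integer(n_cycles)),
            class = "curve_params")
}

#' Closed-form noiseless amplification signal
#'
#' Evaluates the saturating-growth signal X(c) (no baseline, no noise) at
#' arbitrary, possibly fractional, cycle values.
#'
#' @param c_vals numeric cycle values.
#' @param params a \code{curve_params} object.
#' @return numeric vector of signal values.
#' @export
amplification_signal <- function(c_vals, params) {
  g <- (1 + params$efficiency)^c_vals
  params$xmax * params$x0 * g / (params$xmax + params$x0 * (g - 1))
}

#' Simulate one amplification curve
#'
#' @param params a \code{curve_params} object.
#' @param seed integer seed (per-well stream; deterministic).
#' @param well_id,sample_id,target,operator,plate optional annotations.
#' @return an \code{amplification_curve}: list with the annotations plus
#'   \code{cycle} (1..n_cycles) and \code{fluorescence}.
#' @export
simulate_curve <- function(params, seed = 1L, well_id = "w1", sample_id = NA,
                           target = NA, operator = NA, plate = NA) {
  stopifnot(inherits(params, "curve_params"))
  cyc <- seq_len(params$n_cycles)
  x <- amplification_signal(cyc, params)
  if (params$noise_sd > 0) {
    eps <- stream_norm_vec(paste0("curve:", well_id), seed,
                           2L * params$n_cycles, 1)
    x <- x * exp(eps[seq_along(cyc)] * params$noise_sd) +
      eps[params$n_cycles + cyc] * params$noise_sd / 100
  }
  f <- params$baseline + params$drift * cyc + x
  structure(list(well_id = well_id, sample_id = sample_id, target = target,
                 operator = operator, plate = plate,
                 cycle = cyc, fluorescence = f),
            class = "amplification_curve")
}

#' Simulation configuration for a study-shaped experiment
#'
#' Defines a full design: subjects (cases and controls), a target panel with
#' one endogenous reference, operators, extraction methods, timepoints, and
#' replicate wells. A well's starting signal is
#' \deqn{x_0 = \mathrm{yield} \cdot 2^{-A}}
#' where A (log2 scale, Ct-like units) sums the target's base abundance, the
#' group effect for cases, the operator shift (non-reference targets only:
#' a plate-wide shift would cancel in delta-Ct by construction of relative
#' quantification), piecewise-linear time degradation
#' \eqn{d \cdot \max(0, t - L)}, and independent Gaussian subject-, run- and
#' well-level noise on the log2 scale. Wells whose x0 falls below the
#' method's detection limit never amplify (not expressed downstream).
#'
#' @param n_cases,n_controls subject counts per group.
#' @param targets data.frame with columns \code{target},
#'   \code{group_effect} (delta-Ct units; negative = overexpressed in cases),
#'   \code{abundance_mean} (log2 scale; roughly the Ct at threshold ~0.03),
#'   \code{abundance_sd} (between-subject sd), \code{degradation}
#'   (delta-Ct per hour past the lag).
#' @param reference target id of the endogenous reference; exactly one,
#'   must appear in \code{targets}.
#' @param operators data.frame with columns \code{operator}, \code{shift}
#'   (systematic Ct shift applied to non-reference targets).
#' @param methods data.frame with columns \code{method},
#'   \code{yield_factor} (> 0), \code{detection_limit} (x0 units), and
#'   optionally \code{run_sd} (method-specific operator-run noise,
#'   overriding the global \code{run_sd}; extraction workflows differ in
#'   how much processing variability they admit).
#' @param duplicates replicate wells per combination (default 2).
#' @param timepoints_h hours from phlebotomy to plasma extraction.
#' @param lag_h degradation lag L in hours (default 12: no decay before).
#' @param run_sd operator-run noise sd (shared by the duplicates of one
#'   subject x target x operator x method x timepoint processing run).
#' @param well_sd independent per-well noise sd.
#' @param curve a \code{curve_params} giving efficiency, plateau, baseline,
#'   drift and fluorescence noise for generated traces (its \code{x0} is a
#'   placeholder, replaced per well).
#' @param seed master integer seed.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_cases, n_controls, targets, reference, operators,
                       methods, duplicates = 2L, timepoints_h = 0,
                       lag_h = 12, run_sd = 0, well_sd = 0,
                       curve = curve_params(1e-6), seed = 1L) {
  if (n_cases + n_controls < 1) stop("sim_config: zero subjects")
  if (!is.data.frame(targets) || nrow(targets) == 0)
    stop("sim_config: empty targets")
  need <- c("target", "group_effect", "abundance_mean", "abundance_sd",
            "degradation")
  miss <- setdiff(need, names(targets))
  if (length(miss)) stop("sim_config: targets lacks column(s) ",
                         paste(miss, collapse = ", "))
  if (length(reference) != 1 || !reference %in% targets$target)
    stop("sim_config: exactly one reference target, present in targets")
  if (any(targets$abundance_sd < 0) || run_sd < 0 || well_sd < 0)
    stop("sim_config: all sds must be >= 0")
  if (any(methods$yield_factor <= 0))
    stop("sim_config: yield factors must be > 0")
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 targets = targets, reference = reference,
                 operators = operators, methods = methods,
                 duplicates = as.integer(duplicates),
                 timepoints_h = timepoints_h, lag_h = lag_h,
                 run_sd = run_sd, well_sd = well_sd, curve = curve,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Study-design presets
#'
#' \code{"paper_design"} emulates a two-group plasma miRNA reproducibility
#' study: 16 colorectal advanced adenoma cases + 16 controls, a panel of 11
#' target miRNAs with RNU6 as endogenous reference, two operators, duplicate
#' wells, two extraction methods (a Trizol-like low-yield workflow with a
#' high detection limit, and a miRNeasy-like high-yield workflow), and
#' plasma-extraction timepoints 0/12/24/48/72 h with target-specific
#' degradation past a 12 h lag. Per-method-per-operator-pair analyses then
#' cover 11 targets x 32 subjects x 2 operators = 704 target-sample pairs.
#'
#' @param name preset name; currently \code{"paper_design"}.
#' @param n_repeat_subjects subject count for the repeated-acquisition
#'   sub-design (stored as attribute \code{n_repeat_subjects}; default 7).
#' @param seed master seed.
#' @return a \code{sim_config}.
#' @export
study_preset <- function(name = "paper_design", n_repeat_subjects = 7L,
                         seed = 1L) {
  if (!identical(name, "paper_design"))
    stop("unknown preset name: ", name)
  targets <- data.frame(
    target = c("miR-374", "miR-142-3p", "miR-523", "miR-374-5p", "miR-376c",
               "miR-27a", "miR-520d-5p", "miR-122", "miR-485-3p", "miR-21",
               "miR-218", "RNU6"),
    # cases overexpress (negative delta-Ct shift) the adenoma-associated
    # targets; effects in Ct units
    group_effect = c(0, 0, 0, 0, 0, 0, -2.98, -1.32, -3.35, -1.3, -0.85, 0),
    # base log2 abundance: targets offset by their typical delta-Ct level;
    # the reference sits 4 Ct lower (RNU6 is abundant, far above any
    # detection limit), which shifts all delta-Ct levels by a constant
    abundance_mean = 28 + c(-1.8, -7.16, -3.21, -3.27, -0.04, -6.12, 5.54,
                            -2.69, -2.6, -7.59, -3.73, -4),
    abundance_sd = rep(1.5, 12),
    # delta-Ct per hour past the 12 h lag (plasma storage degradation)
    degradation = c(0, 0, 0.038, 0, 0, 0, 0, 0.099, 0.037, 0.023, 0.043, 0),
    stringsAsFactors = FALSE
  )
  cfg <- sim_config(
    n_cases = 16L, n_controls = 16L, targets = targets, reference = "RNU6",
    operators = data.frame(operator = c("op1", "op2"), shift = c(0, 0.25),
                           stringsAsFactors = FALSE),
    methods = data.frame(method = c("trizol_like", "mirneasy_like"),
                         yield_factor = c(0.25, 1),
                         detection_limit = c(2^-30.3, 2^-37),
                         run_sd = c(1.05, 0.6),
                         stringsAsFactors = FALSE),
    duplicates = 2L, timepoints_h = c(0, 12, 24, 48, 72), lag_h = 12,
    run_sd = 0.6, well_sd = 0.5,
    curve = curve_params(1e-6, efficiency = 1, xmax = 3, baseline = 0.05,
                         drift = 0, noise_sd = 0.03),
    seed = seed
  )
  attr(cfg, "n_repeat_subjects") <- as.integer(n_repeat_subjects)
  cfg
}

#' @keywords internal
#' Per-well design table with derived x0 and every injected effect (the
#' truth table).
build_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  subjects <- data.frame(
    sample = sprintf("S%02d", seq_len(config$n_cases + config$n_controls)),
    group = rep(c("case", "control"),
                c(config$n_cases, config$n_controls)),
    stringsAsFactors = FALSE)
  d <- expand.grid(sample = subjects$sample,
                   target = config$targets$target,
                   operator = config$operators$operator,
                   method = config$methods$method,
                   timepoint_h = config$timepoints_h,
                   replicate = seq_len(config$duplicates),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$group <- subjects$group[match(d$sample, subjects$sample)]
  ti <- match(d$target, config$targets$target)
  d$abundance <- config$targets$abundance_mean[ti]
  d$group_shift <- ifelse(d$group == "case",
                          config$targets$group_effect[ti], 0)
  op_shift <- config$operators$shift[match(d$operator,
                                           config$operators$operator)]
  d$operator_shift <- ifelse(d$target == config$reference, 0, op_shift)
  d$degradation_shift <- config$targets$degradation[ti] *
    pmax(0, d$timepoint_h - config$lag_h)
  # subject noise: one draw per subject x target, scaled by that target's sd
  key_st <- paste("subj", d$sample, d$target)
  ust <- !duplicated(key_st)
  draws <- stream_norm(key_st[ust], config$seed, 1)
  d$subject_noise <- draws[match(key_st, key_st[ust])] *
    config$targets$abundance_sd[ti]
  run_sd_m <- if ("run_sd" %in% names(config$methods))
    config$methods$run_sd else rep(config$run_sd, nrow(config$methods))
  key_run <- paste("run", d$sample, d$target, d$operator, d$method,
                   d$timepoint_h)
  if (all(run_sd_m == 0)) {
    d$run_noise <- 0
  } else {
    urun <- !duplicated(key_run)
    rdraws <- stream_norm(key_run[urun], config$seed, 1)
    d$run_noise <- rdraws[match(key_run, key_run[urun])] *
      run_sd_m[match(d$method, config$methods$method)]
  }
  d$well_noise <- stream_norm(paste("well", d$sample, d$target, d$operator,
                                    d$method, d$timepoint_h, d$replicate),
                              config$seed, config$well_sd)
  mi <- match(d$method, config$methods$method)
  a_total <- d$abundance + d$group_shift + d$operator_shift +
    d$degradation_shift + d$subject_noise + d$run_noise + d$well_noise
  d$x0 <- config$methods$yield_factor[mi] * 2^(-a_total)
  d$expressed_expected <- d$x0 >= config$methods$detection_limit[mi]
  d$well_id <- sprintf("W%05d", seq_len(nrow(d)))
  d$plate <- paste(d$operator, d$method, d$timepoint_h, sep = "_")
  d
}

#' Simulate a complete experiment
#'
#' Generates one amplification curve per subject x target x operator x
#' method x timepoint x replicate, plus a truth table recording every
#' injected effect and each well's derived starting signal. Deterministic:
#' the same \code{sim_config} (including its seed) always produces
#' byte-identical output, and per-well RNG streams are keyed by the design
#' coordinates so subsetting a design does not shift other wells' draws.
#'
#' @param config a \code{sim_config}.
#' @return list with \code{curves} (long data.frame: well_id, sample_id,
#'   group, target, operator, method, timepoint_h, replicate, plate, cycle,
#'   fluorescence) and \code{truth} (per-well data.frame).
#' @export
simulate_experiment <- function(config) {
  truth <- build_truth(config)
  p <- config$curve
  n_cyc <- p$n_cycles
  cyc <- seq_len(n_cyc)
  g <- (1 + p$efficiency)^cyc
  # signal matrix: wells x cycles, closed form; non-amplifying wells
  # (below detection limit) stay at zero signal
  x0 <- ifelse(truth$expressed_expected, truth$x0, 0)
  xmat <- outer(x0, g) * p$xmax /
    (p$xmax + outer(x0, g - 1))
  if (p$noise_sd > 0) {
    for (i in seq_len(nrow(truth))) {
      eps <- stream_norm_vec(paste0("curve:", truth$well_id[i]),
                             config$seed, 2L * n_cyc, 1)
      xmat[i, ] <- xmat[i, ] * exp(eps[cyc] * p$noise_sd) +
        eps[n_cyc + cyc] * p$noise_sd / 100
    }
  }
  fmat <- p$baseline + outer(rep(1, nrow(truth)), p$drift * cyc) + xmat
  curves <- data.frame(
    well_id = rep(truth$well_id, each = n_cyc),
    sample_id = rep(truth$sample, each = n_cyc),
    group = rep(truth$group, each = n_cyc),
    target = rep(truth$target, each = n_cyc),
    operator = rep(truth$operator, each = n_cyc),
    method = rep(truth$method, each = n_cyc),
    timepoint_h = rep(truth$timepoint_h, each = n_cyc),
    replicate = rep(truth$replicate, each = n_cyc),
    plate = rep(truth$plate, each = n_cyc),
    cycle = rep(cyc, nrow(truth)),
    fluorescence = as.vector(t(fmat)),
    stringsAsFactors = FALSE)
  list(curves = curves, truth = truth)
}

#' Simulate a Ct table directly (noiseless-curve limit)
#'
#' Fast path for simulation studies: computes each well's Ct analytically
#' from its starting signal under a fixed threshold, bypassing trace
#' generation and Ct calling. In the exponential phase
#' \eqn{Ct = \log(T/x_0)/\log(1+E)}; wells below the detection limit or
#' crossing after the last cycle are not expressed. Identical well-level
#' noise model (and RNG streams) as \code{\link{simulate_experiment}};
#' fluorescence noise is absent, so this is the zero-curve-noise limit of
#' the full pipeline.
#'
#' @param config a \code{sim_config}.
#' @param threshold fixed threshold intensity (default 0.03).
#' @return list with \code{ct} (Ct-export data.frame: sample, group, target,
#'   operator, method, timepoint_h, replicate, ct, threshold, mode) and
#'   \code{truth}.
#' @export
simulate_ct_table <- function(config, threshold = 0.03) {
  truth <- build_truth(config)
  e <- config$curve$efficiency
  ct <- (log2(threshold) - log2(truth$x0)) / log2(1 + e)
  expressed <- truth$expressed_expected & ct <= config$curve$n_cycles &
    ct >= 1
  tab <- data.frame(sample = truth$sample, group = truth$group,
                    target = truth$target, operator = truth$operator,
                    method = truth$method, timepoint_h = truth$timepoint_h,
                    replicate = truth$replicate,
                    ct = ifelse(expressed, ct, NA_real_),
                    threshold = threshold, mode = "FIXED",
                    stringsAsFactors = FALSE)
  list(ct = tab, truth = truth)
}
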