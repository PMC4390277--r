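# Small design fixtures, built in code.

# Ideal doubling curve: deep exponential regime, saturation negligible.
ideal_curve <- function(x0 = 0.001, efficiency = 1, xmax = 1e9,
                        n_cycles = 40L) {
  simulate_curve(curve_params(x0, efficiency = efficiency, xmax = xmax,
                              baseline = 0, drift = 0, noise_sd = 0,
                              n_cycles = n_cycles))
}

# Three-target (one reference) two-group config for fast Ct-level studies.
small_config <- function(seed, shift = 0, group_effect = c(-1.3, 0),
                         subj_sd = 1.5, run_sd = 1.05, well_sd = 0.5,
                         duplicates = 1L, n = 16L, degradation = c(0, 0, 0),
                         timepoints_h = 0) {
  tg <- data.frame(target = c("tA", "tB", "REF"),
                   group_effect = c(group_effect, 0),
                   abundance_mean = c(27, 25, 23),
                   abundance_sd = rep(subj_sd, 3),
                   degradation = degradation,
                   stringsAsFactors = FALSE)
  sim_config(n, n, tg, "REF",
             data.frame(operator = c("op1", "op2"), shift = c(0, shift),
                        stringsAsFactors = FALSE),
             data.frame(method = "m", yield_factor = 1,
                        detection_limit = 2^-40,
                        stringsAsFactors = FALSE),
             duplicates = duplicates, timepoints_h = timepoints_h,
             lag_h = 12, run_sd = run_sd, well_sd = well_sd, seed = seed)
}

# Mean delta-delta-Ct (op1 - op2) of one target from a Ct table.
mean_op_ddct <- function(ct_table, target, reference = "REF") {
  r <- delta_ct_table(ct_table, reference = reference)
  r <- r[r$target == target, ]
  a <- r[r$operator == "op1", ]
  b <- r[r$operator == "op2", ]
  d <- a$delta_ct - b$delta_ct[match(a$sample, b$sample)]
  mean(d, na.rm = TRUE)
}
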