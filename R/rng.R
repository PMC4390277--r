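#' @keywords internal
#' Stable 32-bit string hash (polynomial, mod 2^31 - 1).
#' Used to derive independent per-well RNG streams from one master seed so
#' that subsetting a design never shifts the draws of the remaining wells.
str_hash <- function(x) {
  vapply(x, function(s) {
    b <- utf8ToInt(s)
    h <- 17
    for (v in b) h <- (h * 31 + v) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

#' @keywords internal
#' Derive a per-key seed below 2^31 from the master seed. The extra
#' multiplicative mixing rounds map near-identical keys (e.g. replicate 1
#' vs 2 of one well) to distant seeds: first draws from adjacent
#' set.seed() values are measurably correlated.
derive_seed <- function(master_seed, key) {
  m <- 2147483647
  h <- (as.numeric(master_seed) %% m * 48271 + str_hash(key)) %% m
  # multipliers kept below 2^22 so products stay exact in doubles
  h <- (h * 69621 + 12345) %% m
  h <- (h * 48271 + 54321) %% m
  h %% 2147483646 + 1
}

#' @keywords internal
#' One N(0, sd) draw per key, each from its own derived stream.
#' Restores the caller's RNG state.
stream_norm <- function(keys, master_seed, sd) {
  if (sd == 0) return(numeric(length(keys)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  seeds <- derive_seed(master_seed, keys)
  vapply(seeds, function(s) { set.seed(s); stats::rnorm(1, 0, sd) }, numeric(1))
}

#' @keywords internal
#' A vector of n N(0, sd) draws from the stream keyed by `key`.
stream_norm_vec <- function(key, master_seed, n, sd) {
  if (sd == 0) return(numeric(n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(master_seed, key))
  stats::rnorm(n, 0, sd)
}
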