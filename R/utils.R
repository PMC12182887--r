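# Internal helpers shared across modules.

# population standard deviation (divisor n, not n-1); the per-condition
# "mean +/- std" summaries and histogram bands use this flavor
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

# significance stars at the conventional thresholds
p_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "n.s."
  )
}

# derive a child seed from a root seed; keeps results reproducible while
# giving each stochastic step its own stream. Stays well below 2^31.
child_seed <- function(seed, step) {
  (as.integer(seed) * 7919L + as.integer(step)) %% 2147483029L
}

has_z <- function(tbl) {
  "z" %in% names(tbl) && !all(is.na(tbl$z))
}

check_positions <- function(positions, arg = "positions") {
  if (!is.data.frame(positions)) {
    abort(sprintf("`%s` must be a data frame of positions", arg))
  }
  for (col in c("x", "y")) {
    if (!col %in% names(positions)) {
      abort(sprintf("`%s` is missing required column '%s'", arg, col))
    }
  }
  invisible(positions)
}

zero_or <- function(tbl, col) {
  if (col %in% names(tbl)) tbl[[col]] else rep(0, nrow(tbl))
}
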