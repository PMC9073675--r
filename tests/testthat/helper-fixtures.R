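# Build a single-line replicate-outcome table from a vector of sterile
# generations (NA = censored at the horizon).
make_line <- function(gens, line_id = "L1", failure_mode = NULL) {
  cens <- is.na(gens)
  df <- data.frame(
    line_id = rep(line_id, length.out = length(gens)),
    replicate_id = seq_along(gens),
    sterile_generation = as.numeric(gens),
    censored = as.integer(cens),
    stringsAsFactors = FALSE
  )
  if (!is.null(failure_mode)) df$failure_mode <- failure_mode
  df
}

# Replicate-level table with arbitrary failure times for the distribution
# comparison tests; one pseudo-line, n replicates.
make_failure_tab <- function(gens, horizon = 21) {
  tab <- make_line(gens)
  attr(tab, "horizon") <- horizon
  tab
}

# Severity rank of a class on the Mrt kinetics ordering, with ts_sterile
# above strong (it can only be reached by strengthening every replicate to
# generation 1).
class_rank <- function(cl) {
  c(wild_type = 0, weak = 1, moderate = 2, strong = 3, ts_sterile = 4)[cl]
}
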