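#' @title Mrt phenotype classes
#' @description Class labels used throughout the package, ordered from most
#'   to least severe for the Mrt kinetics proper. `ts_sterile`
#'   (temperature-sensitive sterility, all replicates sterile in the first
#'   generation at the restrictive temperature) and `excluded_low_fitness`
#'   (failures not of the Mrt-sterile type) sit outside that ordering.
#' @format Character vector of the six class labels.
#' @export
mrt_classes <- c("ts_sterile", "excluded_low_fitness", "strong",
                 "moderate", "weak", "wild_type")

# Validate a replicate-outcome table and normalise column types.
# Required columns: line_id, replicate_id, sterile_generation, censored.
# failure_mode is optional and defaults to mrt_sterile/none.
validate_assay_table <- function(x, horizon) {
  need <- c("line_id", "replicate_id", "sterile_generation", "censored")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("assay table is missing column(s): ", paste(miss, collapse = ", "))
  }
  x$censored <- as.logical(x$censored)
  if (anyNA(x$censored)) stop("censored must be 0/1 or logical")
  x$sterile_generation <- suppressWarnings(as.numeric(x$sterile_generation))
  if (is.null(x$failure_mode)) {
    x$failure_mode <- ifelse(x$censored, "none", "mrt_sterile")
  }
  bad_mode <- !x$failure_mode %in% c("mrt_sterile", "non_mrt_failure", "none")
  if (any(bad_mode)) {
    stop("failure_mode must be one of mrt_sterile, non_mrt_failure, none")
  }
  if (any(x$censored & !is.na(x$sterile_generation))) {
    stop("censored replicates must have no sterile_generation")
  }
  if (any(!x$censored & is.na(x$sterile_generation))) {
    stop("non-censored replicates must record a sterile_generation")
  }
  g <- x$sterile_generation[!x$censored]
  if (length(g)) {
    if (any(g < 1 | g != round(g))) {
      stop("sterile_generation must be an integer generation >= 1")
    }
    if (any(g > horizon)) {
      stop("sterile_generation exceeds the assay horizon (", horizon, ")")
    }
  }
  key <- paste(x$line_id, x$replicate_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate line_id x replicate_id keys in assay table")
  }
  x
}

resolve_horizon <- function(x, horizon) {
  horizon <- horizon %||% attr(x, "horizon")
  if (is.null(horizon)) {
    stop("horizon not given and not recorded on the table; pass horizon=")
  }
  stopifnot(is_count(horizon))
  horizon
}

#' Mean time to sterility of a line
#'
#' Mean generation-at-sterility over the replicates of one line that
#' actually went sterile with the Mrt-type phenotype. Censored replicates
#' (still fertile at the assay horizon) and replicates annotated
#' `non_mrt_failure` (low-fitness failures unrelated to Mrt) are excluded
#' from the mean and reported as counts alongside.
#'
#' @param line Data frame of replicate outcomes for a single line (columns
#'   `line_id`, `replicate_id`, `sterile_generation`, `censored`, and
#'   optionally `failure_mode`).
#' @param horizon Assay length in generations (21 for the N2 and
#'   wild-isolate designs, 14 for PB306); defaults to the table's
#'   `"horizon"` attribute.
#' @return List with `mean` (NA if no replicate went sterile), `n_sterile`,
#'   `n_censored`, `n_excluded`.
#' @examples
#' line <- data.frame(line_id = "L1", replicate_id = 1:3,
#'                    sterile_generation = c(12, 15, NA),
#'                    censored = c(0, 0, 1))
#' mean_time_to_sterility(line, horizon = 21)  # mean 13.5
#' @export
mean_time_to_sterility <- function(line, horizon = NULL) {
  if (NROW(line) == 0) stop("line has no replicate outcomes")
  horizon <- resolve_horizon(line, horizon)
  line <- validate_assay_table(as.data.frame(line), horizon)
  if (length(unique(line$line_id)) != 1L) {
    stop("mean_time_to_sterility expects outcomes from a single line")
  }
  excluded <- line$failure_mode == "non_mrt_failure"
  sterile <- !excluded & !line$censored
  censored <- !excluded & line$censored
  m <- if (any(sterile)) mean(line$sterile_generation[sterile]) else NA_real_
  list(mean = m, n_sterile = sum(sterile), n_censored = sum(censored),
       n_excluded = sum(excluded))
}

# Vectorised classification core: per-line summary statistics and class
# assignment for an already-validated table.
classify_core <- function(x, horizon) {
  f <- factor(x$line_id, levels = unique(x$line_id))
  excluded <- x$failure_mode == "non_mrt_failure"
  relevant <- !excluded
  sterile <- relevant & !x$censored
  censored_rel <- relevant & x$censored

  ones <- rep(1L, nrow(x))
  n_reps <- as.vector(rowsum(ones, f))
  n_excl <- as.vector(rowsum(excluded + 0L, f))
  n_rel <- n_reps - n_excl
  n_ster <- as.vector(rowsum(sterile + 0L, f))
  n_cens <- as.vector(rowsum(censored_rel + 0L, f))

  g <- ifelse(sterile, x$sterile_generation, 0)
  sum_t <- as.vector(rowsum(g, f))
  mean_t <- ifelse(n_ster > 0, sum_t / n_ster, NA_real_)
  max_t <- as.vector(tapply(ifelse(sterile, x$sterile_generation, -Inf),
                            f, max))
  max_t[n_ster == 0] <- NA_real_

  # generation-21 bookkeeping (only meaningful when horizon >= 21)
  ster21 <- sterile & !is.na(x$sterile_generation) &
    x$sterile_generation <= 21
  fert21 <- relevant & (x$censored |
                          (!is.na(x$sterile_generation) &
                             x$sterile_generation > 21))
  n_ster21 <- as.vector(rowsum(ster21 + 0L, f))
  n_fert21 <- as.vector(rowsum(fert21 + 0L, f))

  mean_safe <- ifelse(is.na(mean_t), Inf, mean_t)
  max_safe <- ifelse(is.na(max_t), Inf, max_t)

  cls <- rep("wild_type", length(n_reps))
  if (horizon >= 21) {
    # weak: at least 2/3 of relevant replicates sterile by generation 21
    weak <- n_rel > 0 & 3 * n_ster21 >= 2 * n_rel
    cls[weak] <- "weak"
    # moderate: mean < 16 and no replicate still fertile at generation 21
    moderate <- n_rel > 0 & n_fert21 == 0 & mean_safe < 16
    cls[moderate] <- "moderate"
  }
  # strong: every relevant replicate sterile (a censored replicate's time
  # to sterility exceeds the horizon, hence >= 15), mean < 10, max < 15
  strong <- n_rel > 0 & n_cens == 0 & n_ster > 0 &
    mean_safe < 10 & max_safe < 15
  cls[strong] <- "strong"
  # low-fitness exclusion: strict majority of replicates annotated as
  # non-Mrt failures
  cls[2 * n_excl > n_reps] <- "excluded_low_fitness"
  # ts-sterile: every relevant replicate sterile in the first generation
  ts <- n_rel > 0 & n_cens == 0 & n_ster == n_rel & max_safe <= 1
  cls[ts] <- "ts_sterile"

  data.frame(
    line_id = levels(f),
    class = factor(cls, levels = mrt_classes),
    n_reps = n_reps, n_sterile = n_ster, n_censored = n_cens,
    n_excluded = n_excl,
    mean_tts = mean_t, max_tts = max_t,
    stringsAsFactors = FALSE
  )
}

#' Classify one assay line into an Mrt phenotype class
#'
#' Applies the threshold criteria for the heat-sensitive mortal-germline
#' phenotype to one line's replicate outcomes:
#' \describe{
#'   \item{ts_sterile}{all replicates sterile after the first generation at
#'     the restrictive temperature (a temperature-sensitive sterile
#'     mutation, distinct from Mrt kinetics);}
#'   \item{excluded_low_fitness}{a strict majority of replicates annotated
#'     `non_mrt_failure` (generalised low fitness rather than Mrt);}
#'   \item{strong}{mean time to sterility < 10 generations and maximum
#'     time to sterility < 15 (which requires every replicate to have gone
#'     sterile);}
#'   \item{moderate}{mean time to sterility < 16 and no replicate still
#'     fertile at generation 21;}
#'   \item{weak}{at least 2/3 of replicates sterile by generation 21;}
#'   \item{wild_type}{everything else (in particular, at least 2/3 of
#'     replicates fertile at generation 21).}
#' }
#' Classes are tested in the order listed; the first match wins. Replicates
#' annotated `non_mrt_failure` are ignored by the timing criteria. For
#' assays shorter than 21 generations (e.g. the 14-generation PB306 block)
#' the moderate and weak classes are undefined — such lines can only be
#' called `ts_sterile`, `strong`, or `wild_type`, and the result carries a
#' `caveat` attribute saying so.
#'
#' @inheritParams mean_time_to_sterility
#' @return Character scalar, one of [mrt_classes]. Per-line diagnostics
#'   (mean/max time to sterility, replicate counts) are available from
#'   [classify_table()].
#' @examples
#' l578 <- data.frame(line_id = "578", replicate_id = 1:10,
#'                    sterile_generation = c(4, 5, 5, 6, 6, 6, 7, 7, 8, 10),
#'                    censored = 0)
#' classify_line(l578, horizon = 21)  # "strong"
#' @export
classify_line <- function(line, horizon = NULL) {
  res <- classify_table(line, horizon)
  if (nrow(res) != 1L) stop("classify_line expects a single line")
  as.character(res$class[1])
}

#' Classify every line of an assay table
#'
#' Groups a replicate-outcome table by `line_id`, applies the
#' [classify_line()] criteria to each line, and tallies class counts.
#'
#' @param x Replicate-outcome table (one row per line x replicate), e.g.
#'   from [generate_assay_table()] or [read_assay_table()].
#' @inheritParams mean_time_to_sterility
#' @return Object of class `"mrt_classification"`: a data frame with one
#'   row per line (`line_id`, `class`, replicate counts, `mean_tts`,
#'   `max_tts`) plus attributes `counts` (named class tally), `horizon`,
#'   and possibly `caveat`. `summary()` returns the tally.
#' @examples
#' cfg <- synthetic_config(wild_isolate_design(),
#'                         mixture = c(strong = 0.1, wild_type = 0.9),
#'                         seed = 1)
#' cls <- classify_table(generate_assay_table(cfg))
#' summary(cls)
#' @export
classify_table <- function(x, horizon = NULL) {
  x <- as.data.frame(x)
  horizon <- resolve_horizon(x, horizon)
  if (nrow(x) == 0) {
    out <- data.frame(line_id = character(), class = factor(character(),
                                                            levels = mrt_classes),
                      n_reps = integer(), n_sterile = integer(),
                      n_censored = integer(), n_excluded = integer(),
                      mean_tts = numeric(), max_tts = numeric())
    attr(out, "counts") <- table(factor(character(), levels = mrt_classes))
    attr(out, "horizon") <- horizon
    class(out) <- c("mrt_classification", "data.frame")
    return(out)
  }
  x <- validate_assay_table(x, horizon)
  out <- classify_core(x, horizon)
  attr(out, "counts") <- table(out$class)
  attr(out, "horizon") <- horizon
  if (horizon < 21) {
    attr(out, "caveat") <- paste0(
      "horizon ", horizon, " < 21: moderate and weak classes are undefined ",
      "(they require generation-21 information); lines can only be ",
      "ts_sterile, strong, or wild_type")
  }
  class(out) <- c("mrt_classification", "data.frame")
  out
}

#' @export
summary.mrt_classification <- function(object, ...) {
  attr(object, "counts")
}

#' @export
print.mrt_classification <- function(x, ...) {
  cat("Mrt classification of", nrow(x), "line(s) at horizon",
      attr(x, "horizon"), "generations\n")
  tab <- attr(x, "counts")
  tab <- tab[tab > 0 | names(tab) == "wild_type"]
  print(tab)
  caveat <- attr(x, "caveat")
  if (!is.null(caveat)) cat("Note:", caveat, "\n")
  invisible(x)
}

# Two-sample Kolmogorov-Smirnov distance for possibly tied samples,
# evaluated on the pooled order statistics.
ks_distance <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  all <- c(x, y)
  o <- order(all)
  z <- c(rep(1 / n1, n1), rep(-1 / n2, n2))[o]
  cs <- cumsum(z)
  v <- all[o]
  last_of_value <- c(v[-1] != v[-length(v)], TRUE)
  max(abs(cs[last_of_value]))
}

#' Compare time-to-failure distributions of two assay tables
#'
#' Replicate-level comparison of the distribution of generation-at-failure
#' between two assay tables (e.g. MA lines vs ancestral pseudolines), the
#' question underlying the observation that MA lines without an Mrt
#' mutation fail no differently from their unmutated ancestors. Censored
#' replicates are assigned the horizon value, so the statistic compares the
#' full (censoring-aware) failure profiles. The statistic is the
#' Kolmogorov-Smirnov distance between the two empirical distributions;
#' because the data are heavily tied integer generations, the null
#' distribution is obtained by permuting table labels over replicates
#' rather than from the asymptotic KS formula.
#'
#' @param ma_table,ps_table Replicate-outcome tables to compare.
#' @param horizon Assay length; defaults to the tables' common `"horizon"`
#'   attribute.
#' @param n_permutations Number of label permutations (>= 1).
#' @param seed Optional RNG seed for the permutations.
#' @return An object of class `"htest"` with the KS `statistic` and the
#'   permutation `p.value` (computed with +1 smoothing, so never exactly 0).
#' @examples
#' cfg <- synthetic_config(assay_design(20, 10, 21, "ps"),
#'                         mixture = c(wild_type = 1), seed = 2)
#' a <- generate_assay_table(cfg)
#' compare_time_to_failure(a, a, n_permutations = 99)  # D = 0, p = 1
#' @export
compare_time_to_failure <- function(ma_table, ps_table, horizon = NULL,
                                    n_permutations = 999, seed = NULL) {
  if (NROW(ma_table) == 0 || NROW(ps_table) == 0) {
    stop("both tables must be non-empty")
  }
  if (!is_count(n_permutations)) {
    stop("n_permutations must be a positive integer")
  }
  h1 <- resolve_horizon(as.data.frame(ma_table), horizon)
  h2 <- resolve_horizon(as.data.frame(ps_table), horizon)
  ma <- validate_assay_table(as.data.frame(ma_table), h1)
  ps <- validate_assay_table(as.data.frame(ps_table), h2)
  tx <- ifelse(ma$censored, h1, ma$sterile_generation)
  ty <- ifelse(ps$censored, h2, ps$sterile_generation)
  n1 <- length(tx)
  n2 <- length(ty)
  obs <- ks_distance(tx, ty)

  # permute labels over the pooled, pre-sorted replicates; each permutation
  # is O(n) given the fixed sort order
  pooled <- sort(c(tx, ty))
  n <- n1 + n2
  last_of_value <- c(pooled[-1] != pooled[-n], TRUE)
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      z <- rep(-1 / n2, n)
      z[sample.int(n, n1)] <- 1 / n1
      max(abs(cumsum(z)[last_of_value]))
    }, numeric(1))
  })
  p <- (1 + sum(perm_stats >= obs - 1e-12)) / (n_permutations + 1)
  structure(list(
    statistic = c(D = obs),
    p.value = p,
    alternative = "two-sided (distributions differ)",
    method = paste0("Two-sample Kolmogorov-Smirnov permutation test (",
                    n_permutations, " permutations)"),
    data.name = sprintf("%d vs %d replicate failure times (censored at horizon)",
                        n1, n2)
  ), class = "htest")
}
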