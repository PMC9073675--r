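#' Assay design description
#'
#' Dimensions of a mortal-germline assay: how many lines, how many
#' replicates per line, and the censoring horizon (the generation at which
#' still-fertile replicates are scored as censored).
#'
#' @param n_lines Number of lines (>= 1).
#' @param reps_per_line Replicates initiated per line (>= 1).
#' @param assay_generations Assay length in generations (the censoring
#'   horizon; 21 for the N2 and wild-isolate blocks, 14 for PB306).
#' @param label Free-text label for the design.
#' @return Object of class `"assay_design"`.
#' @seealso Preset study designs: [ma_design_n2()], [ma_design_pb306()],
#'   [pseudoline_design()], [wild_isolate_design()].
#' @examples
#' assay_design(34, 10, 21, "N2 MA block")
#' @export
assay_design <- function(n_lines, reps_per_line, assay_generations,
                         label = "assay") {
  stopifnot(is_count(n_lines), is_count(reps_per_line),
            is_count(assay_generations))
  structure(list(n_lines = as.integer(n_lines),
                 reps_per_line = as.integer(reps_per_line),
                 assay_generations = as.integer(assay_generations),
                 label = as.character(label)),
            class = "assay_design")
}

#' @export
print.assay_design <- function(x, ...) {
  cat(sprintf("Assay design '%s': %d lines x %d replicates, horizon %d generations\n",
              x$label, x$n_lines, x$reps_per_line, x$assay_generations))
  invisible(x)
}

#' @rdname assay_design
#' @details The preset constructors encode the study designs: 34 N2 MA
#'   lines x 10 replicates over 21 generations; 33 PB306 MA lines x 10
#'   replicates over 14 generations; 18 ancestral pseudolines x 10
#'   replicates; 95 wild isolates x 3 replicates over 21 generations.
#' @export
ma_design_n2 <- function() assay_design(34, 10, 21, "N2 MA")

#' @rdname assay_design
#' @export
ma_design_pb306 <- function() assay_design(33, 10, 14, "PB306 MA")

#' @rdname assay_design
#' @param horizon Assay length for the pseudoline block (21 for the N2
#'   ancestor, 14 for PB306).
#' @export
pseudoline_design <- function(horizon = 21) {
  assay_design(18, 10, horizon, "ancestral pseudolines")
}

#' @rdname assay_design
#' @export
wild_isolate_design <- function() assay_design(95, 3, 21, "wild isolates")

#' Per-class sterility model for the synthetic generator
#'
#' Each phenotype class is given (i) a per-replicate probability of going
#' sterile before the assay horizon and (ii) a distribution for the
#' generation at sterility: a negative binomial (mean `mu`, dispersion
#' `size`) discretised and truncated to a class support window intersected
#' with `[1, horizon]`, or a point mass (`family = "point"`, for the
#' ts-sterile class whose replicates are all sterile at generation 1).
#' Replicates that do not go sterile are right-censored at the horizon.
#' The `low_fitness` class emits failure mode `non_mrt_failure` for its
#' failed replicates; all other failures are `mrt_sterile`.
#'
#' The defaults are chosen so that lines generated from a class satisfy
#' that class's threshold definition: the support windows make the class
#' criteria hold by construction wherever possible (a strong draw in
#' \[2, 9\] forces mean < 10 and max < 15; a moderate draw in \[10, 21\]
#' can never masquerade as strong; a weak draw in \[16, 21\] can never be
#' moderate). The study reports only the classification thresholds, not
#' the generative law, so these are modelling conventions, not estimates.
#'
#' @param ... Named per-class overrides; each value a list with any of
#'   `family` ("nbinom" or "point"), `mu`, `size`, `support` (length-2
#'   integer window), `p_sterile`, `at` (point-mass location).
#' @return Named list of class specifications (class
#'   `"sterility_model"`).
#' @examples
#' m <- sterility_model(strong = list(mu = 5))
#' m$strong$mu
#' @export
sterility_model <- function(...) {
  defaults <- list(
    strong = list(family = "nbinom", mu = 6, size = 50,
                  support = c(2, 9), p_sterile = 1),
    moderate = list(family = "nbinom", mu = 13, size = 60,
                    support = c(10, 21), p_sterile = 1),
    weak = list(family = "nbinom", mu = 18, size = 30,
                support = c(16, 21), p_sterile = 0.95),
    wild_type = list(family = "nbinom", mu = 15, size = 10,
                     support = c(2, 21), p_sterile = 10 / 180),
    ts_sterile = list(family = "point", at = 1, p_sterile = 1),
    low_fitness = list(family = "nbinom", mu = 5, size = 10,
                       support = c(1, 14), p_sterile = 0.9)
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad)) stop("unknown sterility class(es): ",
                          paste(bad, collapse = ", "))
    for (cl in names(over)) {
      defaults[[cl]][names(over[[cl]])] <- over[[cl]]
    }
  }
  for (cl in names(defaults)) {
    sp <- defaults[[cl]]
    if (!is_prob(sp$p_sterile)) stop("p_sterile must be in [0,1] for ", cl)
  }
  structure(defaults, class = "sterility_model")
}

# Draw n generation-at-sterility values (NA = censored) for one class spec.
draw_sterility <- function(spec, n, horizon) {
  sterile <- stats::runif(n) < spec$p_sterile
  gens <- rep(NA_real_, n)
  k <- sum(sterile)
  if (k > 0) {
    if (spec$family == "point") {
      gens[sterile] <- min(spec$at, horizon)
    } else {
      hi <- min(spec$support[2], horizon)
      lo <- min(spec$support[1], hi)
      p_lo <- if (lo > 0) stats::pnbinom(lo - 1, mu = spec$mu,
                                         size = spec$size) else 0
      p_hi <- stats::pnbinom(hi, mu = spec$mu, size = spec$size)
      u <- stats::runif(k, p_lo, p_hi)
      g <- stats::qnbinom(u, mu = spec$mu, size = spec$size)
      gens[sterile] <- pmin(pmax(g, lo), hi)
    }
  }
  gens
}

#' Configuration for the synthetic assay generator
#'
#' Bundles an [assay_design()], a class mixture (proportion of lines in
#' each phenotype class), a [sterility_model()], and a seed.
#'
#' @param design An [assay_design()].
#' @param mixture Named numeric vector of per-class line proportions; names
#'   must be classes of the model; must sum to 1.
#' @param model A [sterility_model()]; defaults to `sterility_model()`.
#' @param seed Integer seed; if `NULL`, one is drawn when the table is
#'   generated and recorded on the output.
#' @return Object of class `"mrt_synth_config"`.
#' @examples
#' synthetic_config(wild_isolate_design(),
#'                  mixture = c(strong = 6, moderate = 10, weak = 13,
#'                              wild_type = 66) / 95, seed = 42)
#' @export
synthetic_config <- function(design, mixture, model = sterility_model(),
                             seed = NULL) {
  stopifnot(inherits(design, "assay_design"),
            inherits(model, "sterility_model"))
  if (is.null(names(mixture)) || any(names(mixture) == "")) {
    stop("mixture must be a fully named numeric vector")
  }
  bad <- setdiff(names(mixture), names(model))
  if (length(bad)) {
    stop("mixture names not in the sterility model: ",
         paste(bad, collapse = ", "))
  }
  if (any(mixture < 0) || abs(sum(mixture) - 1) > 1e-8) {
    stop("mixture proportions must be non-negative and sum to 1")
  }
  structure(list(design = design, mixture = mixture, model = model,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "mrt_synth_config")
}

#' Generate a synthetic replicate-outcome assay table
#'
#' Emulates the raw survival tables of a mortal-germline assay: each line
#' is assigned a true phenotype class from the configured mixture, then
#' each of its replicates draws a generation-at-sterility (or censoring at
#' the horizon) from that class's sterility model. A single base seed is
#' expanded into one substream per line, so enlarging the design appends
#' lines without perturbing existing ones.
#'
#' @param config An [`synthetic_config()`] object.
#' @return Data frame with columns `line_id`, `replicate_id`,
#'   `sterile_generation` (NA when censored), `censored` (0/1),
#'   `failure_mode` (`mrt_sterile`/`non_mrt_failure`/`none`); attributes
#'   `horizon`, `design`, `seed`, and `true_class` (named by line).
#' @examples
#' cfg <- synthetic_config(assay_design(5, 3, 21),
#'                         mixture = c(wild_type = 1), seed = 1)
#' generate_assay_table(cfg)
#' @export
generate_assay_table <- function(config) {
  stopifnot(inherits(config, "mrt_synth_config"))
  seed <- config$seed %||% draw_seed()
  d <- config$design
  n <- d$n_lines
  r <- d$reps_per_line
  h <- d$assay_generations
  classes <- names(config$mixture)

  line_id <- sprintf("L%04d", seq_len(n))
  true_class <- character(n)
  gens <- matrix(NA_real_, nrow = r, ncol = n)
  for (i in seq_len(n)) {
    with_seed(substream_seed(seed, i), {
      cl <- if (length(classes) == 1L) classes else
        sample(classes, 1L, prob = config$mixture)
      true_class[i] <- cl
      gens[, i] <- draw_sterility(config$model[[cl]], r, h)
    })
  }

  g <- as.vector(gens)
  censored <- is.na(g)
  cls_rep <- rep(true_class, each = r)
  failure_mode <- ifelse(censored, "none",
                         ifelse(cls_rep == "low_fitness",
                                "non_mrt_failure", "mrt_sterile"))
  out <- data.frame(
    line_id = rep(line_id, each = r),
    replicate_id = rep(seq_len(r), times = n),
    sterile_generation = g,
    censored = as.integer(censored),
    failure_mode = failure_mode,
    stringsAsFactors = FALSE
  )
  names(true_class) <- line_id
  attr(out, "horizon") <- h
  attr(out, "design") <- d
  attr(out, "seed") <- seed
  attr(out, "true_class") <- true_class
  out
}

#' Simulate a mutation-accumulation experiment for the Mrt phenotype
#'
#' Each of `n_lines` single-descent lines accumulates Mrt mutations over
#' `t_gens` generations as a Poisson process at the diploid arisal rate
#' `2U` per generation; each new (heterozygous) mutation survives the
#' within-line drift of single-individual selfing descent with probability
#' 1/2 (see [ma_transmission()]). Lines carrying at least one surviving
#' mutation express the strong-Mrt sterility model in the subsequent assay;
#' all other lines behave as wild type. The realised number of mutant lines
#' is returned alongside the assay table, so rate estimation can be checked
#' against truth.
#'
#' @param n_lines Number of MA lines.
#' @param t_gens Generations of mutation accumulation.
#' @param U Haploid genome-wide Mrt mutation rate per generation (>= 0).
#' @param design Optional [assay_design()] providing `reps_per_line` and
#'   the assay horizon (default 10 replicates, horizon 21); its `n_lines`
#'   is overridden by the `n_lines` argument.
#' @param model [sterility_model()] used for the assay phase.
#' @param seed Integer seed (per-line substreams as in
#'   [generate_assay_table()]).
#' @return List with `table` (assay table as in [generate_assay_table()]),
#'   `k_true` (number of mutant lines), and `mutant_lines` (their ids).
#' @examples
#' sim <- generate_ma_experiment(67, 250, U = 6e-5, seed = 7)
#' sim$k_true
#' @export
generate_ma_experiment <- function(n_lines, t_gens, U, design = NULL,
                                   model = sterility_model(), seed = NULL) {
  stopifnot(is_count(n_lines), is_count(t_gens))
  stopifnot(is.numeric(U), length(U) == 1L, is.finite(U))
  if (U < 0) stop("U must be non-negative")
  if (is.null(design)) design <- assay_design(n_lines, 10, 21, "MA")
  stopifnot(inherits(design, "assay_design"))
  r <- design$reps_per_line
  h <- design$assay_generations
  seed <- if (is.null(seed)) draw_seed() else as.integer(seed)

  line_id <- sprintf("L%04d", seq_len(n_lines))
  mutant <- logical(n_lines)
  gens <- matrix(NA_real_, nrow = r, ncol = n_lines)
  for (i in seq_len(n_lines)) {
    with_seed(substream_seed(seed, i), {
      n_arise <- stats::rpois(1L, 2 * U * t_gens)
      n_surv <- stats::rbinom(1L, n_arise, 0.5)
      mutant[i] <- n_surv > 0
      cl <- if (mutant[i]) "strong" else "wild_type"
      gens[, i] <- draw_sterility(model[[cl]], r, h)
    })
  }

  g <- as.vector(gens)
  censored <- is.na(g)
  out <- data.frame(
    line_id = rep(line_id, each = r),
    replicate_id = rep(seq_len(r), times = n_lines),
    sterile_generation = g,
    censored = as.integer(censored),
    failure_mode = ifelse(censored, "none", "mrt_sterile"),
    stringsAsFactors = FALSE
  )
  true_class <- ifelse(mutant, "strong", "wild_type")
  names(true_class) <- line_id
  attr(out, "horizon") <- h
  attr(out, "design") <- design
  attr(out, "seed") <- seed
  attr(out, "true_class") <- true_class
  list(table = out, k_true = sum(mutant), mutant_lines = line_id[mutant])
}
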