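#' Transmission of a new neutral mutation in a single-descent selfing line
#'
#' Simulates the fate of a new mutation in a mutation-accumulation line
#' maintained by transferring a single selfed offspring each generation.
#' Starting from a heterozygous carrier, the single surviving offspring of
#' a selfing parent is homozygous mutant with probability 1/4, heterozygous
#' with probability 1/2, and homozygous wild type with probability 1/4;
#' the walk absorbs at fixation or loss. The loss probability is exactly
#' 1/2 (by symmetry of the Mendelian selfing ratios), which is why the
#' diploid factor of two in the mutation arisal rate cancels when
#' estimating the haploid rate from observed phenotypes.
#'
#' @param n_reps Number of independent replicate transmissions.
#' @param start Starting genotype: `"heterozygous"` (a new mutation), or
#'   the absorbing states `"homozygous_mutant"` / `"homozygous_wildtype"`
#'   (absorbed in 0 generations).
#' @param seed Optional RNG seed.
#' @return Data frame with one row per replicate: `outcome` (factor,
#'   `fixed`/`lost`) and `generations` to absorption.
#' @examples
#' res <- ma_transmission(1000, seed = 1)
#' mean(res$outcome == "lost")  # ~0.5
#' @export
ma_transmission <- function(n_reps = 1,
                            start = c("heterozygous", "homozygous_mutant",
                                      "homozygous_wildtype"),
                            seed = NULL) {
  stopifnot(is_count(n_reps))
  start <- match.arg(start)
  with_seed(seed, {
    if (start != "heterozygous") {
      outcome <- if (start == "homozygous_mutant") "fixed" else "lost"
      return(data.frame(outcome = factor(rep(outcome, n_reps),
                                         levels = c("fixed", "lost")),
                        generations = rep(0L, n_reps)))
    }
    state <- rep(1L, n_reps) # 0 = lost, 1 = het, 2 = fixed
    gens <- rep(0L, n_reps)
    active <- seq_len(n_reps)
    while (length(active)) {
      u <- stats::runif(length(active))
      new_state <- ifelse(u < 0.25, 2L, ifelse(u < 0.75, 1L, 0L))
      gens[active] <- gens[active] + 1L
      state[active] <- new_state
      active <- active[new_state == 1L]
    }
    data.frame(outcome = factor(ifelse(state == 2L, "fixed", "lost"),
                                levels = c("fixed", "lost")),
               generations = gens)
  })
}

#' Wright-Fisher dynamics of Mrt lineages in a finite selfing population
#'
#' Forward simulation of `N` fully selfing, homozygous lineages. Each
#' generation, wild-type lineages mutate irreversibly to Mrt with
#' probability `U`; the next generation is then formed by multinomial
#' resampling of `N` offspring with relative fitness 1 (wild type) vs
#' `1 - s` (Mrt). The lineage (not genotype) resolution matches the
#' mutation-selection recursion of [msb_recursion()], whose equilibrium
#' this process fluctuates around when `N * s` is large.
#'
#' @param N Number of lineages (selfing hermaphrodites).
#' @param U Mutation rate wild type -> Mrt per genome per generation.
#' @param s Selection coefficient against Mrt lineages (`0 <= s < 1`).
#' @param generations Number of generations to simulate.
#' @param q0 Initial Mrt frequency.
#' @param seed Optional RNG seed.
#' @return Object of class `"mrt_wf_trajectory"`: numeric vector of Mrt
#'   frequencies of length `generations + 1` (element 1 is generation 0),
#'   with attributes `N`, `U`, `s`. Has a `plot()` method.
#' @examples
#' tr <- wf_selfing(N = 1000, U = 1e-4, s = 0.01, generations = 200,
#'                  seed = 1)
#' mean(tail(tr, 50))  # fluctuates around ~U/s
#' @export
wf_selfing <- function(N, U, s, generations, q0 = 0, seed = NULL) {
  stopifnot(is_count(N), is_prob(U), is_prob(q0), is_count(generations))
  stopifnot(is.numeric(s), length(s) == 1L, s >= 0, s < 1)
  with_seed(seed, {
    m <- round(q0 * N)
    traj <- numeric(generations + 1)
    traj[1] <- m / N
    for (g in seq_len(generations)) {
      if (U > 0 && m < N) m <- m + stats::rbinom(1L, N - m, U)
      if (m > 0 && m < N) {
        p <- m * (1 - s) / (N - s * m)
        m <- stats::rbinom(1L, N, p)
      }
      traj[g + 1] <- m / N
    }
    structure(traj, N = N, U = U, s = s, q0 = q0,
              class = "mrt_wf_trajectory")
  })
}

#' @export
plot.mrt_wf_trajectory <- function(x, ...) {
  plot(seq_along(x) - 1, as.numeric(x), type = "l",
       xlab = "generation", ylab = "Mrt lineage frequency", ...)
  U <- attr(x, "U"); s <- attr(x, "s")
  if (s > 0) graphics::abline(h = U / s, lty = 2)
  invisible(x)
}

#' @export
print.mrt_wf_trajectory <- function(x, ...) {
  n <- length(x) - 1
  cat(sprintf("Selfing Wright-Fisher trajectory: N = %d, U = %g, s = %g, %d generations\n",
              attr(x, "N"), attr(x, "U"), attr(x, "s"), n))
  cat(sprintf("  final frequency %.4g; mean over last half %.4g\n",
              x[n + 1], mean(x[(floor(n / 2) + 1):(n + 1)])))
  invisible(x)
}

#' End-to-end parameter recovery for the Mrt mutation rate
#'
#' Closes the inference loop: simulate MA experiments with a known true
#' mutation rate ([generate_ma_experiment()]), classify the resulting
#' assay tables ([classify_table()]), count lines scored strong-Mrt as the
#' observed `k`, estimate the rate with its exact Poisson interval
#' ([rate_ci()]), and report bias and empirical interval coverage of the
#' true rate.
#'
#' @param n_experiments Number of simulated experiments.
#' @param true_U True genome-wide Mrt mutation rate.
#' @param n_lines,t_gens MA design (lines and generations).
#' @param reps_per_line,horizon Assay phase design.
#' @param alpha Error level of the interval.
#' @param seed Optional base seed (one substream per experiment).
#' @return Object of class `"mrt_recovery"`: list with `k` (vector of
#'   observed counts), `mean_k`, `expected_k = n_lines * t_gens * true_U`,
#'   `se_mean_k`, `mean_U_hat`, `coverage`, and the inputs.
#' @examples
#' rec <- recover_U(50, true_U = 6e-5, n_lines = 67, t_gens = 250,
#'                  seed = 3)
#' rec$coverage
#' @export
recover_U <- function(n_experiments, true_U, n_lines = 67, t_gens = 250,
                      reps_per_line = 10, horizon = 21, alpha = 0.05,
                      seed = NULL) {
  stopifnot(is_count(n_experiments))
  seed <- if (is.null(seed)) draw_seed() else as.integer(seed)
  design <- assay_design(n_lines, reps_per_line, horizon, "recovery")
  k <- integer(n_experiments)
  covered <- logical(n_experiments)
  U_hat <- numeric(n_experiments)
  for (e in seq_len(n_experiments)) {
    sim <- generate_ma_experiment(n_lines, t_gens, true_U, design = design,
                                  seed = substream_seed(seed, e))
    cls <- classify_table(sim$table)
    k[e] <- sum(cls$class == "strong")
    est <- rate_ci(min(k[e], n_lines), n_lines, t_gens, alpha)
    U_hat[e] <- est$U
    covered[e] <- est$U_low <= true_U && true_U <= est$U_high
  }
  out <- list(
    k = k, mean_k = mean(k),
    expected_k = n_lines * t_gens * true_U,
    se_mean_k = stats::sd(k) / sqrt(n_experiments),
    k_table = table(k),
    mean_U_hat = mean(U_hat),
    coverage = mean(covered),
    n_experiments = n_experiments, true_U = true_U,
    n_lines = n_lines, t_gens = t_gens, alpha = alpha, seed = seed
  )
  class(out) <- "mrt_recovery"
  out
}

#' @export
print.mrt_recovery <- function(x, digits = 3, ...) {
  cat(sprintf("Mrt rate recovery over %d simulated MA experiments (n = %d, t = %d)\n",
              x$n_experiments, x$n_lines, x$t_gens))
  cat(sprintf("  true U = %s; mean U_hat = %s\n",
              signif(x$true_U, digits), signif(x$mean_U_hat, digits)))
  cat(sprintf("  mean k = %s (expected n*t*U = %s, MC se %s)\n",
              signif(x$mean_k, digits), signif(x$expected_k, digits),
              signif(x$se_mean_k, digits)))
  cat(sprintf("  empirical %d%% CI coverage of true U: %s\n",
              round(100 * (1 - x$alpha)), signif(x$coverage, digits)))
  invisible(x)
}
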