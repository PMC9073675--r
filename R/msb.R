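#' Selection coefficient from mutation-selection balance
#'
#' Under mutation-selection balance (MSB) in a (nearly) completely selfing
#' population, the equilibrium frequency of a deleterious phenotype is
#' approximately `q = U / s`, with `U` the genome-wide mutation rate to the
#' phenotype and `s` the (homozygous) selection coefficient against it.
#' Solving for `s` given an observed phenotype frequency `q_hat` gives
#' `s = U / q_hat`.
#'
#' @param U Genome-wide mutation rate to the phenotype, per generation.
#' @param q_hat Observed phenotype frequency in (0, 1].
#' @return Selection coefficient (numeric scalar).
#' @examples
#' s_from_frequency(6e-5, 0.06)       # ~0.001, strong Mrt
#' s_from_frequency(1 / 16750, 1 / 95) # ~0.006, ts-sterile
#' @export
s_from_frequency <- function(U, q_hat) {
  stopifnot(is.numeric(U), length(U) == 1L, is.finite(U), U >= 0)
  stopifnot(is.numeric(q_hat), length(q_hat) == 1L, is.finite(q_hat))
  if (q_hat <= 0) {
    stop("q_hat must be > 0; for a zero count, report a one-sided ",
         "bound on U instead (see rate_ci with k = 0)")
  }
  if (q_hat > 1) stop("q_hat is a frequency and cannot exceed 1")
  U / q_hat
}

#' Phenotype frequency with exact binomial confidence interval
#'
#' Clopper-Pearson exact interval for a phenotype carrier frequency
#' `count / total`, as used for the frequency of Mrt classes among wild
#' isolates.
#'
#' @param count Number of carriers (0..total).
#' @param total Number of strains assayed (>= 1).
#' @param alpha Two-sided error level; 0.05 gives a 95% interval.
#' @return List with `q_hat`, `lower`, `upper`, `count`, `total`, `alpha`.
#' @examples
#' frequency_with_ci(6, 95)  # ~0.063, "~6%"
#' @export
frequency_with_ci <- function(count, total, alpha = 0.05) {
  stopifnot(is_count(count, min = 0), is_count(total, min = 1),
            count <= total, alpha > 0, alpha < 1)
  ci <- stats::binom.test(count, total, conf.level = 1 - alpha)$conf.int
  list(q_hat = count / total, lower = ci[1], upper = ci[2],
       count = as.integer(count), total = as.integer(total), alpha = alpha)
}

#' Deterministic mutation-selection recursion for a selfing population
#'
#' Iterates the one-locus dynamics of a population of fully selfing,
#' homozygous lineages: irreversible mutation wild type -> Mrt,
#' `q' = q + U (1 - q)`, followed by selection against Mrt lineages with
#' fitness `1 - s`, `q'' = q' (1 - s) / (1 - s q')`. For `U << s` the fixed
#' point is close to the classical MSB approximation `q* ~ U / s`; the
#' recursion quantifies the accuracy of that approximation.
#'
#' @param U Mutation rate wild type -> Mrt per genome per generation
#'   (`0 <= U <= 1`).
#' @param s Selection coefficient against Mrt lineages (`0 <= s < 1`).
#' @param q0 Initial Mrt frequency.
#' @param tol Relative convergence tolerance on the per-generation change.
#' @param max_iters Iteration cap; non-convergence is flagged, not an error.
#' @return List with `q_star`, `iterations`, `converged`, and the inputs.
#' @examples
#' msb_recursion(6e-5, 1e-3)$q_star  # ~0.060
#' @export
msb_recursion <- function(U, s, q0 = 0, tol = 1e-12, max_iters = 1e6) {
  stopifnot(is_prob(U), is.numeric(s), length(s) == 1L, s >= 0, s < 1,
            is_prob(q0), tol > 0, max_iters >= 1)
  q <- q0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iters) {
    iter <- iter + 1L
    qm <- q + U * (1 - q)
    qn <- qm * (1 - s) / (1 - s * qm)
    if (abs(qn - q) < tol * max(qn, .Machine$double.xmin)) {
      q <- qn
      converged <- TRUE
      break
    }
    q <- qn
  }
  list(q_star = q, iterations = iter, converged = converged,
       U = U, s = s, q0 = q0, tol = tol)
}

#' Mutation-selection-balance inference report
#'
#' Combines an observed carrier count with a mutation-rate estimate into an
#' MSB-based selection-coefficient estimate `s_hat = U / q_hat`, with an
#' interval obtained by interval arithmetic over the exact binomial interval
#' for `q_hat` and (optionally) a confidence interval for `U`. When the
#' carrier count is itself a lower bound (phenotype classification is
#' conservative), `s_hat` should be read as an upper bound on `s`; set
#' `one_sided = TRUE` to record that.
#'
#' @param U Point estimate of the genome-wide mutation rate to the
#'   phenotype.
#' @param count,total Carrier count among assayed strains.
#' @param alpha Error level for the binomial interval on `q_hat`.
#' @param U_ci Optional length-2 numeric `(U_low, U_high)`, e.g. from
#'   [rate_ci()], propagated into the `s` interval.
#' @param one_sided Logical; mark the report as an upper bound on `s`
#'   (carrier count is a lower bound).
#' @return Object of class `"mrt_msb"` with `s_hat`, `s_low`, `s_high`,
#'   `q` (the [frequency_with_ci()] result), `U`, `U_ci`, `one_sided`.
#' @examples
#' msb_inference(U = 6e-5, count = 6, total = 95)
#' @export
msb_inference <- function(U, count, total, alpha = 0.05, U_ci = NULL,
                          one_sided = FALSE) {
  q <- frequency_with_ci(count, total, alpha)
  if (q$q_hat <= 0) {
    stop("count = 0: s is unidentified; report a bound on U instead")
  }
  s_hat <- s_from_frequency(U, q$q_hat)
  U_lo <- if (is.null(U_ci)) U else U_ci[1]
  U_hi <- if (is.null(U_ci)) U else U_ci[2]
  s_low <- U_lo / q$upper
  s_high <- if (q$lower > 0) U_hi / q$lower else Inf
  out <- list(s_hat = s_hat, s_low = s_low, s_high = s_high, q = q,
              U = U, U_ci = U_ci, one_sided = isTRUE(one_sided))
  class(out) <- "mrt_msb"
  out
}

#' @export
print.mrt_msb <- function(x, digits = 3, ...) {
  cat("Mutation-selection-balance selection inference\n")
  cat(sprintf("  q_hat = %d/%d = %s (%d%% CI %s-%s)\n",
              x$q$count, x$q$total, signif(x$q$q_hat, digits),
              round(100 * (1 - x$q$alpha)),
              signif(x$q$lower, digits), signif(x$q$upper, digits)))
  cat(sprintf("  U = %s  =>  s_hat = U/q_hat = %s%s\n",
              signif(x$U, digits), signif(x$s_hat, digits),
              if (x$one_sided) " (upper bound: carrier count is a lower bound)"
              else ""))
  cat(sprintf("  interval-arithmetic range for s: (%s, %s)\n",
              signif(x$s_low, digits), signif(x$s_high, digits)))
  invisible(x)
}
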