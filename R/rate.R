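#' Point estimate of the genome-wide Mrt mutation rate
#'
#' Computes the haploid per-genome, per-generation mutation rate to the
#' mortal-germline phenotype from a mutation-accumulation (MA) experiment as
#' `U = k / (n * t)`: `k` observed Mrt mutations among `n` lines propagated
#' for `t` generations. Although mutations arise in diploids (arisal rate
#' `2U`), each new neutral mutation in a single-descent selfing line is lost
#' with probability 1/2, so the factor of two cancels and `k/nt` estimates
#' the haploid rate directly (see [ma_transmission()] for the simulation
#' grounding of the 1/2).
#'
#' @param k Observed number of Mrt mutations (non-negative integer; at most
#'   one per line, so `k <= n`).
#' @param n Number of MA lines assayed.
#' @param t Generations of mutation accumulation.
#' @return Rate per genome per generation (numeric scalar).
#' @seealso [rate_ci()] for the exact Poisson confidence interval,
#'   [target_size()] for mutational-target arithmetic.
#' @examples
#' point_rate(k = 1, n = 67, t = 250) # ~6e-5
#' @export
point_rate <- function(k, n, t) {
  stopifnot(is_count(k, min = 0), is_count(n), is_count(t))
  if (k > n) stop("k cannot exceed the number of lines n")
  k / (n * t)
}

#' Exact Poisson confidence bounds for an observed count
#'
#' Garwood's exact two-sided interval for the mean of a Poisson-distributed
#' count `X = k`: the lower bound solves `P(X >= k | lambda_L) = alpha/2`
#' and the upper bound solves `P(X <= k | lambda_U) = alpha/2`. Via the
#' chi-square/Poisson identity, `2 * lambda_L` is the `alpha/2` fractile of
#' a chi-square with `2k` degrees of freedom (0 when `k = 0`), and
#' `2 * lambda_U` is the `1 - alpha/2` fractile with `2(k+1)` df.
#'
#' @param k Observed count (non-negative integer).
#' @param alpha Two-sided error level in (0, 1); `alpha = 0.05` gives the
#'   95% interval.
#' @return Named numeric vector `c(lambda_low, lambda_high)`.
#' @examples
#' poisson_exact_ci(1)           # (0.0253, 5.572)
#' poisson_exact_ci(0)           # (0, 3.689) = (0, -log(0.025))
#' @export
poisson_exact_ci <- function(k, alpha = 0.05) {
  stopifnot(is_count(k, min = 0))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number strictly between 0 and 1")
  }
  lower <- if (k == 0) 0 else stats::qchisq(alpha / 2, df = 2 * k) / 2
  upper <- stats::qchisq(1 - alpha / 2, df = 2 * (k + 1)) / 2
  c(lambda_low = lower, lambda_high = upper)
}

#' Exact confidence interval for the Mrt mutation rate
#'
#' Divides the exact Poisson bounds of [poisson_exact_ci()] by the number of
#' meioses `n * t` to give a `(1 - alpha)` interval for the per-genome,
#' per-generation mutation rate.
#'
#' @inheritParams point_rate
#' @inheritParams poisson_exact_ci
#' @return An object of class `"mrt_rate"`: a list with elements `U`,
#'   `U_low`, `U_high`, `lambda_low`, `lambda_high`, `k`, `n`, `t`,
#'   `meioses` and `alpha`. Has `print()` and `confint()` methods.
#' @examples
#' rate_ci(k = 1, n = 67, t = 250)  # 95% CI ~ (1.5e-6, 3.3e-4)
#' rate_ci(k = 0, n = 67, t = 250)  # one-sided bound, upper ~ 2.2e-4
#' @export
rate_ci <- function(k, n, t, alpha = 0.05) {
  U <- point_rate(k, n, t)
  lam <- poisson_exact_ci(k, alpha)
  meioses <- as.integer(n) * as.integer(t)
  out <- list(
    U = U,
    U_low = unname(lam[1]) / meioses,
    U_high = unname(lam[2]) / meioses,
    lambda_low = unname(lam[1]),
    lambda_high = unname(lam[2]),
    k = as.integer(k), n = as.integer(n), t = as.integer(t),
    meioses = meioses,
    alpha = alpha
  )
  class(out) <- "mrt_rate"
  out
}

#' @export
print.mrt_rate <- function(x, digits = 3, ...) {
  cat("Genome-wide Mrt mutation rate (exact Poisson interval)\n")
  cat(sprintf("  k = %d mutations in %d lines x %d generations = %s meioses\n",
              x$k, x$n, x$t, format(x$meioses, big.mark = ",")))
  cat(sprintf("  U = %s /genome/generation\n", signif(x$U, digits)))
  cat(sprintf("  %d%% CI: (%s, %s)\n", round(100 * (1 - x$alpha)),
              signif(x$U_low, digits), signif(x$U_high, digits)))
  if (x$k == 0) {
    cat("  (k = 0: lower bound fixed at 0; interpret the upper bound\n",
        "   as a one-sided limit)\n", sep = "")
  }
  invisible(x)
}

#' @export
confint.mrt_rate <- function(object, parm = "U", level, ...) {
  ci <- matrix(c(object$U_low, object$U_high), nrow = 1,
               dimnames = list("U", c("lower", "upper")))
  ci
}

#' Mutational target size of a phenotype
#'
#' Converts a genome-wide phenotypic mutation rate into the implied number
#' of nucleotide sites at which a mutation yields the phenotype,
#' `n_sites = U / mu_site`, and the corresponding genome fraction. Defaults
#' are the *C. elegans* values: per-nucleotide mutation rate
#' `2.8e-9`/site/generation and a `1e8` bp genome.
#'
#' @param U Genome-wide phenotypic mutation rate per generation (can be a
#'   point estimate or a confidence bound).
#' @param mu_site Per-nucleotide mutation rate per generation (> 0).
#' @param genome_size Genome size in base pairs (> 0).
#' @return An object of class `"mrt_target_size"`: list with `n_sites`,
#'   `fraction` (of the genome), `percent`, and the inputs.
#' @examples
#' target_size(1 / 16750)  # ~21,300 sites, ~0.02% of the genome
#' @export
target_size <- function(U, mu_site = 2.8e-9, genome_size = 1e8) {
  stopifnot(is.numeric(U), length(U) == 1L, is.finite(U))
  if (U < 0) stop("U must be non-negative")
  stopifnot(mu_site > 0, genome_size > 0)
  n_sites <- U / mu_site
  fraction <- n_sites / genome_size
  out <- list(n_sites = n_sites, fraction = fraction,
              percent = 100 * fraction,
              U = U, mu_site = mu_site, genome_size = genome_size)
  class(out) <- "mrt_target_size"
  out
}

#' @export
print.mrt_target_size <- function(x, digits = 3, ...) {
  cat("Mutational target size\n")
  cat(sprintf("  U = %s, mu_site = %s, genome = %s bp\n",
              signif(x$U, digits), signif(x$mu_site, digits),
              format(x$genome_size, scientific = TRUE)))
  cat(sprintf("  target: %s sites = %s%% of the genome\n",
              signif(x$n_sites, digits), signif(x$percent, digits)))
  invisible(x)
}
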