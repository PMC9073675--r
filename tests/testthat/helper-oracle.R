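# Brute-force oracle for the exact Poisson interval: solves the defining
# tail-sum equations P(X >= k | lambda_L) = alpha/2 and
# P(X <= k | lambda_U) = alpha/2 numerically, using explicit Poisson pmf
# sums (no chi-square identity), so it is independent of the production
# path in poisson_exact_ci().
oracle_poisson_ci <- function(k, alpha) {
  pmf_sum <- function(lam, i) {
    # sum_{j in i} e^-lam lam^j / j!
    sum(exp(-lam + i * log(lam) - lgamma(i + 1)))
  }
  upper <- stats::uniroot(
    function(lam) pmf_sum(lam, 0:k) - alpha / 2,
    interval = c(1e-10, 2 * k + 100), tol = 1e-12
  )$root
  lower <- if (k == 0) 0 else stats::uniroot(
    function(lam) (1 - pmf_sum(lam, 0:(k - 1))) - alpha / 2,
    interval = c(1e-12, 2 * k + 100), tol = 1e-12
  )$root
  c(lower, upper)
}
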