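# Numerical density-product oracle for Gaussian multiplication: evaluates
# both densities pointwise on a fine grid, normalizes the product, and
# extracts its mean and SD by numerical integration. The normalized product
# always lies between the two component means with a width no larger than
# either component, so a window spanning both means plus a 12-max-SD margin
# covers it entirely; the step resolves the narrower component with ~500
# points per SD. Built from the factor parameters only, independent of the
# closed form it checks.
grid_product_oracle <- function(m1, s1, m2, s2) {
  lo <- min(m1, m2) - 12 * max(s1, s2)
  hi <- max(m1, m2) + 12 * max(s1, s2)
  x <- seq(lo, hi, by = min(s1, s2) / 500)
  f <- stats::dnorm(x, m1, s1) * stats::dnorm(x, m2, s2)
  w <- f / sum(f)
  mu <- sum(w * x)
  list(mean = mu, sd = sqrt(sum(w * (x - mu)^2)))
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

# Bernoulli log-likelihood of an aggregated psychometric table under a
# cumulative-normal model; used for local-optimum checks
psy_loglik <- function(agg, pse, sigma) {
  p <- pmin(pmax(stats::pnorm((agg$comparison_ms - pse) / sigma), 1e-12), 1 - 1e-12)
  sum(agg$k * log(p) + (agg$n - agg$k) * log(1 - p))
}
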