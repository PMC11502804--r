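# Independent oracles used to freeze expected values.

# Wald estimator: ratio of reduced-form to first-stage mean differences for
# a single binary instrument (brute-force group means, no matrix algebra).
wald_oracle <- function(y, x, z) {
  (mean(y[z == 1]) - mean(y[z == 0])) /
    (mean(x[z == 1]) - mean(x[z == 0]))
}

# E[plogis(a + s * Z)], Z ~ N(0, 1), by Gauss-Hermite quadrature (direct use
# of pracma's nodes; independent of the sampler under test).
gh_logistic_oracle <- function(a, s, nodes = 80) {
  gh <- pracma::gaussHermite(nodes)
  sum(gh$w * stats::plogis(a + s * sqrt(2) * gh$x)) / sqrt(pi)
}

# Closed-form two-sample power approximation for a standardized mean
# difference d with N per arm at two-sided alpha.
closed_form_power <- function(d, n_per_arm, alpha = 0.05) {
  z <- stats::qnorm(1 - alpha / 2)
  nc <- d * sqrt(n_per_arm / 2)
  stats::pnorm(nc - z) + stats::pnorm(-nc - z)
}

# Deterministic 20-unit table for exact small-sample 2SLS checks.
fixed_iv_table <- function() {
  z <- rep(c(0, 1), each = 10)
  x <- c(0, 1, 0, 0, 1, 0, 0, 1, 0, 0,
         1, 1, 0, 1, 1, 1, 0, 1, 1, 1)
  y <- c(0, 1, 0, 1, 1, 0, 0, 0, 1, 0,
         1, 1, 1, 0, 1, 1, 0, 1, 1, 0)
  t <- rep(c(0, 1), times = 10)
  data.frame(T = t, IV = z, PEB1 = x, PEB2 = y)
}
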