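# Sampling from the structural model. The exogenous noise is drawn separately
# from the deterministic transform so that the calibration loop can reuse one
# set of draws across candidate parameter values (common random numbers).

#' Derive a reproducible child seed from a root seed
#'
#' Simple integer hash keeping results in [1, 2^31 - 2]. Used so that every
#' replicate / task gets its own substream and results are order-independent.
#'
#' @param root Root seed (integer).
#' @param index Task index (integer >= 0).
#' @return An integer seed.
#' @export
derive_seed <- function(root, index) {
  root <- as.double(root) %% 2147483647
  index <- as.double(index) %% 2147483647
  # two rounds of a multiply-mod mix; constants are primes < 2^15 so all
  # intermediates stay exactly representable in doubles
  x <- (root * 30269 + index * 30323 + 14323) %% 2147483563
  x <- (x * 31397 + 7691) %% 2147483563
  as.integer(x + 1)
}

draw_noise <- function(version, n) {
  d <- list(u_t = stats::runif(n), u_iv = stats::runif(n),
            z_u1 = stats::rnorm(n), z_u2 = stats::rnorm(n))
  if (version == "binary") {
    d$u_peb1 <- stats::runif(n)
    d$u_peb2 <- stats::runif(n)
  } else {
    d$z_peb1 <- stats::rnorm(n)
    d$z_peb2 <- stats::rnorm(n)
  }
  d
}

# Deterministic transform of exogenous draws into a sample. `minimal = TRUE`
# returns only the four observed columns (used in tight simulation loops).
simulate_from_draws <- function(params, draws, minimal = FALSE) {
  Tt <- as.integer(draws$u_t < 0.5)
  IV <- as.integer(draws$u_iv < 0.5)
  U1 <- params$phi1 * Tt + params$sigma_u1 * draws$z_u1
  if (params$version == "binary") {
    p1 <- stats::plogis(params$attract_peb1 + params$beta_u1 * U1 +
                          params$beta_iv * IV)
    PEB1 <- as.integer(draws$u_peb1 < p1)
    U2 <- params$phi21 * U1 + params$phi22 * PEB1 +
      params$sigma_u2 * draws$z_u2
    p2 <- stats::plogis(params$attract_peb2 + params$beta_u2 * U2)
    PEB2 <- as.integer(draws$u_peb2 < p2)
    if (minimal) return(list(T = Tt, IV = IV, PEB1 = PEB1, PEB2 = PEB2))
    out <- data.frame(unit_id = seq_along(Tt), T = Tt, IV = IV, U1 = U1,
                      PEB1 = PEB1, U2 = U2, PEB2 = PEB2,
                      p_peb1 = p1, p_peb2 = p2)
  } else {
    PEB1 <- params$attract_peb1 + params$beta_u1 * U1 +
      params$beta_iv * IV + params$sigma_peb1 * draws$z_peb1
    U2 <- params$phi21 * U1 + params$phi22 * PEB1 +
      params$sigma_u2 * draws$z_u2
    PEB2 <- params$attract_peb2 + params$beta_u2 * U2 +
      params$sigma_peb2 * draws$z_peb2
    if (minimal) return(list(T = Tt, IV = IV, PEB1 = PEB1, PEB2 = PEB2))
    out <- data.frame(unit_id = seq_along(Tt), T = Tt, IV = IV, U1 = U1,
                      PEB1 = PEB1, U2 = U2, PEB2 = PEB2)
  }
  attr(out, "params") <- params
  class(out) <- c("simulated_sample", "data.frame")
  out
}

#' Draw a sample from the structural spillover model
#'
#' Samples `n_total` units exactly per the model equations: treatment `T` and
#' nudge `IV` are independent Bernoulli(0.5); `U1 ~ N(phi1 * T, sigma_u1)`;
#' in the binary version PEB1 is Bernoulli with logistic propensity
#' `plogis(attract_peb1 + beta_u1 * U1 + beta_iv * IV)`,
#' `U2 ~ N(phi21 * U1 + phi22 * PEB1, sigma_u2)` using the *realized* PEB1,
#' and PEB2 is Bernoulli with propensity `plogis(attract_peb2 + beta_u2 * U2)`.
#' The continuous version replaces the two Bernoulli draws by Gaussian draws
#' with the same means and SDs `sigma_peb1`, `sigma_peb2`. The same
#' `(params, n_total, seed)` always yields an identical sample.
#'
#' @param params A `generative_params` object.
#' @param n_total Total number of units (>= 2). A design with N per treatment
#'   arm corresponds to `n_total = 2 * N` with the Bernoulli(0.5) split.
#' @param seed Integer seed controlling all randomness of the draw.
#' @return A `simulated_sample` data frame with columns `unit_id`, `T`, `IV`,
#'   `U1`, `PEB1`, `U2`, `PEB2` (plus `p_peb1`, `p_peb2` in the binary
#'   version).
#' @examples
#' p <- generative_params("binary", phi1 = 0.5, beta_iv = 1)
#' s <- sample_dataset(p, 1000, seed = 1)
#' mean(s$PEB1)
#' @export
sample_dataset <- function(params, n_total, seed) {
  validate_params(params)
  n_total <- as.integer(n_total)
  if (is.na(n_total) || n_total < 2) {
    stop("size error: n_total must be an integer >= 2")
  }
  set.seed(as.integer(seed))
  simulate_from_draws(params, draw_noise(params$version, n_total))
}

# One minimal draw using the current RNG state (used inside replicate loops
# where the caller manages seeding).
sample_minimal <- function(params, n_total) {
  simulate_from_draws(params, draw_noise(params$version, n_total),
                      minimal = TRUE)
}

#' Expected logistic mean under Gaussian latent noise
#'
#' Computes `E[plogis(a + s * Z)]` for standard normal `Z` by Gauss-Hermite
#' quadrature. This is the marginal participation probability implied by a
#' logit intercept `a` when a Gaussian latent activation with total SD `s`
#' enters the linear predictor; it is used to anchor synthetic-experiment
#' intercepts to observed marginal rates and as an analytic cross-check of
#' the sampler.
#'
#' @param a Intercept(s) on the logit scale (vectorized).
#' @param s Standard deviation of the Gaussian term (scalar, >= 0).
#' @param nodes Number of Gauss-Hermite nodes.
#' @return Marginal probability, same length as `a`.
#' @export
logistic_normal_mean <- function(a, s, nodes = 64) {
  if (s < 0) stop("invalid-parameter: s must be >= 0")
  if (s == 0) return(stats::plogis(a))
  gh <- pracma::gaussHermite(nodes)
  # E[f(a + s Z)] = (1/sqrt(pi)) * sum w_i f(a + s * sqrt(2) * x_i)
  vapply(a, function(ai) {
    sum(gh$w * stats::plogis(ai + s * sqrt(2) * gh$x)) / sqrt(pi)
  }, numeric(1))
}
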