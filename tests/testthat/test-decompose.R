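# The spillover decomposition, its algebraic identities, the stacked
# sandwich, and the studentized bootstrap.

test_that("on a balanced crossed design tau - delta' equals beta' x stage-1 T path", {
  # 16-unit table with T and IV exactly crossed (orthogonal design)
  Tt <- rep(c(0, 1), each = 8)
  IV <- rep(rep(c(0, 1), each = 4), 2)
  P1 <- c(0, 1, 0, 1, 1, 1, 0, 1, 0, 0, 1, 1, 0, 1, 1, 1)
  P2 <- c(0, 0, 1, 0, 1, 0, 1, 1, 0, 1, 0, 1, 1, 1, 0, 1)
  d <- data.frame(T = Tt, IV = IV, PEB1 = P1, PEB2 = P2)
  dec <- decompose_spillover(d, ci = FALSE)
  # brute-force projection oracle: reduced form and first stage by lm
  s1 <- lm(PEB1 ~ IV + T, data = d)
  tau <- unname(coef(lm(PEB2 ~ T, data = d))["T"])
  expect_equal(unname(dec$tau["estimate"]), tau, tolerance = 1e-12)
  expect_equal(dec$indirect,
               unname(dec$beta_prime["estimate"] * coef(s1)["T"]),
               tolerance = 1e-12)
  # and the decomposition identity holds exactly
  expect_equal(dec$indirect,
               unname(dec$tau["estimate"] - dec$delta_prime["estimate"]))
})

test_that("fast and general indirect statistics agree on random tables", {
  p <- generative_params("binary", phi1 = 0.8, beta_iv = 1, phi22 = 1,
                         beta_u2 = 0.7)
  for (r in 1:8) {
    set.seed(derive_seed(23, r))
    s <- sample_minimal(p, 400)
    fast <- spillpower:::indirect_stat_fast(s$T, s$IV, s$PEB1, s$PEB2)
    gen <- spillpower:::indirect_stat_general(s$T, s$IV, s$PEB1, s$PEB2,
                                              NULL)
    expect_equal(unlist(fast), unlist(gen), tolerance = 1e-10)
  }
})

test_that("a global null yields near-zero components and a CI containing 0", {
  p <- generative_params("binary", phi1 = 0, beta_iv = 1, phi22 = 0)
  s <- sample_dataset(p, 2e5, seed = 19)
  dec <- decompose_spillover(s, settings = bootstrap_settings(
    n_resamples = 499, seed = 3))
  expect_lt(abs(dec$tau["estimate"]), 3 * dec$tau["robust_se"])
  expect_lt(abs(dec$delta_prime["estimate"]),
            3 * dec$delta_prime["robust_se"])
  expect_lt(abs(dec$indirect), 3 * dec$indirect_se)
  expect_lt(dec$indirect_ci95[1], 0)
  expect_gt(dec$indirect_ci95[2], 0)
  expect_gt(dec$first_stage_F, 10)
})

test_that("degenerate inputs raise the documented decomposition errors", {
  d <- data.frame(T = rep(c(0, 1), 10), IV = rep(c(0, 1), each = 10),
                  PEB1 = rep(0, 20), PEB2 = rbinom(20, 1, 0.5))
  expect_error(decompose_spillover(d, ci = FALSE), "degenerate-behavior")
  d2 <- data.frame(T = rep(1, 20), IV = rep(c(0, 1), 10),
                   PEB1 = rbinom(20, 1, 0.5), PEB2 = rbinom(20, 1, 0.5))
  expect_error(decompose_spillover(d2, ci = FALSE), "non-empty")
})

test_that("a constant bootstrap statistic collapses the CI to the point", {
  p <- generative_params("binary", phi1 = 0.5, beta_iv = 1, phi22 = 0.5)
  s <- sample_dataset(p, 500, seed = 29)
  ci <- studentized_bootstrap_ci(
    s, statistic = function(d) c(3.14, 1),
    settings = bootstrap_settings(n_resamples = 200, seed = 1))
  expect_equal(as.vector(ci), c(3.14, 3.14))
})

test_that("exogenous covariates are accepted and leave randomized effects stable", {
  p <- generative_params("binary", phi1 = 0.8, beta_iv = 1, phi22 = 1,
                         beta_u2 = 0.7)
  s <- sample_dataset(p, 30000, seed = 31)
  s$age <- rnorm(nrow(s))
  dec0 <- decompose_spillover(s, ci = FALSE)
  dec1 <- decompose_spillover(s, exogenous = "age", ci = FALSE)
  # covariates are independent of the randomized arms: estimates barely move
  expect_lt(abs(dec0$indirect - dec1$indirect), 2 * dec0$indirect_se)
  expect_equal(dec1$indirect,
               unname(dec1$tau["estimate"] - dec1$delta_prime["estimate"]))
})

test_that("moderated 2SLS recovers a stratum difference in the PEB1 path", {
  base <- list(phi1 = 0.6, beta_u1 = 1, beta_iv = 0.5, phi21 = 0.7,
               beta_u2 = 1, attract_peb1 = 0, attract_peb2 = 0)
  pa <- do.call(generative_params,
                c(list(version = "continuous", phi22 = 0.4), base))
  pb <- do.call(generative_params,
                c(list(version = "continuous", phi22 = 0.8), base))
  n <- 1e5
  sa <- sample_dataset(pa, n, seed = 37)
  sb <- sample_dataset(pb, n, seed = 38)
  d <- rbind(sa, sb)
  d$mod <- rep(c(0, 1), each = n)
  f <- fit_moderated_2sls(d, "mod", contract = "difficulty")
  ct <- f$coefficients
  b2 <- ct[ct$term == "PEB1:mod", ]
  # beta2' estimates beta_u2 * (phi22_b - phi22_a) = 0.4
  expect_lt(abs(b2$estimate - 0.4), 3 * b2$robust_se)
  expect_true(all(f$first_stage_F > 10))
  expect_length(f$first_stage_F, 2)
  # Study-2 contract: no T x moderator column; Study-3 contract adds it
  expect_false("T:mod" %in% ct$term)
  f3 <- fit_moderated_2sls(d, "mod", contract = "domain")
  expect_true("T:mod" %in% f3$coefficients$term)
})

test_that("no true moderation gives a near-zero interaction estimate", {
  p <- generative_params("binary", phi1 = 0.8, beta_iv = 1, phi22 = 1,
                         beta_u2 = 0.7)
  s <- sample_dataset(p, 1e5, seed = 41)
  set.seed(42)
  s$mod <- rbinom(nrow(s), 1, 0.5)
  f <- fit_moderated_2sls(s, "mod", contract = "domain")
  ct <- f$coefficients
  b2 <- ct[ct$term == "PEB1:mod", ]
  d2 <- ct[ct$term == "T:mod", ]
  expect_lt(abs(b2$estimate), 3 * b2$robust_se)
  expect_lt(abs(d2$estimate), 3 * d2$robust_se)
  expect_error(fit_moderated_2sls(s, rep(1, nrow(s))), "no-moderation")
})
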