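# The structural data-generating process: sampling equations, analytic
# marginals, closed-form effects, and reproducibility.

test_that("identical (params, n, seed) give bitwise-identical samples", {
  p <- generative_params("binary", phi1 = 0.4, beta_iv = 0.8, phi22 = 1)
  s1 <- sample_dataset(p, 5000, seed = 42)
  s2 <- sample_dataset(p, 5000, seed = 42)
  expect_identical(s1, s2)
  s3 <- sample_dataset(p, 5000, seed = 43)
  expect_false(identical(s1$PEB1, s3$PEB1))
})

test_that("sample columns honor the model's invariants", {
  for (v in c("binary", "continuous")) {
    p <- generative_params(v, phi1 = 0.5, beta_iv = 1, phi22 = 0.4)
    s <- sample_dataset(p, 20000, seed = 7)
    expect_equal(nrow(s), 20000)
    expect_true(all(s$T %in% 0:1))
    expect_true(all(s$IV %in% 0:1))
    # marginally Bernoulli(0.5) and independent in expectation
    expect_lt(abs(mean(s$T) - 0.5), 3 * sqrt(0.25 / 20000))
    expect_lt(abs(mean(s$IV) - 0.5), 3 * sqrt(0.25 / 20000))
    expect_lt(abs(cor(s$T, s$IV)), 3 / sqrt(20000))
    if (v == "binary") {
      expect_true(all(s$PEB1 %in% 0:1))
      expect_true(all(s$PEB2 %in% 0:1))
      expect_true(all(s$p_peb1 > 0 & s$p_peb1 < 1))
      expect_true(all(s$p_peb2 > 0 & s$p_peb2 < 1))
    } else {
      expect_null(s$p_peb1)
    }
  }
})

test_that("invalid parameters and sizes are rejected", {
  expect_error(generative_params("binary", sigma_u1 = 0),
               "invalid-parameter")
  expect_error(generative_params("continuous", sigma_peb2 = -1),
               "invalid-parameter")
  # binary version ignores outcome sigmas entirely
  expect_silent(generative_params("binary", sigma_peb1 = -1))
  p <- generative_params("binary")
  expect_error(sample_dataset(p, 1, seed = 1), "size error")
})

test_that("an attractiveness of -1.5 yields the 18.2% baseline rate", {
  p <- generative_params("binary", phi1 = 0, beta_u1 = 0, beta_u2 = 0,
                         beta_iv = 0, phi22 = 0,
                         attract_peb1 = -1.5, attract_peb2 = -1.5)
  n <- 4e5
  s <- sample_dataset(p, n, seed = 5)
  base <- plogis(-1.5)  # 0.18242...
  expect_equal(round(base, 3), 0.182)
  mc_se <- sqrt(base * (1 - base) / n)
  expect_lt(abs(mean(s$PEB1) - base), 3 * mc_se)
  expect_lt(abs(mean(s$PEB2) - base), 3 * mc_se)
})

test_that("all-zero coefficients and intercepts give 50% participation", {
  p <- generative_params("binary", phi1 = 0, beta_u1 = 0, beta_u2 = 0,
                         beta_iv = 0, phi22 = 0,
                         attract_peb1 = 0, attract_peb2 = 0)
  s <- sample_dataset(p, 2e5, seed = 9)
  mc_se <- sqrt(0.25 / 2e5)
  expect_lt(abs(mean(s$PEB1) - 0.5), 3 * mc_se)
  expect_lt(abs(mean(s$PEB2) - 0.5), 3 * mc_se)
})

test_that("marginal participation matches the Gauss-Hermite integral over U1", {
  # quadrature oracle computed independently of the sampler
  n <- 3e5
  cases <- list(c(a = -1.5, b = 1, biv = 0),
                c(a = -1.5, b = 0.5, biv = 0.7),
                c(a = -0.5, b = 1.5, biv = 0.3))
  for (cs in cases) {
    p <- generative_params("binary", phi1 = 0, beta_u1 = cs[["b"]],
                           beta_iv = cs[["biv"]],
                           attract_peb1 = cs[["a"]])
    s <- sample_dataset(p, n, seed = 21)
    for (iv in 0:1) {
      expected <- gh_logistic_oracle(cs[["a"]] + cs[["biv"]] * iv,
                                     cs[["b"]])
      got <- mean(s$PEB1[s$IV == iv])
      mc_se <- sqrt(expected * (1 - expected) / sum(s$IV == iv))
      expect_lt(abs(got - expected), 3 * mc_se)
    }
  }
  # package helper agrees with the oracle
  expect_equal(logistic_normal_mean(-1.5, 1), gh_logistic_oracle(-1.5, 1),
               tolerance = 1e-8)
})

test_that("closed-form effects follow the path-product identities", {
  p <- generative_params("continuous", phi1 = 1, beta_u1 = 0.5,
                         phi21 = 0.7, phi22 = 0.4, beta_u2 = 1,
                         attract_peb1 = 0, attract_peb2 = 0)
  eff <- closed_form_effects(p)
  expect_equal(eff$indirect_t_on_peb2, 0.2)
  expect_equal(eff$direct_t_on_peb2, 0.7)
  expect_equal(eff$total_t_on_peb2, 0.9)
  # every treatment path passes through phi1
  p0 <- generative_params("continuous", phi1 = 0, beta_u1 = 2,
                          phi21 = 0.7, phi22 = 1.3, beta_u2 = 0.8)
  eff0 <- closed_form_effects(p0)
  expect_equal(eff0$t_on_peb1, 0)
  expect_equal(eff0$direct_t_on_peb2, 0)
  expect_equal(eff0$total_t_on_peb2, 0)
  expect_error(closed_form_effects(generative_params("binary")),
               "unsupported-version")
})

test_that("continuous-version OLS recovers the closed-form effects", {
  p <- generative_params("continuous", phi1 = 0.6, beta_u1 = 1,
                         beta_iv = 0.5, phi21 = 0.7, phi22 = 0.3,
                         beta_u2 = 1, attract_peb1 = 0, attract_peb2 = 0)
  eff <- closed_form_effects(p)
  n <- 5e5
  s <- sample_dataset(p, n, seed = 13)
  f1 <- lm(PEB1 ~ T, data = s)
  f2 <- lm(PEB2 ~ T, data = s)
  se1 <- summary(f1)$coefficients["T", "Std. Error"]
  se2 <- summary(f2)$coefficients["T", "Std. Error"]
  expect_lt(abs(coef(f1)["T"] - eff$t_on_peb1), 3 * se1)
  expect_lt(abs(coef(f2)["T"] - eff$total_t_on_peb2), 3 * se2)
})

test_that("a zero nudge path makes PEB1 independent of the nudge", {
  p <- generative_params("binary", phi1 = 0.5, beta_iv = 0, phi22 = 0.5)
  reps <- 150
  rej <- 0
  for (r in seq_len(reps)) {
    set.seed(derive_seed(31, r))
    s <- sample_minimal(p, 1500)
    pv <- suppressWarnings(
      chisq.test(table(s$PEB1, s$IV), correct = FALSE)$p.value)
    rej <- rej + (pv < 0.05)
  }
  rate <- rej / reps
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("parameter files round-trip losslessly in YAML and JSON", {
  p <- generative_params("continuous", phi1 = 0.123456789, beta_iv = 2.5,
                         phi22 = 1 / 3, sigma_peb1 = 1.7)
  for (ext in c("yaml", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_params(p, f)
    q <- read_params(f)
    expect_equal(q, p, tolerance = 1e-12)
    unlink(f)
  }
  f <- tempfile(fileext = ".yaml")
  writeLines(c("version: binary", "phi1: 1", "bogus_key: 2"), f)
  expect_error(read_params(f), "unknown parameter key")
  unlink(f)
})
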