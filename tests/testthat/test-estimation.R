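# LPM, 2SLS, probit, Rivers-Vuong and BH adjustment against exact and
# simulation oracles.

test_that("LPM reproduces exact fits and the hand-computed two-group slope", {
  Tt <- c(0, 0, 0, 1, 1, 1)
  f_exact <- fit_lpm(Tt, cbind(T = Tt))
  ct <- f_exact$coefficients
  expect_equal(ct$estimate[ct$term == "T"], 1)
  expect_equal(ct$estimate[ct$term == "(Intercept)"], 0)
  y <- c(0, 0, 1, 1, 0, 1)
  f <- fit_lpm(y, cbind(T = Tt))
  expect_equal(f$coefficients$estimate[f$coefficients$term == "T"], 1 / 3,
               tolerance = 1e-12)
})

test_that("LPM robust SEs match sandwich HC1 on an lm fit", {
  set.seed(10)
  x <- rbinom(200, 1, 0.5)
  w <- rnorm(200)
  y <- 0.3 * x + 0.2 * w + rnorm(200) * (1 + x)
  f <- fit_lpm(y, cbind(x = x, w = w))
  ref <- lm(y ~ x + w)
  se_ref <- sqrt(diag(sandwich::vcovHC(ref, type = "HC1")))
  expect_equal(f$coefficients$robust_se,
               unname(se_ref[c("(Intercept)", "x", "w")]),
               tolerance = 1e-10)
  expect_error(fit_lpm(y, cbind(x = x, x2 = 2 * x)), "collinearity")
})

test_that("2SLS equals OLS when the instrument is the endogenous regressor", {
  set.seed(11)
  x <- rnorm(80)
  y <- 1 + 0.5 * x + rnorm(80)
  f_iv <- fit_2sls(y, endogenous = cbind(x = x), instruments = cbind(x = x))
  f_ols <- lm(y ~ x)
  expect_equal(f_iv$coefficients$estimate, unname(coef(f_ols)),
               tolerance = 1e-10)
})

test_that("just-identified 2SLS equals the brute-force Wald estimator", {
  d <- fixed_iv_table()
  f <- fit_2sls(d$PEB2, endogenous = cbind(PEB1 = d$PEB1),
                instruments = cbind(IV = d$IV))
  expect_equal(f$coefficients$estimate[f$coefficients$term == "PEB1"],
               wald_oracle(d$PEB2, d$PEB1, d$IV), tolerance = 1e-12)
})

test_that("2SLS recovers the closed-form direct and mediated paths", {
  p <- generative_params("continuous", phi1 = 0.6, beta_u1 = 1,
                         beta_iv = 0.5, phi21 = 0.7, phi22 = 0.3,
                         beta_u2 = 1, attract_peb1 = 0, attract_peb2 = 0)
  eff <- closed_form_effects(p)
  s <- sample_dataset(p, 3e5, seed = 17)
  f <- fit_2sls(s$PEB2, endogenous = cbind(PEB1 = s$PEB1),
                instruments = cbind(IV = s$IV),
                exogenous = cbind(T = s$T))
  ct <- f$coefficients
  b_row <- ct[ct$term == "PEB1", ]
  d_row <- ct[ct$term == "T", ]
  expect_lt(abs(b_row$estimate - eff$peb1_on_peb2), 3 * b_row$robust_se)
  expect_lt(abs(d_row$estimate - eff$direct_t_on_peb2), 3 * d_row$robust_se)
  expect_gt(f$first_stage_F["PEB1"], 10)
})

test_that("first-stage robust F matches an independent Wald computation", {
  skip_if_not_installed("car")
  set.seed(12)
  n <- 400
  iv <- rbinom(n, 1, 0.5)
  tt <- rbinom(n, 1, 0.5)
  x <- 0.5 * iv + 0.2 * tt + rnorm(n)
  y <- 0.4 * x + 0.1 * tt + rnorm(n)
  f <- fit_2sls(y, endogenous = cbind(x = x), instruments = cbind(iv = iv),
                exogenous = cbind(T = tt))
  fs <- lm(x ~ iv + tt)
  ref <- car::linearHypothesis(fs, "iv = 0", white.adjust = "hc1")
  expect_equal(unname(f$first_stage_F["x"]), ref$F[2], tolerance = 1e-6)
})

test_that("BH step-up matches the hand-computed example and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)              # m = 1 unchanged
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))  # ties at top rank
  set.seed(14)
  for (i in 1:10) {
    p <- runif(sample(2:12, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "domain error")
})

test_that("probit intercept-only fits are the closed-form MLE", {
  y <- c(rep(1, 182), rep(0, 818))
  f <- fit_probit(y, design = matrix(nrow = 1000, ncol = 0))
  expect_equal(f$coefficients$estimate, qnorm(0.182), tolerance = 1e-6)
  y5 <- rep(c(0, 1), 500)
  f5 <- fit_probit(y5, design = matrix(nrow = 1000, ncol = 0))
  expect_equal(f5$coefficients$estimate, 0, tolerance = 1e-9)
})

test_that("probit recovers a known slope and flags separation", {
  set.seed(15)
  n <- 2e4
  x <- rnorm(n)
  y <- rbinom(n, 1, pnorm(-0.5 + 1 * x))
  f <- fit_probit(y, cbind(x = x))
  row <- f$coefficients[f$coefficients$term == "x", ]
  expect_lt(abs(row$estimate - 1), 3 * row$robust_se)
  xs <- c(rnorm(50, -3), rnorm(50, 3))
  ys <- as.integer(xs > 0)
  expect_error(fit_probit(ys, cbind(x = xs)), "separation|optimization")
})

test_that("Rivers-Vuong control function detects and corrects endogeneity", {
  set.seed(16)
  n <- 4e4
  z <- rnorm(n)
  v <- rnorm(n)
  x <- 0.8 * z + v
  e <- 0.6 * v + rnorm(n)   # Var(e | v) = 1, so probit scale is unchanged
  y <- as.integer(-0.3 + 0.5 * x + e > 0)
  f <- rivers_vuong_cf(y, endogenous = cbind(x = x),
                       instruments = cbind(z = z))
  row <- f$coefficients[f$coefficients$term == "x", ]
  expect_lt(abs(row$estimate - 0.5), 3 * row$robust_se)
  expect_lt(f$endogeneity_p, 0.01)   # endogeneity is real here
  # sign agreement with the 2SLS analogue on the same data
  f2 <- fit_2sls(y, endogenous = cbind(x = x), instruments = cbind(z = z))
  b2 <- f2$coefficients$estimate[f2$coefficients$term == "x"]
  expect_equal(sign(row$estimate), sign(b2))
})

test_that("Rivers-Vuong residual test holds its size under exogeneity", {
  reps <- 120
  rej <- 0
  for (r in seq_len(reps)) {
    set.seed(derive_seed(61, r))
    n <- 800
    z <- rnorm(n)
    x <- 0.8 * z + rnorm(n)       # exogenous: outcome error independent of v
    y <- as.integer(-0.2 + 0.5 * x + rnorm(n) > 0)
    f <- rivers_vuong_cf(y, endogenous = cbind(x = x),
                         instruments = cbind(z = z))
    rej <- rej + (f$endogeneity_p < 0.05)
  }
  rate <- rej / reps
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})
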