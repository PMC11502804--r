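# The synthetic respondent-table generator: schema invariants, marginal
# anchors, parameter recovery, and deterministic fixture output.

test_that("the default configuration reproduces the anchored marginals", {
  cfg <- experiment_design_config(n_study1 = 10000, seed = 5)
  d <- generate_experiment(cfg, studies = 1)
  n <- nrow(d)
  # ~70% uptake: 50.3% baseline + 38.9pp nudge on half the sample
  up_expected <- 0.503 + 0.389 / 2
  expect_lt(abs(mean(d$peb1_done) - up_expected),
            3 * sqrt(up_expected * (1 - up_expected) / n))
  expect_lt(abs(mean(d$peb2_signed) - 0.27),
            3 * sqrt(0.27 * 0.73 / n))
  # 85% of task takers complete all 30 rounds
  doers <- d[d$peb1_done == 1, ]
  expect_lt(abs(mean(doers$peb1_rounds == 30) - 0.85),
            3 * sqrt(0.85 * 0.15 / nrow(doers)))
  # health-domain signing rate in Study 3
  d3 <- generate_experiment(experiment_design_config(n_study3 = 10000,
                                                     seed = 6),
                            studies = 3)
  hh <- d3[d3$petition_health == 1, ]
  expect_lt(abs(mean(hh$peb2_signed) - 0.38),
            3 * sqrt(0.38 * 0.62 / nrow(hh)))
})

test_that("the LPM recovers the injected nudge effect on uptake", {
  cfg <- experiment_design_config(n_study1 = 10000, seed = 7)
  d <- generate_experiment(cfg, studies = 1)
  f <- fit_lpm(d$peb1_done, cbind(nudge = d$nudge_easy,
                                  treated = as.integer(d$arm %in%
                                                         c("winwin", "doom"))))
  row <- f$coefficients[f$coefficients$term == "nudge", ]
  expect_lt(abs(row$estimate - 0.389), 3 * row$robust_se)
})

test_that("injected behavior-on-behavior and arm effects are recoverable", {
  cfg <- experiment_design_config(n_study1 = 10000,
                                  peb1_sign_effect = 0.15,
                                  arm_uptake_effects = c(control = 0,
                                                         winwin = 0.10,
                                                         doom = 0),
                                  seed = 8)
  d <- generate_experiment(cfg, studies = 1)
  # 2SLS of signing on task uptake, instrumented by the nudge
  dd <- data.frame(T = as.integer(d$arm %in% c("winwin", "doom")),
                   IV = d$nudge_easy, PEB1 = d$peb1_done,
                   PEB2 = d$peb2_signed)
  dec <- decompose_spillover(dd, ci = FALSE)
  expect_lt(abs(dec$beta_prime["estimate"] - 0.15),
            3 * dec$beta_prime["robust_se"])
  # arm effect on uptake
  sub <- d[d$arm %in% c("winwin", "control"), ]
  f <- fit_lpm(sub$peb1_done,
               cbind(winwin = as.integer(sub$arm == "winwin"),
                     nudge = sub$nudge_easy))
  row <- f$coefficients[f$coefficients$term == "winwin", ]
  expect_lt(abs(row$estimate - 0.10), 3 * row$robust_se)
})

test_that("with no injected effects arm contrasts reject at about alpha", {
  reps <- 80
  rej <- 0
  for (r in seq_len(reps)) {
    cfg <- experiment_design_config(n_study1 = 1200,
                                    seed = derive_seed(71, r))
    d <- generate_experiment(cfg, studies = 1)
    sub <- d[d$arm %in% c("doom", "control"), ]
    f <- fit_lpm(sub$peb1_done,
                 cbind(doom = as.integer(sub$arm == "doom"),
                       nudge = sub$nudge_easy))
    pv <- f$coefficients$p_value[f$coefficients$term == "doom"]
    rej <- rej + (pv < 0.05)
  }
  rate <- rej / reps
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps) + 0.01)
})

test_that("covariates are balanced across randomized assignments", {
  reps <- 60
  rej <- 0
  for (r in seq_len(reps)) {
    cfg <- experiment_design_config(n_study1 = 1500,
                                    seed = derive_seed(73, r))
    d <- generate_experiment(cfg, studies = 1)
    pv <- suppressWarnings(
      chisq.test(table(d$gender, d$nudge_easy))$p.value)
    rej <- rej + (pv < 0.05)
  }
  expect_lt(abs(rej / reps - 0.05), 3 * sqrt(0.05 * 0.95 / reps) + 0.01)
})

test_that("generated tables satisfy all schema invariants", {
  d <- generate_experiment(experiment_design_config(
    n_study1 = 2000, n_study2 = 1000, n_study3 = 1000, seed = 9))
  expect_invisible(validate_experiment(d))
  expect_true(all(d$petition_health[d$study != 3] == 0))
  expect_true(all(d$difficulty_easy[d$study == 1] == 0))
  expect_true(all(d$arm[d$study != 1] %in% c("control", "doom")))
  expect_true(all(d$performance <= d$peb1_rounds / 30 + 1e-12))
  # a broken row is rejected with a named violation
  bad <- d
  bad$peb1_rounds[bad$peb1_done == 0][1] <- 5
  expect_error(validate_experiment(bad), "zero rounds")
})

test_that("generation is deterministic and infeasible configs are rejected", {
  cfg <- experiment_design_config(n_study1 = 800, seed = 10)
  expect_identical(generate_experiment(cfg, 1), generate_experiment(cfg, 1))
  expect_error(experiment_design_config(uptake_base = 0.8,
                                        nudge_effect = 0.3),
               "probability-overflow")
  expect_error(experiment_design_config(peb1_sign_effect = 0.9),
               "probability-overflow")
})

test_that("the fixture suite is a deterministic 3 x 3 grid of valid files", {
  dir1 <- file.path(tempdir(), "fx1")
  dir2 <- file.path(tempdir(), "fx2")
  cfg <- experiment_design_config()
  m1 <- write_fixture_suite(dir1, seed = 12, sizes = c(300, 800),
                            config = cfg)
  m2 <- write_fixture_suite(dir2, seed = 12, sizes = c(300, 800),
                            config = cfg)
  expect_equal(nrow(m1), 6)   # 3 studies x 2 sizes here
  expect_equal(m1$md5, m2$md5)
  f300 <- file.path(dir1, "experiment_study1_n300.csv")
  expect_invisible(validate_experiment(read_table(f300, "experiment")))
  expect_true(file.exists(file.path(dir1, "MANIFEST.json")))
  unlink(c(dir1, dir2), recursive = TRUE)
})
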