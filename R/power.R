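# Simulation-based power analysis: repeated sampling from a calibrated
# scenario over a grid of per-arm sample sizes, with one significance rule
# per estimand. The indirect spillover uses the studentized-bootstrap
# CI-excludes-zero decision exactly as the analysis plan prescribes; the
# other estimands use two-sided robust regression p-values at alpha.

power_estimands <- function() {
  c("t_on_peb1", "total_spillover", "direct_spillover",
    "indirect_spillover")
}

#' Settings for the power simulation
#'
#' @param reps Monte-Carlo replicates per grid cell (default 1000, >= 50).
#' @param alpha Significance level (default 0.05).
#' @param n_per_arm_grid Per-arm sample sizes; total n per replicate is
#'   `2 * n_per_arm` with a stochastic Bernoulli(0.5) split across arms.
#' @param bootstrap_B_inner Bootstrap resamples per replicate for the
#'   indirect-effect decision (default 999; 10,000 reproduces the headline
#'   procedure at higher cost).
#' @param seed Root seed; each replicate gets its own derived substream so
#'   cells are order-independent.
#' @param estimands Which estimands to evaluate (default all four).
#' @return A `power_settings` object.
#' @export
power_settings <- function(reps = 1000, alpha = 0.05,
                           n_per_arm_grid = c(150, 200, 250, 350, 500,
                                              750, 1000, 1250),
                           bootstrap_B_inner = 999, seed = 1,
                           estimands = power_estimands()) {
  reps <- as.integer(reps)
  if (reps < 50) stop("reps must be >= 50")
  if (!(alpha > 0 && alpha < 0.5)) stop("alpha must lie in (0, 0.5)")
  estimands <- match.arg(estimands, power_estimands(), several.ok = TRUE)
  structure(list(reps = reps, alpha = alpha,
                 n_per_arm_grid = as.integer(n_per_arm_grid),
                 bootstrap_B_inner = as.integer(bootstrap_B_inner),
                 seed = as.integer(seed), estimands = estimands),
            class = "power_settings")
}

# HC1-robust two-sided p-value for the slope of a simple regression of y on
# a binary x (the LPM / reduced-form significance rule), via group moments.
lpm_slope_p <- function(y, x) {
  n <- length(y)
  n1 <- sum(x); n0 <- n - n1
  if (n1 < 2 || n0 < 2) return(NA_real_)
  y1 <- y[x == 1L]; y0 <- y[x == 0L]
  b <- mean(y1) - mean(y0)
  s1 <- sum((y1 - mean(y1))^2); s0 <- sum((y0 - mean(y0))^2)
  se <- sqrt((s1 / n1^2 + s0 / n0^2) * n / (n - 2))
  if (se == 0) return(NA_real_)
  2 * stats::pnorm(-abs(b / se))
}

# HC1-robust p-value of delta' in the just-identified 2SLS (direct effect).
direct_effect_p <- function(Tt, IV, P1, P2) {
  fit <- tryCatch(
    tsls_core(P2, endo = matrix(P1, ncol = 1, dimnames = list(NULL, "PEB1")),
              inst = matrix(IV, ncol = 1, dimnames = list(NULL, "IV")),
              exog = cbind("(Intercept)" = 1, T = Tt)),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  z <- fit$coefficients["T"] / sqrt(fit$vcov["T", "T"])
  2 * stats::pnorm(-abs(z))
}

# Bootstrap CI-excludes-zero decision for the indirect effect, using the
# fast statistic and the RNG stream already set by the caller.
indirect_rejects <- function(Tt, IV, P1, P2, B, level) {
  base <- indirect_stat_fast(Tt, IV, P1, P2)
  if (is.null(base)) return(NA)
  n <- length(Tt)
  tstar <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    for (try in 1:100) {
      idx <- sample.int(n, n, replace = TRUE)
      sb <- indirect_stat_fast(Tt[idx], IV[idx], P1[idx], P2[idx])
      if (!is.null(sb) && is.finite(sb$indirect_se) && sb$indirect_se > 0) {
        tstar[b] <- (sb$indirect - base$indirect) / sb$indirect_se
        break
      }
    }
  }
  ok <- is.finite(tstar)
  if (sum(ok) < B / 2) return(NA)
  a <- 1 - level
  q <- stats::quantile(tstar[ok], c(1 - a / 2, a / 2), names = FALSE)
  lo <- base$indirect - base$indirect_se * q[1]
  hi <- base$indirect - base$indirect_se * q[2]
  (lo > 0) || (hi < 0)
}

#' Run the power simulation over a sample-size grid
#'
#' For each per-arm sample size and replicate, draws `2 * n_per_arm` units
#' from the generative model and records, per estimand, whether the study's
#' decision rule rejects: treatment-on-PEB1 and total spillover by HC1-robust
#' regression p < alpha, direct spillover by the 2SLS p-value of the
#' treatment coefficient, indirect spillover by the studentized bootstrap CI
#' excluding zero. Replicates where a decision is not computable (degenerate
#' columns) are dropped from that cell's denominator and counted in
#' `degenerate`; a cell with more than 5% degenerate replicates triggers a
#' warning.
#'
#' @param params A `generative_params` object (typically calibrated).
#' @param settings A [power_settings()] object.
#' @param scenario_label Optional label stored in the output.
#' @return A data frame with one row per (n_per_arm, estimand):
#'   `scenario`, `version`, `n_per_arm`, `estimand`, `reps`, `rejections`,
#'   `degenerate`, `power`, `mc_se`.
#' @export
run_power_grid <- function(params, settings = power_settings(),
                           scenario_label = NA_character_) {
  validate_params(params)
  est <- settings$estimands
  cells <- list()
  for (n_arm in settings$n_per_arm_grid) {
    n_tot <- 2L * n_arm
    rej <- stats::setNames(integer(length(est)), est)
    valid <- stats::setNames(integer(length(est)), est)
    for (r in seq_len(settings$reps)) {
      set.seed(derive_seed(settings$seed, n_arm * 100000 + r))
      s <- sample_minimal(params, n_tot)
      if ("t_on_peb1" %in% est) {
        p <- lpm_slope_p(s$PEB1, s$T)
        if (is.finite(p)) {
          valid["t_on_peb1"] <- valid["t_on_peb1"] + 1L
          rej["t_on_peb1"] <- rej["t_on_peb1"] + (p < settings$alpha)
        }
      }
      if ("total_spillover" %in% est) {
        p <- lpm_slope_p(s$PEB2, s$T)
        if (is.finite(p)) {
          valid["total_spillover"] <- valid["total_spillover"] + 1L
          rej["total_spillover"] <- rej["total_spillover"] +
            (p < settings$alpha)
        }
      }
      if ("direct_spillover" %in% est) {
        p <- direct_effect_p(s$T, s$IV, s$PEB1, s$PEB2)
        if (is.finite(p)) {
          valid["direct_spillover"] <- valid["direct_spillover"] + 1L
          rej["direct_spillover"] <- rej["direct_spillover"] +
            (p < settings$alpha)
        }
      }
      if ("indirect_spillover" %in% est) {
        dec <- indirect_rejects(s$T, s$IV, s$PEB1, s$PEB2,
                                B = settings$bootstrap_B_inner,
                                level = 1 - settings$alpha)
        if (!is.na(dec)) {
          valid["indirect_spillover"] <- valid["indirect_spillover"] + 1L
          rej["indirect_spillover"] <- rej["indirect_spillover"] + dec
        }
      }
    }
    for (e in est) {
      pw <- if (valid[e] > 0) rej[e] / valid[e] else NA_real_
      deg <- settings$reps - valid[e]
      if (deg > 0.05 * settings$reps) {
        warning(sprintf(
          "power cell n_per_arm=%d estimand=%s: %d of %d replicates degenerate",
          n_arm, e, deg, settings$reps))
      }
      cells[[length(cells) + 1]] <- data.frame(
        scenario = scenario_label, version = params$version,
        n_per_arm = n_arm, estimand = e,
        reps = valid[[e]], rejections = rej[[e]], degenerate = deg,
        power = unname(pw),
        mc_se = unname(sqrt(pw * (1 - pw) / valid[[e]])))
    }
  }
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  out
}

#' Sensitivity of power to the strength of the salience nudge
#'
#' Re-solves `beta_iv` so the measured nudge-on-PEB1 Cohen's d hits each
#' requested level (all other parameters held at the base calibration), then
#' runs the power grid for the direct and indirect spillover estimands at
#' each level.
#'
#' @param base Calibrated base parameters (the middle scenario in the study
#'   design).
#' @param iv_d_levels Target Cohen's d levels for the nudge effect on PEB1.
#' @param settings A [power_settings()] object (its `estimands` are
#'   overridden to the two spillover estimands).
#' @param calib Calibration settings used for the 1-D re-solve of `beta_iv`.
#' @return Long data frame of power cells with an extra `level` column.
#' @export
sensitivity_iv_strength <- function(base,
                                    iv_d_levels = c(0.2, 0.4, 0.6, 0.8),
                                    settings = power_settings(),
                                    calib = calibration_settings()) {
  validate_params(base)
  settings$estimands <- c("direct_spillover", "indirect_spillover")
  out <- list()
  for (lv in iv_d_levels) {
    set.seed(calib$seed)
    draws <- draw_noise(base$version, calib$n_inner)
    p_lv <- adjust_param(base, "beta_iv", "d_iv_peb1", lv, draws,
                         skip_tol = 0.3 * calib$tolerance)
    cells <- run_power_grid(p_lv, settings,
                            scenario_label = sprintf("iv_d=%.2g", lv))
    cells$level <- lv
    out[[length(out) + 1]] <- cells
  }
  do.call(rbind, out)
}

#' Sensitivity of power to the baseline attractiveness of a behavior
#'
#' Fixes the logit-scale attractiveness intercept of PEB1 or PEB2 at each
#' requested level (the defaults correspond to base probabilities of about
#' 0.01, 0.05, 0.10, 0.20 and 0.40), holding every other parameter at the
#' base calibration, and runs the power grid for the direct and indirect
#' spillover estimands. Binary version only.
#'
#' @param base Calibrated binary-version base parameters.
#' @param which `"peb1"` or `"peb2"`.
#' @param levels Logit-scale intercept levels.
#' @param settings A [power_settings()] object (estimands overridden as in
#'   [sensitivity_iv_strength()]).
#' @return Long data frame of power cells with an extra `level` column.
#' @export
sensitivity_attractiveness <- function(base, which = c("peb1", "peb2"),
                                       levels = c(-4.59512, -2.94439,
                                                  -2.19725, -1.3862,
                                                  -0.4045651),
                                       settings = power_settings()) {
  validate_params(base)
  which <- match.arg(which)
  if (base$version != "binary") {
    stop("attractiveness sensitivity is defined for the binary version only")
  }
  field <- if (which == "peb1") "attract_peb1" else "attract_peb2"
  settings$estimands <- c("direct_spillover", "indirect_spillover")
  out <- list()
  for (lv in levels) {
    p_lv <- base
    p_lv[[field]] <- lv
    cells <- run_power_grid(p_lv, settings,
                            scenario_label = sprintf("%s=%.5g", field, lv))
    cells$level <- lv
    out[[length(out) + 1]] <- cells
  }
  do.call(rbind, out)
}
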