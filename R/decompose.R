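# Spillover decomposition: total effect tau from OLS of PEB2 on T, direct
# effect delta' and behavior-on-behavior effect beta' from 2SLS of PEB2 on
# (instrumented) PEB1 and T, indirect effect tau - delta' with a studentized
# bootstrap CI. The pivot's standard error comes from the analytic sandwich
# of the stacked moment conditions of the two regressions sharing
# observations, so no inner bootstrap is needed.

#' Bootstrap settings for the indirect-effect confidence interval
#'
#' @param n_resamples Number of bootstrap resamples (default 10,000, the
#'   study's headline procedure; power loops typically use 999).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the resampling.
#' @param inner_se_method How the per-resample SE of the pivot is obtained;
#'   only `"stacked_sandwich"` (analytic sandwich of the stacked moment
#'   conditions) is implemented.
#' @return A `bootstrap_settings` list.
#' @export
bootstrap_settings <- function(n_resamples = 10000, level = 0.95, seed = 1,
                               inner_se_method = "stacked_sandwich") {
  n_resamples <- as.integer(n_resamples)
  if (n_resamples < 100) stop("n_resamples must be >= 100")
  if (!(level > 0 && level < 1)) stop("level must lie in (0, 1)")
  inner_se_method <- match.arg(inner_se_method, "stacked_sandwich")
  structure(list(n_resamples = n_resamples, level = level,
                 seed = as.integer(seed),
                 inner_se_method = inner_se_method),
            class = "bootstrap_settings")
}

# Fast indirect-effect statistic for the no-covariate binary-design case:
# columns T, IV (0/1) and PEB1, PEB2 (binary or continuous). Returns the
# point estimate tau - delta' and its stacked-sandwich SE, plus the
# component coefficients. Written with raw cross-moments so the bootstrap
# loop stays cheap. Returns NULL on a degenerate or singular input.
indirect_stat_fast <- function(Tt, IV, P1, P2) {
  n <- as.double(length(Tt))
  sT <- as.double(sum(Tt))
  sIV <- as.double(sum(IV))
  if (sT == 0 || sT == n || sIV == 0 || sIV == n) return(NULL)
  r1 <- range(P1)
  if (r1[1] == r1[2]) return(NULL)

  # scalar moments as doubles (cofactor products overflow integers)
  sP1 <- as.double(sum(P1)); sy <- as.double(sum(P2))
  sTy <- as.double(sum(Tt * P2))
  sIVy <- as.double(sum(IV * P2))
  sTP1 <- as.double(sum(Tt * P1))
  sIVP1 <- as.double(sum(IV * P1))
  sIVT <- as.double(sum(IV * Tt))

  # OLS of P2 on (1, T): gamma = mean in T=0, tau = mean difference
  gamma <- (sy - sTy) / (n - sT)
  tau <- sTy / sT - gamma
  e3 <- P2 - gamma - tau * Tt

  # just-identified 2SLS of P2 on (1, P1, T) with instruments (1, IV, T):
  # solve A2 b = r with A2[i, j] = Z_i . Xs_j via cofactors
  a11 <- n;   a12 <- sP1;   a13 <- sT
  a21 <- sIV; a22 <- sIVP1; a23 <- sIVT
  a31 <- sT;  a32 <- sTP1;  a33 <- sT
  C11 <- a22 * a33 - a23 * a32
  C12 <- a23 * a31 - a21 * a33
  C13 <- a21 * a32 - a22 * a31
  C21 <- a13 * a32 - a12 * a33
  C22 <- a11 * a33 - a13 * a31
  C23 <- a12 * a31 - a11 * a32
  C31 <- a12 * a23 - a13 * a22
  C32 <- a13 * a21 - a11 * a23
  C33 <- a11 * a22 - a12 * a21
  det2 <- a11 * C11 + a12 * C12 + a13 * C13
  if (!is.finite(det2) || abs(det2) < 1e-10 * n^3) return(NULL)
  r1v <- sy; r2v <- sIVy; r3v <- sTy
  alpha <- (C11 * r1v + C21 * r2v + C31 * r3v) / det2
  beta <- (C12 * r1v + C22 * r2v + C32 * r3v) / det2
  delta <- (C13 * r1v + C23 * r2v + C33 * r3v) / det2
  e2 <- P2 - alpha - beta * P1 - delta * Tt

  # stacked moment sandwich for (gamma, tau, alpha', beta', delta'):
  # var(tau - delta') = sum_i u_i^2 with u = (K1[2,] G1_i) - (K2[3,] G2_i),
  # G1_i = X3_i e3_i, G2_i = Z_i e2_i
  dK1 <- sT * (n - sT)
  w1 <- -sT / dK1; w2 <- n / dK1
  v1 <- -C13 / det2; v2 <- -C23 / det2; v3 <- -C33 / det2
  u <- e3 * (w1 + w2 * Tt) + e2 * (v1 + v2 * IV + v3 * Tt)
  v_ind <- sum(u * u)
  if (!is.finite(v_ind) || v_ind < 0) return(NULL)

  list(tau = tau, gamma = gamma,
       alpha_prime = alpha, beta_prime = beta, delta_prime = delta,
       indirect = tau - delta, indirect_se = sqrt(v_ind))
}

# Generic version allowing an exogenous covariate block (matrix X without
# intercept). Used when `exogenous` is supplied; the fast path above covers
# the common no-covariate case.
indirect_stat_general <- function(Tt, IV, P1, P2, X) {
  n <- length(Tt)
  X3 <- cbind(1, Tt, X)
  Z <- cbind(1, IV, Tt, X)
  Xs <- cbind(1, P1, Tt, X)
  b3 <- tryCatch(solve(crossprod(X3), crossprod(X3, P2)),
                 error = function(e) NULL)
  if (is.null(b3)) return(NULL)
  e3 <- drop(P2 - X3 %*% b3)
  A2 <- crossprod(Z, Xs)
  b2 <- tryCatch(solve(A2, crossprod(Z, P2)), error = function(e) NULL)
  if (is.null(b2)) return(NULL)
  e2 <- drop(P2 - Xs %*% b2)
  K1 <- solve(crossprod(X3))
  K2 <- solve(A2)
  G <- cbind(X3 * e3, Z * e2)
  Bmat <- crossprod(G)
  # weight vector picking tau (block 1) minus delta' (block 2)
  w <- c(K1[2, ], -K2[3, ])
  v_ind <- drop(crossprod(w, Bmat %*% w))
  if (!is.finite(v_ind) || v_ind < 0) return(NULL)
  list(tau = b3[2], gamma = b3[1],
       alpha_prime = b2[1], beta_prime = b2[2], delta_prime = b2[3],
       indirect = b3[2] - b2[3], indirect_se = sqrt(v_ind))
}

extract_exog <- function(data, exogenous) {
  if (is.null(exogenous)) return(NULL)
  if (is.character(exogenous)) {
    miss <- setdiff(exogenous, names(data))
    if (length(miss)) stop("exogenous column(s) not in data: ",
                           paste(miss, collapse = ", "))
    X <- as.matrix(data[exogenous])
  } else {
    X <- as_design_matrix(exogenous, "x")
  }
  X
}

check_decomposable <- function(Tt, IV, P1) {
  if (length(unique(Tt)) < 2) stop("both treatment groups must be non-empty")
  if (length(unique(IV)) < 2) stop("both instrument groups must be non-empty")
  r <- range(P1)
  if (r[1] == r[2]) {
    stop("degenerate-behavior: PEB1 is constant (all ", r[1],
         "); the first stage is not identified")
  }
  invisible(TRUE)
}

#' Decompose a treatment's total spillover into direct and indirect parts
#'
#' Estimates the total spillover effect `tau` of the treatment on the
#' non-targeted behavior (OLS of PEB2 on T, HC1 robust), the direct effect
#' `delta_prime` and the behavior-on-behavior effect `beta_prime` (2SLS of
#' PEB2 on PEB1 and T with PEB1 instrumented by the salience nudge), and the
#' indirect effect `tau - delta_prime` with a studentized bootstrap
#' confidence interval. The indirect effect is declared significant iff the
#' CI excludes zero.
#'
#' @param data Data frame with columns `T`, `IV`, `PEB1`, `PEB2` (a
#'   `simulated_sample` works directly).
#' @param exogenous Optional extra exogenous covariates: column names in
#'   `data` or a numeric matrix (no intercept; it is added internally).
#' @param settings A [bootstrap_settings()] object.
#' @param ci Compute the studentized bootstrap CI (set to `FALSE` for point
#'   estimates only, e.g. inside calibration loops).
#' @return A `spillover_decomposition`: named coefficient vectors `tau`,
#'   `delta_prime`, `beta_prime` (each with `estimate`, `robust_se`,
#'   `p_value`), `indirect` (point estimate `tau - delta_prime`),
#'   `indirect_se` (stacked-sandwich SE), `indirect_ci95`, `first_stage_F`,
#'   `n`, and `n_bootstrap`.
#' @export
decompose_spillover <- function(data, exogenous = NULL,
                                settings = bootstrap_settings(),
                                ci = TRUE) {
  need <- c("T", "IV", "PEB1", "PEB2")
  if (!all(need %in% names(data))) {
    stop("data must contain columns ", paste(need, collapse = ", "))
  }
  Tt <- as.numeric(data$T); IV <- as.numeric(data$IV)
  P1 <- as.numeric(data$PEB1); P2 <- as.numeric(data$PEB2)
  check_decomposable(Tt, IV, P1)
  X <- extract_exog(data, exogenous)

  exog <- if (is.null(X)) {
    matrix(1, length(Tt), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    cbind("(Intercept)" = 1, X)
  }
  # total effect: OLS of PEB2 on T (model of the reduced form)
  lpm_tot <- fit_lpm(P2, cbind(T = Tt, X), add_intercept = TRUE)
  tau_row <- lpm_tot$coefficients[lpm_tot$coefficients$term == "T", ]
  # 2SLS with residuals at the original PEB1 values
  ts <- tsls_core(P2, endo = matrix(P1, ncol = 1,
                                    dimnames = list(NULL, "PEB1")),
                  inst = matrix(IV, ncol = 1, dimnames = list(NULL, "IV")),
                  exog = cbind(exog, T = Tt))
  se2 <- sqrt(diag(ts$vcov))
  stat <- if (is.null(X)) indirect_stat_fast(Tt, IV, P1, P2) else
    indirect_stat_general(Tt, IV, P1, P2, X)
  if (is.null(stat)) stop("degenerate-behavior: decomposition not computable")

  as_coef <- function(est, se) {
    z <- est / se
    c(estimate = est, robust_se = se, t_stat = z,
      p_value = 2 * stats::pnorm(-abs(z)),
      ci_low = est - stats::qnorm(0.975) * se,
      ci_high = est + stats::qnorm(0.975) * se)
  }
  out <- list(
    tau = as_coef(tau_row$estimate, tau_row$robust_se),
    delta_prime = as_coef(unname(ts$coefficients["T"]), unname(se2["T"])),
    beta_prime = as_coef(unname(ts$coefficients["PEB1"]),
                         unname(se2["PEB1"])),
    indirect = unname(tau_row$estimate - ts$coefficients["T"]),
    indirect_se = stat$indirect_se,
    indirect_ci95 = c(NA_real_, NA_real_),
    first_stage_F = unname(ts$first_stage_F["PEB1"]),
    n = length(Tt), n_bootstrap = 0L,
    settings = settings
  )
  if (ci) {
    bci <- studentized_bootstrap_ci(data, statistic = NULL,
                                    settings = settings,
                                    exogenous = exogenous)
    out$indirect_ci95 <- unname(bci)
    out$n_bootstrap <- attr(bci, "n_resamples")
  }
  class(out) <- "spillover_decomposition"
  out
}

#' @export
print.spillover_decomposition <- function(x, ...) {
  cat("Spillover decomposition, n =", x$n, "\n")
  f <- function(nm, v) {
    cat(sprintf("  %-22s %8.4f  (robust SE %.4f, p = %.4f)\n",
                nm, v["estimate"], v["robust_se"], v["p_value"]))
  }
  f("total (tau)", x$tau)
  f("direct (delta')", x$delta_prime)
  f("PEB1 effect (beta')", x$beta_prime)
  cat(sprintf("  %-22s %8.4f  (stacked-sandwich SE %.4f)\n",
              "indirect (tau-delta')", x$indirect, x$indirect_se))
  if (!anyNA(x$indirect_ci95)) {
    cat(sprintf("    studentized bootstrap CI [%0.4f, %0.4f] (B = %d)\n",
                x$indirect_ci95[1], x$indirect_ci95[2], x$n_bootstrap))
  }
  cat(sprintf("  first-stage robust F = %.1f\n", x$first_stage_F))
  invisible(x)
}

#' Studentized bootstrap confidence interval for the indirect effect
#'
#' Resamples units with replacement; per resample computes the pivot
#' `t* = (theta* - theta_hat) / se*`, where by default `theta` is the
#' indirect spillover effect `tau - delta_prime` and `se` its analytic
#' sandwich from the stacked moment conditions of the two regressions.
#' The interval is `theta_hat - se_hat * q(t*, (1 + level) / 2)` to
#' `theta_hat - se_hat * q(t*, (1 - level) / 2)`. Resamples with a
#' degenerate treatment, instrument, or first-behavior column are redrawn
#' (up to 100 times each, then counted invalid); if fewer than half the
#' requested resamples are valid the bootstrap fails with an error.
#'
#' @param data As in [decompose_spillover()].
#' @param statistic Optional custom statistic: `function(data) c(est, se)`.
#'   The default is the internal indirect-effect statistic.
#' @param settings A [bootstrap_settings()] object.
#' @param exogenous Passed to the default statistic.
#' @return Numeric `c(lower, upper)` with attributes `n_resamples` (valid
#'   resamples used) and `t_quantiles`.
#' @export
studentized_bootstrap_ci <- function(data, statistic = NULL,
                                     settings = bootstrap_settings(),
                                     exogenous = NULL) {
  Tt <- as.numeric(data$T); IV <- as.numeric(data$IV)
  P1 <- as.numeric(data$PEB1); P2 <- as.numeric(data$PEB2)
  X <- extract_exog(data, exogenous)
  n <- length(Tt)
  use_default <- is.null(statistic)

  stat0 <- if (use_default) {
    s <- if (is.null(X)) indirect_stat_fast(Tt, IV, P1, P2) else
      indirect_stat_general(Tt, IV, P1, P2, X)
    if (is.null(s)) stop("degenerate-behavior: statistic not computable ",
                         "on the original sample")
    c(s$indirect, s$indirect_se)
  } else {
    statistic(data)
  }
  theta <- stat0[1]; se <- stat0[2]
  if (!is.finite(se) || se <= 0) {
    stop("bootstrap-failure: statistic SE not computable on original sample")
  }

  set.seed(settings$seed)
  B <- settings$n_resamples
  tstar <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    for (try in 1:100) {
      idx <- sample.int(n, n, replace = TRUE)
      sb <- if (use_default) {
        if (is.null(X)) {
          indirect_stat_fast(Tt[idx], IV[idx], P1[idx], P2[idx])
        } else {
          indirect_stat_general(Tt[idx], IV[idx], P1[idx], P2[idx],
                                X[idx, , drop = FALSE])
        }
      } else {
        res <- tryCatch(statistic(data[idx, , drop = FALSE]),
                        error = function(e) NULL)
        if (is.null(res)) NULL else list(indirect = res[1],
                                         indirect_se = res[2])
      }
      if (!is.null(sb) && is.finite(sb$indirect_se) &&
            sb$indirect_se > 0) {
        tstar[b] <- (sb$indirect - theta) / sb$indirect_se
        break
      }
    }
  }
  ok <- is.finite(tstar)
  if (sum(ok) < B / 2) {
    stop("bootstrap-failure: only ", sum(ok), " of ", B,
         " resamples produced a valid studentized pivot")
  }
  alpha <- 1 - settings$level
  q <- stats::quantile(tstar[ok], c(1 - alpha / 2, alpha / 2), names = FALSE)
  # degenerate case: pivot identically 0 collapses to the point estimate
  ci <- c(theta - se * q[1], theta - se * q[2])
  attr(ci, "n_resamples") <- sum(ok)
  attr(ci, "t_quantiles") <- q
  ci
}

#' Moderated spillover decomposition (two endogenous regressors)
#'
#' Fits the two-equation first stage with excluded instruments `IV` and
#' `IV x moderator`, endogenous regressors `PEB1` and `PEB1 x moderator`,
#' and a second stage of PEB2 on both instrumented regressors plus the
#' exogenous block. Under the `"difficulty"` contract the exogenous block is
#' `(1, T)`; under the `"domain"` contract it additionally includes
#' `T x moderator`, whose coefficient estimates the difference in the direct
#' treatment effect between domains. The coefficient on the instrumented
#' interaction answers whether the behavior-on-behavior effect differs
#' across moderator strata.
#'
#' @param data Data frame with columns `T`, `IV`, `PEB1`, `PEB2`.
#' @param moderator Binary moderator: a column name in `data` or a vector.
#' @param contract `"difficulty"` (no T-by-moderator term) or `"domain"`
#'   (with it).
#' @param moderator_name Label stored in the result (defaults to the column
#'   name or `"moderator"`).
#' @return A `moderated_2sls` object: `coefficients` table,
#'   `first_stage_F` (one robust Wald F per endogenous regressor),
#'   `moderator_name`, `contract`, `n`.
#' @export
fit_moderated_2sls <- function(data, moderator,
                               contract = c("difficulty", "domain"),
                               moderator_name = NULL) {
  contract <- match.arg(contract)
  if (is.character(moderator) && length(moderator) == 1) {
    if (!moderator %in% names(data)) {
      stop("moderator column not in data: ", moderator)
    }
    if (is.null(moderator_name)) moderator_name <- moderator
    m <- as.numeric(data[[moderator]])
  } else {
    m <- as.numeric(moderator)
    if (is.null(moderator_name)) moderator_name <- "moderator"
  }
  if (length(unique(m)) < 2) {
    stop("no-moderation error: the moderator is constant")
  }
  Tt <- as.numeric(data$T); IV <- as.numeric(data$IV)
  P1 <- as.numeric(data$PEB1); P2 <- as.numeric(data$PEB2)
  check_decomposable(Tt, IV, P1)
  if (length(unique(P1 * m)) < 2) {
    stop("degenerate-behavior: PEB1 x moderator is constant")
  }
  endo <- cbind(PEB1 = P1, "PEB1:m" = P1 * m)
  colnames(endo) <- c("PEB1", paste0("PEB1:", moderator_name))
  inst <- cbind(IV = IV, "IV:m" = IV * m)
  colnames(inst) <- c("IV", paste0("IV:", moderator_name))
  exog <- cbind("(Intercept)" = 1, T = Tt)
  if (contract == "domain") {
    exog <- cbind(exog, "T:m" = Tt * m)
    colnames(exog)[3] <- paste0("T:", moderator_name)
  }
  fit <- tsls_core(P2, endo, inst, exog)
  out <- list(coefficients = coef_table(fit$coefficients,
                                        sqrt(diag(fit$vcov)),
                                        names(fit$coefficients)),
              first_stage_F = fit$first_stage_F,
              moderator_name = moderator_name, contract = contract,
              n = fit$n, vcov = fit$vcov)
  class(out) <- "moderated_2sls"
  out
}

#' @export
print.moderated_2sls <- function(x, ...) {
  cat("Moderated 2SLS (", x$contract, " contract, moderator = ",
      x$moderator_name, "), n = ", x$n, "\n", sep = "")
  print(x$coefficients, digits = 4, row.names = FALSE)
  cat("First-stage robust F:",
      paste(sprintf("%s = %.1f", names(x$first_stage_F), x$first_stage_F),
            collapse = ", "), "\n")
  invisible(x)
}
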