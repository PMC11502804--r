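# Analysis-plan estimators: linear probability models with HC1 robust
# standard errors, generic 2SLS (one or two endogenous regressors), probit
# and the Rivers-Vuong control-function robustness check, and the BH step-up
# correction. OLS robust inference is delegated to sandwich/lmtest; 2SLS is
# implemented here with base matrix algebra (no IV package is assumed).

as_design_matrix <- function(design, default_name = "x") {
  if (is.null(design)) return(NULL)
  if (is.data.frame(design)) design <- as.matrix(design)
  if (is.vector(design)) {
    design <- matrix(design, ncol = 1,
                     dimnames = list(NULL, default_name))
  }
  if (ncol(design) > 0 && is.null(colnames(design))) {
    colnames(design) <- paste0(default_name, seq_len(ncol(design)))
  }
  storage.mode(design) <- "double"
  design
}

check_full_rank <- function(X, what = "design") {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinearity error: ", what, " is rank deficient; offending ",
         "column(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

coef_table <- function(est, se, terms, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  t_stat <- est / se
  data.frame(term = terms,
             estimate = unname(est),
             robust_se = unname(se),
             t_stat = unname(t_stat),
             p_value = 2 * stats::pnorm(-abs(unname(t_stat))),
             ci_low = unname(est - z * se),
             ci_high = unname(est + z * se),
             stringsAsFactors = FALSE)
}

#' Linear probability model with HC1-robust inference
#'
#' OLS of a (typically binary) outcome on a user-supplied design, with
#' heteroskedasticity-robust (HC1) standard errors and two-sided p-values
#' from the standard-normal reference.
#'
#' @param y Outcome vector.
#' @param design Regressor table (data frame or matrix) including the
#'   intercept column, or omitted entirely via `~`-style wrappers. If
#'   `add_intercept` is `TRUE` an intercept column is prepended.
#' @param add_intercept Prepend an intercept column (default `TRUE` when no
#'   column named `(Intercept)` is present).
#' @return An object of class `lpm_fit` with elements `coefficients` (a data
#'   frame with `term`, `estimate`, `robust_se`, `t_stat`, `p_value`,
#'   `ci_low`, `ci_high`), `vcov`, and `n`.
#' @export
fit_lpm <- function(y, design, add_intercept = !("(Intercept)" %in%
                                                   colnames(as_design_matrix(design)))) {
  X <- as_design_matrix(design, default_name = "x")
  if (add_intercept) X <- cbind("(Intercept)" = 1, X)
  n <- length(y)
  if (nrow(X) != n) stop("y and design have different numbers of rows")
  if (n <= ncol(X)) stop("insufficient-data: need n > number of regressors")
  check_full_rank(X)
  dat <- as.data.frame(X, optional = TRUE)
  dat$.y <- as.numeric(y)
  fit <- stats::lm(.y ~ 0 + ., data = dat)
  V <- sandwich::vcovHC(fit, type = "HC1")
  ct <- lmtest::coeftest(fit, vcov. = V, df = Inf)
  out <- list(coefficients = coef_table(ct[, 1], ct[, 2],
                                        terms = colnames(X)),
              vcov = V, n = n, fitted = stats::fitted(fit),
              residuals = stats::residuals(fit))
  class(out) <- "lpm_fit"
  out
}

#' @export
print.lpm_fit <- function(x, ...) {
  cat("Linear probability model (HC1 robust), n =", x$n, "\n")
  print(x$coefficients, digits = 4, row.names = FALSE)
  invisible(x)
}

# Core 2SLS computation shared by fit_2sls, the spillover decomposition and
# the moderated models. Robust covariance uses residuals at the ORIGINAL
# endogenous values with HC1 scaling; the first-stage F per endogenous
# regressor is the heteroskedasticity-robust Wald F of the excluded
# instruments.
tsls_core <- function(y, endo, inst, exog) {
  n <- length(y)
  Xs <- cbind(exog, endo)      # structural design
  Z <- cbind(exog, inst)       # instrument set
  if (ncol(Z) < ncol(Xs)) {
    stop("identification error: fewer instruments than endogenous regressors")
  }
  check_full_rank(Z, what = "instrument block")
  ZtZ <- crossprod(Z)
  ZtXs <- crossprod(Z, Xs)
  Xhat <- Z %*% solve(ZtZ, ZtXs)
  Bm <- crossprod(Xhat, Xs)
  Bm_inv <- tryCatch(solve(Bm), error = function(e) {
    stop("identification error: first stage numerically singular ",
         "(weak or collinear instruments)")
  })
  b <- drop(Bm_inv %*% crossprod(Xhat, y))
  e <- drop(y - Xs %*% b)
  k <- ncol(Xs)
  meat <- crossprod(Xhat * e)
  V <- Bm_inv %*% meat %*% t(Bm_inv) * n / (n - k)
  dimnames(V) <- list(colnames(Xs), colnames(Xs))
  names(b) <- colnames(Xs)

  # robust first-stage Wald F of the excluded instruments, per endogenous col
  p_inst <- ncol(inst)
  fs_F <- vapply(seq_len(ncol(endo)), function(j) {
    bz <- solve(ZtZ, crossprod(Z, endo[, j]))
    ez <- drop(endo[, j] - Z %*% bz)
    ZtZ_inv <- solve(ZtZ)
    Vz <- ZtZ_inv %*% crossprod(Z * ez) %*% ZtZ_inv * n / (n - ncol(Z))
    idx <- ncol(exog) + seq_len(p_inst)
    bi <- bz[idx]
    drop(t(bi) %*% solve(Vz[idx, idx, drop = FALSE]) %*% bi) / p_inst
  }, numeric(1))
  names(fs_F) <- colnames(endo)

  list(coefficients = b, vcov = V, residuals = e, first_stage_F = fs_F,
       n = n, k_exog = ncol(exog))
}

#' Two-stage least squares with robust inference
#'
#' Classical 2SLS for one or two endogenous regressors (just- or
#' over-identified). The second-stage robust covariance is the HC1 sandwich
#' computed with residuals at the original (not fitted) endogenous values;
#' the reported first-stage F is the robust Wald F of the excluded
#' instruments in each first-stage regression.
#'
#' @param y Outcome vector.
#' @param endogenous Endogenous regressor(s): vector, matrix, or data frame.
#' @param instruments Excluded instrument(s), at least as many columns as
#'   `endogenous`.
#' @param exogenous Optional exogenous block (intercept is added when the
#'   block is missing or lacks an `(Intercept)` column).
#' @return An object of class `tsls_fit` with `coefficients` (term-level data
#'   frame), `vcov`, `first_stage_F` (one per endogenous regressor), and `n`.
#' @export
fit_2sls <- function(y, endogenous, instruments, exogenous = NULL) {
  endo <- as_design_matrix(endogenous, "endo")
  inst <- as_design_matrix(instruments, "iv")
  exog <- as_design_matrix(exogenous, "x")
  if (is.null(exog)) {
    exog <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else if (!("(Intercept)" %in% colnames(exog))) {
    exog <- cbind("(Intercept)" = 1, exog)
  }
  fit <- tsls_core(as.numeric(y), endo, inst, exog)
  out <- list(coefficients = coef_table(fit$coefficients,
                                        sqrt(diag(fit$vcov)),
                                        names(fit$coefficients)),
              vcov = fit$vcov, first_stage_F = fit$first_stage_F,
              n = fit$n, residuals = fit$residuals)
  class(out) <- "tsls_fit"
  out
}

#' @export
print.tsls_fit <- function(x, ...) {
  cat("2SLS fit (HC1 robust, residuals at original endogenous values), n =",
      x$n, "\n")
  print(x$coefficients, digits = 4, row.names = FALSE)
  cat("First-stage robust F:",
      paste(sprintf("%s = %.1f", names(x$first_stage_F), x$first_stage_F),
            collapse = ", "), "\n")
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classical FDR step-up adjustment (sorted ascending,
#' `adjusted(i) = min over j >= i of min(1, p(j) * m / j)`), returned in the
#' original order. Significance under the study's inference criteria is
#' declared at adjusted p < 0.05.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("domain error: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Maximum-likelihood probit fit
#'
#' Probit regression by iteratively reweighted least squares, with standard
#' errors from the inverse information matrix and two-sided normal p-values.
#' Used as the non-linear robustness check for the linear probability models.
#'
#' @param y Binary outcome vector (both classes must be present).
#' @param design Regressor table; an intercept is prepended unless a column
#'   named `(Intercept)` is already present.
#' @return An object of class `probit_fit` with a `coefficients` table and
#'   the underlying `glm` object.
#' @export
fit_probit <- function(y, design) {
  X <- as_design_matrix(design, "x")
  if (!("(Intercept)" %in% colnames(X))) X <- cbind("(Intercept)" = 1, X)
  y <- as.numeric(y)
  if (length(unique(y[!is.na(y)])) < 2) {
    stop("degenerate-outcome: y must contain both classes")
  }
  check_full_rank(X)
  dat <- as.data.frame(X, optional = TRUE)
  dat$.y <- y
  fit <- suppressWarnings(
    stats::glm(.y ~ 0 + ., family = stats::binomial(link = "probit"),
               data = dat)
  )
  if (!fit$converged) {
    stop("optimization error: probit IRLS did not converge (",
         fit$iter, " iterations)")
  }
  eta <- stats::predict(fit, type = "link")
  if (max(abs(eta)) > 12) {
    stop("separation error: fitted probit index diverges ",
         "(perfect or quasi-perfect separation)")
  }
  sm <- summary(fit)$coefficients
  out <- list(coefficients = coef_table(sm[, 1], sm[, 2], colnames(X)),
              glm = fit, n = length(y))
  class(out) <- "probit_fit"
  out
}

#' @export
print.probit_fit <- function(x, ...) {
  cat("Probit fit, n =", x$n, "\n")
  print(x$coefficients, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Rivers-Vuong control-function estimator
#'
#' Two-step control-function estimator for a binary outcome with a
#' (possibly) endogenous regressor: step one regresses the endogenous
#' variable on the instruments and exogenous block by OLS; step two fits a
#' probit of the outcome on the endogenous regressor, the exogenous block,
#' and the first-stage residual. The z-test on the residual term is the
#' endogeneity diagnostic (a non-significant residual is consistent with
#' exogeneity).
#'
#' @param y Binary outcome.
#' @param endogenous Single endogenous regressor (vector).
#' @param instruments Excluded instrument(s).
#' @param exogenous Optional exogenous block (intercept handled as in
#'   [fit_2sls()]).
#' @return An object of class `rivers_vuong_fit`: `coefficients` table (the
#'   control-function residual term is named `first_stage_residual`),
#'   `endogeneity_p` for the residual z-test, and the first-stage `lm`.
#' @export
rivers_vuong_cf <- function(y, endogenous, instruments, exogenous = NULL) {
  endo <- as_design_matrix(endogenous, "endo")
  if (ncol(endo) != 1) stop("rivers_vuong_cf handles one endogenous regressor")
  inst <- as_design_matrix(instruments, "iv")
  exog <- as_design_matrix(exogenous, "x")
  if (is.null(exog)) {
    exog <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else if (!("(Intercept)" %in% colnames(exog))) {
    exog <- cbind("(Intercept)" = 1, exog)
  }
  Z <- cbind(exog, inst)
  check_full_rank(Z, "instrument block")
  b1 <- qr.solve(Z, endo[, 1])
  vhat <- endo[, 1] - drop(Z %*% b1)
  X2 <- cbind(exog, endo, first_stage_residual = vhat)
  pf <- fit_probit(y, X2)
  res_row <- pf$coefficients[pf$coefficients$term == "first_stage_residual", ]
  out <- list(coefficients = pf$coefficients,
              endogeneity_p = res_row$p_value,
              first_stage_coef = b1, n = length(y))
  class(out) <- "rivers_vuong_fit"
  out
}

#' @export
print.rivers_vuong_fit <- function(x, ...) {
  cat("Rivers-Vuong control-function probit, n =", x$n, "\n")
  print(x$coefficients, digits = 4, row.names = FALSE)
  cat(sprintf("Endogeneity diagnostic (residual z-test): p = %.4f\n",
              x$endogeneity_p))
  invisible(x)
}
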