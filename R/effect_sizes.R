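# Cohen's d machinery. All scenario targets are stated as standardized mean
# differences with the classical pooled SD (unbiased group variances, no
# small-sample correction).

#' Cohen's d for a two-group comparison
#'
#' Standardized mean difference `(mean(y | g = 1) - mean(y | g = 0)) / s_p`
#' with the pooled standard deviation
#' `s_p = sqrt(((n1 - 1) s1^2 + (n0 - 1) s0^2) / (n1 + n0 - 2))` using
#' unbiased group variances. Binary outcomes are handled like any other
#' numeric outcome.
#'
#' @param y Numeric (or 0/1) outcome vector.
#' @param g Binary grouping vector (0/1 or logical), same length as `y`.
#' @return Cohen's d (scalar).
#' @examples
#' cohens_d_by_group(c(0, 1, 1, 1, 0, 0, 0, 1), rep(c(1, 0), each = 4))
#' @export
cohens_d_by_group <- function(y, g) {
  if (length(y) != length(g)) stop("y and g must have the same length")
  g <- as.integer(as.logical(g))
  y1 <- y[g == 1L]; y0 <- y[g == 0L]
  n1 <- length(y1); n0 <- length(y0)
  if (n1 < 2 || n0 < 2) {
    stop("insufficient-data: each group needs at least 2 units (n1 = ",
         n1, ", n0 = ", n0, ")")
  }
  sp2 <- ((n1 - 1) * stats::var(y1) + (n0 - 1) * stats::var(y0)) /
    (n1 + n0 - 2)
  if (sp2 <= 0) stop("degenerate-outcome: zero pooled variance")
  (mean(y1) - mean(y0)) / sqrt(sp2)
}

pooled_sd_by_group <- function(y, g) {
  g <- as.integer(as.logical(g))
  y1 <- y[g == 1L]; y0 <- y[g == 0L]
  n1 <- length(y1); n0 <- length(y0)
  if (n1 < 2 || n0 < 2) stop("insufficient-data: each group needs >= 2 units")
  sqrt(((n1 - 1) * stats::var(y1) + (n0 - 1) * stats::var(y0)) /
         (n1 + n0 - 2))
}

new_effect_size_set <- function(d_t_peb1, d_iv_peb1, d_total_peb2,
                                d_direct_peb2) {
  es <- list(d_t_peb1 = d_t_peb1,
             d_iv_peb1 = d_iv_peb1,
             d_total_peb2 = d_total_peb2,
             d_direct_peb2 = d_direct_peb2,
             # indirect d is defined by the subtraction rule, exactly
             d_indirect_peb2 = d_total_peb2 - d_direct_peb2)
  class(es) <- "effect_size_set"
  es
}

#' @export
print.effect_size_set <- function(x, ...) {
  cat("Effect sizes (Cohen's d):\n")
  cat(sprintf("  T  -> PEB1          : %8.4f\n", x$d_t_peb1))
  cat(sprintf("  IV -> PEB1          : %8.4f\n", x$d_iv_peb1))
  cat(sprintf("  total   T -> PEB2   : %8.4f\n", x$d_total_peb2))
  cat(sprintf("  direct  T -> PEB2   : %8.4f\n", x$d_direct_peb2))
  cat(sprintf("  indirect T -> PEB2  : %8.4f  (total - direct)\n",
              x$d_indirect_peb2))
  invisible(x)
}

#' Measure the scenario effect sizes on a simulated sample
#'
#' Computes the five standardized effect sizes that define a power scenario:
#' group-difference Cohen's d of PEB1 by treatment and by nudge, the
#' group-difference d of PEB2 by treatment (total spillover), the direct
#' spillover d, and the indirect spillover d. The direct d is the 2SLS
#' direct-effect coefficient (delta-prime from the decomposition) divided by
#' the pooled SD of PEB2 across treatment groups; the indirect d then follows
#' from the subtraction rule `indirect = total - direct`, which therefore
#' holds exactly by construction.
#'
#' @param sample A `simulated_sample` (or any data frame with columns `T`,
#'   `IV`, `PEB1`, `PEB2`).
#' @param decomposition Optional `spillover_decomposition` for the same
#'   sample; computed (without bootstrap CI) if omitted.
#' @return An `effect_size_set`.
#' @export
measure_effect_sizes <- function(sample, decomposition = NULL) {
  need <- c("T", "IV", "PEB1", "PEB2")
  if (!all(need %in% names(sample))) {
    stop("sample must contain columns ", paste(need, collapse = ", "))
  }
  if (is.null(decomposition)) {
    decomposition <- decompose_spillover(sample, ci = FALSE)
  }
  d_t_peb1 <- cohens_d_by_group(sample$PEB1, sample$T)
  d_iv_peb1 <- cohens_d_by_group(sample$PEB1, sample$IV)
  d_total <- cohens_d_by_group(sample$PEB2, sample$T)
  d_direct <- decomposition$delta_prime["estimate"] /
    pooled_sd_by_group(sample$PEB2, sample$T)
  new_effect_size_set(d_t_peb1, d_iv_peb1, d_total, unname(d_direct))
}
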