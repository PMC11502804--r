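# Table I/O and assembly of publication-style result tables. CSV is the
# single interchange format; output files carry a provenance header comment
# (package version, seed, config hash) and readers skip '#' comment lines.

#' Read and validate a tabular input file
#'
#' Reads a CSV (comment lines starting with `#` are skipped) and validates
#' it against one of the two supported schemas: `"simulated"` (columns `T`,
#' `IV`, `PEB1`, `PEB2`, optionally `unit_id`, `U1`, `U2`, `p_peb1`,
#' `p_peb2`) or `"experiment"` (the respondent schema checked by
#' [validate_experiment()]). Row order is preserved. Schema violations
#' report the offending rule, row and column.
#'
#' @param path CSV file path.
#' @param schema `"simulated"` or `"experiment"`.
#' @return The validated data frame.
#' @export
read_table <- function(path, schema = c("simulated", "experiment")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty-input: ", path, " contains no data rows")
  if (schema == "simulated") {
    need <- c("T", "IV", "PEB1", "PEB2")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("schema violation: missing column(s): ",
           paste(miss, collapse = ", "))
    }
    for (col in need) {
      if (!is.numeric(df[[col]])) {
        stop("schema violation: column ", col, " must be numeric")
      }
    }
    for (col in c("T", "IV")) {
      bad <- which(!(df[[col]] %in% 0:1))
      if (length(bad)) {
        stop("schema violation: column ", col, " must be 0/1 (row ",
             bad[1], ")")
      }
    }
  } else {
    validate_experiment(df)
  }
  df
}

#' Write a CSV with a provenance header
#'
#' Prepends comment lines recording the package version, the seed, and a
#' hash of the generating configuration, so every output is traceable to
#' its run. Files written this way are read back by [read_table()].
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param seed Root seed of the run (recorded, not used).
#' @param config Optional configuration object; a stable hash of its
#'   serialized form is recorded.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path, seed = NA, config = NULL) {
  ver <- as.character(utils::packageVersion("spillpower"))
  cfg_hash <- if (is.null(config)) "none" else {
    x <- config
    class(x) <- NULL
    # md5 of the canonical JSON serialization
    tmp <- tempfile()
    on.exit(unlink(tmp), add = TRUE)
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
    unname(tools::md5sum(tmp))
  }
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c(sprintf("# spillpower %s", ver),
               sprintf("# seed: %s", seed),
               sprintf("# config_md5: %s", cfg_hash)), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

results_columns <- function() c("contrast", "term", "statistic", "value")

#' Assemble a publication-style results table
#'
#' Binds per-contrast estimation outputs into one long table (one row per
#' contrast, term, and statistic) mirroring the column structure of the
#' study's coefficient tables: estimates, robust SEs, raw and BH-adjusted
#' p-values, confidence bounds, sample size, plus -- for spillover layouts --
#' the bootstrapped CI of the indirect effect and the first-stage F. The BH
#' adjustment is applied once per assembled table (one family per table),
#' over the focal (non-intercept) terms.
#'
#' @param estimates Named list of estimation outputs; names are the contrast
#'   labels. Allowed classes per layout: `lpm_fit`/`probit_fit` for
#'   `"study1_peb1"`, `spillover_decomposition` for `"study1_spillover"`,
#'   `moderated_2sls` for `"moderation"`.
#' @param layout One of `"study1_peb1"`, `"study1_spillover"`,
#'   `"moderation"`.
#' @return A long-format data frame with columns `contrast`, `term`,
#'   `statistic`, `value`; empty input yields a zero-row table with the
#'   same columns.
#' @export
render_results_table <- function(estimates,
                                 layout = c("study1_peb1",
                                            "study1_spillover",
                                            "moderation")) {
  layout <- match.arg(layout)
  empty <- data.frame(contrast = character(), term = character(),
                      statistic = character(), value = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(estimates)) return(empty)
  if (is.null(names(estimates)) || any(names(estimates) == "")) {
    stop("estimates must be a named list (names are contrast labels)")
  }
  allowed <- switch(layout,
                    study1_peb1 = c("lpm_fit", "probit_fit"),
                    study1_spillover = "spillover_decomposition",
                    moderation = "moderated_2sls")
  ok <- vapply(estimates, function(e) inherits(e, allowed), logical(1))
  if (!all(ok)) {
    stop("layout error: layout '", layout, "' cannot render objects of ",
         "class ", paste(unique(vapply(estimates[!ok], function(e)
           class(e)[1], character(1))), collapse = ", "))
  }

  rows <- list()
  emit <- function(contrast, term, statistic, value) {
    rows[[length(rows) + 1]] <<- data.frame(
      contrast = contrast, term = term, statistic = statistic,
      value = as.numeric(value), stringsAsFactors = FALSE)
  }
  for (nm in names(estimates)) {
    e <- estimates[[nm]]
    if (layout %in% "study1_peb1") {
      ct <- e$coefficients
      for (i in seq_len(nrow(ct))) {
        emit(nm, ct$term[i], "estimate", ct$estimate[i])
        emit(nm, ct$term[i], "robust_se", ct$robust_se[i])
        emit(nm, ct$term[i], "p_raw", ct$p_value[i])
        emit(nm, ct$term[i], "ci_low", ct$ci_low[i])
        emit(nm, ct$term[i], "ci_high", ct$ci_high[i])
      }
      emit(nm, "(model)", "n", e$n)
    } else if (layout == "study1_spillover") {
      for (tm in c("beta_prime", "delta_prime", "tau")) {
        v <- e[[tm]]
        lab <- switch(tm, beta_prime = "PEB1", delta_prime = "T_direct",
                      tau = "T_total")
        emit(nm, lab, "estimate", v["estimate"])
        emit(nm, lab, "robust_se", v["robust_se"])
        emit(nm, lab, "p_raw", v["p_value"])
        emit(nm, lab, "ci_low", v["ci_low"])
        emit(nm, lab, "ci_high", v["ci_high"])
      }
      emit(nm, "indirect", "estimate", e$indirect)
      emit(nm, "indirect", "boot_ci_low", e$indirect_ci95[1])
      emit(nm, "indirect", "boot_ci_high", e$indirect_ci95[2])
      emit(nm, "(model)", "first_stage_F", e$first_stage_F)
      emit(nm, "(model)", "n", e$n)
    } else {
      ct <- e$coefficients
      for (i in seq_len(nrow(ct))) {
        emit(nm, ct$term[i], "estimate", ct$estimate[i])
        emit(nm, ct$term[i], "robust_se", ct$robust_se[i])
        emit(nm, ct$term[i], "p_raw", ct$p_value[i])
        emit(nm, ct$term[i], "ci_low", ct$ci_low[i])
        emit(nm, ct$term[i], "ci_high", ct$ci_high[i])
      }
      for (j in seq_along(e$first_stage_F)) {
        emit(nm, names(e$first_stage_F)[j], "first_stage_F",
             e$first_stage_F[j])
      }
      emit(nm, "(model)", "n", e$n)
    }
  }
  out <- do.call(rbind, rows)
  # one BH family per assembled table, over focal (non-intercept) terms
  focal <- out$statistic == "p_raw" & out$term != "(Intercept)"
  if (any(focal)) {
    adj <- out[focal, ]
    adj$statistic <- "p_bh"
    adj$value <- bh_adjust(adj$value)
    out <- rbind(out, adj)
  }
  rownames(out) <- NULL
  out
}
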