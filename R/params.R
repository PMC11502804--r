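#' Structural parameters of the spillover data-generating process
#'
#' Container for all path coefficients of the latent-activation causal model.
#' A randomized framing treatment `T` shifts the first activation system `U1`
#' (strength `phi1`); `U1` drives uptake of the targeted behavior PEB1
#' (strength `beta_u1`) together with a randomized salience nudge `IV`
#' (strength `beta_iv`) and the behavior's intrinsic attractiveness
#' (`attract_peb1`, on the logit scale in the binary version). The second
#' activation system `U2` inherits from `U1` (autocorrelation `phi21`) and
#' from the realized PEB1 (`phi22`), and drives the non-targeted behavior
#' PEB2 (strength `beta_u2`, intercept `attract_peb2`).
#'
#' Two observation models are supported. In the `"binary"` version PEB1 and
#' PEB2 are Bernoulli draws of logistic propensities; in the `"continuous"`
#' version they are Gaussian with standard deviations `sigma_peb1` and
#' `sigma_peb2` (ignored, and flagged unused, in the binary version).
#'
#' @param version `"binary"` or `"continuous"` observation model.
#' @param phi1 Treatment -> U1 path coefficient.
#' @param phi21 U1 -> U2 autocorrelation path.
#' @param phi22 PEB1 -> U2 path (the behavior-on-behavior channel).
#' @param beta_u1 U1 -> PEB1 path.
#' @param beta_u2 U2 -> PEB2 path.
#' @param beta_iv Nudge -> PEB1 path (instrument strength).
#' @param attract_peb1,attract_peb2 Intrinsic attractiveness intercepts
#'   (logit scale in the binary version, outcome scale in the continuous one).
#' @param sigma_u1,sigma_u2 Standard deviations of the activation systems;
#'   must be strictly positive.
#' @param sigma_peb1,sigma_peb2 Outcome noise SDs, continuous version only.
#' @return An object of class `generative_params` (a validated named list).
#' @examples
#' p <- generative_params("binary", phi1 = 0.5, beta_iv = 1)
#' p$phi1
#' @export
generative_params <- function(version = c("binary", "continuous"),
                              phi1 = 0, phi21 = 0.6, phi22 = 0,
                              beta_u1 = 1, beta_u2 = 1, beta_iv = 0,
                              attract_peb1 = -1.5, attract_peb2 = -1.5,
                              sigma_u1 = 1, sigma_u2 = 1,
                              sigma_peb1 = 1, sigma_peb2 = 1) {
  version <- match.arg(version)
  p <- list(version = version,
            phi1 = as.numeric(phi1), phi21 = as.numeric(phi21),
            phi22 = as.numeric(phi22),
            beta_u1 = as.numeric(beta_u1), beta_u2 = as.numeric(beta_u2),
            beta_iv = as.numeric(beta_iv),
            attract_peb1 = as.numeric(attract_peb1),
            attract_peb2 = as.numeric(attract_peb2),
            sigma_u1 = as.numeric(sigma_u1), sigma_u2 = as.numeric(sigma_u2),
            sigma_peb1 = as.numeric(sigma_peb1),
            sigma_peb2 = as.numeric(sigma_peb2))
  class(p) <- "generative_params"
  validate_params(p)
  p
}

#' @export
print.generative_params <- function(x, ...) {
  cat("Generative parameters (", x$version, " version)\n", sep = "")
  cat(sprintf("  paths : phi1=%.4g phi21=%.4g phi22=%.4g\n",
              x$phi1, x$phi21, x$phi22))
  cat(sprintf("          beta_u1=%.4g beta_u2=%.4g beta_iv=%.4g\n",
              x$beta_u1, x$beta_u2, x$beta_iv))
  cat(sprintf("  intercepts: attract_peb1=%.4g attract_peb2=%.4g\n",
              x$attract_peb1, x$attract_peb2))
  cat(sprintf("  noise : sigma_u1=%.4g sigma_u2=%.4g", x$sigma_u1, x$sigma_u2))
  if (x$version == "continuous") {
    cat(sprintf(" sigma_peb1=%.4g sigma_peb2=%.4g\n", x$sigma_peb1, x$sigma_peb2))
  } else {
    cat("  (sigma_peb1/sigma_peb2 unused in binary version)\n")
  }
  invisible(x)
}

validate_params <- function(p) {
  if (!inherits(p, "generative_params")) {
    stop("invalid-parameter: expected a 'generative_params' object")
  }
  num <- setdiff(names(p), "version")
  bad <- num[!vapply(p[num], function(v) is.numeric(v) && length(v) == 1 &&
                       is.finite(v), logical(1))]
  if (length(bad)) {
    stop("invalid-parameter: non-finite or non-scalar field(s): ",
         paste(bad, collapse = ", "))
  }
  sig <- c("sigma_u1", "sigma_u2")
  if (p$version == "continuous") sig <- c(sig, "sigma_peb1", "sigma_peb2")
  nonpos <- sig[vapply(p[sig], function(v) v <= 0, logical(1))]
  if (length(nonpos)) {
    stop("invalid-parameter: sigma field(s) must be strictly positive: ",
         paste(nonpos, collapse = ", "))
  }
  invisible(TRUE)
}

param_field_names <- function() {
  c("version", "phi1", "phi21", "phi22", "beta_u1", "beta_u2", "beta_iv",
    "attract_peb1", "attract_peb2",
    "sigma_u1", "sigma_u2", "sigma_peb1", "sigma_peb2")
}

#' Write generative parameters to a flat key-value config file
#'
#' Serializes to YAML or JSON (chosen by file extension) with keys named
#' exactly as the `generative_params` fields; `read_params()` round-trips
#' losslessly.
#'
#' @param params A `generative_params` object.
#' @param path Output file; extension `.json` selects JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  x <- params[param_field_names()]
  class(x) <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path, precision = 15L)
  }
  invisible(path)
}

#' Read generative parameters from a config file
#'
#' @param path A YAML or JSON file as written by [write_params()], with keys
#'   named exactly as the `generative_params` fields. Unknown keys are
#'   rejected.
#' @return A validated `generative_params` object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(x), param_field_names())
  if (length(unknown)) {
    stop("unknown parameter key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  }
  do.call(generative_params, x)
}

#' Closed-form path effects of the continuous-version model
#'
#' In the linear (continuous) observation model the causal effects are exact
#' products of path coefficients: the treatment effect on PEB1 is
#' `beta_u1 * phi1`; the behavior-on-behavior effect of PEB1 on PEB2 is
#' `beta_u2 * phi22`; the direct treatment effect on PEB2 (not mediated by
#' PEB1) is `beta_u2 * phi21 * phi1`; and the total treatment effect on PEB2
#' is the sum of the direct effect and the indirect product
#' `(beta_u1 * phi1) * (beta_u2 * phi22)`. No closed form exists for the
#' binary version (the logistic link breaks the products); callers must
#' simulate instead.
#'
#' @param params A continuous-version `generative_params` object.
#' @return A named list with elements `t_on_peb1`, `peb1_on_peb2`,
#'   `direct_t_on_peb2`, `indirect_t_on_peb2`, and `total_t_on_peb2`.
#' @examples
#' p <- generative_params("continuous", phi1 = 1, beta_u1 = 0.5,
#'                        phi21 = 0.7, phi22 = 0.4, beta_u2 = 1)
#' closed_form_effects(p)$total_t_on_peb2  # 0.9
#' @export
closed_form_effects <- function(params) {
  validate_params(params)
  if (params$version != "continuous") {
    stop("unsupported-version: closed-form path effects are exact only in ",
         "the continuous (linear) model; simulate the binary version instead")
  }
  t_on_peb1 <- params$beta_u1 * params$phi1
  peb1_on_peb2 <- params$beta_u2 * params$phi22
  direct <- params$beta_u2 * params$phi21 * params$phi1
  indirect <- t_on_peb1 * peb1_on_peb2
  list(t_on_peb1 = t_on_peb1,
       peb1_on_peb2 = peb1_on_peb2,
       direct_t_on_peb2 = direct,
       indirect_t_on_peb2 = indirect,
       total_t_on_peb2 = direct + indirect)
}
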