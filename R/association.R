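#' Percent-change transform of a log-scale coefficient
#'
#' Converts a regression coefficient estimated on a natural-log outcome
#' scale (or a log odds ratio) into the multiplicative effect expressed
#' as a percentage, `pc = 100 * (exp(beta) - 1)`, with a Wald confidence
#' interval built on the beta scale (`beta +/- z * se`) and pushed
#' through the same map.
#'
#' @param beta Numeric vector of coefficients.
#' @param se Positive standard errors (recycled against `beta`).
#' @param conf_mult Normal CI multiplier (default 1.96 for 95%).
#' @return A data.frame with columns `pc`, `ci_low`, `ci_high` (percent).
#' @export
#' @examples
#' percent_change(0.154, 0.028)  # 16.65 (10.43, 23.22)
#' percent_change(0.015, 0.007)  # 1.51 (0.18, 2.86)
percent_change <- function(beta, se, conf_mult = 1.96) {
  if (any(se <= 0)) stop("standard errors must be strictly positive")
  data.frame(pc = 100 * (exp(beta) - 1),
             ci_low = 100 * (exp(beta - conf_mult * se) - 1),
             ci_high = 100 * (exp(beta + conf_mult * se) - 1))
}

# one fitted contrast, the common currency of the association module
association_result <- function(outcome, exposure, beta, se, p_value, n_used,
                               adjust_set, model) {
  pc <- percent_change(beta, se)
  structure(
    list(outcome = outcome, exposure = exposure,
         beta = beta, se = se,
         pc = pc$pc, ci_low = pc$ci_low, ci_high = pc$ci_high,
         p_value = p_value, n_used = n_used,
         adjust_set = adjust_set, model = model),
    class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s model: %s ~ %s  (n = %d)\n",
              x$model, x$outcome, x$exposure, x$n_used))
  cat(sprintf("  beta = %.3f (SE %.3f), PC = %.2f%% (%.2f, %.2f), P = %.3g\n",
              x$beta, x$se, x$pc, x$ci_low, x$ci_high, x$p_value))
  if (length(x$adjust_set)) {
    cat("  adjusted for:", paste(x$adjust_set, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.association_result <- function(x, ...) {
  data.frame(outcome = x$outcome, exposure = x$exposure, model = x$model,
             beta = x$beta, se = x$se, pc = x$pc,
             ci_low = x$ci_low, ci_high = x$ci_high,
             p_value = x$p_value, n_used = x$n_used,
             adjust_set = paste(x$adjust_set, collapse = "+"),
             stringsAsFactors = FALSE)
}

# complete-case subset on a variable set, preserving FID for clustering
.complete_cases <- function(data, vars) {
  vars <- unique(c(vars, intersect("FID", names(data))))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  cc <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars,
             drop = FALSE]
  cc
}

# beta/se/p for one term, optionally with family-clustered robust SE
.extract_term <- function(fit, term, robust, cluster) {
  co <- summary(fit)$coefficients
  if (!term %in% rownames(co)) {
    stop("term '", term, "' absent from the fitted model (degenerate design?)")
  }
  beta <- co[term, 1]
  if (robust == "family") {
    V <- sandwich::vcovCL(fit, cluster = cluster)
    se <- sqrt(V[term, term])
    p <- 2 * stats::pnorm(-abs(beta / se))
  } else {
    se <- co[term, 2]
    p <- co[term, 4]
  }
  list(beta = beta, se = se, p = p)
}

#' Adjusted genotype-lipid association with percent-change reporting
#'
#' Ordinary least squares of the natural-log lipid concentration on the
#' additive genotype code plus the covariate adjustment set, on complete
#' cases. The genotype coefficient is a log-scale slope, so the reported
#' percent change is the multiplicative effect per risk allele.
#'
#' @param data Cohort data.frame with `genotype_code`, the lipid column
#'   and the covariates.
#' @param lipid Lipid column name (see [lipid_names()]).
#' @param covariates Adjustment set (default [adjustment_defaults()]).
#' @param robust `"none"` (model-based SEs, default) or `"family"`
#'   (cluster-robust by `FID`, accounting for relatedness).
#' @param log_scale Log-transform the outcome (default `TRUE`; the raw
#'   scale is retained as an option but percent change is only coherent
#'   on the log scale).
#' @return An `association_result`.
#' @export
fit_lipid_association <- function(data, lipid,
                                  covariates = adjustment_defaults(),
                                  robust = c("none", "family"),
                                  log_scale = TRUE) {
  robust <- match.arg(robust)
  vars <- c(lipid, "genotype_code", covariates)
  cc <- .complete_cases(data, vars)
  n <- nrow(cc)
  if (n < length(covariates) + 2L) {
    stop("too few complete cases (", n, ") for the requested model")
  }
  if (stats::var(cc$genotype_code) == 0) {
    stop("degenerate design: genotype_code is constant")
  }
  if (log_scale) {
    if (any(cc[[lipid]] <= 0)) {
      stop("lipid '", lipid, "' has non-positive values; cannot log-transform")
    }
    cc$.y <- log(cc[[lipid]])
  } else {
    cc$.y <- cc[[lipid]]
  }
  fml <- stats::reformulate(c("genotype_code", covariates), response = ".y")
  fit <- stats::lm(fml, data = cc)
  est <- .extract_term(fit, "genotype_code", robust, cc$FID)
  association_result(outcome = lipid, exposure = "genotype_code",
                     beta = est$beta, se = est$se, p_value = est$p,
                     n_used = n, adjust_set = covariates, model = "linear")
}

# shared logistic fit with separation / degeneracy diagnostics
.fit_logistic <- function(cc, term, rhs, covariates, outcome_label, model_label,
                          robust) {
  if (length(unique(cc$T2DM)) < 2L) {
    stop("outcome has a single class: logistic model undefined")
  }
  fml <- stats::reformulate(rhs, response = "T2DM")
  fit <- withCallingHandlers(
    stats::glm(fml, data = cc, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        stop("perfect or quasi-perfect separation detected for '", term,
             "': estimates unreliable", call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) {
    stop("logistic model for '", outcome_label, "' did not converge")
  }
  est <- .extract_term(fit, term, robust, cc$FID)
  association_result(outcome = outcome_label, exposure = term,
                     beta = est$beta, se = est$se, p_value = est$p,
                     n_used = nrow(cc), adjust_set = covariates,
                     model = model_label)
}

#' Adjusted genotype-disease association (logistic, per-allele)
#'
#' Logistic regression of disease status on the additive genotype code.
#' Model 1 adjusts for the conventional risk factors; Model 2
#' additionally adjusts for TC, TG, LDL-C and HDL-C, asking whether the
#' genotype-disease association survives conditioning on the lipid
#' profile. The genotype coefficient is the per-allele log odds ratio;
#' the percent change is `100 * (OR - 1)`.
#'
#' @inheritParams fit_lipid_association
#' @param model 1 (covariates only) or 2 (covariates + TC, TG, LDL_C,
#'   HDL_C).
#' @return An `association_result` with `model` `"logistic"`.
#' @export
fit_disease_association <- function(data, model = 1,
                                    covariates = adjustment_defaults(),
                                    robust = c("none", "family")) {
  robust <- match.arg(robust)
  stopifnot(model %in% c(1, 2))
  extra <- if (model == 2) c("TC", "TG", "LDL_C", "HDL_C") else character(0)
  vars <- c("T2DM", "genotype_code", covariates, extra)
  cc <- .complete_cases(data, vars)
  if (stats::var(cc$genotype_code) == 0) {
    stop("degenerate design: genotype_code is constant")
  }
  .fit_logistic(cc, term = "genotype_code",
                rhs = c("genotype_code", covariates, extra),
                covariates = c(covariates, extra),
                outcome_label = "T2DM",
                model_label = paste0("logistic (model ", model, ")"),
                robust = robust)
}

#' Lipid-to-disease association (logistic, per mmol/L)
#'
#' Logistic regression of disease status on one lipid concentration
#' entered untransformed, so the reported percent change is the excess
#' odds per 1 mmol/L.
#'
#' @inheritParams fit_lipid_association
#' @return An `association_result`.
#' @export
fit_lipid_to_disease <- function(data, lipid,
                                 covariates = adjustment_defaults(),
                                 robust = c("none", "family")) {
  robust <- match.arg(robust)
  vars <- c("T2DM", lipid, covariates)
  cc <- .complete_cases(data, vars)
  if (stats::var(cc[[lipid]]) == 0) {
    stop("degenerate design: ", lipid, " is constant")
  }
  .fit_logistic(cc, term = lipid, rhs = c(lipid, covariates),
                covariates = covariates, outcome_label = "T2DM",
                model_label = "logistic (lipid)", robust = robust)
}

#' Subgroup (stratified) association analysis
#'
#' Splits the cohort on a binary stratifier — BMI dichotomised at a
#' cutpoint (default 24 kg/m^2), smoking, or drinking status — and runs
#' the supplied association fit within each stratum with the stratifying
#' variable removed from the adjustment set. Empty strata are skipped
#' with a warning rather than aborting the analysis.
#'
#' @param data Cohort data.frame.
#' @param stratifier `"bmi"`, `"smoker"` or `"drinker"`.
#' @param fit Fitting function, e.g. [fit_lipid_association()] or
#'   [fit_disease_association()]; it must accept `data` and
#'   `covariates` arguments.
#' @param ... Further arguments passed to `fit` (e.g. `lipid`, `model`).
#' @param covariates Adjustment set before removal of the stratifier.
#' @param bmi_cutoff BMI cutpoint (used when `stratifier = "bmi"`).
#' @return Named list of `association_result`s (one per stratum), with a
#'   `sizes` attribute giving the stratum sizes.
#' @export
subgroup_analysis <- function(data, stratifier = c("bmi", "smoker", "drinker"),
                              fit, ..., covariates = adjustment_defaults(),
                              bmi_cutoff = 24) {
  stratifier <- match.arg(stratifier)
  if (stratifier == "bmi") {
    if (!"BMI" %in% names(data)) stop("data lacks a BMI column")
    keep <- !is.na(data$BMI)
    strata <- ifelse(data$BMI >= bmi_cutoff,
                     paste0("BMI>=", bmi_cutoff), paste0("BMI<", bmi_cutoff))
    drop_var <- "BMI"
  } else {
    if (!stratifier %in% names(data)) stop("data lacks a ", stratifier, " column")
    keep <- !is.na(data[[stratifier]])
    strata <- ifelse(data[[stratifier]] == 1,
                     stratifier, paste0("non", stratifier))
    drop_var <- stratifier
  }
  data <- data[keep, , drop = FALSE]
  strata <- strata[keep]
  covariates <- setdiff(covariates, drop_var)

  out <- list()
  sizes <- integer(0)
  for (s in sort(unique(strata))) {
    sub <- data[strata == s, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("stratum '", s, "' is empty; skipped")
      next
    }
    res <- tryCatch(fit(data = sub, covariates = covariates, ...),
                    error = function(e) {
                      warning("stratum '", s, "' skipped: ",
                              conditionMessage(e))
                      NULL
                    })
    if (!is.null(res)) {
      out[[s]] <- res
      sizes[s] <- nrow(sub)
    }
  }
  if (!length(out)) stop("no stratum could be analysed")
  attr(out, "sizes") <- sizes
  out
}
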