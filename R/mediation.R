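#' Construct a mediator/outcome model pair from known coefficients
#'
#' Bundles the two regressions of a counterfactual mediation analysis —
#' a linear model for the continuous mediator and a logistic model for
#' the binary outcome — into one object. [fit_mediation_models()] builds
#' this from data; this constructor builds it directly from
#' coefficients, which is how closed forms are validated against the
#' Monte-Carlo oracle.
#'
#' @param beta0,beta1 Mediator-model intercept and exposure coefficient
#'   (mediator units per unit exposure).
#' @param sigma2 Mediator residual variance (> 0).
#' @param theta0,theta1,theta2 Outcome-model intercept, exposure log-OR
#'   and mediator log-OR.
#' @param theta3 Exposure-by-mediator interaction log-OR (default 0: no
#'   interaction).
#' @param beta2,theta_c Optional named covariate coefficient vectors for
#'   the mediator and outcome models.
#' @param mediator Mediator label.
#' @param covariate_means Optional named vector of covariate values at
#'   which conditional (interaction-model) effects are evaluated.
#' @return An object of class `mediation_models`.
#' @export
mediation_models <- function(beta0, beta1, sigma2,
                             theta0, theta1, theta2, theta3 = 0,
                             beta2 = NULL, theta_c = NULL,
                             mediator = "M", covariate_means = NULL) {
  if (sigma2 <= 0) stop("sigma2 must be strictly positive")
  structure(
    list(mediator = mediator,
         covariates = union(names(beta2), names(theta_c)),
         interaction = theta3 != 0,
         beta0 = beta0, beta1 = beta1, beta2 = beta2, sigma2 = sigma2,
         theta0 = theta0, theta1 = theta1, theta2 = theta2,
         theta3 = theta3, theta_c = theta_c,
         covariate_means = covariate_means,
         mediator_fit = NULL, outcome_fit = NULL, data = NULL,
         n = NA_integer_),
    class = "mediation_models")
}

#' Fit the two regressions of a counterfactual mediation analysis
#'
#' On the identical complete-case set: (1) the mediator lipid (raw
#' mmol/L scale) regressed by least squares on the additive genotype
#' code and the covariates; (2) disease status regressed logistically on
#' the genotype code, the mediator and the same covariates (optionally
#' with a genotype-by-mediator interaction).
#'
#' @param data Cohort data.frame.
#' @param mediator Lipid column used as the mediator.
#' @param covariates Adjustment set (default [adjustment_defaults()]).
#' @param interaction Include an exposure-by-mediator interaction term
#'   in the outcome model (default `FALSE`).
#' @return A `mediation_models` object carrying the extracted
#'   coefficients (`beta0`, `beta1`, `sigma2`, `theta0`, `theta1`,
#'   `theta2`, `theta3`), the fitted `lm`/`glm` objects, and the shared
#'   complete-case data.
#' @export
fit_mediation_models <- function(data, mediator,
                                 covariates = adjustment_defaults(),
                                 interaction = FALSE) {
  vars <- c("T2DM", "genotype_code", mediator, covariates)
  cc <- .complete_cases(data, vars)
  n <- nrow(cc)
  if (n < length(covariates) + 4L) {
    stop("too few complete cases (", n, ") for the mediation models")
  }
  if (stats::var(cc$genotype_code) == 0) {
    stop("degenerate design: genotype_code is constant")
  }
  if (stats::var(cc[[mediator]]) == 0) {
    stop("degenerate design: mediator '", mediator, "' is constant")
  }
  if (length(unique(cc$T2DM)) < 2L) {
    stop("outcome has a single class: logistic model undefined")
  }

  m_fml <- stats::reformulate(c("genotype_code", covariates),
                              response = mediator)
  mm <- stats::lm(m_fml, data = cc)

  out_terms <- c("genotype_code", mediator,
                 if (interaction) paste0("genotype_code:", mediator),
                 covariates)
  o_fml <- stats::reformulate(out_terms, response = "T2DM")
  om <- stats::glm(o_fml, data = cc, family = stats::binomial())
  if (!om$converged) stop("outcome logistic model did not converge")

  bm <- stats::coef(mm)
  bo <- stats::coef(om)
  int_name <- paste0("genotype_code:", mediator)
  cm <- colMeans(cc[, covariates, drop = FALSE])

  obj <- mediation_models(
    beta0 = bm[["(Intercept)"]],
    beta1 = bm[["genotype_code"]],
    sigma2 = summary(mm)$sigma^2,
    theta0 = bo[["(Intercept)"]],
    theta1 = bo[["genotype_code"]],
    theta2 = bo[[mediator]],
    theta3 = if (interaction) bo[[int_name]] else 0,
    beta2 = bm[covariates],
    theta_c = bo[covariates],
    mediator = mediator,
    covariate_means = cm)
  obj$interaction <- interaction
  obj$mediator_fit <- mm
  obj$outcome_fit <- om
  obj$data <- cc
  obj$n <- n
  obj
}

#' @export
print.mediation_models <- function(x, ...) {
  cat("mediation models for mediator", x$mediator,
      if (!is.na(x$n)) paste0("(n = ", x$n, ")"), "\n")
  cat(sprintf("  mediator model:  beta1 = %.4f (units per allele), sigma2 = %.4f\n",
              x$beta1, x$sigma2))
  cat(sprintf("  outcome model:   theta1 = %.4f, theta2 = %.4f%s\n",
              x$theta1, x$theta2,
              if (x$interaction) sprintf(", theta3 = %.4f", x$theta3) else ""))
  invisible(x)
}

#' Natural direct and indirect effects on the odds-ratio scale
#'
#' Closed-form regression-based natural effects for a continuous
#' (normal) mediator and a logistic outcome under the rare-outcome
#' approximation, for the exposure contrast `a` versus `a_star`
#' (default per-allele, 1 vs 0). Without interaction:
#' \deqn{OR^{d} = e^{\theta_1 (a - a^*)}, \quad
#'       OR^{i} = e^{\theta_2 \beta_1 (a - a^*)}, \quad
#'       OR^{t} = OR^{d} \times OR^{i}.}
#' With an exposure-by-mediator interaction \eqn{\theta_3}, the standard
#' normal-mediator closed forms apply and the mediator model intercept,
#' covariate values and residual variance enter the direct effect.
#'
#' @param models A `mediation_models` object.
#' @param a,a_star Exposure levels being contrasted (default 1 vs 0).
#' @param covariate_values Named covariate vector for conditional
#'   effects under interaction (default: the model's covariate means).
#' @return List of class `natural_effects`: `or_direct`, `or_indirect`,
#'   `or_total`, `contrast`.
#' @export
natural_effects <- function(models, a = 1, a_star = 0,
                            covariate_values = NULL) {
  stopifnot(inherits(models, "mediation_models"))
  if (a == a_star) {
    warning("contrast with a == a_star: identity odds ratios returned")
    return(structure(list(or_direct = 1, or_indirect = 1, or_total = 1,
                          contrast = c(a = a, a_star = a_star)),
                     class = "natural_effects"))
  }
  d <- a - a_star
  if (!models$interaction || models$theta3 == 0) {
    log_ord <- models$theta1 * d
    log_ori <- models$theta2 * models$beta1 * d
  } else {
    cv <- covariate_values
    if (is.null(cv)) cv <- models$covariate_means
    cov_shift <- if (length(models$beta2)) {
      sum(models$beta2 * cv[names(models$beta2)])
    } else 0
    mu_astar <- models$beta0 + models$beta1 * a_star + cov_shift
    log_ord <- (models$theta1 +
                  models$theta3 * (mu_astar + models$theta2 * models$sigma2)) * d +
      0.5 * models$theta3^2 * models$sigma2 * (a^2 - a_star^2)
    log_ori <- (models$theta2 * models$beta1 +
                  models$theta3 * models$beta1 * a) * d
  }
  structure(list(or_direct = exp(log_ord),
                 or_indirect = exp(log_ori),
                 or_total = exp(log_ord + log_ori),
                 contrast = c(a = a, a_star = a_star)),
            class = "natural_effects")
}

#' @export
print.natural_effects <- function(x, ...) {
  cat(sprintf("natural effects (contrast %s vs %s):\n",
              format(x$contrast[["a"]]), format(x$contrast[["a_star"]])))
  cat(sprintf("  OR direct %.4f, OR indirect %.4f, OR total %.4f\n",
              x$or_direct, x$or_indirect, x$or_total))
  invisible(x)
}

#' Proportion mediated on the excess-odds scale
#'
#' Share of the total exposure effect flowing through the mediator:
#' \deqn{PM = \frac{OR^{d}(OR^{i} - 1)}{OR^{d} OR^{i} - 1}.}
#' `pm_formula = "as_printed"` computes the variant
#' \eqn{OR^{d}(OR^{d} - 1)/(OR^{d} OR^{i} - 1)} that occasionally
#' appears in the applied literature; it is internally inconsistent
#' (it does not vanish when the indirect effect is null and can exceed 1
#' for a near-null mediated path) and is provided for auditability only.
#'
#' A null total effect leaves the proportion undefined; `NA` is returned
#' with a warning, never a silent 0.
#'
#' @param or_direct,or_indirect Natural direct and indirect odds ratios
#'   (both > 0).
#' @param pm_formula `"corrected"` (default, the standard form) or
#'   `"as_printed"`.
#' @param tol Null-total-effect tolerance on the log-OR scale.
#' @return The proportion mediated (may fall outside `[0, 1]` for
#'   inconsistent direct/indirect signs), or `NA` when undefined.
#' @export
#' @examples
#' proportion_mediated(1.047, 1.0014)   # about 0.030
#' proportion_mediated(1.2, 1)          # exactly 0: nothing mediated
proportion_mediated <- function(or_direct, or_indirect,
                                pm_formula = c("corrected", "as_printed"),
                                tol = 1e-8) {
  pm_formula <- match.arg(pm_formula)
  if (or_direct <= 0 || or_indirect <= 0) stop("odds ratios must be positive")
  total <- or_direct * or_indirect
  if (abs(log(total)) <= tol) {
    warning("proportion mediated undefined: total effect is null")
    return(NA_real_)
  }
  num <- switch(pm_formula,
                corrected = or_direct * (or_indirect - 1),
                as_printed = or_direct * (or_direct - 1))
  num / (total - 1)
}

#' Bootstrap mediation analysis with family resampling
#'
#' Point estimates from the full data ([fit_mediation_models()] +
#' [natural_effects()] + [proportion_mediated()]), with nonparametric
#' percentile confidence intervals obtained by resampling whole families
#' with replacement (respecting the within-family correlation of
#' genotypes and phenotypes). Individual-level resampling is available
#' for comparison. Bootstrap replicates with a degenerate design (e.g. a
#' constant genotype after resampling) are redrawn up to a retry cap.
#'
#' @inheritParams fit_mediation_models
#' @param n_boot Number of bootstrap replicates (at least 200).
#' @param seed Integer RNG seed (mandatory: CIs are resampling-based).
#' @param a,a_star Exposure contrast (default per-allele, 1 vs 0).
#' @param resample `"family"` (default) or `"individual"`.
#' @param pm_formula Passed to [proportion_mediated()].
#' @param conf_level Confidence level for the percentile intervals.
#' @param max_retry Redraw cap per replicate for degenerate designs.
#' @return An object of class `mediation_result`: point estimates
#'   `or_direct`, `or_indirect`, `or_total`, `pm`; percentile intervals
#'   `ci_direct`, `ci_indirect`, `ci_total`, `ci_pm`; `n_boot`,
#'   `contrast`, `mediator`, `n_used`, and the bootstrap draws in
#'   `$boot`.
#' @export
bootstrap_mediation <- function(data, mediator,
                                covariates = adjustment_defaults(),
                                n_boot = 1000, seed,
                                a = 1, a_star = 0,
                                resample = c("family", "individual"),
                                pm_formula = c("corrected", "as_printed"),
                                conf_level = 0.95,
                                max_retry = 25L) {
  resample <- match.arg(resample)
  pm_formula <- match.arg(pm_formula)
  if (missing(seed)) stop("bootstrap_mediation() requires an explicit seed")
  if (n_boot < 200) stop("n_boot must be at least 200 for stable percentiles")

  models <- fit_mediation_models(data, mediator, covariates)
  ne <- natural_effects(models, a = a, a_star = a_star)
  pm_hat <- suppressWarnings(
    proportion_mediated(ne$or_direct, ne$or_indirect, pm_formula))

  cc <- models$data
  Xm <- stats::model.matrix(models$mediator_fit)
  ym <- cc[[mediator]]
  Xo <- stats::model.matrix(models$outcome_fit)
  yo <- cc$T2DM
  start_o <- stats::coef(models$outcome_fit)
  j_g_m <- match("genotype_code", colnames(Xm))
  j_g_o <- match("genotype_code", colnames(Xo))
  j_m_o <- match(mediator, colnames(Xo))

  units <- if (resample == "family" && "FID" %in% names(cc)) {
    split(seq_len(nrow(cc)), cc$FID)
  } else {
    as.list(seq_len(nrow(cc)))
  }
  n_units <- length(units)

  d <- a - a_star
  boot <- matrix(NA_real_, nrow = n_boot, ncol = 4,
                 dimnames = list(NULL, c("or_direct", "or_indirect",
                                         "or_total", "pm")))
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    ok <- FALSE
    for (try in seq_len(max_retry)) {
      rows <- unlist(units[sample.int(n_units, n_units, replace = TRUE)],
                     use.names = FALSE)
      res <- .boot_one(Xm[rows, , drop = FALSE], ym[rows],
                       Xo[rows, , drop = FALSE], yo[rows],
                       j_g_m, j_g_o, j_m_o, start_o)
      if (!is.null(res)) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("bootstrap replicate ", b, " degenerate after ", max_retry,
           " redraws")
    }
    ord <- exp(res$theta1 * d)
    ori <- exp(res$theta2 * res$beta1 * d)
    pm_b <- ord * (if (pm_formula == "corrected") ori - 1 else ord - 1) /
      (ord * ori - 1)
    boot[b, ] <- c(ord, ori, ord * ori, pm_b)
  }

  alpha <- (1 - conf_level) / 2
  ci <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE, na.rm = TRUE)
  structure(
    list(or_direct = ne$or_direct, or_indirect = ne$or_indirect,
         or_total = ne$or_total, pm = pm_hat,
         ci_direct = ci[, "or_direct"], ci_indirect = ci[, "or_indirect"],
         ci_total = ci[, "or_total"], ci_pm = ci[, "pm"],
         n_boot = n_boot, contrast = c(a = a, a_star = a_star),
         mediator = mediator, n_used = models$n,
         resample = resample, pm_formula = pm_formula,
         boot = boot),
    class = "mediation_result")
}

# one bootstrap refit on prebuilt design matrices; NULL if degenerate
.boot_one <- function(Xm, ym, Xo, yo, j_g_m, j_g_o, j_m_o, start_o) {
  if (length(unique(Xm[, j_g_m])) < 2L) return(NULL)
  if (length(unique(yo)) < 2L) return(NULL)
  fm <- stats::.lm.fit(Xm, ym)
  if (fm$rank < ncol(Xm)) return(NULL)
  fo <- tryCatch(
    suppressWarnings(stats::glm.fit(Xo, yo, family = stats::binomial(),
                                    start = start_o,
                                    control = list(maxit = 50))),
    error = function(e) NULL)
  if (is.null(fo) || !fo$converged || fo$rank < ncol(Xo)) return(NULL)
  co <- fo$coefficients
  if (any(!is.finite(co)) || max(abs(co)) > 50) return(NULL)
  list(beta1 = fm$coefficients[j_g_m],
       theta1 = co[j_g_o],
       theta2 = co[j_m_o])
}

#' @export
print.mediation_result <- function(x, ...) {
  fmt <- function(est, ci) sprintf("%.4f (%.4f, %.4f)", est, ci[1], ci[2])
  cat(sprintf("mediation analysis: mediator %s, n = %d, %d bootstrap draws (%s resampling)\n",
              x$mediator, x$n_used, x$n_boot, x$resample))
  cat("  OR direct:  ", fmt(x$or_direct, x$ci_direct), "\n")
  cat("  OR indirect:", fmt(x$or_indirect, x$ci_indirect), "\n")
  cat("  OR total:   ", fmt(x$or_total, x$ci_total), "\n")
  if (is.na(x$pm)) {
    cat("  PM: undefined (null total effect)\n")
  } else {
    cat(sprintf("  PM: %.1f%% (%.1f%%, %.1f%%)\n",
                100 * x$pm, 100 * x$ci_pm[1], 100 * x$ci_pm[2]))
  }
  invisible(x)
}

#' Monte-Carlo potential-outcome oracle for the natural effects
#'
#' Validates the closed-form natural effects by brute force: draws
#' covariates from the supplied sample, simulates potential mediator
#' values \eqn{M(a^*) \sim N(\beta_0 + \beta_1 a^* + \beta_2' c,
#' \sigma^2)} (independently per counterfactual regime), averages the
#' outcome-model risks \eqn{E[Y(a, M(a^*))]} over draws, and forms the
#' empirical odds ratios of the natural direct and indirect contrasts.
#' Delta-method Monte-Carlo standard errors for the log odds ratios are
#' returned, using the full covariance of the three mean risks (the
#' regimes share covariate draws).
#'
#' @param models A `mediation_models` object (fitted or constructed).
#' @param covariate_data Data.frame of covariates sampled from; defaults
#'   to the fitted complete-case data, or no covariates if the models
#'   carry none.
#' @param n_mc Number of Monte-Carlo draws (at least 1e5 recommended).
#' @param seed Optional RNG seed.
#' @param a,a_star Exposure contrast.
#' @return List of class `mc_oracle`: `or_direct`, `or_indirect`,
#'   `se_log_direct`, `se_log_indirect`, mean risks `risk_a_mstar`,
#'   `risk_astar_mstar`, `risk_a_ma`, and `n_mc`.
#' @export
mc_counterfactual_oracle <- function(models, covariate_data = NULL,
                                     n_mc = 1e5, seed = NULL,
                                     a = 1, a_star = 0) {
  stopifnot(inherits(models, "mediation_models"))
  if (n_mc < 1e4) stop("n_mc too small for a stable oracle (use >= 1e4)")
  if (!is.null(seed)) set.seed(seed)

  if (is.null(covariate_data) && !is.null(models$data) &&
      length(models$covariates)) {
    covariate_data <- models$data[, models$covariates, drop = FALSE]
  }

  lin_med_c <- 0
  lin_out_c <- 0
  if (!is.null(covariate_data) && nrow(covariate_data) > 0 &&
      length(models$beta2)) {
    idx <- sample.int(nrow(covariate_data), n_mc, replace = TRUE)
    C <- as.matrix(covariate_data[idx, names(models$beta2), drop = FALSE])
    lin_med_c <- as.numeric(C %*% models$beta2)
    lin_out_c <- as.numeric(C[, names(models$theta_c), drop = FALSE] %*%
                              models$theta_c)
  }

  sd_m <- sqrt(models$sigma2)
  draw_m <- function(expo) {
    models$beta0 + models$beta1 * expo + lin_med_c +
      stats::rnorm(n_mc, 0, sd_m)
  }
  risk <- function(expo, med) {
    stats::plogis(models$theta0 + models$theta1 * expo +
                    models$theta2 * med + models$theta3 * expo * med +
                    lin_out_c)
  }
  # each counterfactual regime gets its own mediator draw so the three
  # mean risks are (conditionally on covariates) independent estimates
  p_astar_mstar <- risk(a_star, draw_m(a_star))  # E[Y(a*, M(a*))]
  p_a_mstar <- risk(a, draw_m(a_star))           # E[Y(a,  M(a*))]
  p_a_ma <- risk(a, draw_m(a))                   # E[Y(a,  M(a))]

  P <- c(mean(p_astar_mstar), mean(p_a_mstar), mean(p_a_ma))
  odds <- P / (1 - P)
  or_direct <- odds[2] / odds[1]
  or_indirect <- odds[3] / odds[2]

  Sigma <- stats::cov(cbind(p_astar_mstar, p_a_mstar, p_a_ma)) / n_mc
  dlogit <- 1 / (P * (1 - P))
  g_d <- c(-dlogit[1], dlogit[2], 0)
  g_i <- c(0, -dlogit[2], dlogit[3])
  se_log_direct <- sqrt(as.numeric(t(g_d) %*% Sigma %*% g_d))
  se_log_indirect <- sqrt(as.numeric(t(g_i) %*% Sigma %*% g_i))

  structure(
    list(or_direct = or_direct, or_indirect = or_indirect,
         se_log_direct = se_log_direct, se_log_indirect = se_log_indirect,
         risk_astar_mstar = P[1], risk_a_mstar = P[2], risk_a_ma = P[3],
         n_mc = n_mc, contrast = c(a = a, a_star = a_star)),
    class = "mc_oracle")
}

#' @export
print.mc_oracle <- function(x, ...) {
  cat(sprintf("Monte-Carlo potential-outcome oracle (n_mc = %g)\n", x$n_mc))
  cat(sprintf("  OR direct %.5f (SE of log: %.2g), OR indirect %.5f (SE of log: %.2g)\n",
              x$or_direct, x$se_log_direct, x$or_indirect, x$se_log_indirect))
  cat(sprintf("  mean risks: Y(a*,M(a*)) %.4g, Y(a,M(a*)) %.4g, Y(a,M(a)) %.4g\n",
              x$risk_astar_mstar, x$risk_a_mstar, x$risk_a_ma))
  invisible(x)
}
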