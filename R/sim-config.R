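#' Construct a cohort simulation configuration
#'
#' Defines the generating model for a family-structured case-control
#' cohort: founder genotypes are binomial(2, `risk_allele_freq`) (i.e.
#' Hardy-Weinberg), offspring genotypes follow Mendelian transmission,
#' log-lipids are linear in the additive genotype code with a shared
#' family random intercept, and disease status is Bernoulli with a
#' logistic model containing a direct genotype effect and a designated
#' lipid mediator.
#'
#' The generating equations are, per individual \eqn{i} in family
#' \eqn{f}:
#' \deqn{\ln L_{i} = \mu_{0L} + \beta_{gL} G_i + c_L' X_i + u_f +
#'   \epsilon_{iL}, \quad u_f \sim N(0, \sigma_u^2), \;
#'   \epsilon_{iL} \sim N(0, \sigma_L^2)}
#' \deqn{\mathrm{logit}\, P(Y_i = 1) = \theta_0 + \theta_d G_i +
#'   \theta_m M_i + c_Y' X_i}
#' where \eqn{G_i} is the 0/1/2 risk-allele count, \eqn{M_i} the
#' designated mediator lipid on the raw mmol/L scale and \eqn{X_i} the
#' covariates. Lipid intercepts \eqn{\mu_{0L}} are set so the marginal
#' raw-scale means match `lipid_means`; \eqn{\theta_0} is calibrated
#' numerically so the expected prevalence equals `target_prevalence`
#' (unless `baseline_logit` is supplied).
#'
#' @param n_families Number of families to simulate.
#' @param seed Integer RNG seed. Mandatory: there is no default, so every
#'   simulated cohort is reproducible by construction.
#' @param risk_allele_freq Founder frequency of the risk allele, in
#'   `[0, 1]` (degenerate 0/1 allowed for fixation checks; the HWE test
#'   itself requires a polymorphic SNP).
#' @param family_size_probs Named probability vector over family sizes;
#'   names are the sizes (`"1"`, `"2"`, `"3"`). The default mixes
#'   singletons, pairs and trios with mean size about 2.02.
#' @param size2_structure How two-member families are built: `"mix"`
#'   (half full-sib pairs, half parent-offspring pairs), `"sibpair"`, or
#'   `"parent_offspring"`.
#' @param lipid_means Named vector of target marginal lipid means
#'   (mmol/L) for the six traits in [lipid_names()].
#' @param lipid_effects Named vector of per-risk-allele genotype effects
#'   \eqn{\beta_{gL}} on the natural-log lipid scale. Traits omitted get 0;
#'   unknown names are an error.
#' @param residual_sd Named vector of per-lipid residual SDs on the log
#'   scale (all strictly positive).
#' @param family_sd Nonnegative SD of the shared family random intercept
#'   on the log-lipid scale.
#' @param covariate_effects List with elements `lipid` (named coefficient
#'   vector applied to every log-lipid, or a per-lipid list of such
#'   vectors) and `disease` (named coefficient vector on the logit scale).
#' @param covariate_dist List of marginal covariate distribution
#'   parameters: `age_mean`, `age_sd`, `age_min` (normal truncated below),
#'   `bmi_mean`, `bmi_sd`, `bmi_min`, and Bernoulli rates `sex_p` (male),
#'   `smoker_p`, `drinker_p`, `hypertension_p`, `chd_p`.
#' @param mediator Name of the lipid entering the disease model.
#' @param theta_direct Disease log-OR per risk allele not through the
#'   mediator.
#' @param theta_mediator Disease log-OR per 1 mmol/L of the mediator.
#' @param target_prevalence Target disease prevalence (used to calibrate
#'   the baseline logit when `baseline_logit` is `NULL`).
#' @param baseline_logit Optional fixed intercept for the disease model;
#'   overrides prevalence calibration when supplied.
#' @param genotype_missing_rate Fraction of genotype calls set to missing
#'   (default 0: complete data).
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [make_scenario()] for ready-made configurations,
#'   [simulate_cohort()] to generate data, [simulation_truth()] for the
#'   implied true effect sizes.
#' @export
sim_config <- function(n_families,
                       seed,
                       risk_allele_freq = 0.34,
                       family_size_probs = c("1" = 0.10, "2" = 0.78, "3" = 0.12),
                       size2_structure = c("mix", "sibpair", "parent_offspring"),
                       lipid_means = c(TC = 3.18, TG = 1.58, LDL_C = 2.29,
                                       HDL_C = 0.98, APO_A = 1.12, APO_B = 0.77),
                       lipid_effects = NULL,
                       residual_sd = c(TC = 0.32, TG = 0.55, LDL_C = 0.34,
                                       HDL_C = 0.36, APO_A = 0.34, APO_B = 0.30),
                       family_sd = 0.12,
                       covariate_effects = NULL,
                       covariate_dist = NULL,
                       mediator = "TC",
                       theta_direct = 0,
                       theta_mediator = 0,
                       target_prevalence = 0.38,
                       baseline_logit = NULL,
                       genotype_missing_rate = 0) {
  size2_structure <- match.arg(size2_structure)
  if (missing(seed) || is.null(seed)) {
    stop("sim_config() requires an explicit integer seed")
  }
  stopifnot(length(seed) == 1L, is.finite(seed), seed == round(seed))
  if (!is.numeric(n_families) || length(n_families) != 1L || n_families < 1) {
    stop("n_families must be a positive integer")
  }
  if (!is.numeric(risk_allele_freq) || risk_allele_freq < 0 ||
      risk_allele_freq > 1) {
    stop("risk_allele_freq must lie in [0, 1]")
  }
  if (is.null(names(family_size_probs)) ||
      any(is.na(suppressWarnings(as.integer(names(family_size_probs)))))) {
    stop("family_size_probs must be named by integer family sizes")
  }
  sizes <- as.integer(names(family_size_probs))
  if (any(sizes < 1L)) stop("family sizes must be >= 1")
  if (any(family_size_probs < 0) || sum(family_size_probs) <= 0) {
    stop("family_size_probs must have positive total mass")
  }
  if (any(sizes > 3L)) {
    stop("family sizes above 3 are not supported by the default structures")
  }

  lipids <- lipid_names()
  lipid_means <- .complete_named(lipid_means, lipids, what = "lipid_means")
  residual_sd <- .complete_named(residual_sd, lipids, what = "residual_sd")
  if (any(residual_sd <= 0)) stop("residual_sd must be strictly positive")
  if (family_sd < 0) stop("family_sd must be nonnegative")

  be <- stats::setNames(numeric(length(lipids)), lipids)
  if (!is.null(lipid_effects)) {
    unknown <- setdiff(names(lipid_effects), lipids)
    if (length(unknown) > 0) {
      stop("unknown lipid name(s) in lipid_effects: ",
           paste(unknown, collapse = ", "))
    }
    be[names(lipid_effects)] <- lipid_effects
  }

  if (is.null(covariate_effects)) {
    covariate_effects <- list(
      lipid = c(age = 0.001, sex = -0.03, BMI = 0.004, smoker = -0.01,
                drinker = 0.01, hypertension = 0.02, CHD = 0.01),
      disease = c(age = 0.03, sex = -0.30, BMI = 0.04, smoker = -0.20,
                  drinker = -0.30, hypertension = 0.45, CHD = 0.05))
  }
  if (!all(c("lipid", "disease") %in% names(covariate_effects))) {
    stop("covariate_effects must have elements 'lipid' and 'disease'")
  }

  if (is.null(covariate_dist)) {
    covariate_dist <- list(age_mean = 57, age_sd = 10, age_min = 40,
                           bmi_mean = 26.2, bmi_sd = 4.3, bmi_min = 15,
                           sex_p = 0.49, smoker_p = 0.46, drinker_p = 0.35,
                           hypertension_p = 0.70, chd_p = 0.28)
  }
  rates <- unlist(covariate_dist[c("sex_p", "smoker_p", "drinker_p",
                                   "hypertension_p", "chd_p")])
  if (any(rates < 0 | rates > 1)) stop("covariate rates must lie in [0, 1]")

  if (!mediator %in% lipids) {
    stop("mediator must be one of: ", paste(lipids, collapse = ", "))
  }
  if (target_prevalence <= 0 || target_prevalence >= 1) {
    stop("target_prevalence must lie strictly in (0, 1)")
  }
  if (genotype_missing_rate < 0 || genotype_missing_rate >= 1) {
    stop("genotype_missing_rate must lie in [0, 1)")
  }

  structure(
    list(n_families = as.integer(n_families),
         seed = as.integer(seed),
         risk_allele_freq = risk_allele_freq,
         family_size_probs = family_size_probs / sum(family_size_probs),
         size2_structure = size2_structure,
         lipid_means = lipid_means,
         lipid_effects = be,
         residual_sd = residual_sd,
         family_sd = family_sd,
         covariate_effects = covariate_effects,
         covariate_dist = covariate_dist,
         mediator = mediator,
         theta_direct = theta_direct,
         theta_mediator = theta_mediator,
         target_prevalence = target_prevalence,
         baseline_logit = baseline_logit,
         genotype_missing_rate = genotype_missing_rate),
    class = "sim_config")
}

# fill a partially specified named vector against a full name set
.complete_named <- function(x, full_names, what) {
  if (is.null(names(x)) && length(x) == length(full_names)) {
    names(x) <- full_names
  }
  unknown <- setdiff(names(x), full_names)
  if (length(unknown) > 0) {
    stop("unknown name(s) in ", what, ": ", paste(unknown, collapse = ", "))
  }
  if (!all(full_names %in% names(x))) {
    stop(what, " must cover all of: ", paste(full_names, collapse = ", "))
  }
  x[full_names]
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_families, "families, seed", x$seed, "\n")
  cat(sprintf("  risk-allele freq %.3f; target prevalence %.2f; mediator %s\n",
              x$risk_allele_freq, x$target_prevalence, x$mediator))
  cat(sprintf("  theta_direct = %.4f, theta_mediator = %.4f (per mmol/L)\n",
              x$theta_direct, x$theta_mediator))
  nz <- x$lipid_effects[x$lipid_effects != 0]
  if (length(nz)) {
    cat("  lipid effects (log scale):",
        paste(sprintf("%s=%.3f", names(nz), nz), collapse = ", "), "\n")
  } else {
    cat("  lipid effects: all zero\n")
  }
  invisible(x)
}

#' Ready-made simulation scenarios
#'
#' Three canned configurations used throughout tests and validation:
#'
#' * `"paper_like"`: 2885 families (about 5800 individuals), risk-allele
#'   frequency 0.34, disease prevalence 0.38, per-allele direct disease
#'   log-OR 0.154, per-allele log-lipid effects between -0.018 and 0.049
#'   across the six traits, and a TC-mediated disease path of log(1.06)
#'   per mmol/L — the magnitudes of a single-SNP family study of lipids
#'   and type 2 diabetes.
#' * `"null"`: identical cohort structure with every genotype and
#'   mediator effect set to zero (type-I error and coverage studies).
#' * `"strong_mediation"`: a TC effect large enough that about half of
#'   the total genotype-disease effect flows through the mediator
#'   (implied proportion mediated close to 0.5).
#'
#' @param name One of `"paper_like"`, `"null"`, `"strong_mediation"`.
#' @param seed Integer RNG seed (mandatory, forwarded to [sim_config()]).
#' @param n_families Optional override of the scenario's family count.
#' @return A `sim_config` object.
#' @export
#' @examples
#' cfg <- make_scenario("null", seed = 1, n_families = 50)
#' cfg$theta_direct
make_scenario <- function(name = c("paper_like", "null", "strong_mediation"),
                          seed, n_families = NULL) {
  name <- match.arg(name)
  if (missing(seed)) stop("make_scenario() requires an explicit seed")
  nf <- if (is.null(n_families)) 2885L else as.integer(n_families)
  switch(
    name,
    paper_like = sim_config(
      n_families = nf, seed = seed,
      risk_allele_freq = 0.34,
      lipid_effects = c(TC = 0.049, TG = -0.018, LDL_C = 0.039,
                        HDL_C = 0.015, APO_A = 0.015, APO_B = 0.015),
      theta_direct = 0.154,
      theta_mediator = log(1.06),
      mediator = "TC",
      target_prevalence = 0.38),
    null = sim_config(
      n_families = nf, seed = seed,
      risk_allele_freq = 0.34,
      lipid_effects = NULL,
      theta_direct = 0,
      theta_mediator = 0,
      mediator = "TC",
      target_prevalence = 0.38),
    strong_mediation = sim_config(
      n_families = nf, seed = seed,
      risk_allele_freq = 0.34,
      lipid_effects = c(TC = 0.10),
      theta_direct = 0.12,
      theta_mediator = 0.36,
      mediator = "TC",
      target_prevalence = 0.38))
}

# mean of Normal(mu, sd) truncated below at lo
.trunc_norm_mean <- function(mu, sd, lo) {
  a <- (lo - mu) / sd
  mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

# expected covariate values under the configured marginals
.covariate_means <- function(cd) {
  c(age = .trunc_norm_mean(cd$age_mean, cd$age_sd, cd$age_min),
    sex = cd$sex_p,
    BMI = .trunc_norm_mean(cd$bmi_mean, cd$bmi_sd, cd$bmi_min),
    smoker = cd$smoker_p,
    drinker = cd$drinker_p,
    hypertension = cd$hypertension_p,
    CHD = cd$chd_p)
}

# per-lipid covariate coefficient vector (shared or per-lipid list)
.lipid_cov_effects <- function(config, lipid) {
  ce <- config$covariate_effects$lipid
  if (is.list(ce)) {
    if (!lipid %in% names(ce)) stop("no covariate effects for lipid ", lipid)
    ce[[lipid]]
  } else {
    ce
  }
}

# log-scale intercept so that the marginal raw-scale mean of `lipid`
# matches the configured target (lognormal moment correction; covariate
# contributions entered at their expectations, a first-order calibration)
.lipid_intercept <- function(config, lipid) {
  s2 <- config$residual_sd[[lipid]]^2 + config$family_sd^2
  ce <- .lipid_cov_effects(config, lipid)
  cm <- .covariate_means(config$covariate_dist)
  cov_shift <- sum(ce[names(ce)] * cm[names(ce)])
  log(config$lipid_means[[lipid]]) - 0.5 * s2 -
    config$lipid_effects[[lipid]] * 2 * config$risk_allele_freq - cov_shift
}

#' True effect sizes implied by a simulation configuration
#'
#' Derives, deterministically from a [sim_config()], the quantities the
#' analysis modules are expected to recover: the true percent change per
#' allele for each lipid, the raw-scale (mmol/L per allele) mediator
#' slope, and the mediation decomposition (direct, indirect and total
#' odds ratios plus the proportion mediated) under the no-interaction
#' closed form.
#'
#' The raw-scale mediator slope is the population least-squares slope of
#' \eqn{E[M \mid G]} on \eqn{G} over the Hardy-Weinberg genotype
#' distribution, using the lognormal form of the generator
#' (\eqn{E[M \mid G=g] \propto e^{\beta_g g}}).
#'
#' @param config A `sim_config`.
#' @return An object of class `simulation_truth`: list with `config`,
#'   `pc_true` (named percent changes), `beta1_raw`, `or_direct`,
#'   `or_indirect`, `or_total`, `total_log_or`, `pm`.
#' @export
simulation_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$risk_allele_freq
  q <- 1 - p
  pi_g <- c(q^2, 2 * p * q, p^2)
  g <- 0:2

  pc_true <- 100 * (exp(config$lipid_effects) - 1)

  # E[M | G = g] on the raw scale, normalised to the target mean
  bg <- config$lipid_effects[[config$mediator]]
  w <- exp(bg * g)
  m_g <- config$lipid_means[[config$mediator]] * w / sum(pi_g * w)
  g_bar <- sum(pi_g * g)
  var_g <- sum(pi_g * g^2) - g_bar^2
  beta1_raw <- if (var_g > 0) {
    sum(pi_g * (g - g_bar) * m_g) / var_g
  } else {
    0
  }

  or_direct <- exp(config$theta_direct)
  or_indirect <- exp(config$theta_mediator * beta1_raw)
  or_total <- or_direct * or_indirect
  pm <- if (abs(log(or_total)) > 1e-10) {
    proportion_mediated(or_direct, or_indirect)
  } else {
    NA_real_
  }

  structure(
    list(config = config,
         pc_true = pc_true,
         beta1_raw = beta1_raw,
         or_direct = or_direct,
         or_indirect = or_indirect,
         or_total = or_total,
         total_log_or = log(or_total),
         pm = pm),
    class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("simulation_truth\n")
  cat("  true percent change per allele:\n")
  for (l in names(x$pc_true)) {
    cat(sprintf("    %-6s %+6.2f%%\n", l, x$pc_true[[l]]))
  }
  cat(sprintf("  mediator (%s) raw-scale slope: %.4f mmol/L per allele\n",
              x$config$mediator, x$beta1_raw))
  cat(sprintf("  OR direct %.4f, indirect %.4f, total %.4f; PM %s\n",
              x$or_direct, x$or_indirect, x$or_total,
              ifelse(is.na(x$pm), "undefined (null total effect)",
                     sprintf("%.3f", x$pm))))
  invisible(x)
}
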