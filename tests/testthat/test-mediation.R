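test_that("proportion mediated handles its boundary cases exactly", {
  # nothing flows through the mediator
  expect_equal(proportion_mediated(1.2, 1), 0)
  # everything flows through the mediator
  expect_equal(proportion_mediated(1, 1.3), 1)
  # full-precision odds ratios of realistic magnitude
  expect_equal(proportion_mediated(1.047, 1.0014), 0.03024, tolerance = 1e-3)
  # the variant formula is inconsistent: same inputs give a wildly
  # different share, and a null mediated path no longer returns 0
  expect_equal(proportion_mediated(1.04, 1.01, pm_formula = "as_printed"),
               0.8254, tolerance = 1e-3)
  expect_gt(proportion_mediated(1.2, 1, pm_formula = "as_printed"), 1)
  expect_warning(pm0 <- proportion_mediated(1, 1), "undefined")
  expect_true(is.na(pm0))
  expect_error(proportion_mediated(-1, 1.1), "positive")
})

test_that("no-interaction natural effects follow the closed form", {
  m <- mediation_models(beta0 = 3, beta1 = 0.16, sigma2 = 1,
                        theta0 = -1, theta1 = 0.15, theta2 = 0.06)
  ne <- natural_effects(m)
  expect_equal(ne$or_direct, exp(0.15))
  expect_equal(ne$or_indirect, exp(0.06 * 0.16))
  expect_equal(ne$or_total, ne$or_direct * ne$or_indirect)

  # blocked mediator path: indirect OR is one regardless of beta1
  m0 <- mediation_models(beta0 = 3, beta1 = 0.9, sigma2 = 1,
                         theta0 = -1, theta1 = 0.15, theta2 = 0)
  expect_equal(natural_effects(m0)$or_indirect, 1)

  # two-allele contrast doubles the log effects
  ne2 <- natural_effects(m, a = 2, a_star = 0)
  expect_equal(log(ne2$or_direct), 2 * log(ne$or_direct))

  expect_warning(id <- natural_effects(m, a = 1, a_star = 1), "identity")
  expect_equal(id$or_total, 1)
})

test_that("fitted mediation models recover generating coefficients at large n", {
  cfg <- make_scenario("strong_mediation", seed = 71, n_families = 10000)
  truth <- simulation_truth(cfg)
  d <- simulate_cohort(cfg)
  mm <- fit_mediation_models(d, "TC")

  se_b1 <- summary(mm$mediator_fit)$coefficients["genotype_code", 2]
  se_t1 <- summary(mm$outcome_fit)$coefficients["genotype_code", 2]
  se_t2 <- summary(mm$outcome_fit)$coefficients["TC", 2]
  expect_lt(abs(mm$beta1 - truth$beta1_raw), 2.5 * se_b1)
  expect_lt(abs(mm$theta1 - cfg$theta_direct), 2.5 * se_t1)
  expect_lt(abs(mm$theta2 - cfg$theta_mediator), 2.5 * se_t2)

  ne <- natural_effects(mm)
  pm_hat <- proportion_mediated(ne$or_direct, ne$or_indirect)
  expect_equal(pm_hat, truth$pm, tolerance = 0.1)
})

test_that("a null mediator path is recovered as theta2 near zero", {
  d <- simulate_cohort(make_scenario("null", seed = 72, n_families = 2000))
  mm <- fit_mediation_models(d, "TC")
  se_t2 <- summary(mm$outcome_fit)$coefficients["TC", 2]
  expect_lt(abs(mm$theta2), 3 * se_t2)
})

test_that("degenerate mediation inputs raise errors", {
  d <- tiny_cohort(seed = 73, n_families = 200)
  d_const <- d; d_const$TC <- 3
  expect_error(fit_mediation_models(d_const, "TC"), "constant")
  d_g <- d; d_g$genotype_code <- 1L
  expect_error(fit_mediation_models(d_g, "TC"), "degenerate")
})

test_that("proportion mediated is invariant to mediator unit rescaling", {
  d <- tiny_cohort(seed = 74, n_families = 800)
  mm1 <- fit_mediation_models(d, "TC")
  d2 <- d
  d2$TC <- d2$TC * 38.67   # mmol/L -> mg/dL
  mm2 <- fit_mediation_models(d2, "TC")
  ne1 <- natural_effects(mm1); ne2 <- natural_effects(mm2)
  expect_equal(ne1$or_indirect, ne2$or_indirect, tolerance = 1e-8)
  expect_equal(proportion_mediated(ne1$or_direct, ne1$or_indirect),
               proportion_mediated(ne2$or_direct, ne2$or_indirect),
               tolerance = 1e-8)
})

test_that("bootstrap mediation is deterministic given a seed", {
  d <- tiny_cohort(seed = 75, n_families = 300)
  b1 <- bootstrap_mediation(d, "TC", n_boot = 200, seed = 99)
  b2 <- bootstrap_mediation(d, "TC", n_boot = 200, seed = 99)
  expect_identical(b1$ci_direct, b2$ci_direct)
  expect_identical(b1$ci_indirect, b2$ci_indirect)
  expect_identical(b1$boot, b2$boot)
  expect_error(bootstrap_mediation(d, "TC", n_boot = 50, seed = 1),
               "at least 200")
  expect_error(bootstrap_mediation(d, "TC", n_boot = 200), "seed")
})

test_that("noisier mediators widen the indirect-effect interval", {
  # with a strong mediator path the indirect-effect uncertainty is
  # dominated by the genotype-mediator slope, whose SE scales with the
  # mediator's residual SD
  base <- list(n_families = 700, lipid_effects = c(TC = 0.10),
               theta_direct = 0.12, theta_mediator = 0.36)
  width <- function(res_sd, seed) {
    cfg <- do.call(sim_config, c(base, list(
      seed = seed,
      residual_sd = c(TC = res_sd, TG = 0.55, LDL_C = 0.34, HDL_C = 0.36,
                      APO_A = 0.34, APO_B = 0.30))))
    d <- simulate_cohort(cfg)
    b <- bootstrap_mediation(d, "TC", n_boot = 300, seed = seed + 1)
    diff(b$ci_indirect)
  }
  # residual variance scaled x4 across paired seeds
  w_narrow <- vapply(81:83, function(s) width(0.32, s), numeric(1))
  w_wide <- vapply(81:83, function(s) width(0.64, s), numeric(1))
  expect_true(all(w_wide > w_narrow))
})

test_that("oracle indirect effect collapses to one when the mediator path is blocked", {
  m <- mediation_models(beta0 = 3, beta1 = 0.4, sigma2 = 0.8,
                        theta0 = -1.5, theta1 = 0.2, theta2 = 0)
  o <- mc_counterfactual_oracle(m, n_mc = 2e5, seed = 5)
  expect_lt(abs(log(o$or_indirect)), 4 * o$se_log_indirect + 1e-8)
  expect_error(mc_counterfactual_oracle(m, n_mc = 100), "too small")
})

test_that("interaction closed form matches the oracle in the rare-outcome regime", {
  m <- mediation_models(beta0 = 2.5, beta1 = 0.3, sigma2 = 0.36,
                        theta0 = -8.5, theta1 = 0.12, theta2 = 0.15,
                        theta3 = 0.05)
  o <- mc_counterfactual_oracle(m, n_mc = 4e5, seed = 6)
  expect_lt(o$risk_astar_mstar, 0.01)
  ne <- natural_effects(m)
  expect_lt(abs(log(ne$or_direct) - log(o$or_direct)),
            3 * o$se_log_direct)
  expect_lt(abs(log(ne$or_indirect) - log(o$or_indirect)),
            3 * o$se_log_indirect)
})

test_that("oracle and closed form diverge measurably at common-outcome prevalence", {
  # the rare-outcome approximation degrades when prevalence is ~0.38;
  # the oracle quantifies this rather than hiding it
  m <- mediation_models(beta0 = 3.18, beta1 = 0.16, sigma2 = 1.0,
                        theta0 = -1.0, theta1 = 0.154, theta2 = 0.058)
  o <- mc_counterfactual_oracle(m, n_mc = 4e5, seed = 7)
  expect_gt(o$risk_astar_mstar, 0.2)
  gap <- abs(log(natural_effects(m)$or_direct) - log(o$or_direct))
  # the divergence is real but modest for these effect sizes
  expect_lt(gap, 0.05)
})
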