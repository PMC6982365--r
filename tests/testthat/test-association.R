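test_that("percent-change transform reproduces published beta/PC pairs at 2 decimals", {
  t2dm <- percent_change(0.154, 0.028)
  expect_equal(round(t2dm$pc, 2), 16.65)
  hdl <- percent_change(0.015, 0.007)
  expect_equal(round(hdl$pc, 2), 1.51)

  null <- percent_change(0, 0.02)
  expect_equal(null$pc, 0)
  # back-transformed CI is multiplicatively symmetric around the estimate
  expect_equal((1 + null$ci_high / 100) * (1 + null$ci_low / 100), 1,
               tolerance = 1e-12)
  expect_error(percent_change(0.1, 0), "strictly positive")
})

test_that("percent change is monotone in beta and near-linear for small effects", {
  betas <- seq(-0.5, 0.5, by = 0.01)
  pcs <- percent_change(betas, se = rep(0.01, length(betas)))$pc
  expect_true(all(diff(pcs) > 0))
  small <- c(-0.009, -0.001, 0.0005, 0.004, 0.009)
  rel_err <- abs(percent_change(small, 0.01)$pc - 100 * small) /
    abs(100 * small)
  expect_true(all(rel_err < 0.01))
})

test_that("association result obeys its internal identities", {
  d <- tiny_cohort(seed = 2, n_families = 400)
  fit <- fit_lipid_association(d, "TC")
  expect_equal(fit$pc, 100 * (exp(fit$beta) - 1))
  expect_equal(fit$ci_low, 100 * (exp(fit$beta - 1.96 * fit$se) - 1))
  expect_equal(fit$ci_high, 100 * (exp(fit$beta + 1.96 * fit$se) - 1))
  expect_true(fit$ci_low <= fit$pc && fit$pc <= fit$ci_high)
  expect_identical(fit$adjust_set, adjustment_defaults())
  df <- as.data.frame(fit)
  expect_equal(df$beta, fit$beta)
})

test_that("degenerate designs are rejected with informative errors", {
  d <- tiny_cohort(seed = 3, n_families = 200)
  d_const <- d; d_const$genotype_code <- 0L
  expect_error(fit_lipid_association(d_const, "TC"), "degenerate")
  expect_error(fit_disease_association(d_const, model = 1), "degenerate")
  d_one <- d; d_one$T2DM <- 1L
  expect_error(fit_disease_association(d_one, model = 1), "single class")
  d_neg <- d; d_neg$TC[1] <- -1
  expect_error(fit_lipid_association(d_neg, "TC"), "non-positive")
})

test_that("disease model 2 keeps the same complete cases as model 1", {
  d <- tiny_cohort(seed = 5, n_families = 500)
  m1 <- fit_disease_association(d, model = 1)
  m2 <- fit_disease_association(d, model = 2)
  expect_identical(m1$n_used, m2$n_used)
  expect_true(all(c("TC", "TG", "LDL_C", "HDL_C") %in% m2$adjust_set))
  # lipid missingness shrinks model 2 only
  d$TC[1:10] <- NA
  m1b <- fit_disease_association(d, model = 1)
  m2b <- fit_disease_association(d, model = 2)
  expect_identical(m1b$n_used, m1$n_used)
  expect_equal(m2b$n_used, m2$n_used - 10L)
})

test_that("family-clustered and plain SEs agree when the family effect vanishes", {
  cfg <- sim_config(n_families = 2470, seed = 17,
                    lipid_effects = c(TC = 0.049), family_sd = 0)
  d <- simulate_cohort(cfg)
  plain <- fit_lipid_association(d, "TC", robust = "none")
  clus <- fit_lipid_association(d, "TC", robust = "family")
  expect_equal(plain$beta, clus$beta)
  expect_lt(abs(clus$se - plain$se) / plain$se, 0.05)
})

test_that("lipid-to-disease model recovers the per-mmol/L mediator effect", {
  cfg <- sim_config(n_families = 2870, seed = 23,
                    theta_direct = 0, theta_mediator = 0.13, mediator = "TC")
  d <- simulate_cohort(cfg)
  fit <- fit_lipid_to_disease(d, "TC")
  expect_lt(abs(fit$beta - 0.13), 3 * fit$se)
  expect_equal(fit$pc, 100 * (exp(0.13) - 1), tolerance = 0.25)

  # protective, HDL-like mediator: sign recovered and significant
  cfgn <- sim_config(n_families = 2870, seed = 24,
                     theta_direct = 0, theta_mediator = -0.5,
                     mediator = "HDL_C")
  dn <- simulate_cohort(cfgn)
  fitn <- fit_lipid_to_disease(dn, "HDL_C")
  expect_lt(fitn$pc, 0)
  expect_lt(fitn$p_value, 0.05)

  # null mediator path: percent change near zero
  d0 <- simulate_cohort(make_scenario("null", seed = 25, n_families = 2000))
  fit0 <- fit_lipid_to_disease(d0, "TC")
  expect_lt(abs(fit0$beta), 3 * fit0$se)
})

test_that("subgroup analysis partitions the cohort and strips the stratifier", {
  d <- tiny_cohort(seed = 31, n_families = 600)
  res <- subgroup_analysis(d, "bmi", fit = fit_disease_association, model = 1)
  sizes <- attr(res, "sizes")
  expect_length(res, 2L)
  expect_equal(sum(sizes), sum(!is.na(d$BMI)))
  for (r in res) expect_false("BMI" %in% r$adjust_set)

  res_s <- subgroup_analysis(d, "smoker", fit = fit_lipid_association,
                             lipid = "TC")
  expect_setequal(names(res_s), c("smoker", "nonsmoker"))
  expect_equal(sum(attr(res_s, "sizes")), nrow(d))
  for (r in res_s) expect_false("smoker" %in% r$adjust_set)
})

test_that("a genotype effect confined to smokers surfaces in the smoker stratum", {
  set.seed(33)
  d <- tiny_cohort(seed = 33, n_families = 2000)
  lp <- -0.6 + 0.5 * d$genotype_code * d$smoker
  d$T2DM <- rbinom(nrow(d), 1, plogis(lp))
  res <- subgroup_analysis(d, "smoker", fit = fit_disease_association,
                           model = 1)
  expect_gt(res[["smoker"]]$pc, res[["nonsmoker"]]$pc)
  expect_lt(res[["smoker"]]$p_value, 0.01)
})

test_that("homogeneous effects give compatible stratum estimates", {
  agree <- vapply(1:20, function(i) {
    d <- simulate_cohort(make_scenario("paper_like", seed = 200 + i,
                                       n_families = 1000))
    res <- subgroup_analysis(d, "drinker", fit = fit_disease_association,
                             model = 1)
    z <- abs(res[[1]]$beta - res[[2]]$beta) /
      sqrt(res[[1]]$se^2 + res[[2]]$se^2)
    z < 2
  }, logical(1))
  expect_gte(mean(agree), 0.85)
})
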