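test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(n_families = 100), "seed")
  expect_error(sim_config(100, seed = 1, risk_allele_freq = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(100, seed = 1,
                          family_size_probs = c("1" = 0, "2" = 0)),
               "positive total mass")
  expect_error(sim_config(100, seed = 1,
                          family_size_probs = c("0" = 1)), ">= 1")
  expect_error(sim_config(100, seed = 1,
                          lipid_effects = c(CHOLESTEROL = 0.1)),
               "unknown lipid")
  expect_error(sim_config(100, seed = 1, residual_sd = rep(0, 6)),
               "strictly positive")
  expect_error(make_scenario("not_a_scenario", seed = 1))
})

test_that("same seed gives a bit-identical cohort and TSV", {
  cfg <- make_scenario("paper_like", seed = 77, n_families = 120)
  d1 <- simulate_cohort(cfg)
  d2 <- simulate_cohort(cfg)
  expect_identical(d1, d2)

  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_cohort(d1, f1); write_cohort(d2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  rt <- read_cohort(f1)
  expect_equal(nrow(rt), nrow(d1))
  expect_equal(rt$TC, d1$TC, tolerance = 1e-12)
})

test_that("founder genotypes follow Hardy-Weinberg proportions", {
  cfg <- sim_config(n_families = 10000, seed = 5, risk_allele_freq = 0.5,
                    family_size_probs = c("1" = 1))
  set.seed(cfg$seed)
  fam <- simulate_families(cfg)
  props <- as.numeric(table(factor(fam$genotype_code, 0:2))) / nrow(fam)
  expect_equal(props, c(0.25, 0.50, 0.25), tolerance = 0.02)

  # fixation: no risk alleles anywhere
  cfg0 <- sim_config(n_families = 500, seed = 6, risk_allele_freq = 0)
  set.seed(cfg0$seed)
  expect_true(all(simulate_families(cfg0)$genotype_code == 0L))
})

test_that("full-sib genotype codes show the enumerated kinship correlation", {
  # brute-force enumeration of parental transmissions gives exactly 1/2
  expect_equal(sib_genotype_correlation(0.34), 0.5, tolerance = 1e-12)
  expect_equal(sib_genotype_correlation(0.1), 0.5, tolerance = 1e-12)

  cfg <- sim_config(n_families = 10000, seed = 8,
                    family_size_probs = c("2" = 1),
                    size2_structure = "sibpair")
  set.seed(cfg$seed)
  fam <- simulate_families(cfg)
  g <- matrix(fam$genotype_code, ncol = 2, byrow = TRUE)
  expect_equal(cor(g[, 1], g[, 2]), sib_genotype_correlation(0.34),
               tolerance = 0.03)
  expect_true(all(fam$PID == "0" & fam$MID == "0"))
})

test_that("trio children are consistent with Mendelian transmission", {
  cfg <- sim_config(n_families = 2000, seed = 12,
                    family_size_probs = c("3" = 1))
  set.seed(cfg$seed)
  fam <- simulate_families(cfg)
  byfam <- split(fam, fam$FID)
  viol <- vapply(byfam, function(f) {
    child <- f[f$PID != "0", ]
    father <- f$genotype_code[f$IID == child$PID]
    mother <- f$genotype_code[f$IID == child$MID]
    # child count must be attainable from one allele per parent
    lo <- (father == 2) + (mother == 2)
    hi <- (father > 0) + (mother > 0)
    child$genotype_code < lo || child$genotype_code > hi
  }, logical(1))
  expect_false(any(viol))
})

test_that("phenotype generator hits the target prevalence and keeps lipids positive", {
  cfg <- make_scenario("paper_like", seed = 21, n_families = 2500)
  d <- simulate_cohort(cfg)
  expect_gt(nrow(d), 4500)
  expect_lt(abs(mean(d$T2DM) - cfg$target_prevalence), 0.03)
  for (l in lipid_names()) {
    expect_true(all(d[[l]] > 0))
    expect_false(anyNA(d[[l]]))
  }
  expect_false(anyNA(d$genotype_code))
  # family sizes average near two members
  expect_equal(nrow(d) / length(unique(d$FID)), 2.02, tolerance = 0.05)
})

test_that("noise-free limit returns the generating lipid effect exactly", {
  zero_cov <- list(
    lipid = c(age = 0, sex = 0, BMI = 0, smoker = 0, drinker = 0,
              hypertension = 0, CHD = 0),
    disease = c(age = 0, sex = 0, BMI = 0, smoker = 0, drinker = 0,
                hypertension = 0, CHD = 0))
  cfg <- sim_config(n_families = 1000, seed = 31,
                    lipid_effects = c(TC = 0.05),
                    residual_sd = rep(1e-8, 6), family_sd = 0,
                    covariate_effects = zero_cov)
  d <- simulate_cohort(cfg)
  fit <- fit_lipid_association(d, "TC", covariates = character(0))
  expect_equal(fit$beta, 0.05, tolerance = 1e-6)
})

test_that("genotype contrast in mean log-lipid is twice the per-allele effect", {
  cfg <- sim_config(n_families = 2870, seed = 41,
                    lipid_effects = c(TC = 0.05))
  d <- simulate_cohort(cfg)
  tt <- t.test(log(d$TC[d$genotype_code == 2]),
               log(d$TC[d$genotype_code == 0]))
  diff2_0 <- unname(diff(rev(tt$estimate)))
  # expected contrast is exactly 2 * beta_g; allow 3 SEs of sampling error
  # plus the mild SE understatement from within-family correlation
  expect_lt(abs(diff2_0 - 2 * 0.05), 3.5 * tt$stderr)
})

test_that("null genotype-disease effect yields odds ratios near one", {
  ors <- vapply(1:15, function(i) {
    d <- simulate_cohort(make_scenario("null", seed = 100 + i,
                                       n_families = 600))
    exp(fit_disease_association(d, model = 1)$beta)
  }, numeric(1))
  expect_equal(mean(ors), 1, tolerance = 0.05)
})

test_that("founder genotype counts pass the package HWE test in nearly all cohorts", {
  cfg <- sim_config(n_families = 5000, seed = 52,
                    family_size_probs = c("1" = 1))
  set.seed(cfg$seed)
  pass <- vapply(1:1000, function(i) {
    fam <- simulate_families(cfg)
    g <- fam$genotype_code[fam$founder]
    hwe_test(genotype_counts(g))$p_value > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.98)
})

test_that("scenario library encodes the intended generating parameters", {
  pl <- make_scenario("paper_like", seed = 1)
  expect_equal(pl$theta_direct, 0.154)
  expect_equal(pl$n_families, 2885L)
  expect_equal(pl$risk_allele_freq, 0.34)
  expect_equal(pl$target_prevalence, 0.38)
  expect_equal(unname(pl$lipid_effects["TC"]), 0.049)

  nl <- make_scenario("null", seed = 1)
  expect_true(all(nl$lipid_effects == 0))
  expect_equal(nl$theta_direct, 0)

  sm <- simulation_truth(make_scenario("strong_mediation", seed = 1))
  expect_equal(sm$pm, 0.5, tolerance = 0.05)
})

test_that("simulation truth is recomputable and internally consistent", {
  cfg <- make_scenario("paper_like", seed = 3)
  t1 <- simulation_truth(cfg)
  t2 <- simulation_truth(cfg)
  expect_identical(t1[-1], t2[-1])
  expect_equal(t1$pc_true[["TC"]], 100 * (exp(0.049) - 1))
  expect_equal(t1$or_total, t1$or_direct * t1$or_indirect)
  expect_equal(t1$or_direct, exp(cfg$theta_direct))
  # raw-scale mediator slope is near mean_M * (exp(beta_g) - 1)
  expect_equal(t1$beta1_raw, 3.18 * (exp(0.049) - 1), tolerance = 0.03)

  p <- tempfile(fileext = ".json")
  write_truth(t1, p)
  j <- jsonlite::read_json(p)
  expect_equal(j$or_direct, t1$or_direct, tolerance = 1e-12)
})

test_that("configured genotype missingness propagates as NA codes", {
  cfg <- sim_config(n_families = 800, seed = 61,
                    genotype_missing_rate = 0.1)
  d <- simulate_cohort(cfg)
  miss <- mean(is.na(d$genotype_code))
  expect_gt(miss, 0.05)
  expect_lt(miss, 0.15)
  expect_true(all(d$genotype[is.na(d$genotype_code)] == "./."))
})
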