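#' Simulate family structures, genotypes and covariates
#'
#' Draws family sizes from the configured distribution and builds
#' pedigrees: singletons, two-member families (full-sib pairs with
#' ungenotyped parents, or parent-offspring pairs), and parent-parent-
#' child trios. Founder genotypes are binomial(2, `risk_allele_freq`)
#' (Hardy-Weinberg); offspring receive one allele from each parent by
#' Mendelian transmission. For sib pairs both parental genotypes are
#' drawn internally and discarded, so the sibs share transmissions but
#' carry `PID = MID = "0"` in the output (PLINK `.fam` convention:
#' `"0"` means the parent is not in the data).
#'
#' The `founder` column marks individuals whose genotype was drawn
#' directly from the population (singletons and observed parents), as
#' opposed to by transmission; Hardy-Weinberg QC is calibrated on these.
#'
#' Covariates are drawn independently from the configured marginals:
#' truncated-normal age and BMI, Bernoulli sex (1 = male, 0 = female),
#' smoking, drinking, hypertension and coronary heart disease.
#'
#' This function does not touch the RNG seed; use [simulate_cohort()]
#' for seeded end-to-end generation.
#'
#' @param config A [sim_config()].
#' @return A data.frame with one row per individual: `FID`, `IID`,
#'   `PID`, `MID`, `sex`, `age`, `BMI`, `smoker`, `drinker`,
#'   `hypertension`, `CHD`, `genotype_code`, `genotype`, `founder`.
#' @export
simulate_families <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$risk_allele_freq
  nf <- config$n_families
  sizes <- as.integer(names(config$family_size_probs))
  fam_size <- sizes[sample.int(length(sizes), nf, replace = TRUE,
                               prob = config$family_size_probs)]

  fam_type <- character(nf)
  fam_type[fam_size == 1L] <- "S"
  fam_type[fam_size == 3L] <- "TRIO"
  i2 <- which(fam_size == 2L)
  if (length(i2)) {
    fam_type[i2] <- switch(
      config$size2_structure,
      sibpair = "SIB",
      parent_offspring = "PO",
      mix = ifelse(stats::runif(length(i2)) < 0.5, "SIB", "PO"))
  }

  transmit <- function(g_parent) stats::rbinom(length(g_parent), 1L, g_parent / 2)

  blocks <- list()

  iS <- which(fam_type == "S")
  if (length(iS)) {
    blocks$S <- data.frame(
      FID = iS, member = 1L, PIDm = 0L, MIDm = 0L,
      genotype_code = stats::rbinom(length(iS), 2L, p),
      sex = NA_integer_, founder = TRUE)
  }

  iSIB <- which(fam_type == "SIB")
  if (length(iSIB)) {
    gf <- stats::rbinom(length(iSIB), 2L, p)
    gm <- stats::rbinom(length(iSIB), 2L, p)
    sib <- function(memb) data.frame(
      FID = iSIB, member = memb, PIDm = 0L, MIDm = 0L,
      genotype_code = transmit(gf) + transmit(gm),
      sex = NA_integer_, founder = FALSE)
    blocks$SIB1 <- sib(1L)
    blocks$SIB2 <- sib(2L)
  }

  iPO <- which(fam_type == "PO")
  if (length(iPO)) {
    gp <- stats::rbinom(length(iPO), 2L, p)        # observed parent
    gh <- stats::rbinom(length(iPO), 2L, p)        # ungenotyped co-parent
    sex_parent <- stats::rbinom(length(iPO), 1L, config$covariate_dist$sex_p)
    blocks$PO_parent <- data.frame(
      FID = iPO, member = 1L, PIDm = 0L, MIDm = 0L,
      genotype_code = gp, sex = sex_parent, founder = TRUE)
    blocks$PO_child <- data.frame(
      FID = iPO, member = 2L,
      PIDm = ifelse(sex_parent == 1L, 1L, 0L),
      MIDm = ifelse(sex_parent == 1L, 0L, 1L),
      genotype_code = transmit(gp) + transmit(gh),
      sex = NA_integer_, founder = FALSE)
  }

  iT <- which(fam_type == "TRIO")
  if (length(iT)) {
    gf <- stats::rbinom(length(iT), 2L, p)
    gm <- stats::rbinom(length(iT), 2L, p)
    blocks$T_father <- data.frame(
      FID = iT, member = 1L, PIDm = 0L, MIDm = 0L,
      genotype_code = gf, sex = 1L, founder = TRUE)
    blocks$T_mother <- data.frame(
      FID = iT, member = 2L, PIDm = 0L, MIDm = 0L,
      genotype_code = gm, sex = 0L, founder = TRUE)
    blocks$T_child <- data.frame(
      FID = iT, member = 3L, PIDm = 1L, MIDm = 2L,
      genotype_code = transmit(gf) + transmit(gm),
      sex = NA_integer_, founder = FALSE)
  }

  d <- do.call(rbind, blocks)
  d <- d[order(d$FID, d$member), , drop = FALSE]
  rownames(d) <- NULL
  n <- nrow(d)

  d$IID <- paste0("F", d$FID, "_", d$member)
  d$PID <- ifelse(d$PIDm > 0L, paste0("F", d$FID, "_", d$PIDm), "0")
  d$MID <- ifelse(d$MIDm > 0L, paste0("F", d$FID, "_", d$MIDm), "0")
  d$PIDm <- d$MIDm <- d$member <- NULL

  cd <- config$covariate_dist
  # fill undetermined sexes; covariates drawn independently across members
  need_sex <- is.na(d$sex)
  d$sex[need_sex] <- stats::rbinom(sum(need_sex), 1L, cd$sex_p)
  d$age <- .rtrunc_norm(n, cd$age_mean, cd$age_sd, cd$age_min)
  d$BMI <- .rtrunc_norm(n, cd$bmi_mean, cd$bmi_sd, cd$bmi_min)
  d$smoker <- stats::rbinom(n, 1L, cd$smoker_p)
  d$drinker <- stats::rbinom(n, 1L, cd$drinker_p)
  d$hypertension <- stats::rbinom(n, 1L, cd$hypertension_p)
  d$CHD <- stats::rbinom(n, 1L, cd$chd_p)

  d$genotype <- c("A/A", "A/C", "C/C")[d$genotype_code + 1L]
  if (config$genotype_missing_rate > 0) {
    drop <- stats::runif(n) < config$genotype_missing_rate
    d$genotype_code[drop] <- NA_integer_
    d$genotype[drop] <- "./."
  }

  d$FID <- paste0("F", d$FID)
  d[, c("FID", "IID", "PID", "MID", "sex", "age", "BMI", "smoker",
        "drinker", "hypertension", "CHD", "genotype_code", "genotype",
        "founder")]
}

# inverse-CDF sampler for Normal(mu, sd) truncated below at lo
.rtrunc_norm <- function(n, mu, sd, lo) {
  p_lo <- stats::pnorm(lo, mu, sd)
  stats::qnorm(p_lo + stats::runif(n) * (1 - p_lo), mu, sd)
}

#' Fill in lipid phenotypes and disease status
#'
#' Generates the six log-normal lipid traits (genotype effect + covariate
#' effects + shared family random intercept + residual noise on the log
#' scale, returned in mmol/L) and Bernoulli disease status from the
#' logistic model with a direct genotype effect and the designated lipid
#' mediator. When `baseline_logit` is not fixed in the config, the
#' intercept is calibrated by root-finding on this cohort's realized
#' linear predictors so the expected prevalence equals the target.
#'
#' This function does not touch the RNG seed; use [simulate_cohort()]
#' for seeded end-to-end generation.
#'
#' @param records Output of [simulate_families()].
#' @param config The same [sim_config()].
#' @return `records` with the six lipid columns and `T2DM` appended.
#'   Attributes: `realized_prevalence`, `baseline_logit`.
#' @export
simulate_phenotypes <- function(records, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(c("genotype_code", "FID") %in% names(records))) {
    stop("records must come from simulate_families()")
  }
  n <- nrow(records)
  g <- records$genotype_code
  g_fit <- ifelse(is.na(g), 0L, g)  # missing genotypes carry no effect

  fids <- unique(records$FID)
  u_fam <- stats::rnorm(length(fids), 0, config$family_sd)
  u <- u_fam[match(records$FID, fids)]

  cm_names <- c("age", "sex", "BMI", "smoker", "drinker", "hypertension", "CHD")
  X <- as.matrix(records[, cm_names])

  for (lipid in lipid_names()) {
    ce <- .lipid_cov_effects(config, lipid)
    eta <- .lipid_intercept(config, lipid) +
      config$lipid_effects[[lipid]] * g_fit +
      as.numeric(X[, names(ce), drop = FALSE] %*% ce) +
      u +
      stats::rnorm(n, 0, config$residual_sd[[lipid]])
    records[[lipid]] <- exp(eta)
  }

  ced <- config$covariate_effects$disease
  lp <- config$theta_direct * g_fit +
    config$theta_mediator * records[[config$mediator]] +
    as.numeric(X[, names(ced), drop = FALSE] %*% ced)

  b0 <- config$baseline_logit
  if (is.null(b0)) {
    b0 <- stats::uniroot(
      function(b) mean(stats::plogis(b + lp)) - config$target_prevalence,
      interval = c(-50, 50), tol = 1e-10)$root
  }
  records$T2DM <- stats::rbinom(n, 1L, stats::plogis(b0 + lp))

  attr(records, "realized_prevalence") <- mean(records$T2DM)
  attr(records, "baseline_logit") <- b0
  records
}

#' Simulate a complete, reproducible family cohort
#'
#' Seeds the RNG from `config$seed` and runs [simulate_families()] then
#' [simulate_phenotypes()]. The same config therefore always yields a
#' bit-identical cohort.
#'
#' @param config A [sim_config()] or a scenario name accepted by
#'   [make_scenario()] (in which case `seed` must be given).
#' @param seed Seed used only when `config` is a scenario name.
#' @return Cohort data.frame (see [simulate_families()] and
#'   [simulate_phenotypes()] for columns and attributes).
#' @export
#' @examples
#' cohort <- simulate_cohort(make_scenario("null", seed = 7, n_families = 40))
#' nrow(cohort)
simulate_cohort <- function(config, seed = NULL) {
  if (is.character(config)) {
    config <- make_scenario(config, seed = seed)
  }
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  simulate_phenotypes(simulate_families(config), config)
}

#' Write / read a cohort TSV
#'
#' Plain tab-separated text with the PLINK-style family columns first
#' (`PID`/`MID` are `"0"` for individuals whose parents are not in the
#' data). Writing then reading round-trips the analysis columns.
#'
#' @param data Cohort data.frame.
#' @param path Output file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the cohort data.frame.
#' @export
write_cohort <- function(data, path) {
  cols <- c("FID", "IID", "PID", "MID", "sex", "age", "genotype_code",
            "genotype", lipid_names(), "T2DM", "BMI", "smoker", "drinker",
            "hypertension", "CHD")
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  utils::write.table(data[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = list(FID = "character",
                                           IID = "character",
                                           PID = "character",
                                           MID = "character"))
  required <- c("FID", "IID", "genotype_code", lipid_names(), "T2DM")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    stop("cohort file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  d
}

#' Write the simulation truth as JSON
#'
#' Serialises a [simulation_truth()] object (generating parameters plus
#' the implied true effects) to a JSON sidecar so any analysis run on the
#' cohort can be checked against its generating model.
#'
#' @param truth A `simulation_truth` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  payload <- list(
    config = unclass(truth$config),
    pc_true = as.list(truth$pc_true),
    beta1_raw = truth$beta1_raw,
    or_direct = truth$or_direct,
    or_indirect = truth$or_indirect,
    or_total = truth$or_total,
    total_log_or = truth$total_log_or,
    pm = truth$pm)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}
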