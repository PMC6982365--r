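#' Descriptive baseline table by disease status
#'
#' Builds the classical "Table 1": mean and SD per group for continuous
#' variables, percentages for categorical variables, the genotype
#' distribution, and a comparison P value per row. By default groups are
#' compared with unpaired tests (Welch t-test; Pearson chi-square
#' without continuity correction). When a within-family case-control
#' `pairing` is supplied, the paired t-test and McNemar's chi-square
#' test (without continuity correction) are used instead.
#'
#' @param data Cohort data.frame with a binary `T2DM` column.
#' @param pairing Optional data.frame with columns `case` and `control`
#'   holding `IID`s of one-to-one matched pairs.
#' @param continuous,categorical Variable sets; defaults cover age, BMI,
#'   the six lipids, sex and the binary risk factors.
#' @return A data.frame of class `descriptive_table` with columns
#'   `variable`, `level`, `cases`, `controls`, `test`, `p_value`, and
#'   attributes `n_cases`, `n_controls`.
#' @export
descriptive_table <- function(data, pairing = NULL,
                              continuous = c("age", "BMI", lipid_names()),
                              categorical = c("sex", "drinker", "smoker",
                                              "hypertension", "CHD")) {
  if (!"T2DM" %in% names(data)) stop("data lacks a T2DM column")
  cases <- data[data$T2DM == 1, , drop = FALSE]
  controls <- data[data$T2DM == 0, , drop = FALSE]
  if (nrow(cases) == 0L || nrow(controls) == 0L) {
    stop("need both cases and controls for a descriptive table")
  }

  paired <- !is.null(pairing)
  if (paired) {
    stopifnot(all(c("case", "control") %in% names(pairing)))
    i_case <- match(pairing$case, data$IID)
    i_ctrl <- match(pairing$control, data$IID)
    ok <- !is.na(i_case) & !is.na(i_ctrl)
    if (!any(ok)) {
      warning("pairing requested but no valid pairs found; ",
              "falling back to unpaired tests")
      paired <- FALSE
    } else {
      i_case <- i_case[ok]
      i_ctrl <- i_ctrl[ok]
    }
  }

  rows <- list()
  add_row <- function(variable, level, cases, controls, test, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, level = level, cases = cases, controls = controls,
      test = test, p_value = p, stringsAsFactors = FALSE)
  }

  msd <- function(x) sprintf("%.2f ± %.2f", mean(x, na.rm = TRUE),
                             stats::sd(x, na.rm = TRUE))
  for (v in continuous) {
    if (paired) {
      x <- data[[v]][i_case]
      y <- data[[v]][i_ctrl]
      keep <- !is.na(x) & !is.na(y)
      p <- if (sum(keep) > 1) stats::t.test(x[keep], y[keep],
                                            paired = TRUE)$p.value else NA_real_
      test <- "paired t"
    } else {
      p <- stats::t.test(cases[[v]], controls[[v]])$p.value
      test <- "t"
    }
    add_row(v, "", msd(cases[[v]]), msd(controls[[v]]), test, p)
  }

  pct <- function(x) sprintf("%.1f%%", 100 * mean(x == 1, na.rm = TRUE))
  for (v in categorical) {
    if (paired) {
      x <- data[[v]][i_case]
      y <- data[[v]][i_ctrl]
      keep <- !is.na(x) & !is.na(y)
      tab <- table(factor(x[keep], levels = 0:1),
                   factor(y[keep], levels = 0:1))
      p <- tryCatch(stats::mcnemar.test(tab, correct = FALSE)$p.value,
                    error = function(e) NA_real_)
      test <- "McNemar"
    } else {
      tab <- table(data$T2DM, data[[v]])
      p <- tryCatch(
        stats::chisq.test(tab, correct = FALSE)$p.value,
        warning = function(w) suppressWarnings(
          stats::chisq.test(tab, correct = FALSE)$p.value))
      test <- "chi-square"
    }
    add_row(v, "", pct(cases[[v]]), pct(controls[[v]]), test, p)
  }

  if ("genotype_code" %in% names(data)) {
    gtab <- table(factor(data$T2DM, levels = 0:1),
                  factor(data$genotype_code, levels = 0:2))
    p_g <- tryCatch(
      stats::chisq.test(gtab, correct = FALSE)$p.value,
      warning = function(w) suppressWarnings(
        stats::chisq.test(gtab, correct = FALSE)$p.value))
    for (gg in 0:2) {
      add_row("risk-allele count", as.character(gg),
              sprintf("%.1f%%", 100 * mean(cases$genotype_code == gg,
                                           na.rm = TRUE)),
              sprintf("%.1f%%", 100 * mean(controls$genotype_code == gg,
                                           na.rm = TRUE)),
              "chi-square", p_g)
    }
  }

  out <- do.call(rbind, rows)
  attr(out, "n_cases") <- nrow(cases)
  attr(out, "n_controls") <- nrow(controls)
  attr(out, "paired") <- paired
  class(out) <- c("descriptive_table", "data.frame")
  out
}

#' @export
print.descriptive_table <- function(x, ...) {
  cat(sprintf("Baseline characteristics: %d cases, %d controls (%s tests)\n",
              attr(x, "n_cases"), attr(x, "n_controls"),
              if (isTRUE(attr(x, "paired"))) "paired" else "unpaired"))
  df <- as.data.frame(x)
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Assemble a pipeline configuration
#'
#' @param scenario Simulation scenario name for [make_scenario()], or
#'   `NULL` when `input` (or `sim`) is given.
#' @param input Optional path to an existing cohort TSV
#'   ([read_cohort()]).
#' @param sim Optional explicit [sim_config()] (overrides `scenario`).
#' @param seed Integer seed for every stochastic stage (mandatory).
#' @param out_dir Output directory for the report bundle.
#' @param risk_allele Risk allele used to (re)code genotypes when the
#'   additive code is absent from the input.
#' @param covariates Model-1 adjustment set.
#' @param model2_lipids Lipids added in disease Model 2.
#' @param bmi_cutoff BMI cutpoint for subgroup analysis.
#' @param mediators Lipids to run the mediation decomposition on.
#' @param n_boot Bootstrap replicates per mediator.
#' @param n_families Family count when simulating a scenario.
#' @param robust `"none"` or `"family"` standard errors for the
#'   association models.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = "paper_like", input = NULL, sim = NULL,
                            seed, out_dir = tempfile("pleiomed_run_"),
                            risk_allele = "C",
                            covariates = adjustment_defaults(),
                            model2_lipids = c("TC", "TG", "LDL_C", "HDL_C"),
                            bmi_cutoff = 24,
                            mediators = lipid_names(),
                            n_boot = 500,
                            n_families = 2885,
                            robust = c("none", "family")) {
  if (missing(seed)) stop("pipeline_config() requires an explicit seed")
  robust <- match.arg(robust)
  structure(
    list(scenario = scenario, input = input, sim = sim,
         seed = as.integer(seed), out_dir = out_dir,
         risk_allele = risk_allele, covariates = covariates,
         model2_lipids = model2_lipids, bmi_cutoff = bmi_cutoff,
         mediators = mediators, n_boot = n_boot,
         n_families = as.integer(n_families), robust = robust),
    class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Convenience wrapper mapping a YAML document's fields onto
#' [pipeline_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configurations")
  }
  args <- yaml::read_yaml(path)
  do.call(pipeline_config, args)
}

#' Run the full pleiotropy/mediation analysis pipeline
#'
#' End-to-end orchestration: data acquisition (simulation or TSV input),
#' genotype QC (call rate, allele frequency, Hardy-Weinberg on the
#' pooled sample and on controls), the descriptive table, the six
#' genotype-lipid associations, disease Models 1 and 2, the six
#' lipid-to-disease models, subgroup analyses of the disease model, and
#' the bootstrap mediation decomposition for each configured mediator.
#' Results are written as TSV (human precision: beta to 3 decimals,
#' PC/OR to 2, PM to 1) plus a full-precision JSON report and a run log.
#' A stage failure aborts with the stage name; outputs written before
#' the failure are retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the report bundle: list with `data`, `qc`,
#'   `descriptives`, `associations`, `lipid_to_disease`, `subgroups`,
#'   `mediation`, `truth` (when simulated), `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  log_msg <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    writeLines(log_lines, log_path)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_msg("FAILED at stage '", name, "': ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  log_msg("pleiomed pipeline, seed ", config$seed)
  set.seed(config$seed)

  truth <- NULL
  data <- stage("data", {
    if (!is.null(config$input)) {
      log_msg("reading cohort from ", config$input)
      read_cohort(config$input)
    } else {
      sim <- config$sim
      if (is.null(sim)) {
        sim <- make_scenario(config$scenario, seed = config$seed,
                             n_families = config$n_families)
      }
      truth <- simulation_truth(sim)
      log_msg("simulating scenario '",
              if (is.null(config$sim)) config$scenario else "custom",
              "' with ", sim$n_families, " families")
      simulate_cohort(sim)
    }
  })
  log_msg("cohort: ", nrow(data), " individuals, ",
          length(unique(data$FID)), " families, prevalence ",
          sprintf("%.4f", mean(data$T2DM)))

  qc <- stage("qc", {
    if (!"genotype_code" %in% names(data)) {
      data$genotype_code <- code_additive(data$genotype, config$risk_allele)
    }
    cr <- call_rate(data$genotype_code)
    counts_all <- genotype_counts(data$genotype_code)
    counts_ctrl <- genotype_counts(data$genotype_code[data$T2DM == 0])
    hwe_all <- hwe_test(counts_all)
    hwe_ctrl <- hwe_test(counts_ctrl)
    hwe_founders <- if ("founder" %in% names(data)) {
      hwe_test(genotype_counts(data$genotype_code[data$founder]))
    } else {
      NULL
    }
    log_msg(sprintf("QC: call rate %.4f; allele freq %.4f; HWE P (pooled) %.4g; HWE P (controls) %.4g",
                    cr$call_rate, hwe_all$allele_freq, hwe_all$p_value,
                    hwe_ctrl$p_value))
    list(call_rate = cr, counts = counts_all,
         hwe_pooled = hwe_all, hwe_controls = hwe_ctrl,
         hwe_founders = hwe_founders)
  })

  descr <- stage("descriptives", descriptive_table(data))
  utils::write.table(as.data.frame(descr),
                     file.path(config$out_dir, "descriptives.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_msg("descriptives written (", nrow(descr), " rows)")

  assoc <- stage("associations", {
    res <- lapply(lipid_names(), function(l) {
      fit_lipid_association(data, l, covariates = config$covariates,
                            robust = config$robust)
    })
    m1 <- fit_disease_association(data, model = 1,
                                  covariates = config$covariates,
                                  robust = config$robust)
    m2 <- fit_disease_association(data, model = 2,
                                  covariates = config$covariates,
                                  robust = config$robust)
    c(res, list(m1, m2))
  })
  assoc_df <- do.call(rbind, lapply(assoc, as.data.frame))
  log_msg("associations: ", nrow(assoc_df), " rows (6 lipids + 2 disease models)")

  l2d <- stage("lipid_to_disease", {
    lapply(lipid_names(), function(l) {
      fit_lipid_to_disease(data, l, covariates = config$covariates,
                           robust = config$robust)
    })
  })
  l2d_df <- do.call(rbind, lapply(l2d, as.data.frame))

  assoc_out <- rbind(assoc_df, l2d_df)
  tsv <- assoc_out
  tsv$beta <- sprintf("%.3f", tsv$beta)
  tsv$se <- sprintf("%.3f", tsv$se)
  for (cn in c("pc", "ci_low", "ci_high")) tsv[[cn]] <- sprintf("%.2f", tsv[[cn]])
  utils::write.table(tsv, file.path(config$out_dir, "associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  subgroups <- stage("subgroups", {
    out <- list()
    for (s in c("bmi", "smoker", "drinker")) {
      out[[s]] <- subgroup_analysis(data, stratifier = s,
                                    fit = fit_disease_association,
                                    model = 1,
                                    covariates = config$covariates,
                                    bmi_cutoff = config$bmi_cutoff)
    }
    out
  })
  sub_df <- do.call(rbind, lapply(names(subgroups), function(s) {
    do.call(rbind, lapply(names(subgroups[[s]]), function(lev) {
      d <- as.data.frame(subgroups[[s]][[lev]])
      cbind(stratifier = s, stratum = lev, d)
    }))
  }))
  utils::write.table(sub_df, file.path(config$out_dir, "subgroups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_msg("subgroups: ", nrow(sub_df), " stratum fits")

  mediation <- stage("mediation", {
    out <- list()
    for (i in seq_along(config$mediators)) {
      m <- config$mediators[[i]]
      out[[m]] <- bootstrap_mediation(
        data, mediator = m, covariates = config$covariates,
        n_boot = config$n_boot, seed = config$seed + 1000L + i)
      log_msg(sprintf("mediation %s: OR_d %.4f, OR_i %.4f, PM %s (%d boot)",
                      m, out[[m]]$or_direct, out[[m]]$or_indirect,
                      ifelse(is.na(out[[m]]$pm), "NA",
                             sprintf("%.3f", out[[m]]$pm)),
                      config$n_boot))
    }
    out
  })
  med_df <- do.call(rbind, lapply(mediation, function(x) {
    data.frame(mediator = x$mediator,
               or_direct = x$or_direct,
               ci_d_low = x$ci_direct[1], ci_d_high = x$ci_direct[2],
               or_indirect = x$or_indirect,
               ci_i_low = x$ci_indirect[1], ci_i_high = x$ci_indirect[2],
               or_total = x$or_total,
               ci_t_low = x$ci_total[1], ci_t_high = x$ci_total[2],
               pm_pct = 100 * x$pm,
               ci_pm_low_pct = 100 * x$ci_pm[1],
               ci_pm_high_pct = 100 * x$ci_pm[2],
               n_used = x$n_used, n_boot = x$n_boot,
               stringsAsFactors = FALSE)
  }))
  med_tsv <- med_df
  for (cn in grep("^or_|^ci_[dit]", names(med_tsv), value = TRUE)) {
    med_tsv[[cn]] <- sprintf("%.2f", med_tsv[[cn]])
  }
  for (cn in grep("pm", names(med_tsv), value = TRUE)) {
    med_tsv[[cn]] <- sprintf("%.1f", as.numeric(med_tsv[[cn]]))
  }
  utils::write.table(med_tsv, file.path(config$out_dir, "mediation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  report <- list(
    seed = config$seed,
    n_individuals = nrow(data),
    n_families = length(unique(data$FID)),
    prevalence = mean(data$T2DM),
    qc = list(call_rate = qc$call_rate$call_rate,
              allele_freq = qc$hwe_pooled$allele_freq,
              hwe_p_pooled = qc$hwe_pooled$p_value,
              hwe_p_controls = qc$hwe_controls$p_value,
              hwe_p_founders = if (!is.null(qc$hwe_founders))
                qc$hwe_founders$p_value else NULL),
    descriptives = as.data.frame(descr),
    associations = assoc_out,
    subgroups = sub_df,
    mediation = med_df,
    truth = if (!is.null(truth)) {
      list(pc_true = as.list(truth$pc_true), beta1_raw = truth$beta1_raw,
           or_direct = truth$or_direct, or_indirect = truth$or_indirect,
           or_total = truth$or_total, pm = truth$pm)
    } else NULL)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null", pretty = TRUE)
  log_msg("report.json written")

  invisible(list(data = data, qc = qc, descriptives = descr,
                 associations = assoc, lipid_to_disease = l2d,
                 subgroups = subgroups, mediation = mediation,
                 truth = truth,
                 files = file.path(config$out_dir,
                                   c("descriptives.tsv", "associations.tsv",
                                     "subgroups.tsv", "mediation.tsv",
                                     "report.json", "run.log"))))
}
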