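#' Code a biallelic genotype additively as the risk-allele count
#'
#' Converts allele-pair strings such as `"A/C"` into the 0/1/2 additive
#' dosage of the designated risk allele. Coding is symmetric in allele
#' order (`"A/C"` and `"C/A"` both count one risk allele). Missing
#' genotypes (`NA`, `""`, `"0/0"`, `"./."`) are returned as `NA` so they
#' drop out of downstream complete-case fits.
#'
#' @param genotype Character vector of slash-separated allele pairs.
#' @param risk_allele Single character, the allele whose copies are counted.
#' @param sep Allele separator inside the genotype string (default `"/"`).
#' @return Integer vector of risk-allele counts (0, 1, 2) with `NA` for
#'   missing calls.
#' @export
#' @examples
#' code_additive(c("A/A", "A/C", "C/C", "C/A"), risk_allele = "C")
code_additive <- function(genotype, risk_allele, sep = "/") {
  stopifnot(is.character(risk_allele), length(risk_allele) == 1L,
            nchar(risk_allele) == 1L)
  genotype <- as.character(genotype)
  missing_tokens <- c("", "0/0", "./.", "N/N")
  is_missing <- is.na(genotype) | genotype %in% missing_tokens
  out <- rep(NA_integer_, length(genotype))
  if (all(is_missing)) {
    return(out)
  }
  parts <- strsplit(genotype[!is_missing], sep, fixed = TRUE)
  bad_pair <- vapply(parts, length, integer(1)) != 2L
  if (any(bad_pair)) {
    stop("malformed genotype string(s): ",
         paste(unique(genotype[!is_missing][bad_pair]), collapse = ", "))
  }
  alleles <- unlist(parts, use.names = FALSE)
  alphabet <- unique(alleles)
  if (length(alphabet) > 2L) {
    stop("more than two alleles observed (", paste(alphabet, collapse = ", "),
         "): the SNP must be biallelic")
  }
  if (!(risk_allele %in% alphabet) && length(alphabet) == 2L) {
    stop("risk allele '", risk_allele, "' not in the SNP's alphabet (",
         paste(alphabet, collapse = ", "), ")")
  }
  counts <- vapply(parts, function(p) sum(p == risk_allele), integer(1))
  out[!is_missing] <- counts
  out
}

#' Tally additive genotype codes
#'
#' @param code Integer vector of 0/1/2 additive genotype codes (`NA`
#'   allowed and dropped).
#' @return An object of class `genotype_counts`: a named integer vector
#'   with elements `n_0`, `n_1`, `n_2`.
#' @export
#' @examples
#' genotype_counts(c(0, 1, 1, 2, NA))
genotype_counts <- function(code) {
  code <- code[!is.na(code)]
  if (!all(code %in% 0:2)) {
    stop("genotype codes must be 0, 1 or 2")
  }
  out <- c(n_0 = sum(code == 0L), n_1 = sum(code == 1L), n_2 = sum(code == 2L))
  structure(as.integer(out), names = names(out), class = "genotype_counts")
}

# coerce a plain length-3 vector (n0, n1, n2) when convenient
as_genotype_counts <- function(x) {
  if (inherits(x, "genotype_counts")) return(x)
  x <- as.integer(x)
  if (length(x) != 3L || any(x < 0)) {
    stop("genotype counts must be three nonnegative integers (n_0, n_1, n_2)")
  }
  structure(x, names = c("n_0", "n_1", "n_2"), class = "genotype_counts")
}

#' Risk-allele frequency from genotype counts
#'
#' @param counts A `genotype_counts` object or a length-3 vector
#'   `(n_0, n_1, n_2)` of additive-code tallies.
#' @return Risk-allele frequency in `[0, 1]`.
#' @export
#' @examples
#' allele_freq(c(10, 10, 10))
allele_freq <- function(counts) {
  counts <- as_genotype_counts(counts)
  n <- sum(counts)
  if (n == 0L) {
    stop("cannot compute an allele frequency from zero individuals")
  }
  (counts[["n_1"]] + 2 * counts[["n_2"]]) / (2 * n)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson chi-square comparison of observed genotype counts against the
#' Hardy-Weinberg expectation \eqn{(q^2 N, 2pqN, p^2 N)} where \eqn{p} is
#' the risk-allele frequency estimated from the same counts, on 1 degree
#' of freedom and without continuity correction. A monomorphic SNP has no
#' defined test and raises an error rather than reporting chi-square 0.
#'
#' @param counts A `genotype_counts` object or a length-3 vector
#'   `(n_0, n_1, n_2)`.
#' @return An object of class `hwe_result`: list with `chi2`, `df`,
#'   `p_value`, `allele_freq`, `n`, and the observed/expected counts.
#' @export
#' @examples
#' hwe_test(c(25, 50, 25))  # exact HWE proportions: chi2 = 0
#' hwe_test(c(10, 10, 10))
hwe_test <- function(counts) {
  counts <- as_genotype_counts(counts)
  n <- sum(counts)
  if (n == 0L) {
    stop("cannot test HWE on zero individuals")
  }
  p <- allele_freq(counts)
  if (p <= 0 || p >= 1) {
    stop("HWE test undefined for a monomorphic SNP (allele frequency ",
         format(p), ")")
  }
  q <- 1 - p
  expected <- c(q^2, 2 * p * q, p^2) * n
  chi2 <- sum((as.numeric(counts) - expected)^2 / expected)
  structure(
    list(chi2 = chi2,
         df = 1L,
         p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
         allele_freq = p,
         n = n,
         observed = as.integer(counts),
         expected = expected),
    class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat("Hardy-Weinberg equilibrium test (1 df, no continuity correction)\n")
  cat(sprintf("  N = %d, risk-allele frequency = %.4f\n", x$n, x$allele_freq))
  cat(sprintf("  observed: %s   expected: %s\n",
              paste(x$observed, collapse = "/"),
              paste(sprintf("%.1f", x$expected), collapse = "/")))
  cat(sprintf("  chi-square = %.4f, P = %.4g\n", x$chi2, x$p_value))
  invisible(x)
}

#' Genotype call-rate check
#'
#' Fraction of non-missing genotype calls, compared against a minimum
#' acceptable call rate (default 0.95, the usual genotyping QC cutoff).
#'
#' @param genotype Vector of genotype strings or additive codes; `NA`
#'   counts as a missing call.
#' @param min_rate Minimum acceptable call rate.
#' @return List with `call_rate`, `n_called`, `n_total`, and logical `pass`.
#' @export
call_rate <- function(genotype, min_rate = 0.95) {
  stopifnot(min_rate >= 0, min_rate <= 1)
  n_total <- length(genotype)
  if (n_total == 0L) stop("no genotype calls supplied")
  missing_tokens <- c("", "0/0", "./.", "N/N")
  n_called <- sum(!(is.na(genotype) | as.character(genotype) %in% missing_tokens))
  rate <- n_called / n_total
  list(call_rate = rate, n_called = n_called, n_total = n_total,
       pass = rate >= min_rate)
}
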