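# Independent brute-force oracles used to freeze expected values.

# Exact correlation of two full sibs' additive genotype codes under
# random mating at risk-allele frequency p, by enumeration of the nine
# parental genotype pairs and their Mendelian transmissions.
sib_genotype_correlation <- function(p) {
  q <- 1 - p
  pg <- c(q^2, 2 * p * q, p^2)              # HWE parent genotype probs
  g <- 0:2
  e_s <- 0; e_s2 <- 0; e_s1s2 <- 0
  for (i in 1:3) {
    for (j in 1:3) {
      w <- pg[i] * pg[j]
      tf <- g[i] / 2                        # P(transmit risk allele)
      tm <- g[j] / 2
      # child code = Bern(tf) + Bern(tm); sibs iid given parents
      mu <- tf + tm
      v <- tf * (1 - tf) + tm * (1 - tm)
      e_s <- e_s + w * mu
      e_s2 <- e_s2 + w * (v + mu^2)
      e_s1s2 <- e_s1s2 + w * mu^2
    }
  }
  (e_s1s2 - e_s^2) / (e_s2 - e_s^2)
}

# Hand-computed HWE chi-square for counts (10, 10, 10):
# p = 0.5, expected (7.5, 15, 7.5), chi2 = 2*(2.5^2/7.5) + 5^2/15 = 10/3.
hwe_101010_chi2 <- 10 / 3

# a small cohort for structural tests
tiny_cohort <- function(seed = 11, n_families = 150,
                        scenario = "paper_like") {
  simulate_cohort(make_scenario(scenario, seed = seed,
                                n_families = n_families))
}
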